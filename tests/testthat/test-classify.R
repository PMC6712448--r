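test_that("spectrum counts and fractions follow the pyrimidine classes", {
  # 10 C->A substitutions observed on both strands collapse to one class
  v <- rbind(make_variants(5, ref = "C", alt = "A"),
             make_variants(5, ref = "G", alt = "T"))
  sp <- compute_spectrum(v)
  expect_equal(unname(sp$counts[["C>A"]]), 10)
  expect_equal(unname(sp$fractions[["C>A"]]), 1.0)
  expect_equal(sum(sp$fractions), 1.0)

  v2 <- rbind(make_variants(25, ref = "C", alt = "A"),
              make_variants(2, ref = "C", alt = "G"),
              make_variants(73, ref = "C", alt = "T"))
  sp2 <- compute_spectrum(v2)
  expect_equal(unname(sp2$fractions[c("C>A", "C>G", "C>T")]),
               c(0.25, 0.02, 0.73))

  sp0 <- compute_spectrum(make_variant()[0, ])
  expect_true(all(sp0$counts == 0))
  expect_true(all(is.nan(sp0$fractions)))
})

test_that("non-SNV records are ignored and reported", {
  v <- rbind(make_variant(ref = "C", alt = "A"),
             make_variant(ref = "CT", alt = "C"),   # deletion
             make_variant(ref = "A", alt = "AGG"))  # insertion
  sp <- compute_spectrum(v)
  expect_equal(sp$total, 1)
  expect_equal(sp$n_ignored, 2)
})

test_that("the spectrum is invariant under strand complementation", {
  set.seed(21)
  bases <- c("A", "C", "G", "T")
  for (rep_i in 1:5) {
    n <- 200
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    v <- make_variants(n)
    v$ref <- ref; v$alt <- alt
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    v2 <- v
    v2$ref <- unname(comp[ref]); v2$alt <- unname(comp[alt])
    expect_equal(compute_spectrum(v)$counts, compute_spectrum(v2)$counts)
  }
})

test_that("classification thresholds are strict inequalities", {
  pole_like <- make_spectrum(0.45, 0.01)
  expect_equal(classify_tumor(9515, pole_like), "pole_category")
  expect_equal(classify_tumor(500, pole_like), "nonhypermutator")
  expect_equal(classify_tumor(501, make_spectrum(0.25, 0.03)),
               "common_hypermutator")  # C>G exactly 3% is not POLE
  expect_equal(classify_tumor(501, make_spectrum(0.20, 0.01)),
               "common_hypermutator")  # C>A exactly 20% is not POLE
  expect_equal(classify_tumor(501, make_spectrum(0.2000001, 0.0299999)),
               "pole_category")
  expect_equal(classify_tumor(1041, make_spectrum(0.10, 0.05)),
               "common_hypermutator")
  expect_error(classify_tumor(-1, pole_like), "nonnegative")
})

test_that("crossing the C>G boundary moves a hypermutator between the two
           hypermutator classes only", {
  for (cg in c(0.001, 0.01, 0.029, 0.03, 0.031, 0.08)) {
    lab <- classify_tumor(1200, make_spectrum(0.30, cg))
    expect_true(lab %in% c("pole_category", "common_hypermutator"))
    expect_equal(lab == "pole_category", cg < 0.03)
  }
})

test_that("mutations per megabase is count over footprint, footprint required", {
  expect_equal(mutations_per_mb(500, 50), 10)
  expect_equal(mutations_per_mb(0, 45), 0)
  expect_equal(mutations_per_mb(1050, 50), 21)
  expect_error(mutations_per_mb(100), "footprint")
  expect_error(mutations_per_mb(100, 0), "footprint")
  expect_error(mutations_per_mb(100, -3), "footprint")
})

test_that("protein-change parsing handles missense, nonsense and prefixes", {
  p <- parse_protein_change("P286R")
  expect_equal(p[c("ref_aa", "residue", "alt_aa", "mutation_type")],
               list(ref_aa = "P", residue = 286L, alt_aa = "R",
                    mutation_type = "missense"))
  q <- parse_protein_change("Q196*")
  expect_equal(q$mutation_type, "nonsense")
  expect_equal(q$alt_aa, "*")
  expect_equal(parse_protein_change("p.V411L")$residue, 411L)
  expect_error(parse_protein_change("286R"), "cannot parse")
  expect_error(parse_protein_change("B286R"), "amino-acid")
})

test_that("POLE annotation flags domain membership and hotspots", {
  ann <- annotate_pole(c("P286R", "R47W", "S297Y", "F367C", "V411L"))
  expect_equal(ann$in_exonuclease_domain, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(ann$is_hotspot, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  # boundaries of the 86-427 domain
  bound <- annotate_pole(c("A85G", "A86G", "A427G", "A428G"))
  expect_equal(bound$in_exonuclease_domain, c(FALSE, TRUE, TRUE, FALSE))
  # compound entries split into independent annotations
  comp <- annotate_pole("P1207S, V1218I")
  expect_equal(nrow(comp), 2)
  expect_equal(comp$residue, c(1207L, 1218L))
  expect_false(any(comp$in_exonuclease_domain))
})

test_that("the packaged 27-case POLE table is fully reproduced", {
  cases <- read_pole_cases()
  expect_equal(nrow(cases), 27)
  # hypermutator-ness from the count rule matches the printed class 27/27
  hyper_from_count <- cases$nonsyn_snv_count > 500
  hyper_printed <- cases$classification != "nonhypermutator"
  expect_equal(hyper_from_count, hyper_printed)
  # recomputed exonuclease-domain flag matches the printed Yes/No 27/27
  domain_recomputed <- vapply(cases$protein_change, function(pc) {
    any(annotate_pole(pc)$in_exonuclease_domain)
  }, logical(1), USE.NAMES = FALSE)
  expect_equal(domain_recomputed, cases$exonuclease_domain == "Yes")
  # mutation types agree with the parser
  types <- vapply(cases$protein_change, function(pc) {
    paste(unique(annotate_pole(pc)$mutation_type), collapse = ",")
  }, "", USE.NAMES = FALSE)
  expect_equal(types == "nonsense", cases$mutation_type == "Nonsense")
})

test_that("tumor profiles aggregate counts, spectrum and label per tumor", {
  v <- rbind(
    make_variants(30, tumor_id = "A", ref = "C", alt = "T"),
    make_variants(10, tumor_id = "A", ref = "C", alt = "T",
                  consequence = "synonymous_SNV"),
    make_variants(5, tumor_id = "B", ref = "C", alt = "A", gene = "POLE",
                  protein_change = "P286R")
  )
  prof <- build_tumor_profiles(v, footprint_mb = 40)
  expect_equal(prof$tumor_id, c("A", "B"))
  expect_equal(prof$nonsyn_snv_count, c(30, 5))
  expect_equal(prof$total_snv_count, c(40, 5))
  expect_equal(prof$frac_C.T, c(1, 0))
  expect_equal(prof$mutations_per_mb, c(1, 0.125))
  expect_equal(prof$label, c("nonhypermutator", "nonhypermutator"))
  expect_equal(prof$pole_hotspots, c("", "P286R"))

  # spectrum_set switch: nonsynonymous-only changes the denominator
  prof_ns <- build_tumor_profiles(v, footprint_mb = 40,
                                  spectrum_set = "nonsynonymous")
  expect_equal(prof_ns$nonsyn_snv_count, prof$nonsyn_snv_count)
  expect_equal(prof_ns$frac_C.A, c(0, 1))
})
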