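test_that("catalog building places SNVs in the right trinucleotide context", {
  # sequence A A C A G: position 3 has ref C, flanks A (pos 2) and A (pos 4)
  genome <- c(chr1 = "AACAG")
  v <- make_variant(chrom = "chr1", pos = 3, ref = "C", alt = "A")
  cat96 <- build_catalog(v, genome)
  expect_equal(sum(cat96), 1)
  expect_equal(unname(cat96[["A[C>A]A"]]), 1)

  # purine-reference site: G>T at a G flanked by T and G reads T G G on the
  # forward strand; on the pyrimidine strand that is C flanked by C and A
  genome2 <- c(chr1 = "ATGGA")
  v2 <- make_variant(chrom = "chr1", pos = 3, ref = "G", alt = "T")
  cat2 <- build_catalog(v2, genome2)
  expect_equal(unname(cat2[["C[C>A]A"]]), 1)

  # empty input: all zeros
  cat0 <- build_catalog(make_variant()[0, ], genome)
  expect_true(all(cat0 == 0))
})

test_that("contig-edge and mismatching sites are skipped with warning", {
  genome <- c(chr1 = "ACGTA")
  v <- rbind(
    make_variant(chrom = "chr1", pos = 1, ref = "A", alt = "G"),  # edge
    make_variant(chrom = "chr1", pos = 3, ref = "C", alt = "A"),  # ref is G
    make_variant(chrom = "chr9", pos = 3, ref = "C", alt = "A"),  # no contig
    make_variant(chrom = "chr1", pos = 2, ref = "C", alt = "T")   # usable
  )
  expect_warning(cat96 <- build_catalog(v, genome), "skipped")
  expect_equal(sum(cat96), 1)
  expect_equal(unname(cat96[["A[C>T]G"]]), 1)
})

test_that("a single-signature catalog is recovered with weight 1", {
  sigs <- synthetic_signature_matrix()
  set.seed(31)
  for (nm in sigs$names) {
    cat96 <- random_mixture_catalog(
      sigs, stats::setNames(as.numeric(sigs$names == nm), sigs$names),
      n = 1000)
    e <- refit_exposures(cat96, sigs)
    expect_equal(names(e$weights), nm)
    expect_equal(unname(e$weights), 1, tolerance = 0.02)
    expect_lt(e$reconstruction_error, 0.01)
  }
})

test_that("two-signature mixtures are recovered within 0.05", {
  sigs <- synthetic_signature_matrix()
  set.seed(32)
  w <- c(Sig.MMR = 0.3, Sig.POLE = 0.7, Sig.Flat = 0, Sig.TC = 0)
  cat96 <- random_mixture_catalog(sigs, w, n = 5000)
  e <- refit_exposures(cat96, sigs)
  expect_setequal(names(e$weights), c("Sig.MMR", "Sig.POLE"))
  expect_equal(unname(e$weights[["Sig.POLE"]]), 0.7, tolerance = 0.05)
  expect_equal(unname(e$weights[["Sig.MMR"]]), 0.3, tolerance = 0.05)
})

test_that("components below the cutoff are discarded and renormalized", {
  sigs <- synthetic_signature_matrix()
  set.seed(33)
  w <- c(Sig.MMR = 0.66, Sig.POLE = 0.30, Sig.Flat = 0, Sig.TC = 0.04)
  cat96 <- random_mixture_catalog(sigs, w, n = 20000)
  e <- refit_exposures(cat96, sigs, cutoff = 0.06)
  expect_false("Sig.TC" %in% names(e$weights))
  expect_equal(sum(e$weights), 1, tolerance = 1e-9)
  expect_equal(unname(e$weights[["Sig.MMR"]]), 0.66 / 0.96,
               tolerance = 0.05)
})

test_that("exposures are invariant to scaling the catalog", {
  sigs <- synthetic_signature_matrix()
  set.seed(34)
  cat96 <- random_mixture_catalog(
    sigs, c(Sig.MMR = 0.5, Sig.POLE = 0.5, Sig.Flat = 0, Sig.TC = 0))
  e1 <- refit_exposures(cat96, sigs)
  e7 <- refit_exposures(cat96 * 7L, sigs)
  expect_equal(e1$weights, e7$weights, tolerance = 1e-12)
  expect_equal(e1$reconstruction_error, e7$reconstruction_error,
               tolerance = 1e-12)
})

test_that("degenerate catalogs are refused", {
  sigs <- synthetic_signature_matrix()
  zeros <- stats::setNames(numeric(96), context_labels_96())
  expect_error(refit_exposures(zeros, sigs), "zero")
  sparse <- zeros; sparse[1] <- 10
  expect_error(refit_exposures(sparse, sigs), "at least 50")
  expect_error(refit_exposures(sparse, sigs, min_mutations = 5), NA)
})

test_that("forward selection matches exhaustive subset search", {
  sigs <- synthetic_signature_matrix()
  sub3 <- signature_matrix(sigs$weights[, 1:3])
  set.seed(35)
  n_match <- 0
  n_iter <- 40
  for (i in seq_len(n_iter)) {
    k <- sample(1:3, 1)
    w <- numeric(3)
    w[sample(3, k)] <- as.numeric(stats::rmultinom(1, 10, rep(1, k))) / 10
    cat96 <- random_mixture_catalog(sub3, stats::setNames(w, sub3$names),
                                    n = 3000)
    fwd <- refit_exposures(cat96, sub3)$weights
    orc <- exhaustive_refit_oracle(cat96, sub3)
    same <- setequal(names(fwd), names(orc)) &&
      max(abs(fwd[names(orc)] - orc)) < 0.02
    n_match <- n_match + same
  }
  expect_gte(n_match / n_iter, 0.95)
})

test_that("group scores carry absent signatures as zero and test two groups", {
  e_hi <- structure(list(weights = c(Sig.POLE = 0.8, Sig.MMR = 0.2),
                         reconstruction_error = 0),
                    class = "exposure_vector")
  e_lo <- structure(list(weights = c(Sig.MMR = 1),
                         reconstruction_error = 0),
                    class = "exposure_vector")
  exposures <- c(
    stats::setNames(rep(list(e_hi), 4), paste0("P", 1:4)),
    stats::setNames(rep(list(e_lo), 6), paste0("C", 1:6))
  )
  labels <- c(stats::setNames(rep("pole_category", 4), paste0("P", 1:4)),
              stats::setNames(rep("common_hypermutator", 6), paste0("C", 1:6)))
  res <- signature_score_by_group(exposures, labels, "Sig.POLE")
  expect_equal(unname(res$scores[["pole_category"]]), rep(0.8, 4))
  expect_equal(unname(res$scores[["common_hypermutator"]]), rep(0, 6))
  expect_lt(res$p_value, 0.05)

  # identical exposures across groups: p indistinguishable from 1
  same <- c(stats::setNames(rep(list(e_hi), 5), paste0("P", 1:5)),
            stats::setNames(rep(list(e_hi), 5), paste0("C", 1:5)))
  labels2 <- c(stats::setNames(rep("pole_category", 5), paste0("P", 1:5)),
               stats::setNames(rep("common_hypermutator", 5), paste0("C", 1:5)))
  res2 <- signature_score_by_group(same, labels2, "Sig.POLE")
  expect_gte(res2$p_value, 0.99)

  expect_error(signature_score_by_group(exposures, labels[-1], "Sig.POLE"),
               "no label")
})

test_that("separated exposure distributions give a significant contrast", {
  set.seed(36)
  mk <- function(w) structure(list(weights = c(Sig.POLE = w),
                                   reconstruction_error = 0),
                              class = "exposure_vector")
  pole_ids <- paste0("P", 1:10)
  other_ids <- paste0("C", 1:50)
  exposures <- c(
    stats::setNames(lapply(runif(10, 0.5, 0.9), mk), pole_ids),
    stats::setNames(lapply(runif(50, 0, 0.1), mk), other_ids)
  )
  labels <- c(stats::setNames(rep("pole_category", 10), pole_ids),
              stats::setNames(rep("common_hypermutator", 50), other_ids))
  res <- signature_score_by_group(exposures, labels, "Sig.POLE")
  expect_gt(median(res$scores$pole_category),
            median(res$scores$common_hypermutator))
  expect_lt(res$p_value, 0.05)
})
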