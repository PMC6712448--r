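# Synthetic-cohort generator: three mutational processes, clinical
# covariates and immune-gene expression with the statistical structure the
# analysis assumes, so every stage is testable without patient data.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so simulation helpers do not
#' perturb the session stream.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic reference genome for context extraction
#'
#' A small fixed random genome (two 50 kb contigs by default) generated from
#' an internal seed, so trinucleotide contexts exist for catalog building.
#' Deterministic and independent of the caller's RNG state.
#'
#' @param lengths named integer vector of contig lengths.
#' @return named character vector of contig sequences.
#' @export
synthetic_reference <- function(lengths = c(chr1 = 50000L, chr2 = 50000L)) {
  with_seed(990131, {
    vapply(lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

#' Synthetic 96x4 reference signature matrix
#'
#' Four deterministic, clearly separated signature shapes for testing and
#' simulation: a C>T-rich mismatch-repair-deficiency-like signature
#' (`Sig.MMR`), a C>A-rich proofreading-deficiency-like signature
#' (`Sig.POLE`), a flat signature (`Sig.Flat`) and a T>C-rich signature
#' (`Sig.TC`). Columns sum to 1. These are synthetic stand-ins, not COSMIC
#' signatures; refitting against real cohorts should load the user's
#' reference matrix with [read_signature_matrix()].
#'
#' @return `signature_matrix` object.
#' @export
synthetic_signature_matrix <- function() {
  ctx <- context_labels_96()
  cls <- rep(sub_classes(), each = 16)
  within_block <- rep(seq_len(16), times = 6)
  shape <- function(block_mass, peak_pos, peak_frac = 0.5) {
    # block_mass: named mass per substitution class; inside each block a
    # smooth peak at peak_pos keeps the column far from uniform
    w <- numeric(96)
    for (b in names(block_mass)) {
      idx <- which(cls == b)
      prof <- exp(-((seq_len(16) - peak_pos)^2) / 18)
      prof <- peak_frac * prof / sum(prof) + (1 - peak_frac) / 16
      w[idx] <- block_mass[[b]] * prof
    }
    w / sum(w)
  }
  w <- cbind(
    Sig.MMR = shape(c("C>T" = 0.70, "T>C" = 0.18, "C>A" = 0.04,
                      "C>G" = 0.04, "T>A" = 0.02, "T>G" = 0.02), 11),
    Sig.POLE = shape(c("C>A" = 0.55, "C>T" = 0.30, "T>G" = 0.08,
                       "C>G" = 0.01, "T>A" = 0.03, "T>C" = 0.03), 14),
    Sig.Flat = rep(1 / 96, 96),
    Sig.TC = shape(c("T>C" = 0.65, "T>A" = 0.15, "C>T" = 0.10,
                     "C>A" = 0.04, "C>G" = 0.03, "T>G" = 0.03), 4)
  )
  rownames(w) <- ctx
  signature_matrix(w)
}

#' Cohort simulation parameters
#'
#' Defaults describe a large surgical colorectal-cancer cohort: 92.6%
#' nonhypermutators (median 71 nonsynonymous SNVs), 6.3% common-
#' hypermutators (C>T-rich, counts above 500) and 1.1% POLE category tumors
#' (C>A-rich / C>G-poor ultramutators with 1,698-9,515 nonsynonymous SNVs),
#' with class-conditional clinical covariates (POLE category: younger,
#' mostly men) and immune-gene expression shifts (PD-L1/PD-1 up in both
#' hypermutator classes, CD8A up in the POLE category, CTLA-4 unshifted).
#'
#' @param n_tumors cohort size.
#' @param prevalence named class probabilities (sum to 1).
#' @param seed integer seed; the whole cohort is a pure function of the
#'   spec including this seed.
#' @param nonsyn_fraction fraction of SNVs that are nonsynonymous.
#' @param expression_coverage fraction of tumors with expression data.
#' @param expression_sd per-gene fold-change noise SD (log2 units).
#' @param qc_noise named per-criterion fractions of extra decoy variants
#'   that fail each false-positive criterion.
#' @return `cohort_spec` object (a validated list of parameters).
#' @export
cohort_spec <- function(n_tumors = 1000L,
                        prevalence = c(nonhypermutator = 0.926,
                                       common_hypermutator = 0.063,
                                       pole_category = 0.011),
                        seed = 1L,
                        nonsyn_fraction = 0.7,
                        expression_coverage = 0.98,
                        expression_sd = 1,
                        qc_noise = c(q1 = 0.02, q2 = 0.02, q3 = 0.02,
                                     q4 = 0.02, q5 = 0.02, q6 = 0.01)) {
  spec <- list(
    n_tumors = as.integer(n_tumors),
    prevalence = prevalence[TUMOR_LABELS],
    seed = as.integer(seed),
    nonsyn_fraction = nonsyn_fraction,
    expression_coverage = expression_coverage,
    expression_sd = expression_sd,
    qc_noise = qc_noise,
    # nonsynonymous SNV count distributions (log-normal, truncated so the
    # latent class always satisfies its own count rule); the
    # nonhypermutator median (65) is set so the cohort-wide median of the
    # three-class mixture lands at 71
    snv_count = list(
      nonhypermutator = list(meanlog = log(65), sdlog = 0.9,
                             min = 1, max = 500),
      common_hypermutator = list(meanlog = log(1200), sdlog = 0.45,
                                 min = 501, max = 3500),
      pole_category = list(meanlog = log(3400), sdlog = 0.50,
                           min = 1698, max = 9515)
    ),
    # six-class substitution spectra; the POLE category draws its C>A and
    # C>G fractions per tumor from the stated ranges and spreads the
    # remainder over the other classes
    spectrum = list(
      nonhypermutator = c("C>A" = 0.08, "C>G" = 0.06, "C>T" = 0.45,
                          "T>A" = 0.07, "T>C" = 0.26, "T>G" = 0.08),
      common_hypermutator = c("C>A" = 0.08, "C>G" = 0.05, "C>T" = 0.55,
                              "T>A" = 0.05, "T>C" = 0.22, "T>G" = 0.05),
      pole_category = list(c_to_a_range = c(0.25, 0.50),
                           c_to_g_range = c(0.005, 0.02),
                           rest = c("C>T" = 0.60, "T>A" = 0.10,
                                    "T>C" = 0.20, "T>G" = 0.10))
    ),
    clinical = list(
      age_mean = c(66, 68, 46), age_sd = c(12, 12, 13),
      age_min = c(20, 29, 30), age_max = c(93, 87, 85),
      male_frac = c(0.586, 0.509, 0.90),
      right_frac = c(0.291, 0.719, 0.40),
      por_muc_frac = c(0.045, 0.281, 0.20),
      size_meanlog = log(c(45, 55, 60)), size_sdlog = 0.35,
      size_min = 14, size_max = 158,
      pt_low_frac = c(0.225, 0.228, 0.20),
      pstage_low_frac = c(0.465, 0.667, 0.80),
      lvi_frac = c(0.512, 0.614, 0.40),
      vi_frac = c(0.663, 0.491, 0.50),
      mmr_measured_frac = c(0.058, 0.368, 0.60),
      mmr_deficient_frac = c(0.041, 1.0, 0.0)
    ),
    # log2 fold-change shifts by class and gene
    expression_effects = list(
      genes = c("PD-L1", "PD-1", "CTLA-4", "CD8A"),
      nonhypermutator = c(0, 0, 0, 0),
      common_hypermutator = c(1.5, 1.5, 0, 0),
      pole_category = c(1.5, 1.5, 0, 1.5)
    ),
    pole_mutations = list(
      hotspot_changes = c("P286R", "S297Y", "F367C", "V411L"),
      hotspot_probs = c(0.7, 0.1, 0.1, 0.1),
      passenger_changes = c("R47W", "V533M", "E767D", "E1199D", "P1207S",
                            "R1289C", "Y1813C", "T1904A", "K1942*",
                            "T2049A", "D1131E", "A1200T"),
      passenger_rate = c(nonhypermutator = 0.015,
                         common_hypermutator = 0.12,
                         pole_category = 0)
    )
  )
  validate_cohort_spec(structure(spec, class = "cohort_spec"))
}

validate_cohort_spec <- function(spec) {
  if (abs(sum(spec$prevalence) - 1) > 1e-9) {
    stop("class prevalences must sum to 1")
  }
  if (spec$n_tumors < 1) stop("n_tumors must be positive")
  for (cl in c("nonhypermutator", "common_hypermutator")) {
    s <- spec$spectrum[[cl]]
    if (abs(sum(s) - 1) > 1e-9) {
      stop("spectrum for ", cl, " does not sum to 1")
    }
    if (s[["C>A"]] > 0.20 && s[["C>G"]] < 0.03) {
      stop("spectrum for ", cl, " satisfies the POLE-category rule; ",
           "it must violate it by construction")
    }
  }
  pc <- spec$spectrum$pole_category
  if (pc$c_to_a_range[1] <= 0.20 || pc$c_to_g_range[2] >= 0.03) {
    stop("POLE-category spectrum ranges must satisfy C>A > 0.20 and ",
         "C>G < 0.03 by construction")
  }
  if (abs(sum(pc$rest) - 1) > 1e-9) {
    stop("POLE-category residual spectrum must sum to 1")
  }
  spec
}

# positions usable for each reference base (contig interiors only)
genome_base_index <- function(genome) {
  lapply(stats::setNames(nm = c("A", "C", "G", "T")), function(b) {
    do.call(rbind, lapply(names(genome), function(chrom) {
      s <- genome[[chrom]]
      pos <- which(strsplit(s, "", fixed = TRUE)[[1]] == b)
      pos <- pos[pos > 1 & pos < nchar(s)]
      data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
    }))
  })
}

rtrunc_lnorm <- function(n, meanlog, sdlog, min, max) {
  x <- round(stats::rlnorm(n, meanlog, sdlog))
  pmin(pmax(x, min), max)
}

draw_class_spectrum <- function(spec, class) {
  s <- spec$spectrum[[class]]
  if (class != "pole_category") return(s)
  ca <- stats::runif(1, s$c_to_a_range[1], s$c_to_a_range[2])
  cg <- stats::runif(1, s$c_to_g_range[1], s$c_to_g_range[2])
  rest <- (1 - ca - cg) * s$rest
  c("C>A" = ca, "C>G" = cg, rest)[sub_classes()]
}

# QC metrics for variants that pass every false-positive criterion
passing_qc_metrics <- function(n) {
  depth <- 20L + stats::rpois(n, 80)
  vr <- pmax(2L, stats::rbinom(n, depth, 0.3))
  fwd <- 1L + stats::rbinom(n, vr - 2L, 0.5)
  data.frame(
    quality = round(60 + stats::rexp(n, 1 / 120), 1),
    depth = depth,
    var_reads_fwd = fwd,
    var_reads_rev = vr - fwd,
    avg_clipped_length = round(stats::runif(n, 100, 200), 1),
    avg_pos_as_fraction = round(stats::runif(n, 0.05, 0.95), 3)
  )
}

#' Simulate the somatic SNVs of one tumor
#'
#' Draws `n_snv` SNVs whose substitution classes follow a multinomial at
#' the class spectrum, placed uniformly on the synthetic genome at
#' positions whose reference base matches the drawn class (both strands
#' represented with probability 1/2 each), with QC metrics that pass all
#' false-positive criteria. Exactly `n_nonsyn` records are annotated
#' nonsynonymous (default ~70% of `n_snv`), the rest synonymous, so the
#' hypermutator rule is exercised on the correct count.
#'
#' Uses the ambient RNG stream; seed control belongs to the caller
#' ([simulate_cohort()] seeds once for the whole cohort).
#'
#' @param class latent class label (one of the three tumor labels).
#' @param n_snv number of SNVs (>= 0).
#' @param spectrum named 6-vector of substitution-class probabilities.
#' @param genome named character vector of contig sequences.
#' @param tumor_id identifier attached to the records.
#' @param n_nonsyn how many records to annotate nonsynonymous.
#' @param base_index optional precomputed [genome_base_index()] result.
#' @return variant table of `n_snv` rows.
#' @export
simulate_tumor_variants <- function(class, n_snv, spectrum,
                                    genome = synthetic_reference(),
                                    tumor_id = "T1",
                                    n_nonsyn = round(0.7 * n_snv),
                                    base_index = NULL) {
  stopifnot(class %in% TUMOR_LABELS, n_snv >= 0, n_nonsyn <= n_snv)
  empty <- variant_calls(data.frame(
    tumor_id = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0)))
  if (n_snv == 0) return(empty)
  if (is.null(base_index)) base_index <- genome_base_index(genome)
  spectrum <- spectrum[sub_classes()]
  if (abs(sum(spectrum) - 1) > 1e-6) stop("spectrum must sum to 1")

  cls <- sample(sub_classes(), n_snv, replace = TRUE, prob = spectrum)
  pyr <- substr(cls, 1, 1)               # C or T
  alt_pyr <- substr(cls, 3, 3)
  on_pyrimidine <- stats::runif(n_snv) < 0.5
  ref <- ifelse(on_pyrimidine, pyr, unname(.complement[pyr]))
  alt <- ifelse(on_pyrimidine, alt_pyr, unname(.complement[alt_pyr]))

  chrom <- character(n_snv)
  pos <- integer(n_snv)
  for (b in unique(ref)) {
    sel <- which(ref == b)
    idx <- base_index[[b]]
    pick <- sample(nrow(idx), length(sel), replace = TRUE)
    chrom[sel] <- idx$chrom[pick]
    pos[sel] <- idx$pos[pick]
  }

  consequence <- rep("synonymous_SNV", n_snv)
  if (n_nonsyn > 0) {
    consequence[sample(n_snv, n_nonsyn)] <- "nonsynonymous_SNV"
  }
  df <- data.frame(
    tumor_id = tumor_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    passing_qc_metrics(n_snv),
    consequence = consequence, gene = NA_character_,
    protein_change = NA_character_, stringsAsFactors = FALSE
  )
  variant_calls(df)
}

# partition a base index: positions divisible by 7 are reserved for
# blacklist decoys so blacklisted sites never collide with real mutations
index_stratum <- function(base_index, reserved) {
  lapply(base_index, function(idx) {
    sel <- (idx$pos %% 7 == 0) == reserved
    idx[sel, , drop = FALSE]
  })
}

# decoy variants engineered to fail exactly the targeted criterion (a few
# may additionally fail others, which is harmless: they must be discarded);
# criterion-6 decoys live on the reserved position stratum
simulate_decoys <- function(n_by_crit, class, spectrum, genome, tumor_id,
                            nonsyn_fraction, base_index_clean,
                            base_index_reserved) {
  n <- sum(n_by_crit)
  if (n == 0) {
    return(list(variants = NULL, blacklist = NULL))
  }
  n6 <- n_by_crit[6]
  v <- simulate_tumor_variants(class, n - n6, spectrum, genome, tumor_id,
                               n_nonsyn = stats::rbinom(1, n - n6,
                                                        nonsyn_fraction),
                               base_index = base_index_clean)
  if (n6 > 0) {
    v6 <- simulate_tumor_variants(class, n6, spectrum, genome, tumor_id,
                                  n_nonsyn = stats::rbinom(1, n6,
                                                           nonsyn_fraction),
                                  base_index = base_index_reserved)
    v <- rbind(v, v6)
  }
  crit <- rep(seq_along(n_by_crit), c(n_by_crit[-6], n_by_crit[6]))
  i1 <- crit == 1; i2 <- crit == 2; i3 <- crit == 3
  i4 <- crit == 4; i5 <- crit == 5
  v$quality[i1] <- round(stats::runif(sum(i1), 0, 59.9), 1)
  v$depth[i2] <- sample(2:19, sum(i2), replace = TRUE)
  v$var_reads_fwd[i2] <- 1
  v$var_reads_rev[i2] <- 1
  v$var_reads_rev[i3] <- 0
  v$avg_clipped_length[i4] <- round(stats::runif(sum(i4), 20, 99.9), 1)
  v$avg_pos_as_fraction[i5] <- round(stats::runif(sum(i5), 0, 0.049), 3)
  bl <- v[crit == 6, c("chrom", "pos", "ref", "alt")]
  list(variants = v, blacklist = bl)
}

#' Simulate immune-gene expression records for labeled tumors
#'
#' Per tumor and gene, a matched tumor/normal pair of normalized log2
#' values whose fold change is baseline noise plus the class-conditional
#' shift from `effects`.
#'
#' @param labels named character vector: tumor id -> class label.
#' @param effects `expression_effects` list as in [cohort_spec()].
#' @param sd fold-change noise SD.
#' @return expression data.frame (`tumor_id`, `gene`, `tumor_value`,
#'   `normal_value`, `fold_change`).
#' @export
simulate_expression <- function(labels, effects = cohort_spec()$expression_effects,
                                sd = 1) {
  ids <- names(labels)
  genes <- effects$genes
  df <- expand.grid(tumor_id = ids, gene = genes,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  shift_mat <- rbind(nonhypermutator = effects$nonhypermutator,
                     common_hypermutator = effects$common_hypermutator,
                     pole_category = effects$pole_category)
  colnames(shift_mat) <- genes
  shifts <- shift_mat[cbind(labels[df$tumor_id], df$gene)]
  df$normal_value <- round(stats::rnorm(nrow(df), 8, 1.5), 4)
  df$fold_change <- round(stats::rnorm(nrow(df), 0, sd) + shifts, 4)
  df$tumor_value <- df$normal_value + df$fold_change
  df[, c("tumor_id", "gene", "tumor_value", "normal_value", "fold_change")]
}

simulate_clinical_row <- function(class, spec) {
  i <- match(class, TUMOR_LABELS)
  cp <- spec$clinical
  age <- as.integer(round(pmin(cp$age_max[i], pmax(cp$age_min[i],
           stats::rnorm(1, cp$age_mean[i], cp$age_sd[i])))))
  size <- as.integer(round(pmin(cp$size_max, pmax(cp$size_min,
           stats::rlnorm(1, cp$size_meanlog[i], cp$size_sdlog)))))
  pt_low <- stats::runif(1) < cp$pt_low_frac[i]
  pT <- if (pt_low) sample(c("Tis", "T1", "T2"), 1, prob = c(0.02, 0.18, 0.80))
        else sample(c("T3", "T4"), 1, prob = c(0.565, 0.435))
  ps_low <- stats::runif(1) < cp$pstage_low_frac[i]
  pStage <- if (ps_low) sample(c("0", "I", "II"), 1, prob = c(0.01, 0.37, 0.62))
            else sample(c("III", "IV"), 1, prob = c(0.73, 0.27))
  mmr <- "unknown"
  if (stats::runif(1) < cp$mmr_measured_frac[i]) {
    mmr <- if (stats::runif(1) < cp$mmr_deficient_frac[i]) "MMR_D" else "MMR_P"
  }
  data.frame(
    age = age,
    sex = if (stats::runif(1) < cp$male_frac[i]) "man" else "woman",
    location = if (stats::runif(1) < cp$right_frac[i]) "right" else "left",
    histology = if (stats::runif(1) < cp$por_muc_frac[i]) "por_or_muc"
                else "well_or_mod",
    tumor_size_mm = size,
    pT = pT, pStage = pStage,
    lymphatic_invasion = stats::runif(1) < cp$lvi_frac[i],
    vessel_invasion = stats::runif(1) < cp$vi_frac[i],
    mmr_status = mmr,
    stringsAsFactors = FALSE
  )
}

#' Simulate a full cohort
#'
#' Fully reproducible from `spec$seed`. Per tumor: a latent class is drawn
#' from the prevalences; the nonsynonymous SNV count from the
#' class-conditional distribution; SNVs with the class spectrum and
#' QC metrics passing all filters; extra decoy variants engineered to fail
#' each false-positive criterion at the configured rates (criterion-6
#' decoys populate the returned blacklist); a POLE protein change (hotspot
#' for POLE-category tumors, occasional out-of-domain passengers
#' elsewhere); clinical covariates and immune-gene expression from
#' class-conditional distributions. The truth table records every latent
#' assignment for recovery scoring.
#'
#' @param spec `cohort_spec` object.
#' @return list with `variants` (one table, all tumors), `clinical`,
#'   `expression`, `truth`, `blacklist` (a `blacklist` object) and
#'   `genome`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  spec <- validate_cohort_spec(spec)
  genome <- synthetic_reference()
  base_index <- genome_base_index(genome)
  index_clean <- index_stratum(base_index, reserved = FALSE)
  index_reserved <- index_stratum(base_index, reserved = TRUE)
  with_seed(spec$seed, {
    n <- spec$n_tumors
    ids <- sprintf("T%04d", seq_len(n))
    classes <- sample(TUMOR_LABELS, n, replace = TRUE,
                      prob = spec$prevalence)
    variant_parts <- vector("list", n)
    clinical_parts <- vector("list", n)
    bl_parts <- list()
    truth_parts <- vector("list", n)
    for (i in seq_len(n)) {
      cl <- classes[i]
      cd <- spec$snv_count[[cl]]
      n_nonsyn <- rtrunc_lnorm(1, cd$meanlog, cd$sdlog, cd$min, cd$max)
      n_total <- max(n_nonsyn, round(n_nonsyn / spec$nonsyn_fraction))
      spectrum <- draw_class_spectrum(spec, cl)
      v <- simulate_tumor_variants(cl, n_total, spectrum, genome, ids[i],
                                   n_nonsyn = n_nonsyn,
                                   base_index = index_clean)
      n_decoy <- vapply(spec$qc_noise, function(q) {
        stats::rbinom(1, n_total, q)
      }, integer(1))
      dec <- simulate_decoys(n_decoy, cl, spectrum, genome, ids[i],
                             spec$nonsyn_fraction, index_clean,
                             index_reserved)
      # POLE annotation: hotspot driver for POLE-category tumors,
      # out-of-domain passenger elsewhere at a low rate
      pm <- spec$pole_mutations
      pole_change <- NA_character_
      if (cl == "pole_category") {
        pole_change <- sample(pm$hotspot_changes, 1, prob = pm$hotspot_probs)
      } else if (stats::runif(1) < pm$passenger_rate[[cl]]) {
        pole_change <- sample(pm$passenger_changes, 1)
      }
      if (!is.na(pole_change)) {
        cand <- which(v$consequence == "nonsynonymous_SNV")
        if (length(cand) > 0) {
          j <- cand[1]
          v$gene[j] <- "POLE"
          v$protein_change[j] <- pole_change
          if (endsWith(pole_change, "*")) v$consequence[j] <- "nonsense"
        }
      }
      variant_parts[[i]] <- rbind(v, dec$variants)
      if (!is.null(dec$blacklist) && nrow(dec$blacklist) > 0) {
        bl_parts[[length(bl_parts) + 1]] <- dec$blacklist
      }
      clin <- simulate_clinical_row(cl, spec)
      clinical_parts[[i]] <- cbind(data.frame(tumor_id = ids[i],
                                              stringsAsFactors = FALSE),
                                   clin)
      truth_parts[[i]] <- data.frame(
        tumor_id = ids[i], true_label = cl, n_nonsyn = n_nonsyn,
        n_snv_total = n_total, n_decoys = sum(n_decoy),
        pole_change = pole_change, stringsAsFactors = FALSE
      )
    }
    variants <- do.call(rbind, variant_parts)
    rownames(variants) <- NULL
    bl_df <- if (length(bl_parts) > 0) do.call(rbind, bl_parts) else
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0))
    labels <- stats::setNames(classes, ids)
    expr_ids <- sort(sample(ids, round(spec$expression_coverage * n)))
    expression <- simulate_expression(labels[expr_ids],
                                      spec$expression_effects,
                                      sd = spec$expression_sd)
    list(
      variants = variants,
      clinical = clinical_records(do.call(rbind, clinical_parts)),
      expression = expression,
      truth = do.call(rbind, truth_parts),
      blacklist = blacklist(bl_df$chrom, bl_df$pos, bl_df$ref, bl_df$alt),
      genome = genome
    )
  })
}
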