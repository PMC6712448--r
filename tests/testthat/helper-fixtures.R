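# Shared fixture builders. All fixtures are constructed in code.

# a single variant row with QC metrics that pass every filter criterion
make_variant <- function(tumor_id = "T1", chrom = "chr1", pos = 100,
                         ref = "C", alt = "A", quality = 200, depth = 80,
                         fwd = 10, rev = 12, clip = 150, posfrac = 0.5,
                         consequence = "nonsynonymous_SNV", gene = NA,
                         protein_change = NA) {
  data.frame(tumor_id = tumor_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, quality = quality, depth = depth,
             var_reads_fwd = fwd, var_reads_rev = rev,
             avg_clipped_length = clip, avg_pos_as_fraction = posfrac,
             consequence = consequence, gene = gene,
             protein_change = protein_change, stringsAsFactors = FALSE)
}

make_variants <- function(n, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) make_variant(...)))
}

# a spectrum object for classification tests without building variants
make_spectrum <- function(c_to_a, c_to_g, total = 1000) {
  rest <- 1 - c_to_a - c_to_g
  fr <- c("C>A" = c_to_a, "C>G" = c_to_g, "C>T" = rest * 0.6,
          "T>A" = rest * 0.1, "T>C" = rest * 0.2, "T>G" = rest * 0.1)
  structure(list(counts = round(fr * total), fractions = fr,
                 total = total, n_ignored = 0L),
            class = "mutation_spectrum")
}

pole_cases_path <- function() {
  system.file("extdata", "pole_mutation_cases.tsv", package = "poleclass")
}

read_pole_cases <- function() {
  utils::read.delim(pole_cases_path(), stringsAsFactors = FALSE)
}

group_counts_path <- function() {
  system.file("extdata", "crc_cohort_group_counts.tsv",
              package = "poleclass")
}

# independent Fisher oracle: enumerate all 2x2 tables with the observed
# margins, point probabilities from binomial coefficients
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  N <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  lp <- vapply(ks, function(k) {
    lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(N, c1)
  }, numeric(1))
  p <- exp(lp)
  p_obs <- p[ks == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# permutation oracle for the two-sided Mann-Whitney p-value
mw_permutation_oracle <- function(x, y, n_perm = 20000) {
  n <- length(x)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n * (n + 1) / 2
  }
  obs <- abs(u_of(seq_len(n)) - n * length(y) / 2)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample(length(pooled), n)
    if (abs(u_of(idx) - n * length(y) / 2) >= obs - 1e-9) hits <- hits + 1
  }
  hits / n_perm
}

# exhaustive oracle for signature selection: best subset of each size with
# the same constrained fit, grown while the relative improvement >= rel_tol
exhaustive_refit_oracle <- function(catalog, sigs, cutoff = 0.06,
                                    rel_tol = 1e-3) {
  m <- as.numeric(catalog) / sum(catalog)
  P <- sigs$weights
  K <- ncol(P)
  best_of_size <- function(s) {
    subsets <- utils::combn(K, s, simplify = FALSE)
    fits <- lapply(subsets, function(ss) {
      f <- poleclass:::fit_signature_subset(m, P[, ss, drop = FALSE])
      list(subset = ss, fit = f)
    })
    fits[[which.min(vapply(fits, function(f) f$fit$sse, numeric(1)))]]
  }
  prev <- list(subset = integer(0), fit = list(sse = sum(m^2)))
  for (s in seq_len(K)) {
    cur <- best_of_size(s)
    if ((prev$fit$sse - cur$fit$sse) / prev$fit$sse < rel_tol && s > 1) break
    prev <- cur
  }
  w <- stats::setNames(prev$fit$weights, sigs$names[prev$subset])
  keep <- w >= cutoff
  if (!any(keep)) keep <- w == max(w)
  w[keep] / sum(w[keep])
}

# draw a random multinomial catalog from a mixture of signature columns
random_mixture_catalog <- function(sigs, weights, n = 5000) {
  mix <- as.numeric(sigs$weights %*% weights)
  stats::setNames(as.numeric(stats::rmultinom(1, n, mix)),
                  context_labels_96())
}

expand_group_counts <- function() {
  # reconstruct an individual-level clinical table from the marginal group
  # counts (variables independent within group; Fisher only needs margins)
  gc <- utils::read.delim(group_counts_path(), stringsAsFactors = FALSE,
                          check.names = FALSE)
  sizes <- c(nonhypermutator = 843, common_hypermutator = 57,
             pole_category = 10)
  levels2 <- function(var) gc[gc$variable == var, ]
  out <- lapply(names(sizes), function(g) {
    n <- sizes[[g]]
    col <- function(var) {
      rows <- levels2(var)
      rep(rows$level, times = rows[[g]])
    }
    df <- data.frame(
      tumor_id = sprintf("%s_%03d", substr(g, 1, 2), seq_len(n)),
      age = rep(67L, n), sex = col("sex"), location = col("location"),
      histology = col("histology"), tumor_size_mm = rep(45L, n),
      pT = ifelse(col("pT") == "Tis-T2", "T2", "T3"),
      pStage = ifelse(col("pStage") == "0-II", "II", "III"),
      lymphatic_invasion = col("lymphatic_invasion") == "yes",
      vessel_invasion = col("vessel_invasion") == "yes",
      mmr_status = "unknown", stringsAsFactors = FALSE
    )
    df$label <- g
    df
  })
  do.call(rbind, out)
}
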