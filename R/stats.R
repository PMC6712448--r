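# Exact and rank-based cohort statistics, expression normalization, and the
# three-group clinicopathological comparison report.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p by the minimum-likelihood convention: the sum of the
#' hypergeometric probabilities of every table with the observed margins
#' whose point probability does not exceed that of the observed table
#' (within a 1e-7 relative tie tolerance). Deterministic; probabilities are
#' accumulated from the exact hypergeometric mass.
#'
#' @param a,b,c,d cell counts: rows are the two category levels, columns the
#'   two groups, so the table is `rbind(c(a, b), c(c, d))`.
#' @return list with `p_value` and `odds_ratio` (sample odds ratio
#'   `(a*d)/(b*c)`, `Inf`/`NaN` allowed for zero cells).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (length(counts) != 4 || any(is.na(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop("cells must be four nonnegative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("empty table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  k <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(k, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(p, 1), odds_ratio = (a * d) / (b * c))
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from midranks. For small untied samples
#' (`min(n, m) <= exact_max`, default 8) the exact null distribution is
#' used; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric vectors (both nonempty).
#' @param exact_max largest `min(n, m)` for which the exact distribution is
#'   used (ties always force the approximation).
#' @return list with `U` (statistic for `x`), `p_value` and `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  if (anyNA(x) || anyNA(y)) stop("NA values in input")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && min(n, m) <= exact_max) {
    # exact two-sided p from the null distribution of U
    p <- 2 * min(stats::pwilcox(U, n, m),
                 1 - stats::pwilcox(U - 1, n, m))
    return(list(U = U, p_value = min(p, 1), method = "exact"))
  }
  mu <- n * m / 2
  tie_tab <- table(c(x, y))
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(U = U, p_value = min(p, 1), method = "normal")
}

#' Normalize raw expression intensities to the 75th percentile
#'
#' Log2-transforms the raw signal intensities of one sample and subtracts
#' the sample's 75th percentile of the log2 values, so each sample's
#' normalized 75th percentile is 0 and per-sample scale factors cancel.
#'
#' @param raw_intensities positive numeric vector (one sample).
#' @return numeric vector of normalized log2 values.
#' @export
normalize_expression <- function(raw_intensities) {
  if (length(raw_intensities) == 0) stop("empty sample")
  if (any(is.na(raw_intensities)) || any(raw_intensities <= 0)) {
    stop("raw intensities must all be positive")
  }
  lg <- log2(raw_intensities)
  lg - stats::quantile(lg, 0.75, names = FALSE)
}

#' Pairwise fold-change comparison of one gene across tumor groups
#'
#' Compares per-patient tumor-vs-normal fold changes (log scale) for a gene
#' between the three classification groups with two-sided Mann-Whitney U
#' tests: nonhypermutator vs common-hypermutator, nonhypermutator vs POLE
#' category, and common-hypermutator vs POLE category. No multiplicity
#' adjustment is applied.
#'
#' @param records expression data.frame (`tumor_id`, `gene`, `fold_change`).
#' @param labels named character vector mapping tumor id to label.
#' @param gene gene symbol.
#' @return list with `fold_changes` (per-group list) and `p_values` (named:
#'   `NH_vs_CH`, `NH_vs_PC`, `CH_vs_PC`).
#' @export
compare_expression_by_group <- function(records, labels, gene) {
  rec <- records[records$gene == gene, ]
  if (nrow(rec) == 0) stop("gene '", gene, "' absent from expression table")
  unlabeled <- setdiff(rec$tumor_id, names(labels))
  if (length(unlabeled) > 0) {
    stop("no label for tumor(s): ",
         paste(utils::head(unlabeled, 5), collapse = ", "))
  }
  grp <- labels[rec$tumor_id]
  fc <- split(rec$fold_change, factor(grp, levels = TUMOR_LABELS))
  if (any(lengths(fc) == 0)) {
    stop("empty group(s): ",
         paste(TUMOR_LABELS[lengths(fc) == 0], collapse = ", "))
  }
  pair_p <- function(g1, g2) mann_whitney_u(fc[[g1]], fc[[g2]])$p_value
  list(
    fold_changes = fc,
    p_values = c(
      NH_vs_CH = pair_p("nonhypermutator", "common_hypermutator"),
      NH_vs_PC = pair_p("nonhypermutator", "pole_category"),
      CH_vs_PC = pair_p("common_hypermutator", "pole_category")
    )
  )
}

fmt_count_pct <- function(k, n) {
  sprintf("%d (%.1f)", k, if (n > 0) 100 * k / n else 0)
}

fmt_median_range <- function(x) {
  sprintf("%g (%g-%g)", stats::median(x), min(x), max(x))
}

#' Three-group clinicopathological comparison report
#'
#' Builds the standard cohort comparison of clinicopathological
#' characteristics across the three classification groups: per-group counts
#' with percentages (categorical variables, with pT dichotomized Tis-T2 vs
#' T3-T4 and pStage 0-II vs III-IV) or medians with ranges (age, tumor
#' size), plus two-sided p-values comparing the POLE category against each
#' of the other groups (Fisher's exact test for categorical variables,
#' Mann-Whitney U for continuous ones). P-values are reported to three
#' decimals and no multiplicity adjustment is applied. When a comparison
#' group is empty the p columns are `NA`.
#'
#' @param profiles tumor profile data.frame (see [build_tumor_profiles()]);
#'   only `tumor_id` and `label` are used, so a minimal data.frame works.
#' @param clinical clinical data.frame (see [read_clinical_table()]).
#' @return list with `groups` (named group sizes) and `table` (data.frame:
#'   `variable`, `level`, one formatted column per group, `p_NH_vs_PC`,
#'   `p_CH_vs_PC`).
#' @export
build_group_comparison <- function(profiles, clinical) {
  clinical <- clinical_records(clinical)
  missing_ids <- setdiff(profiles$tumor_id, clinical$tumor_id)
  if (length(missing_ids) > 0) {
    stop("tumor id(s) missing from clinical table: ",
         paste(utils::head(missing_ids, 10), collapse = ", "))
  }
  d <- merge(profiles[, c("tumor_id", "label")], clinical, by = "tumor_id")
  d$label <- factor(d$label, levels = TUMOR_LABELS)
  groups <- split(d, d$label)
  sizes <- vapply(groups, nrow, integer(1))
  has <- sizes > 0
  can_compare <- function(g) has[[g]] && has[["pole_category"]]

  round3 <- function(p) round(p, 3)
  cont_p <- function(col, g) {
    if (!can_compare(g)) return(NA_real_)
    round3(mann_whitney_u(groups[[g]][[col]],
                          groups[["pole_category"]][[col]])$p_value)
  }
  cat_p <- function(pred, g) {
    if (!can_compare(g)) return(NA_real_)
    x <- pred(groups[[g]]); y <- pred(groups[["pole_category"]])
    round3(fisher_exact_2x2(sum(x), sum(y), sum(!x), sum(!y))$p_value)
  }

  rows <- list()
  add_row <- function(variable, level, cells, p_nh = NA_real_,
                      p_ch = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, level = level,
      nonhypermutator = cells[1], common_hypermutator = cells[2],
      pole_category = cells[3], p_NH_vs_PC = p_nh, p_CH_vs_PC = p_ch,
      stringsAsFactors = FALSE
    )
  }
  cells_cont <- function(col) {
    vapply(TUMOR_LABELS, function(g) {
      if (has[[g]]) fmt_median_range(groups[[g]][[col]]) else "-"
    }, character(1))
  }
  cells_cat <- function(pred) {
    vapply(TUMOR_LABELS, function(g) {
      if (has[[g]]) fmt_count_pct(sum(pred(groups[[g]])), sizes[[g]])
      else "-"
    }, character(1))
  }

  add_row("age_years", "median (range)", cells_cont("age"),
          cont_p("age", "nonhypermutator"),
          cont_p("age", "common_hypermutator"))
  dich <- list(
    sex = list(levels = c("man", "woman"),
               pred = function(g) g$sex == "man"),
    location = list(levels = c("right", "left"),
                    pred = function(g) g$location == "right"),
    histology = list(levels = c("well_or_mod", "por_or_muc"),
                     pred = function(g) g$histology == "well_or_mod")
  )
  for (var in names(dich)) {
    pred <- dich[[var]]$pred
    lv <- dich[[var]]$levels
    add_row(var, lv[1], cells_cat(pred),
            cat_p(pred, "nonhypermutator"),
            cat_p(pred, "common_hypermutator"))
    add_row(var, lv[2], cells_cat(function(g) !pred(g)))
  }
  add_row("tumor_size_mm", "median (range)", cells_cont("tumor_size_mm"),
          cont_p("tumor_size_mm", "nonhypermutator"),
          cont_p("tumor_size_mm", "common_hypermutator"))
  pt_pred <- function(g) g$pT %in% c("Tis", "T1", "T2")
  add_row("pT", "Tis-T2", cells_cat(pt_pred),
          cat_p(pt_pred, "nonhypermutator"),
          cat_p(pt_pred, "common_hypermutator"))
  add_row("pT", "T3-T4", cells_cat(function(g) !pt_pred(g)))
  ps_pred <- function(g) g$pStage %in% c("0", "I", "II")
  add_row("pStage", "0-II", cells_cat(ps_pred),
          cat_p(ps_pred, "nonhypermutator"),
          cat_p(ps_pred, "common_hypermutator"))
  add_row("pStage", "III-IV", cells_cat(function(g) !ps_pred(g)))
  lvi_pred <- function(g) g$lymphatic_invasion
  add_row("lymphatic_invasion", "yes", cells_cat(lvi_pred),
          cat_p(lvi_pred, "nonhypermutator"),
          cat_p(lvi_pred, "common_hypermutator"))
  vi_pred <- function(g) g$vessel_invasion
  add_row("vessel_invasion", "yes", cells_cat(vi_pred),
          cat_p(vi_pred, "nonhypermutator"),
          cat_p(vi_pred, "common_hypermutator"))

  list(groups = sizes, table = do.call(rbind, rows))
}
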