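# 96-context mutation catalogs and signature-exposure refitting by
# constrained decomposition with forward signature selection.

#' Build a 96-context mutation catalog from SNVs
#'
#' Each SNV is placed into one of the 96 pyrimidine-normalized trinucleotide
#' contexts using the two flanking reference bases. Sites with a purine
#' reference are reverse-complemented together with their context. Variants
#' whose flanking base is unavailable (contig edge, unknown contig, or a
#' reference base disagreeing with the call) are skipped with a warning.
#'
#' @param variants variant table for one tumor (non-SNVs are ignored).
#' @param context_source either a named character vector of contig sequences
#'   (names = chrom), or a function `(chrom, pos) -> 3-base string` returning
#'   the reference trinucleotide centered on `pos` (or `NA` if unavailable).
#' @return named numeric vector of length 96 (canonical context order) with
#'   attribute `tumor_id`; the sum equals the number of usable SNVs.
#' @export
build_catalog <- function(variants, context_source) {
  variants <- variant_calls(variants)
  v <- variants[is_snv(variants$ref, variants$alt), ]
  counts <- stats::setNames(numeric(96), context_labels_96())
  attr(counts, "tumor_id") <- if (nrow(variants) > 0)
    variants$tumor_id[1] else NA_character_
  if (nrow(v) == 0) return(counts)

  if (is.function(context_source)) {
    tri <- mapply(context_source, v$chrom, v$pos)
  } else {
    seqs <- context_source
    tri <- mapply(function(chrom, pos) {
      if (!(chrom %in% names(seqs))) return(NA_character_)
      s <- seqs[[chrom]]
      if (pos < 2 || pos > nchar(s) - 1) return(NA_character_)
      toupper(substr(s, pos - 1, pos + 1))
    }, v$chrom, v$pos)
  }
  tri <- as.character(tri)
  usable <- !is.na(tri) & nchar(tri) == 3 &
    substr(tri, 2, 2) == v$ref & !grepl("[^ACGT]", tri)
  if (any(!usable)) {
    warning(sum(!usable), " SNV(s) skipped: flanking context unavailable ",
            "or reference base mismatch")
  }
  v <- v[usable, ]
  tri <- tri[usable]
  if (nrow(v) == 0) return(counts)

  purine <- v$ref %in% c("A", "G")
  tri[purine] <- revcomp(tri[purine])
  alt <- ifelse(purine, .complement[v$alt], v$alt)
  labels <- paste0(substr(tri, 1, 1), "[", substr(tri, 2, 2), ">", alt, "]",
                   substr(tri, 3, 3))
  tab <- table(factor(labels, levels = context_labels_96()))
  counts[] <- as.numeric(tab)
  counts
}

# Constrained least squares on the probability simplex: minimize
# || m - P w ||^2 subject to w >= 0, sum(w) = 1. Solved as nonnegative
# least squares on a system augmented with a heavily weighted sum row,
# then renormalized. Returns list(weights, sse).
fit_signature_subset <- function(m, P, lambda = 100) {
  A <- rbind(P, rep(lambda, ncol(P)))
  b <- c(m, lambda)
  w <- pracma::lsqnonneg(A, b)$x
  s <- sum(w)
  if (s <= 0) {
    w <- rep(1 / ncol(P), ncol(P))
  } else {
    w <- w / s
  }
  resid <- m - as.vector(P %*% w)
  list(weights = w, sse = sum(resid^2))
}

#' Refit signature exposures for one catalog
#'
#' Estimates the contribution of fixed reference signatures to a tumor's
#' normalized 96-context catalog by iterative forward selection: starting
#' from the empty set, the signature whose inclusion most reduces the
#' sum-of-squares reconstruction error (under nonnegative weights summing
#' to 1) is added, until the relative error improvement drops below
#' `rel_tol`. Signatures whose fitted weight falls below `cutoff` are then
#' discarded and the remaining weights renormalized. Deterministic given
#' its inputs.
#'
#' Catalogs with fewer than `min_mutations` mutations are refused: refitting
#' a sparse catalog is unstable, and only heavily mutated tumors are
#' meaningfully decomposed.
#'
#' @param catalog named numeric vector of 96 counts (see [build_catalog()]),
#'   or any numeric vector of length 96 in canonical order.
#' @param signatures `signature_matrix` of reference signatures.
#' @param cutoff minimum retained weight (default 0.06).
#' @param min_mutations minimum catalog total (default 50).
#' @param rel_tol relative error-improvement stopping threshold.
#' @return `exposure_vector` object: list with `weights` (named, only kept
#'   signatures, summing to 1) and `reconstruction_error` (sum of squared
#'   differences between the normalized catalog and its reconstruction
#'   from the pre-cutoff fit).
#' @export
refit_exposures <- function(catalog, signatures, cutoff = 0.06,
                            min_mutations = 50, rel_tol = 1e-3) {
  stopifnot(inherits(signatures, "signature_matrix"))
  if (length(catalog) != 96) stop("catalog must have 96 entries")
  if (any(catalog < 0)) stop("catalog counts must be nonnegative")
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must lie in [0, 1)")
  total <- sum(catalog)
  if (total == 0) stop("catalog total is zero; nothing to refit")
  if (total < min_mutations) {
    stop("catalog holds ", total, " mutations; refitting needs at least ",
         min_mutations, " (see min_mutations)")
  }
  if (!is.null(names(catalog))) {
    if (!setequal(names(catalog), signatures$contexts)) {
      stop("catalog context labels do not match the signature matrix")
    }
    catalog <- catalog[signatures$contexts]
  }
  m <- as.numeric(catalog) / total
  P <- signatures$weights
  K <- ncol(P)

  selected <- integer(0)
  err <- sum(m^2)  # empty-model reconstruction is the zero vector
  fit <- NULL
  while (length(selected) < K) {
    candidates <- setdiff(seq_len(K), selected)
    fits <- lapply(candidates, function(j) {
      fit_signature_subset(m, P[, c(selected, j), drop = FALSE])
    })
    sse <- vapply(fits, `[[`, numeric(1), "sse")
    best <- which.min(sse)
    if ((err - sse[best]) / err < rel_tol) break
    selected <- c(selected, candidates[best])
    fit <- fits[[best]]
    err <- fit$sse
  }
  if (is.null(fit)) {
    # first candidate already failed the improvement rule; keep the single
    # best signature anyway (an empty exposure is not meaningful)
    fits <- lapply(seq_len(K), function(j) {
      fit_signature_subset(m, P[, j, drop = FALSE])
    })
    best <- which.min(vapply(fits, `[[`, numeric(1), "sse"))
    selected <- best
    fit <- fits[[best]]
  }
  w <- stats::setNames(fit$weights, signatures$names[selected])
  keep <- w >= cutoff
  if (!any(keep)) keep <- w == max(w)
  w <- w[keep] / sum(w[keep])
  structure(list(weights = w, reconstruction_error = fit$sse),
            class = "exposure_vector")
}

#' @export
print.exposure_vector <- function(x, ...) {
  cat("exposure_vector (reconstruction SSE ",
      format(x$reconstruction_error, digits = 4), ")\n", sep = "")
  print(round(x$weights, 4))
  invisible(x)
}

#' Compare a signature's exposure between two tumor groups
#'
#' Collects the given signature's weight per tumor (0 when the signature
#' was not retained) and compares the two groups with a two-sided
#' Mann-Whitney U test.
#'
#' @param exposures named list of `exposure_vector`s, keyed by tumor id.
#' @param labels named character vector mapping tumor id to group label;
#'   must cover every tumor in `exposures` and contain exactly two distinct
#'   labels.
#' @param signature signature name.
#' @return list with `scores` (named list of per-group weight vectors),
#'   `U` and `p_value`.
#' @export
signature_score_by_group <- function(exposures, labels, signature) {
  ids <- names(exposures)
  if (is.null(ids)) stop("exposures must be a named list keyed by tumor id")
  unlabeled <- setdiff(ids, names(labels))
  if (length(unlabeled) > 0) {
    stop("no label for tumor(s): ", paste(unlabeled, collapse = ", "))
  }
  score <- vapply(exposures, function(e) {
    w <- e$weights[signature]
    if (is.na(w)) 0 else as.numeric(w)
  }, numeric(1))
  grp <- labels[ids]
  groups <- unique(grp)
  if (length(groups) != 2) {
    stop("signature_score_by_group compares exactly 2 groups, got ",
         length(groups))
  }
  scores <- split(unname(score), factor(grp, levels = groups))
  if (any(lengths(scores) == 0)) stop("empty group")
  mw <- mann_whitney_u(scores[[1]], scores[[2]])
  list(scores = scores, U = mw$U, p_value = mw$p_value)
}
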