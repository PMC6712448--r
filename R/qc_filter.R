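# False-positive removal: six per-variant criteria with reason codes.

#' Construct a false-positive blacklist
#'
#' Site-level blacklist of known recurrent artifacts. A variant matches when
#' its (chrom, pos, ref, alt) tuple is listed.
#'
#' @param chrom,pos,ref,alt vectors of equal length (may be empty).
#' @return A `blacklist` object (set semantics; duplicates dropped).
#' @export
blacklist <- function(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)) {
  keys <- unique(paste(as.character(chrom), as.integer(pos),
                       toupper(ref), toupper(alt), sep = ":"))
  if (length(chrom) == 0) keys <- character(0)
  structure(list(keys = keys), class = "blacklist")
}

#' Read a blacklist from a TSV file (columns chrom, pos, ref, alt)
#' @param path TSV path.
#' @return `blacklist` object.
#' @export
read_blacklist <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(df))) {
    stop("blacklist needs columns chrom, pos, ref, alt")
  }
  blacklist(df$chrom, df$pos, df$ref, df$alt)
}

#' @export
print.blacklist <- function(x, ...) {
  cat("blacklist:", length(x$keys), "site(s)\n")
  invisible(x)
}

#' Apply the six false-positive filters to a variant table
#'
#' A somatic call is discarded when it fulfils at least one of:
#' \enumerate{
#'   \item quality score < 60
#'   \item depth of coverage < 20
#'   \item variant reads observed on one strand only
#'   \item average clipped read length < 100
#'   \item variant sits at a read end (avg_pos_as_fraction < 0.05)
#'   \item site on the false-positive blacklist
#' }
#' All comparisons are strict: a variant exactly at a threshold (quality 60,
#' depth 20, clipped length 100, position fraction 0.05) passes. Criterion 3
#' fails when exactly one strand count is zero while the other is positive;
#' zero reads on both strands is treated as a degenerate call and also fails.
#'
#' A variant whose metric for some criterion is missing (`NA`) passes that
#' criterion with a warning by default; with `strict_missing = TRUE` it
#' fails it instead.
#'
#' @param variants variant table (see [variant_calls()]).
#' @param blacklist `blacklist` object; defaults to empty.
#' @param strict_missing logical; fail criteria whose metric is missing.
#' @return data.frame in input order with the variant columns plus `kept`
#'   (logical) and `failed_criteria` (comma-separated criterion numbers,
#'   `""` when kept).
#' @export
apply_fp_filters <- function(variants, blacklist = NULL,
                             strict_missing = FALSE) {
  variants <- variant_calls(variants)
  n <- nrow(variants)
  if (is.null(blacklist)) blacklist <- poleclass::blacklist()
  stopifnot(inherits(blacklist, "blacklist"))

  eval_crit <- function(value, fails) {
    # fails: logical vector where the metric is present; NA policy applied here
    out <- fails
    miss <- is.na(value)
    if (any(miss)) {
      if (!strict_missing) {
        warning(sum(miss), " variant(s) with missing QC metric passed a ",
                "criterion unevaluated (strict_missing = FALSE)")
      }
      out[miss] <- strict_missing
    }
    out
  }

  if (n == 0) {
    out <- variants
    out$kept <- logical(0)
    out$failed_criteria <- character(0)
    return(out)
  }

  fwd <- variants$var_reads_fwd
  rev <- variants$var_reads_rev
  strand_known <- !is.na(fwd) & !is.na(rev)
  one_strand <- strand_known & (
    (fwd == 0 & rev > 0) | (fwd > 0 & rev == 0) | (fwd == 0 & rev == 0)
  )
  strand_val <- ifelse(strand_known, 1, NA_real_)

  keys <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
                sep = ":")

  fails <- cbind(
    eval_crit(variants$quality, !is.na(variants$quality) & variants$quality < 60),
    eval_crit(variants$depth, !is.na(variants$depth) & variants$depth < 20),
    eval_crit(strand_val, one_strand),
    eval_crit(variants$avg_clipped_length,
              !is.na(variants$avg_clipped_length) &
                variants$avg_clipped_length < 100),
    eval_crit(variants$avg_pos_as_fraction,
              !is.na(variants$avg_pos_as_fraction) &
                variants$avg_pos_as_fraction < 0.05),
    keys %in% blacklist$keys
  )

  out <- variants
  out$kept <- rowSums(fails) == 0
  out$failed_criteria <- apply(fails, 1, function(f) {
    paste(which(f), collapse = ",")
  })
  out
}

#' Summarize filter verdicts
#'
#' @param verdicts output of [apply_fp_filters()].
#' @return list with `n`, `kept`, `discarded` and `by_criterion` (named
#'   integer vector of failure counts for criteria 1-6; a variant failing
#'   several criteria counts once under each).
#' @export
filter_summary <- function(verdicts) {
  stopifnot(all(c("kept", "failed_criteria") %in% names(verdicts)))
  by_crit <- vapply(1:6, function(k) {
    sum(vapply(strsplit(verdicts$failed_criteria, ",", fixed = TRUE),
               function(f) as.character(k) %in% f, logical(1)))
  }, integer(1))
  names(by_crit) <- paste0("criterion_", 1:6)
  list(
    n = nrow(verdicts),
    kept = sum(verdicts$kept),
    discarded = sum(!verdicts$kept),
    by_criterion = by_crit
  )
}

#' Keep only variants passing all filters
#' @param verdicts output of [apply_fp_filters()].
#' @return variant table of kept rows (verdict columns dropped).
#' @export
kept_variants <- function(verdicts) {
  out <- verdicts[verdicts$kept, setdiff(names(verdicts),
                                         c("kept", "failed_criteria"))]
  rownames(out) <- NULL
  out
}
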