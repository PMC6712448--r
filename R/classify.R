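# Tumor-level mutation statistics, three-way classification, and POLE
# exonuclease-domain annotation.

#' Default classification thresholds
#'
#' The three-way classification: tumors exceeding 500 nonsynonymous SNVs are
#' hypermutators; hypermutators whose spectrum has more than 20% C>A and
#' less than 3% C>G transversions form the POLE category (the ultramutated
#' phenotype of proofreading deficiency); the rest are common-hypermutators.
#' All inequalities are strict. The POLE exonuclease (proofreading) domain
#' spans residues 86-427; recurrent pathogenic hotspots sit at residues
#' 286, 297, 367 and 411 (P286R, S297Y, F367C, V411L).
#'
#' @return Named list of thresholds: `hypermutator_count`, `c_to_a_min`,
#'   `c_to_g_max`, `exo_domain` (length-2 residue bounds), `hotspots`.
#' @export
classification_thresholds <- function() {
  list(
    hypermutator_count = 500L,
    c_to_a_min = 0.20,
    c_to_g_max = 0.03,
    exo_domain = c(86L, 427L),
    hotspots = c(286L, 297L, 367L, 411L)
  )
}

TUMOR_LABELS <- c("nonhypermutator", "common_hypermutator", "pole_category")

#' Six-class substitution spectrum of a variant set
#'
#' Counts SNVs by pyrimidine-normalized substitution class and normalizes to
#' fractions. Non-SNV records (indels, MNVs) are ignored; their number is
#' reported. With zero usable SNVs all fractions are `NaN` and the spectrum
#' is flagged undefined (classification of such a tumor falls through to
#' the count rule alone).
#'
#' @param variants variant table.
#' @return `mutation_spectrum` object: list with `counts` and `fractions`
#'   (named over the six classes), `total` and `n_ignored`.
#' @export
compute_spectrum <- function(variants) {
  variants <- variant_calls(variants)
  snv <- is_snv(variants$ref, variants$alt)
  counts <- stats::setNames(integer(6), sub_classes())
  if (any(snv)) {
    cls <- substitution_class(variants$ref[snv], variants$alt[snv])
    tab <- table(factor(cls, levels = sub_classes()))
    counts[] <- as.integer(tab)
  }
  total <- sum(counts)
  fractions <- if (total > 0) counts / total else
    stats::setNames(rep(NaN, 6), sub_classes())
  structure(list(counts = counts, fractions = fractions, total = total,
                 n_ignored = sum(!snv)),
            class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("mutation_spectrum (", x$total, " SNVs, ", x$n_ignored,
      " non-SNV ignored)\n", sep = "")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Classify a tumor from its nonsynonymous SNV count and spectrum
#'
#' Rules (strict inequalities):
#' * `nonsyn_snv_count <= 500` -> nonhypermutator (a count of exactly 500 is
#'   not a hypermutator);
#' * otherwise POLE category iff the spectrum has C>A fraction > 0.20 and
#'   C>G fraction < 0.03 (fractions exactly at a threshold stay
#'   common-hypermutator);
#' * otherwise common-hypermutator.
#'
#' @param nonsyn_snv_count nonnegative integer.
#' @param spectrum `mutation_spectrum` for the same tumor (may have
#'   undefined fractions when the tumor has no SNVs).
#' @param thresholds see [classification_thresholds()].
#' @return One of `"nonhypermutator"`, `"common_hypermutator"`,
#'   `"pole_category"`.
#' @export
classify_tumor <- function(nonsyn_snv_count, spectrum,
                           thresholds = classification_thresholds()) {
  if (length(nonsyn_snv_count) != 1 || is.na(nonsyn_snv_count) ||
      nonsyn_snv_count < 0) {
    stop("nonsyn_snv_count must be a single nonnegative integer")
  }
  if (nonsyn_snv_count <= thresholds$hypermutator_count) {
    return("nonhypermutator")
  }
  fr <- spectrum$fractions
  if (any(is.nan(fr))) {
    # no usable SNVs: hypermutator by count but spectrum undefined
    return("common_hypermutator")
  }
  if (fr[["C>A"]] > thresholds$c_to_a_min &&
      fr[["C>G"]] < thresholds$c_to_g_max) {
    "pole_category"
  } else {
    "common_hypermutator"
  }
}

#' Tumor mutational burden in mutations per megabase
#'
#' @param total_mutation_count nonnegative mutation count.
#' @param footprint_mb callable exome footprint in megabases; required, no
#'   default (it depends on the capture design and coverage).
#' @return mutations per megabase.
#' @export
mutations_per_mb <- function(total_mutation_count, footprint_mb) {
  if (missing(footprint_mb) || !is.numeric(footprint_mb) ||
      length(footprint_mb) != 1 || is.na(footprint_mb) || footprint_mb <= 0) {
    stop("footprint_mb must be a single positive number")
  }
  if (any(total_mutation_count < 0)) stop("negative mutation count")
  total_mutation_count / footprint_mb
}

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Parse a protein-change string
#'
#' Accepts `<refAA><residue><altAA>` with an optional `p.` prefix; the
#' alternate may be `*` (termination, i.e. a nonsense change). Compound
#' entries should be split before parsing (see [annotate_pole()]).
#'
#' @param text single protein change, e.g. `"P286R"`, `"p.V411L"`, `"Q196*"`.
#' @return list with `ref_aa`, `residue`, `alt_aa`, `mutation_type`.
#' @export
parse_protein_change <- function(text) {
  stopifnot(length(text) == 1)
  m <- regmatches(text, regexec("^(?:p\\.)?([A-Z])([0-9]+)([A-Z*])$", text))[[1]]
  if (length(m) == 0) {
    stop("cannot parse protein change '", text,
         "': expected <refAA><residue><altAA|*>, optionally prefixed 'p.'")
  }
  ref_aa <- m[2]; residue <- as.integer(m[3]); alt_aa <- m[4]
  if (!(ref_aa %in% AA_LETTERS)) {
    stop("'", ref_aa, "' is not an amino-acid letter in '", text, "'")
  }
  if (!(alt_aa %in% c(AA_LETTERS, "*"))) {
    stop("'", alt_aa, "' is not an amino-acid letter or '*' in '", text, "'")
  }
  if (residue < 1) stop("residue must be positive in '", text, "'")
  list(ref_aa = ref_aa, residue = residue, alt_aa = alt_aa,
       mutation_type = if (alt_aa == "*") "nonsense" else "missense")
}

#' Annotate POLE protein changes for domain membership and hotspots
#'
#' Flags each change for membership in the exonuclease (proofreading) domain
#' (residues 86-427, inclusive) and for the recurrent pathogenic hotspots
#' (residues 286, 297, 367, 411). Compound entries like `"P1207S, V1218I"`
#' are split on commas and annotated independently.
#'
#' @param protein_changes character vector of protein-change strings.
#' @param thresholds see [classification_thresholds()].
#' @return data.frame with one row per (split) change: `protein_change`,
#'   `residue`, `ref_aa`, `alt_aa`, `mutation_type`,
#'   `in_exonuclease_domain`, `is_hotspot`.
#' @export
annotate_pole <- function(protein_changes,
                          thresholds = classification_thresholds()) {
  changes <- unlist(lapply(protein_changes, function(x) {
    trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  }), use.names = FALSE)
  changes <- changes[nzchar(changes)]
  rows <- lapply(changes, function(ch) {
    p <- parse_protein_change(ch)
    data.frame(
      protein_change = ch,
      residue = p$residue,
      ref_aa = p$ref_aa,
      alt_aa = p$alt_aa,
      mutation_type = p$mutation_type,
      in_exonuclease_domain = p$residue >= thresholds$exo_domain[1] &
        p$residue <= thresholds$exo_domain[2],
      is_hotspot = p$residue %in% thresholds$hotspots,
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0) {
    return(data.frame(protein_change = character(0), residue = integer(0),
                      ref_aa = character(0), alt_aa = character(0),
                      mutation_type = character(0),
                      in_exonuclease_domain = logical(0),
                      is_hotspot = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Build per-tumor mutation profiles from a filtered variant table
#'
#' Aggregates each tumor's nonsynonymous SNV count, total SNV count,
#' substitution spectrum, mutational burden and classification label, and
#' summarizes its POLE annotations.
#'
#' @param variants filtered variant table (possibly many tumors).
#' @param footprint_mb callable footprint in Mb for mutations/Mb.
#' @param spectrum_set which SNVs feed the 20%/3% spectrum rule: `"all"`
#'   (default; synonymous + nonsynonymous) or `"nonsynonymous"`.
#' @param pole_gene gene symbol whose protein changes are annotated
#'   (default `"POLE"`).
#' @param thresholds see [classification_thresholds()].
#' @return data.frame with one row per tumor: counts, the six spectrum
#'   fraction columns (`frac_C.A`, ...), `mutations_per_mb`, `label`,
#'   `pole_domain_mutations` and `pole_hotspots` (comma-separated protein
#'   changes, `""` when none).
#' @export
build_tumor_profiles <- function(variants, footprint_mb,
                                 spectrum_set = c("all", "nonsynonymous"),
                                 pole_gene = "POLE",
                                 thresholds = classification_thresholds()) {
  spectrum_set <- match.arg(spectrum_set)
  variants <- variant_calls(variants)
  ids <- unique(variants$tumor_id)
  by_tumor <- split(seq_len(nrow(variants)),
                    factor(variants$tumor_id, levels = ids))
  frac_cols <- paste0("frac_", gsub(">", ".", sub_classes(), fixed = TRUE))
  rows <- lapply(ids, function(id) {
    v <- variants[by_tumor[[id]], ]
    snv <- v[is_snv(v$ref, v$alt), ]
    nonsyn <- snv[!is.na(snv$consequence) &
                    snv$consequence == "nonsynonymous_SNV", ]
    spec_input <- if (spectrum_set == "all") snv else nonsyn
    spectrum <- compute_spectrum(spec_input)
    label <- classify_tumor(nrow(nonsyn), spectrum, thresholds)
    pole <- v[!is.na(v$gene) & v$gene == pole_gene &
                !is.na(v$protein_change), ]
    ann <- annotate_pole(pole$protein_change, thresholds)
    row <- data.frame(
      tumor_id = id,
      nonsyn_snv_count = nrow(nonsyn),
      total_snv_count = nrow(snv),
      stringsAsFactors = FALSE
    )
    row[frac_cols] <- as.list(unname(spectrum$fractions))
    row$mutations_per_mb <- mutations_per_mb(nrow(v), footprint_mb)
    row$label <- label
    row$pole_domain_mutations <-
      paste(unique(ann$protein_change[ann$in_exonuclease_domain]),
            collapse = ",")
    row$pole_hotspots <-
      paste(unique(ann$protein_change[ann$is_hotspot]), collapse = ",")
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
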