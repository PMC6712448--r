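# Readers and writers for the tabular and VCF formats the pipeline touches.

VARIANT_COLUMNS <- c(
  "tumor_id", "chrom", "pos", "ref", "alt", "quality", "depth",
  "var_reads_fwd", "var_reads_rev", "avg_clipped_length",
  "avg_pos_as_fraction", "consequence", "gene", "protein_change"
)

CONSEQUENCES <- c("nonsynonymous_SNV", "synonymous_SNV", "nonsense", "other")

CLINICAL_COLUMNS <- c(
  "tumor_id", "age", "sex", "location", "histology", "tumor_size_mm",
  "pT", "pStage", "lymphatic_invasion", "vessel_invasion", "mmr_status"
)

CLINICAL_LEVELS <- list(
  sex = c("man", "woman"),
  location = c("right", "left"),
  histology = c("well_or_mod", "por_or_muc"),
  pT = c("Tis", "T1", "T2", "T3", "T4"),
  pStage = c("0", "I", "II", "III", "IV"),
  mmr_status = c("MMR_P", "MMR_D", "unknown")
)

# Default VCF keys holding the per-variant QC metrics (quality is the QUAL
# column itself). Callers can remap when their caller uses other names.
DEFAULT_QC_KEYS <- c(
  depth = "DP", var_reads_fwd = "SAF", var_reads_rev = "SAR",
  avg_clipped_length = "ACL", avg_pos_as_fraction = "APF"
)

#' Construct and validate a variant table
#'
#' The variant table is the unit flowing through filtering, spectrum
#' computation and catalog building: one row per somatic call per tumor,
#' carrying the caller QC annotations needed by the false-positive filters.
#' Missing QC metrics are held as `NA`, never silently defaulted.
#'
#' @param df data.frame with at least `tumor_id`, `chrom`, `pos`, `ref`,
#'   `alt`; QC metric and annotation columns are added as `NA` when absent.
#' @return A validated `data.frame` with the canonical column set.
#' @export
variant_calls <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("tumor_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("variant table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(VARIANT_COLUMNS, names(df))) {
    df[[col]] <- if (col %in% c("consequence", "gene", "protein_change")) {
      rep(NA_character_, nrow(df))
    } else {
      rep(NA_real_, nrow(df))
    }
  }
  df <- df[, VARIANT_COLUMNS]
  df$tumor_id <- as.character(df$tumor_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  for (col in c("quality", "depth", "var_reads_fwd", "var_reads_rev",
                "avg_clipped_length", "avg_pos_as_fraction")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$consequence <- as.character(df$consequence)
  if (nrow(df) > 0) {
    if (any(df$pos < 1, na.rm = TRUE)) stop("variant pos must be >= 1")
    if (any(df$ref == df$alt)) stop("ref and alt must differ")
    bad_cons <- !is.na(df$consequence) & !(df$consequence %in% CONSEQUENCES)
    if (any(bad_cons)) {
      warning("unknown consequence value(s) mapped to 'other': ",
              paste(unique(df$consequence[bad_cons]), collapse = ", "))
      df$consequence[bad_cons] <- "other"
    }
    neg <- function(v) any(!is.na(v) & v < 0)
    if (neg(df$depth) || neg(df$var_reads_fwd) || neg(df$var_reads_rev)) {
      stop("negative depth or strand read count (corrupt input)")
    }
    both <- !is.na(df$depth) & !is.na(df$var_reads_fwd) &
      !is.na(df$var_reads_rev)
    if (any(both & df$var_reads_fwd + df$var_reads_rev > df$depth)) {
      stop("var_reads_fwd + var_reads_rev exceeds depth")
    }
    frac <- df$avg_pos_as_fraction
    if (any(!is.na(frac) & (frac < 0 | frac > 1))) {
      stop("avg_pos_as_fraction must lie in [0, 1]")
    }
  }
  rownames(df) <- NULL
  df
}

#' Read somatic variants from VCF or TSV
#'
#' For VCF input the five QC metrics are pulled from configurable INFO keys
#' (defaults `DP`, `SAF`, `SAR`, `ACL`, `APF`; quality is the QUAL column)
#' and multi-allelic records are split into one row per alternate allele.
#' Consequence and gene annotations are read from `CONS`/`GENE`/`PCHANGE`
#' INFO keys when present. A record lacking a QC metric carries `NA` for it.
#'
#' @param path Path to the input file.
#' @param format `"vcf"` or `"tsv"`. TSV input must carry a header row with
#'   the canonical variant-table column names.
#' @param tumor_id Sample identifier attached to every record (VCF input;
#'   defaults to the file name without extension).
#' @param qc_keys Named character vector remapping the INFO keys that hold
#'   depth, strand counts, clipped length and position fraction.
#' @return A variant table (see [variant_calls()]).
#' @export
read_variants <- function(path, format = c("tsv", "vcf"), tumor_id = NULL,
                          qc_keys = DEFAULT_QC_KEYS) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    return(variant_calls(df))
  }
  keys <- DEFAULT_QC_KEYS
  keys[names(qc_keys)] <- qc_keys
  if (is.null(tumor_id)) {
    tumor_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {
    # single-record files come back as a bare named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(variant_calls(data.frame(tumor_id = character(0),
                                    chrom = character(0), pos = integer(0),
                                    ref = character(0), alt = character(0))))
  }
  info_raw <- function(key) {
    x <- tryCatch(vcfR::extract.info(vcf, element = key),
                  error = function(e) NULL)
    if (is.null(x) || length(x) != nrow(fix)) rep(NA, nrow(fix)) else x
  }
  info_num <- function(key) suppressWarnings(as.numeric(info_raw(key)))
  info_chr <- function(key) as.character(info_raw(key))
  df <- data.frame(
    tumor_id = tumor_id,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    quality = suppressWarnings(as.numeric(fix$QUAL)),
    depth = info_num(keys[["depth"]]),
    var_reads_fwd = info_num(keys[["var_reads_fwd"]]),
    var_reads_rev = info_num(keys[["var_reads_rev"]]),
    avg_clipped_length = info_num(keys[["avg_clipped_length"]]),
    avg_pos_as_fraction = info_num(keys[["avg_pos_as_fraction"]]),
    consequence = info_chr("CONS"),
    gene = info_chr("GENE"),
    protein_change = info_chr("PCHANGE"),
    stringsAsFactors = FALSE
  )
  # split multi-allelic records: one row per alternate allele
  alts <- strsplit(df$alt, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  df <- df[rep(seq_len(nrow(df)), n_alt), ]
  df$alt <- unlist(alts)
  variant_calls(df)
}

#' Write a variant table as TSV
#' @param variants variant table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a variant table as a minimal VCF v4.2 file
#'
#' QC metrics travel in INFO keys `DP`, `SAF`, `SAR`, `ACL`, `APF`;
#' annotations in `CONS`, `GENE`, `PCHANGE`. Round-trips through
#' [read_variants()] with default key mapping.
#'
#' @param variants variant table for a single tumor.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  if (length(unique(variants$tumor_id)) > 1) {
    stop("write_vcf writes one tumor per file")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=poleclass",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth of coverage\">",
    "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Variant reads forward strand\">",
    "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Variant reads reverse strand\">",
    "##INFO=<ID=ACL,Number=1,Type=Float,Description=\"Average clipped read length\">",
    "##INFO=<ID=APF,Number=1,Type=Float,Description=\"Average variant position as fraction of read\">",
    "##INFO=<ID=CONS,Number=1,Type=String,Description=\"Coding consequence\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  fmt <- function(v) ifelse(is.na(v), ".", as.character(v))
  info_field <- function(key, v, quoteless = TRUE) {
    ifelse(is.na(v), NA_character_, paste0(key, "=", v))
  }
  lines <- character(0)
  if (nrow(variants) > 0) {
    parts <- cbind(
      info_field("DP", variants$depth),
      info_field("SAF", variants$var_reads_fwd),
      info_field("SAR", variants$var_reads_rev),
      info_field("ACL", variants$avg_clipped_length),
      info_field("APF", variants$avg_pos_as_fraction),
      info_field("CONS", variants$consequence),
      info_field("GENE", variants$gene),
      info_field("PCHANGE", variants$protein_change)
    )
    info <- apply(parts, 1, function(p) {
      p <- p[!is.na(p)]
      if (length(p) == 0) "." else paste(p, collapse = ";")
    })
    lines <- paste(variants$chrom, variants$pos, ".", variants$ref,
                   variants$alt, fmt(variants$quality), "PASS", info,
                   sep = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a clinical covariate table
#'
#' One row per patient with the cohort covariates: age, sex, tumor location
#' (right side = cecum through transverse colon), histology, size, pT,
#' pStage, lymphatic and vessel invasion, and mismatch-repair status. MMR
#' status is typically known for only a minority of tumors; a missing
#' `mmr_status` column (or empty values) yields `"unknown"`.
#'
#' @param path TSV path with a header row naming the covariates.
#' @return Validated clinical `data.frame`.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  clinical_records(df)
}

#' Validate a clinical covariate data.frame
#' @param df data.frame with the clinical columns; `mmr_status` optional.
#' @return validated data.frame.
#' @export
clinical_records <- function(df) {
  stopifnot(is.data.frame(df))
  if (!("mmr_status" %in% names(df))) df$mmr_status <- "unknown"
  df$mmr_status[is.na(df$mmr_status)] <- "unknown"
  missing_cols <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("clinical table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, CLINICAL_COLUMNS]
  df$tumor_id <- as.character(df$tumor_id)
  df$age <- as.integer(df$age)
  df$tumor_size_mm <- as.integer(df$tumor_size_mm)
  for (col in names(CLINICAL_LEVELS)) {
    df[[col]] <- as.character(df[[col]])
    bad <- which(!(df[[col]] %in% CLINICAL_LEVELS[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("clinical table: value '%s' not allowed in column '%s' (row %d)",
                   df[[col]][bad[1]], col, bad[1]))
    }
  }
  for (col in c("lymphatic_invasion", "vessel_invasion")) {
    v <- df[[col]]
    if (is.character(v)) v <- tolower(v) %in% c("yes", "true", "1")
    df[[col]] <- as.logical(v)
  }
  if (any(df$age < 0 | df$age > 120, na.rm = TRUE)) {
    stop("age out of range [0, 120]")
  }
  if (any(df$tumor_size_mm <= 0, na.rm = TRUE)) {
    stop("tumor_size_mm must be positive")
  }
  rownames(df) <- NULL
  df
}

#' Write a clinical table as TSV
#' @param clinical clinical data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  out <- clinical
  for (col in c("lymphatic_invasion", "vessel_invasion")) {
    out[[col]] <- ifelse(out[[col]], "yes", "no")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a reference signature matrix
#'
#' Tab-separated, first column `Context` holding the 96 trinucleotide labels
#' (e.g. `"A[C>A]A"`), remaining columns one reference signature each.
#' Rows are reordered into the canonical context order; each signature
#' column must sum to 1 within 1e-3.
#'
#' @param path TSV path.
#' @return A `signature_matrix` object: list with `contexts` (96 labels),
#'   `names` (signature names) and `weights` (96 x K numeric matrix).
#' @export
read_signature_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (names(df)[1] != "Context") {
    stop("signature matrix: first column must be 'Context'")
  }
  w <- as.matrix(df[, -1, drop = FALSE])
  rownames(w) <- df$Context
  signature_matrix(w)
}

#' Construct and validate a signature matrix
#'
#' @param weights 96 x K nonnegative matrix; rownames are context labels,
#'   colnames are signature names. Rows may arrive in any order.
#' @return `signature_matrix` object with rows in canonical context order.
#' @export
signature_matrix <- function(weights) {
  stopifnot(is.matrix(weights))
  ctx <- context_labels_96()
  if (nrow(weights) != 96) {
    stop("expected 96 contexts, got ", nrow(weights))
  }
  if (is.null(rownames(weights))) {
    rownames(weights) <- ctx
  }
  if (!setequal(rownames(weights), ctx)) {
    stop("context labels do not match the canonical 96-context set")
  }
  weights <- weights[ctx, , drop = FALSE]
  if (is.null(colnames(weights))) {
    stop("signature matrix must name its signatures (column names)")
  }
  if (anyDuplicated(colnames(weights))) {
    stop("signature names are not unique")
  }
  if (any(weights < 0)) stop("signature weights must be nonnegative")
  sums <- colSums(weights)
  off <- which(abs(sums - 1) > 1e-3)
  if (length(off) > 0) {
    stop("signature column does not sum to 1: ",
         paste(colnames(weights)[off], collapse = ", "))
  }
  structure(list(contexts = ctx, names = colnames(weights),
                 weights = weights),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("signature_matrix: 96 contexts x", length(x$names), "signatures\n")
  cat("signatures:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Write a signature matrix as TSV
#' @param sigs `signature_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(sigs, path) {
  df <- data.frame(Context = sigs$contexts, sigs$weights,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-patient expression table
#'
#' Expected columns: `tumor_id`, `gene`, `tumor_value`, `normal_value`,
#' `fold_change` (log2 scale; fold change = tumor minus matched normal).
#' If `fold_change` is absent it is computed from the two value columns.
#'
#' @param path TSV path.
#' @return data.frame of expression records.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("tumor_id", "gene")
  if (!all(required %in% names(df))) {
    stop("expression table needs columns tumor_id and gene")
  }
  if (!("fold_change" %in% names(df))) {
    if (!all(c("tumor_value", "normal_value") %in% names(df))) {
      stop("expression table needs fold_change or tumor_value/normal_value")
    }
    df$fold_change <- df$tumor_value - df$normal_value
  }
  df
}
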