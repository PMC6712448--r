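# Orchestration: filter -> classify -> signatures -> compare as one
# reproducible run with a config object and a run manifest.

#' Build a pipeline run configuration
#'
#' All classification thresholds live here with their standard defaults
#' (hypermutator count 500, C>A minimum 0.20, C>G maximum 0.03,
#' exonuclease domain 86-427, hotspots 286/297/367/411, signature cutoff
#' 0.06); nothing is hard-coded in the operations, since the hypermutator
#' definition varies between studies.
#'
#' @param variants path to a variant TSV (all tumors, `tumor_id` column) or
#'   a directory of per-tumor VCFs.
#' @param out_dir output directory (created if needed).
#' @param footprint_mb callable exome footprint in Mb (required).
#' @param clinical,expression,signatures,blacklist optional input paths.
#' @param spectrum_set `"all"` or `"nonsynonymous"` (see
#'   [build_tumor_profiles()]).
#' @param signature_cutoff exposure cutoff for [refit_exposures()].
#' @param seed integer seed recorded in the manifest (the analysis stages
#'   are deterministic; the seed matters only when simulation feeds them).
#' @param thresholds see [classification_thresholds()].
#' @return `run_config` object.
#' @export
run_config <- function(variants, out_dir, footprint_mb,
                       clinical = NULL, expression = NULL,
                       signatures = NULL, blacklist = NULL,
                       spectrum_set = "all", signature_cutoff = 0.06,
                       seed = 1L,
                       thresholds = classification_thresholds()) {
  if (missing(footprint_mb)) stop("footprint_mb is required configuration")
  stopifnot(thresholds$exo_domain[1] < thresholds$exo_domain[2],
            thresholds$hypermutator_count > 0)
  structure(list(
    paths = list(variants = variants, clinical = clinical,
                 expression = expression, signatures = signatures,
                 blacklist = blacklist),
    out_dir = out_dir,
    footprint_mb = footprint_mb,
    spectrum_set = spectrum_set,
    signature_cutoff = signature_cutoff,
    seed = as.integer(seed),
    thresholds = thresholds
  ), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Reads the configured inputs, applies the false-positive filters, builds
#' tumor profiles and the three-way classification, refits signature
#' exposures for hypermutated tumors (when a signature matrix and a
#' reference genome are supplied), builds the clinicopathological
#' comparison and per-gene expression comparisons, and writes everything
#' plus a manifest (config, input checksums, versions) to `out_dir`.
#' Deterministic given config and inputs.
#'
#' @param config `run_config` object.
#' @param genome optional named character vector of contig sequences (or a
#'   context-accessor function) for catalog building; without it the
#'   signature stage is skipped with a notice.
#' @param expression_genes genes to compare across groups (default: all
#'   genes in the expression table).
#' @return Invisibly, a list with the in-memory results (`verdicts`,
#'   `profiles`, `exposures`, `comparison`, `expression_p`, `manifest`).
#' @export
run_pipeline <- function(config, genome = NULL, expression_genes = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- config$paths

  variants <- stage("read_variants", {
    p <- paths$variants
    if (dir.exists(p)) {
      files <- list.files(p, pattern = "\\.vcf$", full.names = TRUE)
      if (length(files) == 0) stop("no .vcf files in ", p)
      do.call(rbind, lapply(files, read_variants, format = "vcf"))
    } else {
      read_variants(p, format = "tsv")
    }
  })
  bl <- stage("read_blacklist", {
    if (is.null(paths$blacklist)) blacklist() else
      read_blacklist(paths$blacklist)
  })
  verdicts <- stage("qc_filter", apply_fp_filters(variants, bl))
  kept <- kept_variants(verdicts)
  filter_path <- file.path(config$out_dir, "filter_report.tsv")
  utils::write.table(
    verdicts[, c("tumor_id", "chrom", "pos", "ref", "alt", "kept",
                 "failed_criteria")],
    filter_path, sep = "\t", quote = FALSE, row.names = FALSE)

  profiles <- stage("classify", {
    build_tumor_profiles(kept, footprint_mb = config$footprint_mb,
                         spectrum_set = config$spectrum_set,
                         thresholds = config$thresholds)
  })
  profiles_path <- file.path(config$out_dir, "profiles.tsv")
  utils::write.table(profiles, profiles_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  exposures <- NULL
  exposures_path <- NULL
  if (is.null(paths$signatures) || is.null(genome)) {
    message("signature stage skipped: no signature matrix and/or genome supplied")
  } else {
    exposures <- stage("signature_refit", {
      sigs <- read_signature_matrix(paths$signatures)
      hyper <- profiles$tumor_id[profiles$label != "nonhypermutator"]
      res <- lapply(hyper, function(id) {
        cat96 <- build_catalog(kept[kept$tumor_id == id, ], genome)
        refit_exposures(cat96, sigs, cutoff = config$signature_cutoff)
      })
      stats::setNames(res, hyper)
    })
    if (length(exposures) > 0) {
      sig_names <- read_signature_matrix(paths$signatures)$names
      mat <- t(vapply(exposures, function(e) {
        w <- stats::setNames(numeric(length(sig_names)), sig_names)
        w[names(e$weights)] <- e$weights
        w
      }, numeric(length(sig_names))))
      exp_df <- data.frame(tumor_id = names(exposures), mat,
                           reconstruction_error = vapply(
                             exposures, `[[`, numeric(1),
                             "reconstruction_error"),
                           check.names = FALSE)
      exposures_path <- file.path(config$out_dir, "exposures.tsv")
      utils::write.table(exp_df, exposures_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }

  comparison <- NULL
  if (!is.null(paths$clinical)) {
    comparison <- stage("group_comparison", {
      build_group_comparison(profiles, read_clinical_table(paths$clinical))
    })
    utils::write.table(comparison$table,
                       file.path(config$out_dir, "group_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  expression_p <- NULL
  if (!is.null(paths$expression)) {
    expression_p <- stage("expression_comparison", {
      expr <- read_expression_table(paths$expression)
      expr <- expr[expr$tumor_id %in% profiles$tumor_id, ]
      labels <- stats::setNames(profiles$label, profiles$tumor_id)
      genes <- if (is.null(expression_genes)) unique(expr$gene) else
        expression_genes
      do.call(rbind, lapply(genes, function(g) {
        p <- tryCatch(compare_expression_by_group(expr, labels, g)$p_values,
                      error = function(e) {
                        message("expression comparison for ", g,
                                " not computable: ", conditionMessage(e))
                        c(NH_vs_CH = NA_real_, NH_vs_PC = NA_real_,
                          CH_vs_PC = NA_real_)
                      })
        data.frame(gene = g, comparison = names(p),
                   p_value = round(unname(p), 3),
                   stringsAsFactors = FALSE)
      }))
    })
    utils::write.table(expression_p,
                       file.path(config$out_dir, "expression_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- stage("manifest", {
    input_paths <- Filter(Negate(is.null), paths)
    checksums <- vapply(input_paths, function(p) {
      if (dir.exists(p)) {
        files <- list.files(p, full.names = TRUE)
        unname(tools::md5sum(paste(sort(tools::md5sum(files)),
                                   collapse = "")))
        paste(sort(unname(tools::md5sum(files))), collapse = ",")
      } else {
        unname(tools::md5sum(p))
      }
    }, character(1))
    cfg <- config
    cfg_file <- tempfile()
    dput(unclass(cfg), file = cfg_file)
    m <- list(
      package_version = as.character(utils::packageVersion("poleclass")),
      r_version = R.version.string,
      config = unclass(config),
      config_md5 = unname(tools::md5sum(cfg_file)),
      input_md5 = as.list(checksums)
    )
    unlink(cfg_file)
    jsonlite::write_json(m, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    m
  })

  invisible(list(verdicts = verdicts, profiles = profiles,
                 exposures = exposures, comparison = comparison,
                 expression_p = expression_p, manifest = manifest))
}
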