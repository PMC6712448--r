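# Pyrimidine-normalized substitution classes and the canonical 96-context order.

#' The six pyrimidine-normalized substitution classes
#'
#' Somatic single-base substitutions are reported on the pyrimidine strand,
#' collapsing the 12 strand-specific changes into six classes
#' (C>A, C>G, C>T, T>A, T>C, T>G).
#'
#' @return Character vector of the six class labels, in canonical order.
#' @export
sub_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' Canonical 96 trinucleotide-context labels
#'
#' Labels of the form `"A[C>A]A"`: the substitution class flanked by its 5'
#' and 3' bases. Order is the standard one used for signature matrices:
#' six class blocks (C>A, C>G, C>T, T>A, T>C, T>G), each holding the 16
#' flanking-base combinations in lexicographic order (5' major, 3' minor).
#'
#' @return Character vector of length 96.
#' @export
context_labels_96 <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(sub_classes(), function(cls) {
    as.vector(t(outer(bases, bases, function(f, t) {
      paste0(f, "[", cls, "]", t)
    })))
  }), use.names = FALSE)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse-complement of a DNA string (vectorized)
#' @param x character vector of DNA strings (ACGT).
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE), function(b) {
    paste(rev(b), collapse = "")
  }, character(1))
}

#' Pyrimidine-normalized substitution class of a single-base change
#'
#' Substitutions with a purine reference base are complemented onto the
#' pyrimidine strand (G>T becomes C>A, A>G becomes T>C, and so on), so that
#' every SNV maps to exactly one of six classes.
#'
#' @param ref,alt Single reference and alternate bases (A, C, G or T).
#'   Vectorized; `ref[i] != alt[i]` is required.
#' @return Character vector of class labels from [sub_classes()].
#' @examples
#' substitution_class("C", "A")  # "C>A"
#' substitution_class("G", "T")  # "C>A" (complemented)
#' @export
substitution_class <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (length(ref) != length(alt)) {
    stop("ref and alt must have the same length")
  }
  ok <- ref %in% names(.complement) & alt %in% names(.complement)
  if (!all(ok)) {
    stop("non-ACGT base in substitution: ",
         paste(unique(paste0(ref[!ok], ">", alt[!ok])), collapse = ", "))
  }
  if (any(ref == alt)) {
    stop("ref and alt must differ")
  }
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, .complement[ref], ref)
  a <- ifelse(purine, .complement[alt], alt)
  paste0(r, ">", a)
}

#' Is a variant a single-nucleotide variant?
#' @param ref,alt character vectors of ref/alt alleles.
#' @return logical vector.
#' @keywords internal
is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    toupper(ref) %in% c("A", "C", "G", "T") &
    toupper(alt) %in% c("A", "C", "G", "T") &
    toupper(ref) != toupper(alt)
}
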