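#' Genotype classes at a biallelic site
#'
#' Per-sample genotype calls are reduced to five classes, written the way a
#' VCF (and the original filtering UI) writes them: `"0/0"` homozygous
#' reference, `"0/1"` heterozygous, `"1/1"` homozygous alternative, `"./."`
#' missing (low-quality or low-coverage call), and `"other"` for anything
#' that does not fit the biallelic model at the record under consideration
#' (indices of a different ALT allele, half-calls such as `"0/."`).
#'
#' @format A character vector of the five class labels.
#' @export
gt_classes <- c("0/0", "0/1", "1/1", "./.", "other")

#' The three called genotype classes (no missing, no other)
#' @rdname gt_classes
#' @export
gt_called <- c("0/0", "0/1", "1/1")

#' Classify raw VCF genotype strings
#'
#' Maps GT strings to genotype classes relative to one ALT allele of the
#' record. Phased separators (`|`) are equivalent to unphased (`/`): phase
#' never changes the class. Allele indices other than 0 and `alt_index`
#' (e.g. `"1/2"` when classifying against ALT 1), and half-calls, map to
#' `"other"`. `"."`, `"./."` and `NA` map to `"./."`.
#'
#' @param gt Character vector of GT strings (the GT subfield only).
#' @param alt_index Integer, which ALT allele of the original record this
#'   biallelic view refers to (1 for the first ALT).
#' @return Character vector of classes, same length as `gt`.
#' @examples
#' classify_gt(c("0/0", "0|1", "1/1", "./.", "1/2"))
#' @export
classify_gt <- function(gt, alt_index = 1L) {
  stopifnot(length(alt_index) == 1L, alt_index >= 1L)
  gt <- as.character(gt)
  out <- rep("other", length(gt))
  norm <- gsub("|", "/", gt, fixed = TRUE)
  missing <- is.na(norm) | norm == "." | norm == "./."
  out[missing] <- "./."
  parts <- strsplit(norm[!missing & grepl("^[0-9]+/[0-9]+$", norm)], "/", fixed = TRUE)
  idx <- which(!missing & grepl("^[0-9]+/[0-9]+$", norm))
  if (length(idx)) {
    a <- as.integer(vapply(parts, `[`, "", 1L))
    b <- as.integer(vapply(parts, `[`, "", 2L))
    cls <- rep("other", length(idx))
    cls[a == 0L & b == 0L] <- "0/0"
    cls[(a == 0L & b == alt_index) | (a == alt_index & b == 0L)] <- "0/1"
    cls[a == alt_index & b == alt_index] <- "1/1"
    out[idx] <- cls
  }
  out
}

# Render a genotype class back to a VCF GT string ("other" has no faithful
# biallelic rendering and is refused).
gt_to_vcf <- function(class) {
  stopifnot(all(class %in% setdiff(gt_classes, "other")))
  class
}
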