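#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

fixed_variant_cols <- c("chrom", "pos", "ref", "alt", "rs_id")

new_variant_tbl <- function(df, samples) {
  df <- as_tibble(df)
  clash <- intersect(samples, fixed_variant_cols)
  if (length(clash)) {
    abort(paste0("sample names clash with reserved columns: ",
                 paste(clash, collapse = ", ")))
  }
  structure(df, samples = samples,
            class = c("variant_tbl", class(as_tibble(df))))
}

#' Sample roster of a variant table
#'
#' @param x A variant table as returned by [read_vcf()] or
#'   [simulate_family()], or any tibble carrying per-sample genotype columns.
#' @return Character vector of sample names, in VCF column order.
#' @export
variant_samples <- function(x) {
  s <- attr(x, "samples")
  if (!is.null(s)) return(s)
  setdiff(names(x), c(fixed_variant_cols,
                      "position", "change", "gene", "consequence",
                      "consequence_terms", "aa_change",
                      grep("^maf_", names(x), value = TRUE),
                      "sift", "polyphen", "phenotype"))
}

# dplyr verbs strip subclasses; reattach roster + class after manipulation
restore_variant_tbl <- function(df, template) {
  new_variant_tbl(df, variant_samples(template))
}

#' Read a multi-sample VCF into a variant table
#'
#' Reads a VCF v4.x (plain or bgzipped) and returns one row per data line
#' per ALT allele: multi-allelic records are split, and for the row
#' representing ALT allele *k*, genotypes whose allele indices are not a
#' subset of \{0, k\} are classed `"other"`. Only the GT subfield of FORMAT
#' is interpreted. Samples with no GT field become `"./."` with a warning.
#'
#' @param path Path to the VCF file.
#' @return A `variant_tbl`: a tibble with columns `chrom`, `pos`, `ref`,
#'   `alt`, `rs_id` (NA when the ID column is "."), then one
#'   genotype-class column per sample in VCF column order (see
#'   [gt_classes]). The roster is also available via [variant_samples()].
#' @examples
#' vcf <- system.file("extdata", "trio_demo.vcf", package = "varsieve")
#' read_vcf(vcf)
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
    error = function(e) abort(paste0("malformed VCF '", path, "': ",
                                     conditionMessage(e)))
  )
  gt_mat <- v@gt
  samples <- setdiff(colnames(gt_mat), "FORMAT")
  if (is.null(samples) || length(samples) == 0L) {
    abort(paste0("malformed VCF header in '", path,
                 "': no sample columns on the #CHROM line"))
  }
  fix <- v@fix
  if (nrow(fix) == 0L) {
    empty <- tibble(chrom = character(), pos = integer(),
                    ref = character(), alt = character(),
                    rs_id = character())
    for (s in samples) empty[[s]] <- character()
    return(new_variant_tbl(empty, samples))
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  no_gt <- !grepl("(^|:)GT(:|$)", gt_mat[, "FORMAT"])
  if (any(no_gt)) {
    warn(paste0(sum(no_gt), " record(s) lack a GT field; their genotypes ",
                "are treated as missing"))
  }

  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  row_idx <- rep(seq_len(nrow(fix)), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

  out <- tibble(
    chrom = fix[row_idx, "CHROM"],
    pos = as.integer(fix[row_idx, "POS"]),
    ref = fix[row_idx, "REF"],
    alt = unlist(alt_list, use.names = FALSE),
    rs_id = unname(ifelse(is.na(fix[row_idx, "ID"]) | fix[row_idx, "ID"] == ".",
                          NA_character_, fix[row_idx, "ID"]))
  )
  for (s in samples) {
    out[[s]] <- classify_gt(gt_raw[row_idx, s], alt_index = 1L)
    # rows for the 2nd+ ALT of a multi-allelic record classify against
    # their own allele index
    later <- alt_idx > 1L
    if (any(later)) {
      out[[s]][later] <- vapply(which(later), function(i) {
        classify_gt(gt_raw[row_idx[i], s], alt_index = alt_idx[i])
      }, "")
    }
  }
  dup <- duplicated(out[, c("chrom", "pos", "ref", "alt")])
  if (any(dup)) {
    warn(paste0(sum(dup), " duplicate (chrom,pos,ref,alt) record(s) dropped"))
    out <- out[!dup, , drop = FALSE]
  }
  new_variant_tbl(out, samples)
}

#' Parse region strings of the form "chrom:start-end"
#'
#' Coordinates are 1-based and inclusive at both ends, matching VCF
#' positions. Whitespace and thousands-free digits only; `start` must not
#' exceed `end`.
#'
#' @param text Character vector of region strings.
#' @return A tibble with columns `chrom`, `start`, `end`, one row per input.
#' @examples
#' parse_region(c("1:500-1500", "X:100-100"))
#' @export
parse_region <- function(text) {
  text <- trimws(as.character(text))
  m <- regmatches(text, regexec("^([^:[:space:]]+)\\s*:\\s*([0-9]+)\\s*-\\s*([0-9]+)$", text))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) {
    abort(paste0("cannot parse region string(s): ",
                 paste(text[bad], collapse = ", "),
                 " (expected \"chrom:start-end\")"))
  }
  out <- tibble(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L))
  )
  inv <- out$start > out$end | out$start < 1L
  if (any(inv)) {
    abort(paste0("invalid region bounds (start > end or start < 1): ",
                 paste(text[inv], collapse = ", ")))
  }
  out
}

#' Export filtered, annotated variant rows as CSV
#'
#' Writes an RFC-4180-style CSV (comma delimiter, double-quote escaping, LF
#' endings) with a header row. As in the interactive tool's export dialog,
#' the caller selects which columns to save and in what order.
#'
#' @param rows A tibble of variant rows (typically the `rows` element of a
#'   [run_cascade()] result, or [annotate_variants()] output).
#' @param path Output file path.
#' @param columns Character vector of column names to write, in order.
#'   Default: all atomic columns of `rows`.
#' @return `path`, invisibly.
#' @export
write_variant_csv <- function(rows, path, columns = NULL) {
  rows <- as_tibble(rows)
  atomic <- names(rows)[!vapply(rows, is.list, TRUE)]
  if (is.null(columns)) columns <- atomic
  unknown <- setdiff(columns, names(rows))
  if (length(unknown)) {
    abort(paste0("unknown column(s): ", paste(unknown, collapse = ", "),
                 "; valid columns are: ", paste(atomic, collapse = ", ")))
  }
  readr::write_csv(rows[, columns, drop = FALSE], path, na = "")
  invisible(path)
}

#' Write a variant table back out as VCF
#'
#' Emits a minimal VCF v4.2 with GT-only FORMAT, used by the simulator and
#' for filtered pass-through output. Records containing `"other"` genotype
#' classes cannot be rendered and raise an error.
#'
#' @param x A `variant_tbl`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  samples <- variant_samples(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  writeLines(hdr, con, sep = "\n")
  if (nrow(x)) {
    gt <- vapply(samples, function(s) gt_to_vcf(x[[s]]), character(nrow(x)))
    if (nrow(x) == 1L) gt <- matrix(gt, nrow = 1L)
    lines <- paste(x$chrom, x$pos,
                   ifelse(is.na(x$rs_id), ".", x$rs_id),
                   x$ref, x$alt, ".", ".", ".", "GT",
                   apply(gt, 1L, paste, collapse = "\t"),
                   sep = "\t")
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' @export
print.variant_tbl <- function(x, ...) {
  cat("# A variant table: ", nrow(x), " record(s), ",
      length(variant_samples(x)), " sample(s)\n", sep = "")
  NextMethod()
}
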