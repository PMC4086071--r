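#' Segregation filter with missing-call tolerance
#'
#' Retains the records whose per-sample genotypes are compatible with the
#' inheritance pattern. With a tolerance of N missing values, records where
#' every constrained sample either fulfils its zygosity criterion or is
#' missing are collected first; of those, only records with N or fewer
#' missing constrained samples are kept. `"other"` genotype classes
#' (multi-allelic indices, half-calls) never match an allowed set and do
#' not count as missing. Samples absent from the pattern are ignored
#' entirely. Record order is preserved.
#'
#' @param x A `variant_tbl` (possibly already annotated).
#' @param pattern A [seg_pattern()]; must validate against the roster of
#'   `x` (see [validate_pattern()]).
#' @return The surviving subset of `x`.
#' @examples
#' ped <- pedigree(id = c("FA", "MO", "CH"),
#'                 father = c(NA, NA, "FA"), mother = c(NA, NA, "MO"),
#'                 affected = c("unaffected", "unaffected", "affected"))
#' pat <- pattern_recessive(ped)
#' @export
filter_segregation <- function(x, pattern) {
  report <- validate_pattern(pattern, variant_samples(x))
  if (nrow(report)) {
    abort(paste0("segregation pattern invalid for this variant table: ",
                 paste(ifelse(is.na(report$sample), report$problem,
                              paste0(report$sample, ": ", report$problem)),
                       collapse = "; ")))
  }
  if (!nrow(x)) return(x)
  ok <- rep(TRUE, nrow(x))
  n_miss <- rep(0L, nrow(x))
  for (i in seq_len(nrow(pattern))) {
    g <- x[[pattern$sample[i]]]
    is_missing <- g == "./."
    ok <- ok & (g %in% pattern$allowed[[i]] | is_missing)
    n_miss <- n_miss + as.integer(is_missing)
  }
  restore_variant_tbl(x[ok & n_miss <= max_missing(pattern), , drop = FALSE], x)
}

#' Consequence-type filter
#'
#' A variant survives if at least one of its transcript-level consequence
#' terms is in the allowed set (any-transcript semantics). The initial
#' preferred candidates in exome prioritization are the severe classes,
#' missense (historically "non-synonymous") and stop-lost variants.
#'
#' @param x Annotated rows ([annotate_variants()] output).
#' @param allowed_types Non-empty character vector of SO terms or legacy
#'   aliases (see [so_terms], [so_aliases]); unknown terms are an error.
#' @return The surviving subset of `x`.
#' @export
filter_consequence <- function(x, allowed_types) {
  if (!length(allowed_types)) abort("`allowed_types` must be non-empty")
  allowed_types <- normalize_consequence(allowed_types)
  terms <- consequence_terms_of(x)
  keep <- vapply(terms, function(tt) any(tt %in% allowed_types), TRUE)
  restore_variant_tbl(x[keep, , drop = FALSE], x)
}

consequence_terms_of <- function(x) {
  if ("consequence_terms" %in% names(x)) return(x$consequence_terms)
  if ("consequence" %in% names(x)) {
    if (!nrow(x)) return(list())
    cq <- as.character(x$consequence)
    return(lapply(strsplit(ifelse(is.na(cq), "", cq), "|", fixed = TRUE),
                  function(v) v[nzchar(v)]))
  }
  abort("rows carry no consequence annotation; annotate the table first")
}

#' Allelic-frequency (MAF) filter
#'
#' Discards variants with a relatively high minor allele frequency in the
#' selected reference populations — common variants are unlikely to cause
#' rare hereditary disorders. A variant survives if the maximum MAF across
#' the selected study/population columns is strictly below the threshold,
#' or if it has no MAF annotation in any selected column (novel variants
#' always pass).
#'
#' @param x Annotated rows.
#' @param threshold MAF threshold in [0, 0.5]; strict comparison.
#' @param studies Subset of `c("kg", "esp")` (1000 Genomes, Exome
#'   Sequencing Project); non-empty.
#' @param populations For 1000 Genomes, subset of
#'   `c("all", "eur", "asn", "afr", "amr")` — the combined panel and the
#'   four continental ancestry groups.
#' @return The surviving subset of `x`.
#' @export
filter_frequency <- function(x, threshold, studies = c("kg", "esp"),
                             populations = "all") {
  studies <- match.arg(studies, several.ok = TRUE)
  populations <- match.arg(populations,
                           c("all", "eur", "asn", "afr", "amr"),
                           several.ok = TRUE)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 0.5) {
    abort("`threshold` must be a single MAF value in [0, 0.5]")
  }
  cols <- character()
  if ("kg" %in% studies) cols <- c(cols, paste0("maf_kg_", populations))
  if ("esp" %in% studies) cols <- c(cols, "maf_esp")
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols)) {
    abort(paste0("rows lack MAF column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(as_tibble(x)[, cols, drop = FALSE])
  has_any <- rowSums(!is.na(m)) > 0L
  max_maf <- suppressWarnings(apply(m, 1L, max, na.rm = TRUE))
  keep <- !has_any | max_maf < threshold
  restore_variant_tbl(x[keep, , drop = FALSE], x)
}

#' Region filter
#'
#' Keeps variants whose position falls inside at least one of the given
#' regions; both endpoints are inclusive, coordinates 1-based as in the
#' VCF. Useful when linkage studies point at particular genomic intervals.
#'
#' @param x A `variant_tbl`.
#' @param regions Tibble with columns `chrom`, `start`, `end` (see
#'   [parse_region()]), or a character vector of `"chrom:start-end"`
#'   strings; non-empty.
#' @return The surviving subset of `x`.
#' @export
filter_region <- function(x, regions) {
  if (is.character(regions)) regions <- parse_region(regions)
  if (!nrow(regions)) abort("`regions` must be non-empty")
  keep <- rep(FALSE, nrow(x))
  for (i in seq_len(nrow(regions))) {
    keep <- keep | (x$chrom == regions$chrom[i] &
                      x$pos >= regions$start[i] & x$pos <= regions$end[i])
  }
  restore_variant_tbl(x[keep, , drop = FALSE], x)
}

#' Gene filter
#'
#' Keeps variants annotated to any of the named genes; matching is exact
#' but case-insensitive, and a variant hitting several genes survives if
#' any of them is listed.
#'
#' @param x Annotated rows with a `gene` column.
#' @param genes Non-empty character vector of gene names.
#' @return The surviving subset of `x`.
#' @export
filter_gene <- function(x, genes) {
  if (!length(genes)) abort("`genes` must be non-empty")
  if (!"gene" %in% names(x)) {
    abort("rows carry no gene annotation; annotate the table first")
  }
  if (!nrow(x)) return(x)
  genes <- toupper(as.character(genes))
  gene_col <- as.character(x$gene)
  keep <- vapply(strsplit(ifelse(is.na(gene_col), "", gene_col), "|", fixed = TRUE),
                 function(g) any(toupper(g) %in% genes), TRUE)
  restore_variant_tbl(x[keep, , drop = FALSE], x)
}

#' Run a consecutive filter cascade
#'
#' Applies the configured filters in the declared order, each to the
#' survivors of the previous one, and records the surviving-record count
#' after every step. Because every filter is a pure intersective set
#' operation, the final survivor set does not depend on the order — but the
#' per-step counts (the "funnel") do, and are the main per-run report.
#'
#' @param x A `variant_tbl`.
#' @param store An `annotation_store`, or NULL if no annotation-dependent
#'   filter (consequence, frequency, gene) is configured and no annotated
#'   output is wanted.
#' @param steps Named list of filter configurations, applied in order. The
#'   recognized names and their values:
#'   \describe{
#'     \item{segregation}{a [seg_pattern()]}
#'     \item{consequence}{character vector of allowed SO terms}
#'     \item{frequency}{list with `threshold` and optionally `studies`,
#'       `populations` (see [filter_frequency()])}
#'     \item{region}{regions tibble or `"chrom:start-end"` strings}
#'     \item{gene}{character vector of gene names}
#'   }
#' @return An object of class `var_cascade`: a list with `rows` (the
#'   surviving annotated rows) and `counts` (tibble of `step`,
#'   `n_survivors`). Use [tidy()][generics::tidy] / [glance()]
#'   [generics::glance] / `autoplot()` on it.
#' @export
run_cascade <- function(x, store = NULL, steps = list()) {
  known <- c("segregation", "consequence", "frequency", "region", "gene")
  unknown <- setdiff(names(steps), known)
  if (length(unknown)) {
    abort(paste0("unknown filter step(s): ", paste(unknown, collapse = ", "),
                 "; recognized: ", paste(known, collapse = ", ")))
  }
  needs_annot <- any(c("consequence", "frequency", "gene") %in% names(steps))
  if (needs_annot && is.null(store)) {
    abort("consequence, frequency and gene filters need an annotation store")
  }
  rows <- if (!is.null(store)) annotate_variants(x, store) else x
  counts <- tibble(step = "input", n_survivors = nrow(rows))
  for (nm in names(steps)) {
    cfg <- steps[[nm]]
    rows <- switch(
      nm,
      segregation = filter_segregation(rows, cfg),
      consequence = filter_consequence(rows, cfg),
      frequency = do.call(filter_frequency, c(list(rows), cfg)),
      region = filter_region(rows, cfg),
      gene = filter_gene(rows, cfg)
    )
    counts <- dplyr::bind_rows(counts,
                               tibble(step = nm, n_survivors = nrow(rows)))
  }
  structure(list(rows = rows, counts = counts, steps = steps),
            class = "var_cascade")
}

#' @export
print.var_cascade <- function(x, ...) {
  cat("# Filter cascade:", nrow(x$counts) - 1L, "step(s)\n")
  for (i in seq_len(nrow(x$counts))) {
    cat("  ", format(x$counts$step[i], width = 12), x$counts$n_survivors[i], "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-step survivor counts of a cascade
#' @param x A `var_cascade`.
#' @param ... Unused.
#' @return Tibble with `step`, `n_survivors`, `n_removed`.
#' @export
tidy.var_cascade <- function(x, ...) {
  dplyr::mutate(x$counts,
                n_removed = dplyr::lag(.data$n_survivors, default = .data$n_survivors[1]) -
                  .data$n_survivors)
}

#' One-row cascade summary
#' @param x A `var_cascade`.
#' @param ... Unused.
#' @return Tibble with `n_input`, `n_steps`, `n_survivors`, `prop_retained`.
#' @export
glance.var_cascade <- function(x, ...) {
  n0 <- x$counts$n_survivors[1]
  nk <- x$counts$n_survivors[nrow(x$counts)]
  tibble(n_input = n0, n_steps = nrow(x$counts) - 1L, n_survivors = nk,
         prop_retained = if (n0 > 0) nk / n0 else NA_real_)
}

#' Funnel plot of a filter cascade
#' @param object A `var_cascade`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.var_cascade <- function(object, ...) {
  d <- object$counts
  d$step <- factor(d$step, levels = d$step)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$n_survivors)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_survivors), vjust = -0.4) +
    ggplot2::labs(x = "filter step", y = "surviving variants",
                  title = "Consecutive filtering funnel") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Summary statistics of a variant data set
#'
#' The per-run overview: samples analyzed, total record count, counts by
#' variant type (SNV vs indel, by allele length) and, when an annotation
#' store is given, the distribution across consequence types (a variant
#' counts once for each distinct term it carries, so these counts can sum
#' to more than the variant total).
#'
#' @param x A `variant_tbl`.
#' @param store Optional `annotation_store`.
#' @return An object of class `var_summary`: list with `samples`,
#'   `n_variants`, `by_type` (tibble) and `by_consequence` (tibble, empty
#'   without a store).
#' @export
summarize_variants <- function(x, store = NULL) {
  type <- ifelse(nchar(x$ref) == 1L & nchar(x$alt) == 1L, "SNV", "indel")
  by_type <- dplyr::count(tibble(type = type), .data$type, name = "n")
  by_consequence <- tibble(consequence = character(), n = integer())
  if (!is.null(store) && nrow(x)) {
    terms <- consequence_terms_of(annotate_variants(x, store))
    flat <- unlist(terms, use.names = FALSE)
    if (length(flat)) {
      by_consequence <- dplyr::arrange(
        dplyr::count(tibble(consequence = flat), .data$consequence, name = "n"),
        dplyr::desc(.data$n))
    }
  }
  structure(list(samples = variant_samples(x), n_variants = nrow(x),
                 by_type = by_type, by_consequence = by_consequence),
            class = "var_summary")
}

#' @export
print.var_summary <- function(x, ...) {
  cat("# Variant data set summary\n")
  cat("  samples: ", paste(x$samples, collapse = ", "), "\n", sep = "")
  cat("  variants:", x$n_variants, "\n")
  if (nrow(x$by_type)) {
    for (i in seq_len(nrow(x$by_type))) {
      cat("   ", x$by_type$type[i], ":", x$by_type$n[i], "\n")
    }
  }
  if (nrow(x$by_consequence)) {
    cat("  by consequence type:\n")
    for (i in seq_len(nrow(x$by_consequence))) {
      cat("   ", x$by_consequence$consequence[i], ":",
          x$by_consequence$n[i], "\n")
    }
  }
  invisible(x)
}

#' Consequence-type distribution plot
#' @param object A `var_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.var_summary <- function(object, ...) {
  d <- object$by_consequence
  if (!nrow(d)) d <- tibble(consequence = "(unannotated)", n = object$n_variants)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$consequence, .data$n),
                                  y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "variants",
                  title = "Variants by consequence type") +
    ggplot2::theme_minimal()
}
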