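# Shared fixture builders for the suite. All data is constructed in code;
# the only files on disk are the 10-record demo VCF + annotation TSV under
# inst/extdata.

demo_vcf <- function() system.file("extdata", "trio_demo.vcf", package = "varsieve")
demo_ann <- function() system.file("extdata", "trio_demo.annotations.tsv",
                                   package = "varsieve")

trio_sib_ped <- function() default_trio_sib()

# recessive pattern over the demo VCF's roster
rec_pattern_for_demo <- function(max_missing = 0L) {
  pattern_recessive(trio_sib_ped(), max_missing)
}

# variant table straight from a genotype-class matrix (rows = records)
make_vtbl <- function(gt, samples = colnames(gt)) {
  gt <- matrix(gt, ncol = length(samples))
  df <- tibble::tibble(
    chrom = "1",
    pos = seq_len(nrow(gt)) * 100L,
    ref = "A",
    alt = "G",
    rs_id = NA_character_
  )
  for (j in seq_along(samples)) df[[samples[j]]] <- gt[, j]
  df
}

record_keys <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

# re-import an exported CSV; "chrom:pos" position strings must stay
# character (bare guessing would read them as times)
read_export <- function(path) {
  present <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  as_chr <- intersect(c("position", "change", "rs_id"), present)
  spec <- stats::setNames(lapply(as_chr, function(...) readr::col_character()),
                          as_chr)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = do.call(readr::cols,
                                      c(spec, .default = list(readr::col_guess()))))
}

# every genotype-class vector over n samples (classes incl. missing)
enum_gt_vectors <- function(n, classes = c("0/0", "0/1", "1/1", "./.")) {
  as.matrix(expand.grid(rep(list(classes), n), stringsAsFactors = FALSE))
}

random_pattern <- function(samples, max_missing = NULL) {
  allowed <- lapply(samples, function(s) {
    sample(gt_called, sample.int(3L, 1L))
  })
  names(allowed) <- samples
  if (is.null(max_missing)) max_missing <- sample.int(length(samples) + 1L, 1L) - 1L
  seg_pattern(allowed, max_missing)
}

# third, test-local statement of the segregation semantics (besides
# filter_segregation and expected_survivors), used in the oracle checks
brute_keys <- function(x, pattern) {
  allowed <- stats::setNames(pattern$allowed, pattern$sample)
  mm <- max_missing(pattern)
  keep <- vapply(seq_len(nrow(x)), function(i) {
    g <- vapply(names(allowed), function(s) x[[s]][i], "")
    miss <- g == "./."
    all(miss | mapply(function(gi, s) gi %in% allowed[[s]], g, names(allowed))) &&
      sum(miss) <= mm
  }, TRUE)
  record_keys(x)[keep]
}

# can child dosage arise from parental dosages by Mendelian transmission?
mendel_consistent <- function(father, mother, child) {
  d <- function(g) switch(g, "0/0" = 0L, "0/1" = 1L, "1/1" = 2L)
  alleles <- function(g) switch(g, "0/0" = 0L, "0/1" = c(0L, 1L), "1/1" = 1L)
  any(outer(alleles(father), alleles(mother), `+`) == d(child))
}
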