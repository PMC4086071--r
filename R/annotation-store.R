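#' Sequence Ontology consequence vocabulary
#'
#' Controlled vocabulary of consequence-type terms accepted by
#' [filter_consequence()] and the annotation table, with aliases for the
#' legacy Ensembl labels still in common use (`"non-synonymous"` maps to
#' `missense_variant`, `"stop lost"` to `stop_lost`, ...).
#'
#' @format `so_terms` is a character vector of accepted terms;
#'   `so_aliases` a named character vector mapping legacy labels to terms.
#' @export
so_terms <- c(
  "transcript_ablation", "splice_acceptor_variant", "splice_donor_variant",
  "stop_gained", "frameshift_variant", "stop_lost", "start_lost",
  "inframe_insertion", "inframe_deletion", "missense_variant",
  "splice_region_variant", "incomplete_terminal_codon_variant",
  "synonymous_variant", "stop_retained_variant",
  "coding_sequence_variant", "mature_miRNA_variant",
  "5_prime_UTR_variant", "3_prime_UTR_variant",
  "non_coding_transcript_exon_variant", "intron_variant",
  "non_coding_transcript_variant", "upstream_gene_variant",
  "downstream_gene_variant", "TF_binding_site_variant",
  "regulatory_region_variant", "intergenic_variant"
)

#' @rdname so_terms
#' @export
so_aliases <- c(
  "non-synonymous" = "missense_variant",
  "non_synonymous" = "missense_variant",
  "nonsynonymous" = "missense_variant",
  "missense" = "missense_variant",
  "stop lost" = "stop_lost",
  "stop gained" = "stop_gained",
  "synonymous" = "synonymous_variant",
  "frameshift" = "frameshift_variant"
)

#' Normalize consequence terms against the controlled vocabulary
#'
#' @param terms Character vector of SO terms or legacy aliases.
#' @return Character vector of canonical SO terms.
#' @export
normalize_consequence <- function(terms) {
  terms <- as.character(terms)
  mapped <- ifelse(terms %in% names(so_aliases), so_aliases[terms], terms)
  unknown <- setdiff(mapped, so_terms)
  if (length(unknown)) {
    abort(paste0("unknown consequence term(s): ",
                 paste(unknown, collapse = ", ")))
  }
  unname(mapped)
}

#' Minor allele frequency from genotype counts
#'
#' Derives the alternative-allele frequency from population genotype counts,
#' p = (n_het + 2 n_hom_alt) / (2 (n_hom_ref + n_het + n_hom_alt)), and
#' folds it to the minor allele, min(p, 1 - p), so the result always lies
#' in [0, 0.5] and is symmetric under swapping the reference/alternative
#' roles.
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative integer vectors of
#'   genotype counts; totals must be positive.
#' @return Numeric vector of MAFs in [0, 0.5].
#' @examples
#' maf_from_counts(90, 9, 1) # 0.055
#' @export
maf_from_counts <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- cbind(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(is.na(counts))) {
    abort("genotype counts must be non-negative and non-missing")
  }
  total <- n_hom_ref + n_het + n_hom_alt
  if (any(total == 0)) abort("total genotype count must be positive")
  p <- (n_het + 2 * n_hom_alt) / (2 * total)
  pmin(p, 1 - p)
}

#' Most deleterious value of a damaging-score set
#'
#' A variant hitting several transcripts can carry several SIFT or PolyPhen
#' scores; the displayed value is the most deleterious one. SIFT is more
#' damaging the *lower* the score (minimum is taken); PolyPhen the
#' *higher* (maximum).
#'
#' @param scores Numeric vector of scores in [0, 1]; NAs are dropped.
#' @param index `"sift"` or `"polyphen"`.
#' @return Length-1 numeric, or NA if no non-missing score remains.
#' @examples
#' most_deleterious(c(0.20, 0.01), "sift")     # 0.01
#' most_deleterious(c(0.30, 0.98), "polyphen") # 0.98
#' @export
most_deleterious <- function(scores, index = c("sift", "polyphen")) {
  index <- match.arg(index)
  if (!length(scores)) abort("no scores supplied")
  scores <- scores[!is.na(scores)]
  if (!length(scores)) return(NA_real_)
  if (any(scores < 0 | scores > 1)) abort("scores must lie in [0, 1]")
  if (index == "sift") min(scores) else max(scores)
}

maf_cols <- c("maf_kg_all", "maf_kg_eur", "maf_kg_asn", "maf_kg_afr",
              "maf_kg_amr", "maf_esp")

effect_fields <- c("gene", "transcript_id", "feature_id", "feature_type",
                   "biotype", "consequence", "aa_change", "sift", "polyphen")

annotation_cols <- c("chrom", "pos", "ref", "alt", "rs_id", "effects",
                     maf_cols, "phenotype")

# one effect: gene:transcript:feature_id:feature_type:biotype:consequence:
#             aa_change:sift:polyphen  ("." = absent); effects joined by ","
pack_effects <- function(effects) {
  if (!nrow(effects)) return(".")
  m <- vapply(effect_fields, function(f) {
    v <- as.character(effects[[f]])
    ifelse(is.na(v) | v == "", ".", v)
  }, character(nrow(effects)))
  if (nrow(effects) == 1L) m <- matrix(m, nrow = 1L)
  paste(apply(m, 1L, paste, collapse = ":"), collapse = ",")
}

unpack_effects <- function(packed, key) {
  if (is.na(packed) || packed == "." || packed == "") {
    return(tibble(gene = character(), transcript_id = character(),
                  feature_id = character(), feature_type = character(),
                  biotype = character(), consequence = character(),
                  aa_change = character(), sift = numeric(),
                  polyphen = numeric()))
  }
  parts <- strsplit(strsplit(packed, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != length(effect_fields)
  if (any(bad)) {
    abort(paste0("malformed effect encoding for variant ", key,
                 ": expected ", length(effect_fields),
                 " colon-separated fields per effect"))
  }
  m <- do.call(rbind, parts)
  m[m == "."] <- NA
  out <- as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  names(out) <- effect_fields
  out$sift <- as.numeric(out$sift)
  out$polyphen <- as.numeric(out$polyphen)
  out$consequence <- normalize_consequence(out$consequence)
  out
}

#' Build an annotation store from tibbles
#'
#' The store keeps one row per variant key (`variants`) and a long table of
#' per-transcript effects (`effects`). Variants absent from the store
#' behave as annotated with an empty record.
#'
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `rs_id`, the six MAF columns
#'   (`maf_kg_all`, `maf_kg_eur`, `maf_kg_asn`, `maf_kg_afr`, `maf_kg_amr`,
#'   `maf_esp`) and `phenotype`.
#' @param effects Tibble with the variant key columns plus `gene`,
#'   `transcript_id`, `feature_id`, `feature_type`, `biotype`,
#'   `consequence` (SO term), `aa_change`, `sift`, `polyphen`.
#' @return An object of class `annotation_store`.
#' @export
annotation_store <- function(variants, effects = NULL) {
  variants <- as_tibble(variants)
  for (col in c("rs_id", "phenotype")) {
    if (!col %in% names(variants)) variants[[col]] <- NA_character_
  }
  for (col in maf_cols) {
    if (!col %in% names(variants)) variants[[col]] <- NA_real_
    v <- variants[[col]]
    if (any(!is.na(v) & (v < 0 | v > 0.5))) {
      abort(paste0(col, " values must lie in [0, 0.5] (minor-allele folded)"))
    }
  }
  canonical <- c("chrom", "pos", "ref", "alt", "rs_id", maf_cols, "phenotype")
  variants <- variants[, c(canonical, setdiff(names(variants), canonical))]
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
  if (anyDuplicated(key)) {
    abort(paste0("duplicate annotation key(s): ",
                 paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  if (is.null(effects)) {
    effects <- tibble(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gene = character(),
                      transcript_id = character(), feature_id = character(),
                      feature_type = character(), biotype = character(),
                      consequence = character(), aa_change = character(),
                      sift = numeric(), polyphen = numeric())
  } else {
    effects <- as_tibble(effects)
    effects$consequence <- normalize_consequence(effects$consequence)
    for (col in c("sift", "polyphen")) {
      v <- effects[[col]]
      if (any(!is.na(v) & (v < 0 | v > 1))) {
        abort(paste0(col, " scores must lie in [0, 1]"))
      }
    }
  }
  structure(list(variants = variants, effects = effects),
            class = "annotation_store")
}

#' @export
print.annotation_store <- function(x, ...) {
  cat("# Annotation store: ", nrow(x$variants), " variant(s), ",
      nrow(x$effects), " transcript effect(s)\n", sep = "")
  invisible(x)
}

#' Read an annotation table from TSV
#'
#' The table is tab-delimited with header columns `chrom`, `pos`, `ref`,
#' `alt`, `rs_id`, `effects`, `maf_kg_all`, `maf_kg_eur`, `maf_kg_asn`,
#' `maf_kg_afr`, `maf_kg_amr`, `maf_esp`, `phenotype`. `"."` denotes an
#' absent value. The `effects` column packs the per-transcript effect list
#' as comma-separated records of colon-separated fields
#' `gene:transcript_id:feature_id:feature_type:biotype:consequence:aa_change:sift:polyphen`.
#' Multiple phenotype strings are `;`-separated. An export from a local
#' annotation service (Ensembl VEP, CellBase) can be reshaped into this
#' schema offline.
#'
#' @param path Path to the TSV file.
#' @return An `annotation_store`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    rs_id = readr::col_character(), effects = readr::col_character(),
    maf_kg_all = readr::col_character(), maf_kg_eur = readr::col_character(),
    maf_kg_asn = readr::col_character(), maf_kg_afr = readr::col_character(),
    maf_kg_amr = readr::col_character(), maf_esp = readr::col_character(),
    phenotype = readr::col_character()
  ), na = character(), progress = FALSE)
  missing_cols <- setdiff(annotation_cols, names(tab))
  if (length(missing_cols)) {
    abort(paste0("annotation table '", path, "' lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  incomplete <- which(is.na(tab$pos) | tab$chrom == "" | tab$ref == "" | tab$alt == "")
  if (length(incomplete)) {
    abort(paste0("malformed annotation row(s) at line ",
                 paste(incomplete + 1L, collapse = ", "), " of '", path, "'"))
  }
  dot_na_chr <- function(v) ifelse(v == "." | v == "", NA_character_, v)
  dot_na_num <- function(v) suppressWarnings(as.numeric(dot_na_chr(v)))
  variants <- tibble(
    chrom = tab$chrom, pos = tab$pos, ref = tab$ref, alt = tab$alt,
    rs_id = dot_na_chr(tab$rs_id), phenotype = dot_na_chr(tab$phenotype)
  )
  for (col in maf_cols) variants[[col]] <- dot_na_num(tab[[col]])
  key <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
  eff <- purrr::map2(tab$effects, key, unpack_effects)
  effects <- dplyr::bind_rows(purrr::map2(eff, seq_along(eff), function(e, i) {
    if (!nrow(e)) return(NULL)
    dplyr::bind_cols(tibble(chrom = tab$chrom[i], pos = tab$pos[i],
                            ref = tab$ref[i], alt = tab$alt[i]), e)
  }))
  annotation_store(variants, effects)
}

#' Write an annotation store as TSV
#'
#' Inverse of [read_annotations()]; see that page for the schema.
#'
#' @param store An `annotation_store`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(store, path) {
  v <- store$variants
  key_of <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  eff_by_key <- split(store$effects, key_of(store$effects))
  dot <- function(x) ifelse(is.na(x), ".", as.character(x))
  # %.17g round-trips doubles exactly through as.numeric
  dot_num <- function(x) ifelse(is.na(x), ".", sprintf("%.17g", x))
  out <- tibble(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    rs_id = dot(v$rs_id),
    effects = vapply(key_of(v), function(k) {
      e <- eff_by_key[[k]]
      if (is.null(e)) "." else pack_effects(e)
    }, ""),
  )
  for (col in maf_cols) out[[col]] <- dot_num(v[[col]])
  out$phenotype <- dot(v$phenotype)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Annotate a variant table for display and filtering
#'
#' Left-joins the annotation store onto the variant table: annotation is
#' strictly additive — no variant is dropped, duplicated or reordered, and
#' variants absent from the store get empty annotation fields. The result
#' carries the display columns of the interactive tool's variant panel:
#' `position` (chrom:pos), `change` (ref>alt), `gene` (all genes hit,
#' pipe-separated), per-sample genotype classes, `rs_id`, the six MAF
#' columns, `consequence` (distinct SO terms, pipe-separated; also kept as
#' the list-column `consequence_terms` for filtering), `aa_change`, `sift`
#' and `polyphen` (most deleterious value across transcript effects, see
#' [most_deleterious()]) and `phenotype`.
#'
#' @param x A `variant_tbl`.
#' @param store An `annotation_store`.
#' @return A tibble of annotated rows (still a `variant_tbl`).
#' @export
annotate_variants <- function(x, store) {
  stopifnot(inherits(store, "annotation_store"))
  samples <- variant_samples(x)
  key <- paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  vkey <- paste(store$variants$chrom, store$variants$pos,
                store$variants$ref, store$variants$alt, sep = ":")
  idx <- match(key, vkey)
  eff_by_key <- split(store$effects,
                      paste(store$effects$chrom, store$effects$pos,
                            store$effects$ref, store$effects$alt, sep = ":"))
  eff <- lapply(key, function(k) eff_by_key[[k]])

  out <- tibble(
    chrom = x$chrom, pos = x$pos, ref = x$ref, alt = x$alt,
    position = paste0(x$chrom, ":", x$pos),
    change = paste0(x$ref, ">", x$alt),
    gene = vapply(eff, function(e) {
      if (is.null(e) || !nrow(e)) return(NA_character_)
      g <- unique(stats::na.omit(e$gene))
      if (!length(g)) NA_character_ else paste(g, collapse = "|")
    }, "")
  )
  for (s in samples) out[[s]] <- x[[s]]
  out$rs_id <- dplyr::coalesce(x$rs_id, store$variants$rs_id[idx])
  for (col in maf_cols) out[[col]] <- store$variants[[col]][idx]
  out$consequence_terms <- lapply(eff, function(e) {
    if (is.null(e)) character() else unique(e$consequence)
  })
  out$consequence <- vapply(out$consequence_terms, paste, "", collapse = "|")
  out$aa_change <- vapply(eff, function(e) {
    if (is.null(e)) return(NA_character_)
    a <- unique(stats::na.omit(e$aa_change))
    if (!length(a)) NA_character_ else paste(a, collapse = "|")
  }, "")
  out$sift <- vapply(eff, function(e) {
    if (is.null(e)) NA_real_ else most_deleterious(e$sift, "sift")
  }, 0)
  out$polyphen <- vapply(eff, function(e) {
    if (is.null(e)) NA_real_ else most_deleterious(e$polyphen, "polyphen")
  }, 0)
  out$phenotype <- store$variants$phenotype[idx]
  new_variant_tbl(out, samples)
}
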