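#' Default background allele-frequency sampler
#'
#' Mixture spanning rare and common variation, so that MAF filtering is
#' actually exercised: with probability 1/2 a rare allele frequency drawn
#' uniformly from (0.0005, 0.01), otherwise a common one from (0.01, 0.5).
#'
#' @param n Number of frequencies to draw.
#' @return Numeric vector of alternative-allele frequencies.
#' @export
maf_mixture <- function(n) {
  rare <- stats::runif(n) < 0.5
  ifelse(rare, stats::runif(n, 5e-4, 0.01), stats::runif(n, 0.01, 0.5))
}

# genotype class from alt-allele dosage 0/1/2
dosage_to_class <- function(d) c("0/0", "0/1", "1/1")[d + 1L]

causal_genotypes <- function(ped, model, cases = NULL, controls = NULL) {
  g <- stats::setNames(rep(NA_character_, nrow(ped)), ped$id)
  if (model == "case_control") {
    g[cases] <- "1/1"
    g[controls] <- sample(c("0/0", "0/1"), length(controls), replace = TRUE)
    g[setdiff(ped$id, c(cases, controls))] <- "0/0"
    return(g)
  }
  aff <- ped$affected == "affected"
  unaff <- ped$affected == "unaffected"
  if (model == "recessive") {
    g[aff] <- "1/1"
    parents <- unique(stats::na.omit(c(ped$father[aff], ped$mother[aff])))
    g[unaff] <- sample(c("0/0", "0/1"), sum(unaff), replace = TRUE)
    g[parents] <- "0/1"
  } else if (model == "dominant") {
    g[aff] <- "0/1"
    g[unaff] <- "0/0"
  } else if (model == "de_novo") {
    g[aff] <- "0/1"
    g[unaff] <- "0/0"
  }
  g[is.na(g)] <- "0/0"
  g
}

#' Simulate a family exome with a planted causal variant
#'
#' Generates a multi-sample variant set for a pedigree: background variants
#' follow Hardy-Weinberg genotype frequencies in the founders and Mendelian
#' transmission down the pedigree, and one causal variant is planted with
#' genotypes dictated by the chosen inheritance model (e.g. recessive:
#' carrier parents 0/1, affected 1/1, unaffected 0/0 or 0/1). Noise is
#' configurable: each background genotype is independently masked to
#' missing with `missing_rate`, and replaced by a random *different* called
#' class with `mendel_error_rate` (injecting Mendelian inconsistencies).
#' By default the causal record is left clean so the simulation truth
#' stays exact; set `corrupt_causal = TRUE` to subject it to the same noise
#' and exercise the missing-call tolerance. A matching annotation table is
#' built: every variant gets a gene, one or two transcript effects with
#' consequence terms drawn from a realistic exome mix, MAF columns equal to
#' the folded generating frequency (a few percent left unannotated to act
#' as novel variants), and damaging scores for missense hits. The causal
#' variant receives `causal_consequence` and `causal_maf`.
#'
#' @param ped A [pedigree()]. For `model = "case_control"`, affected
#'   individuals are the cases and unaffected the controls.
#' @param model One of `"recessive"`, `"dominant"`, `"de_novo"`,
#'   `"case_control"`.
#' @param n_background Number of background variants (>= 0).
#' @param maf_sampler Function `n -> allele frequencies` for background
#'   variants; default [maf_mixture()].
#' @param missing_rate,mendel_error_rate Per-genotype noise probabilities
#'   in [0, 1].
#' @param causal_consequence SO term annotated on the causal variant.
#' @param causal_maf Population MAF annotated on the causal variant, or NA
#'   for a novel variant (the default).
#' @param corrupt_causal Apply the noise processes to the causal record
#'   too.
#' @param novel_rate Fraction of background variants left without MAF/rs_id
#'   annotation.
#' @param seed Integer seed; identical configuration and seed give
#'   identical output.
#' @return A list of class `family_sim`: `variants` (a `variant_tbl`),
#'   `store` (an `annotation_store`), `truth` (list with `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `model`, `expected_genotypes`), `pedigree`.
#'   Write it to disk with [write_simulation()].
#' @export
simulate_family <- function(ped, model = c("recessive", "dominant",
                                           "de_novo", "case_control"),
                            n_background = 1000L,
                            maf_sampler = maf_mixture,
                            missing_rate = 0, mendel_error_rate = 0,
                            causal_consequence = "missense_variant",
                            causal_maf = NA_real_,
                            corrupt_causal = FALSE,
                            novel_rate = 0.05,
                            seed = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(ped, "pedigree"))
  if (n_background < 0) abort("`n_background` must be >= 0")
  for (r in c(missing_rate, mendel_error_rate, novel_rate)) {
    if (is.na(r) || r < 0 || r > 1) abort("rates must lie in [0, 1]")
  }
  causal_consequence <- normalize_consequence(causal_consequence)
  if (model == "case_control") {
    cases <- ped$id[ped$affected == "affected"]
    controls <- ped$id[ped$affected == "unaffected"]
    if (!length(cases) || !length(controls)) {
      abort("case_control simulation needs affected and unaffected individuals")
    }
  } else {
    cases <- controls <- NULL
    if (!any(ped$affected == "affected")) {
      abort("simulation needs at least one affected individual")
    }
  }
  set.seed(as.integer(seed))

  ids <- topo_order(ped)
  n <- n_background + 1L
  p <- maf_sampler(n_background)

  # founder dosages ~ Binomial(2, p); children get one allele per parent
  dosage <- matrix(0L, nrow = n_background, ncol = nrow(ped),
                   dimnames = list(NULL, ped$id))
  if (n_background > 0) {
    for (id in ids) {
      r <- ped[ped$id == id, ]
      if (is.na(r$father) && is.na(r$mother)) {
        dosage[, id] <- stats::rbinom(n_background, 2L, p)
      } else {
        transmit <- function(par) {
          if (is.na(par)) stats::rbinom(n_background, 1L, p)  # unlisted parent
          else stats::rbinom(n_background, 1L, dosage[, par] / 2)
        }
        dosage[, id] <- transmit(r$father) + transmit(r$mother)
      }
    }
  }

  causal_at <- if (n_background > 0) sample.int(n, 1L) else 1L
  pos <- 10000L + 150L * (seq_len(n) - 1L)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- unname(vapply(ref, function(b) sample(setdiff(bases, b), 1L), ""))

  gt <- matrix("0/0", nrow = n, ncol = nrow(ped),
               dimnames = list(NULL, ped$id))
  bg_rows <- setdiff(seq_len(n), causal_at)
  if (n_background > 0) gt[bg_rows, ] <- dosage_to_class(dosage)
  gt[causal_at, ] <- causal_genotypes(ped, model, cases, controls)[ped$id]
  planted <- gt[causal_at, ]  # clean truth, recorded before any noise

  noise_rows <- if (corrupt_causal) seq_len(n) else bg_rows
  if (mendel_error_rate > 0 && length(noise_rows)) {
    hit <- matrix(stats::runif(length(noise_rows) * nrow(ped)) < mendel_error_rate,
                  nrow = length(noise_rows))
    for (j in seq_len(nrow(ped))) {
      w <- noise_rows[hit[, j]]
      if (length(w)) {
        gt[w, j] <- vapply(gt[w, j],
                           function(g) sample(setdiff(gt_called, g), 1L), "")
      }
    }
  }
  if (missing_rate > 0 && length(noise_rows)) {
    mask <- matrix(stats::runif(length(noise_rows) * nrow(ped)) < missing_rate,
                   nrow = length(noise_rows))
    for (j in seq_len(nrow(ped))) gt[noise_rows[mask[, j]], j] <- "./."

  }

  variants <- tibble(chrom = "1", pos = pos, ref = ref, alt = alt,
                     rs_id = NA_character_)
  for (j in seq_len(nrow(ped))) variants[[ped$id[j]]] <- gt[, j]

  # --- annotation table ---------------------------------------------------
  bg_terms <- c("intron_variant", "synonymous_variant", "missense_variant",
                "5_prime_UTR_variant", "3_prime_UTR_variant",
                "splice_region_variant", "upstream_gene_variant",
                "downstream_gene_variant", "stop_gained")
  bg_w <- c(0.30, 0.15, 0.20, 0.06, 0.08, 0.05, 0.07, 0.07, 0.02)
  gene_of <- paste0("GENE", sprintf("%04d", (seq_len(n) - 1L) %/% 5L + 1L))
  term1 <- character(n)
  term1[bg_rows] <- sample(bg_terms, length(bg_rows), replace = TRUE, prob = bg_w)
  term1[causal_at] <- causal_consequence
  two_tx <- stats::runif(n) < 0.3
  term2 <- ifelse(two_tx, sample(bg_terms, n, replace = TRUE, prob = bg_w),
                  NA_character_)

  maf_ann <- rep(NA_real_, n)
  if (n_background > 0) maf_ann[bg_rows] <- pmin(p, 1 - p)
  novel <- stats::runif(n) < novel_rate
  maf_ann[novel] <- NA_real_
  maf_ann[causal_at] <- if (is.null(causal_maf)) NA_real_ else causal_maf
  pop_jitter <- function(base) {
    v <- pmin(pmax(base * stats::runif(n, 0.5, 1.5), 0), 0.5)
    ifelse(is.na(base), NA_real_, v)
  }
  rs <- ifelse(is.na(maf_ann), NA_character_,
               paste0("rs", 100000L + seq_len(n)))
  variants$rs_id <- rs

  sift <- ifelse(term1 == "missense_variant",
                 round(stats::runif(n), 3), NA_real_)
  polyphen <- ifelse(term1 == "missense_variant",
                     round(stats::runif(n), 3), NA_real_)
  sift[causal_at] <- 0.01
  polyphen[causal_at] <- 0.98

  eff1 <- tibble(chrom = "1", pos = pos, ref = ref, alt = alt,
                 gene = gene_of,
                 transcript_id = paste0("TX", sprintf("%06d", seq_len(n)), ".1"),
                 feature_id = paste0("EXON", sprintf("%06d", seq_len(n))),
                 feature_type = "exon", biotype = "protein_coding",
                 consequence = term1,
                 aa_change = ifelse(term1 == "missense_variant", "A/V",
                                    NA_character_),
                 sift = sift, polyphen = polyphen)
  eff2 <- tibble(chrom = "1", pos = pos[two_tx], ref = ref[two_tx],
                 alt = alt[two_tx], gene = gene_of[two_tx],
                 transcript_id = paste0("TX", sprintf("%06d", which(two_tx)), ".2"),
                 feature_id = paste0("EXON", sprintf("%06d", which(two_tx)), "b"),
                 feature_type = "exon", biotype = "protein_coding",
                 consequence = term2[two_tx], aa_change = NA_character_,
                 sift = NA_real_, polyphen = NA_real_)
  effects <- dplyr::arrange(dplyr::bind_rows(eff1, eff2), .data$pos)

  ann_variants <- tibble(
    chrom = "1", pos = pos, ref = ref, alt = alt, rs_id = rs,
    maf_kg_all = maf_ann, maf_kg_eur = pop_jitter(maf_ann),
    maf_kg_asn = pop_jitter(maf_ann), maf_kg_afr = pop_jitter(maf_ann),
    maf_kg_amr = pop_jitter(maf_ann), maf_esp = pop_jitter(maf_ann),
    phenotype = NA_character_
  )

  truth <- list(
    chrom = "1", pos = pos[causal_at], ref = ref[causal_at],
    alt = alt[causal_at], gene = gene_of[causal_at], model = model,
    expected_genotypes = as.list(stats::setNames(planted, ped$id))
  )

  structure(list(variants = new_variant_tbl(variants, ped$id),
                 store = annotation_store(ann_variants, effects),
                 truth = truth, pedigree = ped),
            class = "family_sim")
}

#' Write a simulated family bundle to disk
#'
#' Materializes a [simulate_family()] result as a VCF, the annotation TSV
#' of [read_annotations()], a truth JSON naming the planted causal variant
#' and its expected genotypes, and a PED file of the pedigree.
#'
#' @param sim A `family_sim`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `"sim"`.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "family_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, paste0(prefix, ".vcf")),
    annotations = file.path(dir, paste0(prefix, ".annotations.tsv")),
    truth = file.path(dir, paste0(prefix, ".truth.json")),
    ped = file.path(dir, paste0(prefix, ".ped"))
  )
  write_vcf(sim$variants, paths[["vcf"]])
  write_annotations(sim$store, paths[["annotations"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  ped <- sim$pedigree
  writeLines(paste("FAM1", ped$id,
                   ifelse(is.na(ped$father), "0", ped$father),
                   ifelse(is.na(ped$mother), "0", ped$mother),
                   c(male = "1", female = "2", unknown = "0")[ped$sex],
                   c(affected = "2", unaffected = "1", unknown = "0")[ped$affected],
                   sep = "\t"),
             con = paths[["ped"]])
  invisible(paths)
}

#' Brute-force segregation oracle
#'
#' Independent reference implementation of the segregation-filter
#' semantics, written as an explicit per-record, per-sample check with no
#' shared code with [filter_segregation()]. Intended for validation: on any
#' input the surviving key set must equal the filter's.
#'
#' @param x A `variant_tbl`.
#' @param pattern A [seg_pattern()].
#' @return Character vector of `chrom:pos:ref:alt` keys of surviving
#'   records.
#' @export
expected_survivors <- function(x, pattern) {
  allowed <- pattern_allowed(pattern)
  keys <- character()
  for (i in seq_len(nrow(x))) {
    n_missing <- 0L
    compatible <- TRUE
    for (s in names(allowed)) {
      g <- x[[s]][i]
      if (g == "./.") {
        n_missing <- n_missing + 1L
      } else if (!(g %in% allowed[[s]])) {
        compatible <- FALSE
        break
      }
    }
    if (compatible && n_missing <= attr(pattern, "max_missing")) {
      keys <- c(keys, paste(x$chrom[i], x$pos[i], x$ref[i], x$alt[i], sep = ":"))
    }
  }
  keys
}
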