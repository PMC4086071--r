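rec_pattern <- function(max_missing = 0L) {
  seg_pattern(list(FA = "0/1", MO = "0/1", AF = "1/1", UN = c("0/0", "0/1")),
              max_missing)
}

test_that("segregation filter retains the recessive configuration and drops violations", {
  samples <- c("FA", "MO", "AF", "UN")
  x <- make_vtbl(rbind(
    c("0/1", "0/1", "1/1", "0/0"),  # compatible
    c("0/1", "0/1", "0/1", "0/0"),  # affected het
    c("0/0", "0/0", "1/1", "0/0"),  # non-carrier parents
    c("0/1", "0/1", "1/1", "1/1"),  # unaffected hom-alt
    c("0/1", "0/1", "1/1", "0/1")   # compatible (unaffected carrier)
  ), samples)
  out <- filter_segregation(x, rec_pattern())
  expect_equal(record_keys(out), record_keys(x)[c(1, 5)])
})

test_that("missing-call tolerance collects allowed-or-missing then bounds the count", {
  samples <- c("FA", "MO", "AF", "UN")
  x <- make_vtbl(rbind(
    c("0/1", "0/1", "./.", "0/0"),  # 1 missing, rest allowed
    c("./.", "./.", "1/1", "0/0"),  # 2 missing
    c("./.", "0/1", "0/1", "0/0"),  # missing + zygosity violation
    c("./.", "./.", "./.", "./.")   # all 4 missing
  ), samples)
  expect_equal(record_keys(filter_segregation(x, rec_pattern(0L))), character())
  expect_equal(record_keys(filter_segregation(x, rec_pattern(1L))),
               record_keys(x)[1])
  expect_equal(record_keys(filter_segregation(x, rec_pattern(2L))),
               record_keys(x)[1:2])
  expect_equal(record_keys(filter_segregation(x, rec_pattern(4L))),
               record_keys(x)[c(1, 2, 4)])
})

test_that("off-model genotype classes never match and never count as missing", {
  samples <- c("FA", "MO", "AF", "UN")
  x <- make_vtbl(rbind(
    c("0/1", "0/1", "other", "0/0"),
    c("other", "0/1", "1/1", "0/0")
  ), samples)
  expect_equal(nrow(filter_segregation(x, rec_pattern(4L))), 0L)
})

test_that("unconstrained samples are ignored, including for the missing count", {
  x <- make_vtbl(rbind(c("0/1", "./.", "1/1")), c("FA", "STRANGER", "AF"))
  pat <- seg_pattern(list(FA = "0/1", AF = "1/1"), max_missing = 0)
  expect_equal(nrow(filter_segregation(x, pat)), 1L)
})

test_that("an unvalidated pattern is rejected with all problems listed", {
  x <- make_vtbl(rbind(c("0/1", "1/1")), c("A", "B"))
  pat <- seg_pattern(list(A = "0/1", Z = "1/1", Q = "0/0"), max_missing = 0)
  expect_error(filter_segregation(x, pat), "Z.*Q|Q.*Z")
})

test_that("segregation filter matches the brute-force oracle on random patterns", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(3:5, 1)
    samples <- paste0("S", seq_len(n))
    x <- make_vtbl(enum_gt_vectors(n), samples)
    pat <- random_pattern(samples)
    expect_equal(record_keys(filter_segregation(x, pat)),
                 expected_survivors(x, pat))
    expect_equal(expected_survivors(x, pat), brute_keys(x, pat))
  }
})

test_that("missing-tolerance survivors grow monotonically with N", {
  set.seed(33)
  samples <- paste0("S", 1:4)
  x <- make_vtbl(enum_gt_vectors(4L), samples)
  allowed <- stats::setNames(lapply(1:4, function(i) sample(gt_called, 2)), samples)
  prev <- character()
  for (N in 0:4) {
    cur <- record_keys(filter_segregation(x, seg_pattern(allowed, N)))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("consequence filter uses any-transcript semantics and a closed vocabulary", {
  x <- read_vcf(demo_vcf())
  rows <- annotate_variants(x, read_annotations(demo_ann()))
  out <- filter_consequence(rows, c("missense_variant", "stop_lost"))
  expect_setequal(out$pos, c(1000L, 3000L, 6000L, 7000L, 10000L))
  # growing the allowed set only grows the survivors
  out2 <- filter_consequence(rows, c("missense_variant", "stop_lost",
                                     "synonymous_variant"))
  expect_true(all(out$pos %in% out2$pos))
  expect_error(filter_consequence(rows, "not_a_term"), "unknown consequence")
  expect_error(filter_consequence(rows, character()), "non-empty")
  # legacy aliases work
  expect_equal(filter_consequence(rows, "non-synonymous")$pos,
               filter_consequence(rows, "missense_variant")$pos)
})

test_that("frequency filter takes the max over selected columns, strictly", {
  rows <- tibble::tibble(
    chrom = "1", pos = 1:4, ref = "A", alt = "G",
    maf_kg_all = c(0.20, NA, 0.005, 0.005),
    maf_kg_eur = NA_real_, maf_kg_asn = NA_real_,
    maf_kg_afr = NA_real_, maf_kg_amr = NA_real_,
    maf_esp = c(NA, NA, 0.02, 0.009)
  )
  out <- filter_frequency(rows, 0.01)
  # 0.20 fails; novel passes; max(0.005, 0.02) fails; max(0.005, 0.009) passes
  expect_equal(out$pos, c(2L, 4L))
  # restricting to 1000 Genomes only rescues the ESP-common variant
  expect_equal(filter_frequency(rows, 0.01, studies = "kg")$pos, c(2L, 3L, 4L))
  # exact-threshold value is excluded (strict less-than)
  rows$maf_kg_all <- 0.01
  rows$maf_esp <- NA_real_
  expect_equal(nrow(filter_frequency(rows, 0.01)), 0L)
  # survivors shrink weakly as the threshold decreases
  set.seed(9)
  rows2 <- tibble::tibble(chrom = "1", pos = 1:50, ref = "A", alt = "G",
                          maf_kg_all = runif(50, 0, 0.5),
                          maf_kg_eur = NA_real_, maf_kg_asn = NA_real_,
                          maf_kg_afr = NA_real_, maf_kg_amr = NA_real_,
                          maf_esp = NA_real_)
  prev <- rows2$pos
  for (t in c(0.5, 0.1, 0.01, 0)) {
    cur <- filter_frequency(rows2, t)$pos
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_error(filter_frequency(rows, 0.7), "0, 0.5")
})

test_that("region filter is inclusive at both endpoints", {
  x <- read_vcf(demo_vcf())
  expect_equal(filter_region(x, "1:500-1500")$pos, 1000L)
  expect_equal(filter_region(x, "1:1000-1000")$pos, 1000L)
  expect_equal(filter_region(x, parse_region(c("1:2000-3000", "1:9000-9000")))$pos,
               c(2000L, 3000L, 9000L))
  expect_equal(nrow(filter_region(x, "2:1-100000")), 0L)
  expect_error(filter_region(x, character()), "parse|non-empty")
})

test_that("cascade applies filters consecutively and records the funnel", {
  x <- read_vcf(demo_vcf())
  store <- read_annotations(demo_ann())
  pat <- pattern_recessive(trio_sib_ped())
  res <- run_cascade(x, store, list(
    segregation = pat,
    consequence = c("missense_variant", "stop_lost"),
    frequency = list(threshold = 0.01)
  ))
  expect_equal(res$counts$step, c("input", "segregation", "consequence",
                                  "frequency"))
  expect_equal(res$counts$n_survivors, c(10L, 2L, 1L, 1L))
  expect_equal(res$rows$pos, 1000L)
  expect_equal(res$rows$gene, "BCKDK")
  # counts never increase down the cascade
  expect_true(all(diff(res$counts$n_survivors) <= 0))
  # tidy/glance accessors
  td <- tidy(res)
  expect_equal(td$n_removed, c(0L, 8L, 1L, 0L))
  gl <- glance(res)
  expect_equal(gl$n_survivors, 1L)
  expect_equal(gl$n_input, 10L)
})

test_that("empty cascade is the identity; unknown steps are rejected", {
  x <- read_vcf(demo_vcf())
  res <- run_cascade(x)
  expect_equal(nrow(res$rows), 10L)
  expect_equal(res$counts$n_survivors, 10L)
  expect_error(run_cascade(x, NULL, list(bogus = 1)), "unknown filter")
  expect_error(run_cascade(x, NULL, list(gene = "BCKDK")), "annotation store")
})

test_that("the final survivor set is invariant under filter order", {
  x <- read_vcf(demo_vcf())
  store <- read_annotations(demo_ann())
  steps <- list(
    segregation = rec_pattern_for_demo(),
    consequence = c("missense_variant", "stop_lost", "stop_gained"),
    frequency = list(threshold = 0.05),
    region = "1:1-9500"
  )
  perms <- list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3), c(3, 1, 4, 2))
  keys <- lapply(perms, function(p) {
    sort(record_keys(run_cascade(x, store, steps[p])$rows))
  })
  for (k in keys[-1]) expect_equal(k, keys[[1]])
})

test_that("summary reports roster, type and consequence distributions", {
  x <- read_vcf(demo_vcf())
  store <- read_annotations(demo_ann())
  s <- summarize_variants(x, store)
  expect_equal(s$samples, c("FATHER", "MOTHER", "PROBAND", "SIBLING"))
  expect_equal(s$n_variants, 10L)
  expect_equal(s$by_type$n[s$by_type$type == "SNV"], 10L)
  # variants counted once per distinct term: 10 variants, 11 term hits
  expect_equal(sum(s$by_consequence$n), 11L)
  expect_gte(sum(s$by_consequence$n), s$n_variants)
  # empty table keeps the roster with zero counts
  s0 <- summarize_variants(x[0, ])
  expect_equal(s0$n_variants, 0L)
  expect_equal(s0$samples, s$samples)
  # SNV/indel typing by allele length
  xi <- x
  xi$ref[1] <- "AT"
  si <- summarize_variants(xi)
  expect_equal(si$by_type$n[si$by_type$type == "indel"], 1L)
})

test_that("autoplot returns ggplot objects for cascade and summary", {
  x <- read_vcf(demo_vcf())
  store <- read_annotations(demo_ann())
  res <- run_cascade(x, store, list(frequency = list(threshold = 0.05)))
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  expect_s3_class(ggplot2::autoplot(summarize_variants(x, store)), "ggplot")
})
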