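test_that("recessive preset encodes carrier parents, 1/1 affected, 0/0-or-0/1 unaffected", {
  pat <- pattern_recessive(trio_sib_ped())
  allowed <- stats::setNames(pat$allowed, pat$sample)
  expect_equal(allowed$FATHER, "0/1")
  expect_equal(allowed$MOTHER, "0/1")
  expect_equal(allowed$PROBAND, "1/1")
  expect_equal(allowed$SIBLING, c("0/0", "0/1"))
  expect_equal(max_missing(pat), 0L)
})

test_that("recessive preset needs an affected individual; singleton works", {
  ped <- pedigree(id = c("A", "B"), affected = "unaffected")
  expect_error(pattern_recessive(ped), "affected")
  solo <- pedigree(id = "P", affected = "affected")
  pat <- pattern_recessive(solo)
  expect_equal(nrow(pat), 1L)
  expect_equal(pat$allowed[[1]], "1/1")
})

test_that("dominant preset constrains by affection; penetrance relaxes unaffected", {
  ped <- pedigree(id = c("AP", "UP", "AC"),
                  father = c(NA, NA, "AP"), mother = c(NA, NA, "UP"),
                  affected = c("affected", "unaffected", "affected"))
  pat <- pattern_dominant(ped, "complete")
  allowed <- stats::setNames(pat$allowed, pat$sample)
  expect_equal(allowed$AP, c("0/1", "1/1"))
  expect_equal(allowed$AC, c("0/1", "1/1"))
  expect_equal(allowed$UP, "0/0")
  rel <- pattern_dominant(ped, "incomplete")
  rel_allowed <- stats::setNames(rel$allowed, rel$sample)
  expect_equal(rel_allowed$UP, gt_called)
  # relaxing penetrance never shrinks any allowed set
  for (s in pat$sample) {
    expect_true(all(allowed[[s]] %in% rel_allowed[[s]]))
  }
  expect_error(pattern_dominant(pedigree(id = "X", affected = "unknown")),
               "affected")
})

test_that("de novo preset: 0/0 parents, carrier affected, 0/0 unaffected sibs", {
  pat <- pattern_de_novo(trio_sib_ped())
  allowed <- stats::setNames(pat$allowed, pat$sample)
  expect_equal(allowed$FATHER, "0/0")
  expect_equal(allowed$MOTHER, "0/0")
  expect_equal(allowed$PROBAND, c("0/1", "1/1"))
  expect_equal(allowed$SIBLING, "0/0")
  one_parent <- pedigree(id = c("MO", "CH"), mother = c(NA, "MO"),
                         affected = c("unaffected", "affected"))
  expect_error(pattern_de_novo(one_parent), "both parents")
})

test_that("case-control presets match the loss-of-function configuration", {
  pat <- pattern_case_control(c("c1", "c2"), c("n1", "n2"), "recessive")
  allowed <- stats::setNames(pat$allowed, pat$sample)
  expect_equal(allowed$c1, "1/1")
  expect_equal(allowed$c2, "1/1")
  expect_equal(allowed$n1, c("0/0", "0/1"))
  expect_equal(allowed$n2, c("0/0", "0/1"))
  dom <- pattern_case_control("case", "ctrl", "dominant")
  dom_allowed <- stats::setNames(dom$allowed, dom$sample)
  expect_equal(dom_allowed$case, c("0/1", "1/1"))
  expect_equal(dom_allowed$ctrl, "0/0")
  expect_error(pattern_case_control(c("a", "b"), c("b", "c")), "both groups")
  expect_error(pattern_case_control(character(), "a"), "no cases")
})

test_that("pattern validation reports all violations at once", {
  pat <- seg_pattern(list(A = "0/1", B = "1/1"), max_missing = 1)
  expect_equal(nrow(validate_pattern(pat, c("A", "B", "C"))), 0L)
  rep <- validate_pattern(pat, c("A"))
  expect_equal(rep$sample, "B")
  expect_match(rep$problem, "roster")
  expect_error(seg_pattern(list(A = character())), "non-empty")
  expect_error(seg_pattern(list(A = "2/2")), "subsets")
  expect_error(seg_pattern(list(A = "0/1"), max_missing = 2), "exceed")
})

test_that("pedigree invariants are enforced", {
  expect_error(pedigree(id = c("A", "A")), "duplicate")
  expect_error(pedigree(id = "A", father = "A"), "own")
  expect_error(pedigree(id = c("A", "B"), father = c("B", "A")), "cycle")
  expect_error(pedigree(id = c("K"), father = "Z"), "not in pedigree")
  expect_error(pedigree(id = c("C", "P"), father = c(NA, "P"),
                        mother = c(NA, "P")), "identical|not in")
})

test_that("PED files round-trip through read_ped", {
  path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c(
    "# family file",
    "FAM1\tFA\t0\t0\t1\t1",
    "FAM1\tMO\t0\t0\t2\t1",
    "FAM1\tCH\tFA\tMO\t1\t2",
    "FAM1\tSI\tFA\tMO\t2\t-9"
  ), path)
  ped <- read_ped(path)
  expect_equal(ped$id, c("FA", "MO", "CH", "SI"))
  expect_equal(ped$affected, c("unaffected", "unaffected", "affected", "unknown"))
  expect_equal(ped$sex, c("male", "female", "male", "female"))
  expect_equal(ped$father, c(NA, NA, "FA", "FA"))
  expect_error(read_ped(tempfile()), "not found")
})

test_that("presets retain genotype vectors generated under their own model", {
  ped <- trio_sib_ped()
  # recessive transmission: carrier x carrier, affected 1/1, sib not 1/1
  set.seed(11)
  for (i in 1:20) {
    sib <- sample(c("0/0", "0/1"), 1)
    x <- make_vtbl(matrix(c("0/1", "0/1", "1/1", sib), nrow = 1),
                   samples = ped$id)
    expect_equal(nrow(filter_segregation(x, pattern_recessive(ped))), 1L)
  }
  # de novo: everyone 0/0 except the affected carrier
  x <- make_vtbl(matrix(c("0/0", "0/0", "0/1", "0/0"), nrow = 1),
                 samples = ped$id)
  expect_equal(nrow(filter_segregation(x, pattern_de_novo(ped))), 1L)
})

test_that("recessive preset discards every Mendelian-inconsistent trio vector", {
  ped <- pedigree(id = c("FA", "MO", "CH"),
                  father = c(NA, NA, "FA"), mother = c(NA, NA, "MO"),
                  affected = c("unaffected", "unaffected", "affected"))
  pat <- pattern_recessive(ped)
  vectors <- enum_gt_vectors(3L, classes = gt_called)  # all 27 called vectors
  x <- make_vtbl(vectors, samples = ped$id)
  kept <- filter_segregation(x, pat)
  expect_gt(nrow(kept), 0L)
  for (i in seq_len(nrow(kept))) {
    expect_true(mendel_consistent(kept$FA[i], kept$MO[i], kept$CH[i]))
  }
  # and the retained set is exactly the model's own configuration
  expect_equal(nrow(kept), 1L)
  expect_equal(c(kept$FA, kept$MO, kept$CH), c("0/1", "0/1", "1/1"))
})
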