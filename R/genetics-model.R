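#' Construct a pedigree
#'
#' A pedigree is a tibble with one row per individual: `id`, `father`,
#' `mother` (NA when not in the pedigree), `sex`
#' (`"male"`/`"female"`/`"unknown"`) and `affected`
#' (`"affected"`/`"unaffected"`/`"unknown"`). Parentage must be acyclic and
#' parents, when named, must be distinct individuals present in the
#' pedigree.
#'
#' @param id,father,mother,sex,affected Vectors of equal length (father,
#'   mother may contain NA; sex and affected are recycled scalars or full
#'   vectors).
#' @return A tibble of class `pedigree`.
#' @examples
#' pedigree(
#'   id = c("FA", "MO", "NA19600", "SIB"),
#'   father = c(NA, NA, "FA", "FA"),
#'   mother = c(NA, NA, "MO", "MO"),
#'   sex = c("male", "female", "male", "female"),
#'   affected = c("unaffected", "unaffected", "affected", "unaffected")
#' )
#' @export
pedigree <- function(id, father = NA_character_, mother = NA_character_,
                     sex = "unknown", affected = "unknown") {
  ped <- tibble(id = as.character(id),
                father = as.character(father),
                mother = as.character(mother),
                sex = rep_len(as.character(sex), length(id)),
                affected = rep_len(as.character(affected), length(id)))
  validate_pedigree(ped)
}

validate_pedigree <- function(ped) {
  problems <- character()
  if (nrow(ped) == 0L) problems <- c(problems, "pedigree has no individuals")
  if (anyDuplicated(ped$id)) {
    problems <- c(problems, paste0("duplicate ids: ",
                                   paste(unique(ped$id[duplicated(ped$id)]), collapse = ", ")))
  }
  for (col in c("father", "mother")) {
    bad <- !is.na(ped[[col]]) & !(ped[[col]] %in% ped$id)
    if (any(bad)) {
      problems <- c(problems, paste0(col, " of ", paste(ped$id[bad], collapse = ", "),
                                     " not in pedigree"))
    }
    self <- !is.na(ped[[col]]) & ped[[col]] == ped$id
    if (any(self)) {
      problems <- c(problems, paste0(paste(ped$id[self], collapse = ", "),
                                     " is its own ", col))
    }
  }
  same <- !is.na(ped$father) & !is.na(ped$mother) & ped$father == ped$mother
  if (any(same)) {
    problems <- c(problems, paste0("father and mother identical for ",
                                   paste(ped$id[same], collapse = ", ")))
  }
  bad_sex <- !ped$sex %in% c("male", "female", "unknown")
  if (any(bad_sex)) problems <- c(problems, "sex must be male/female/unknown")
  bad_aff <- !ped$affected %in% c("affected", "unaffected", "unknown")
  if (any(bad_aff)) problems <- c(problems, "affected must be affected/unaffected/unknown")
  if (!length(problems) && is.null(topo_order(ped))) {
    problems <- c(problems, "parentage contains a cycle")
  }
  if (length(problems)) {
    abort(paste0("invalid pedigree: ", paste(problems, collapse = "; ")))
  }
  structure(ped, class = c("pedigree", class(as_tibble(ped))))
}

# ids ordered parents-before-children; NULL if cyclic
topo_order <- function(ped) {
  remaining <- ped$id
  placed <- character()
  parents_of <- function(i) {
    r <- ped[ped$id == i, ]
    stats::na.omit(c(r$father, r$mother))
  }
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      all(setdiff(parents_of(i), placed) %in% character(0))
    }, TRUE)]
    if (!length(ready)) return(NULL)
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

#' Read a PED-style pedigree file
#'
#' Whitespace-delimited, six columns in the de facto standard order:
#' family id, individual id, father id, mother id, sex (1 = male,
#' 2 = female, other = unknown) and phenotype (2 = affected,
#' 1 = unaffected, other = unknown). `0` denotes an absent parent. Lines
#' starting with `#` are ignored; only the first family is expected (all
#' rows are used regardless of family id).
#'
#' @param path Path to the PED file.
#' @return A `pedigree` tibble.
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) abort(paste0("PED file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) abort(paste0("PED file '", path, "' has no data rows"))
  fields <- strsplit(trimws(lines), "[ \t]+")
  short <- vapply(fields, length, 0L) < 6L
  if (any(short)) {
    abort(paste0("PED file '", path, "': row(s) ",
                 paste(which(short), collapse = ", "), " have fewer than 6 columns"))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  pedigree(
    id = m[, 2L],
    father = ifelse(m[, 3L] == "0", NA_character_, m[, 3L]),
    mother = ifelse(m[, 4L] == "0", NA_character_, m[, 4L]),
    sex = c("1" = "male", "2" = "female")[m[, 5L]] |>
      (\(x) ifelse(is.na(x), "unknown", x))(),
    affected = c("2" = "affected", "1" = "unaffected")[m[, 6L]] |>
      (\(x) ifelse(is.na(x), "unknown", x))()
  )
}

#' Segregation pattern: per-sample allowed genotype sets
#'
#' The single source of truth for the segregation filter: each constrained
#' sample has a non-empty allowed subset of \{"0/0", "0/1", "1/1"\}, and
#' `max_missing` missing calls are tolerated across the constrained
#' samples. Inheritance-model presets ([pattern_recessive()] and friends)
#' compile to this type; any pedigree and model can also be written
#' directly.
#'
#' @param allowed Named list: sample name -> character vector of allowed
#'   genotype classes (subset of `gt_called`).
#' @param max_missing Non-negative integer, the maximum number of
#'   constrained samples whose genotype may be missing (`"./."`) while the
#'   record is still retained.
#' @return A tibble of class `seg_pattern` with columns `sample` and
#'   `allowed` (list-column), and a `max_missing` attribute.
#' @examples
#' seg_pattern(list(FA = "0/1", MO = "0/1", CH = "1/1"), max_missing = 1)
#' @export
seg_pattern <- function(allowed, max_missing = 0L) {
  if (!is.list(allowed) || is.null(names(allowed)) ||
      any(!nzchar(names(allowed))) || !length(allowed)) {
    abort("`allowed` must be a non-empty named list of genotype-class sets")
  }
  allowed <- lapply(allowed, function(a) sort(unique(as.character(a))))
  bad <- vapply(allowed, function(a) length(a) == 0L || !all(a %in% gt_called), TRUE)
  if (any(bad)) {
    abort(paste0("allowed sets must be non-empty subsets of {",
                 paste(gt_called, collapse = ", "), "}; offending sample(s): ",
                 paste(names(allowed)[bad], collapse = ", ")))
  }
  max_missing <- as.integer(max_missing)
  if (is.na(max_missing) || max_missing < 0L) {
    abort("`max_missing` must be a non-negative integer")
  }
  if (max_missing > length(allowed)) {
    abort("`max_missing` cannot exceed the number of constrained samples")
  }
  structure(
    tibble(sample = names(allowed), allowed = unname(allowed)),
    max_missing = max_missing,
    class = c("seg_pattern", class(tibble()))
  )
}

#' @export
print.seg_pattern <- function(x, ...) {
  cat("# Segregation pattern (max_missing = ", attr(x, "max_missing"), ")\n",
      sep = "")
  for (i in seq_len(nrow(x))) {
    cat("  ", x$sample[i], ": {", paste(x$allowed[[i]], collapse = ", "),
        "}\n", sep = "")
  }
  invisible(x)
}

#' Maximum tolerated missing calls of a pattern
#' @param pattern A `seg_pattern`.
#' @return Integer.
#' @export
max_missing <- function(pattern) attr(pattern, "max_missing")

pattern_allowed <- function(pattern) {
  stats::setNames(pattern$allowed, pattern$sample)
}

affected_ids <- function(ped) ped$id[ped$affected == "affected"]

# intersect role constraints; empty intersection = model/pedigree conflict
intersect_constraint <- function(sets, id, set) {
  cur <- sets[[id]]
  new <- if (is.null(cur)) set else intersect(cur, set)
  if (!length(new)) {
    abort(paste0("model is inconsistent with the pedigree: sample '", id,
                 "' has an empty allowed set"))
  }
  sets[[id]] <- new
  sets
}

#' Autosomal-recessive segregation pattern
#'
#' Affected individuals must be homozygous alternative (`1/1`); their
#' in-pedigree parents must be carriers (`0/1`); unaffected individuals may
#' be heterozygous or homozygous reference (`0/1` or `0/0`). Individuals of
#' unknown affection status are constrained only through parenthood of an
#' affected child.
#'
#' @param ped A [pedigree()].
#' @param max_missing Missing-call tolerance (see [seg_pattern()]).
#' @return A `seg_pattern`.
#' @export
pattern_recessive <- function(ped, max_missing = 0L) {
  aff <- affected_ids(ped)
  if (!length(aff)) abort("recessive model needs at least one affected individual")
  sets <- list()
  for (i in seq_len(nrow(ped))) {
    if (ped$affected[i] == "affected") {
      sets <- intersect_constraint(sets, ped$id[i], "1/1")
    } else if (ped$affected[i] == "unaffected") {
      sets <- intersect_constraint(sets, ped$id[i], c("0/0", "0/1"))
    }
  }
  for (a in aff) {
    r <- ped[ped$id == a, ]
    for (p in stats::na.omit(c(r$father, r$mother))) {
      sets <- intersect_constraint(sets, p, "0/1")
    }
  }
  seg_pattern(sets, max_missing)
}

#' Autosomal-dominant segregation pattern
#'
#' Affected individuals carry at least one alternative allele
#' (`0/1` or `1/1`). Under complete penetrance unaffected individuals must
#' be homozygous reference; under incomplete penetrance their constraint is
#' relaxed to all three called classes (they still count toward the
#' missing-call tolerance).
#'
#' @inheritParams pattern_recessive
#' @param penetrance `"complete"` or `"incomplete"`.
#' @return A `seg_pattern`.
#' @export
pattern_dominant <- function(ped, penetrance = c("complete", "incomplete"),
                             max_missing = 0L) {
  penetrance <- match.arg(penetrance)
  aff <- affected_ids(ped)
  if (!length(aff)) abort("dominant model needs at least one affected individual")
  sets <- list()
  for (i in seq_len(nrow(ped))) {
    if (ped$affected[i] == "affected") {
      sets <- intersect_constraint(sets, ped$id[i], c("0/1", "1/1"))
    } else if (ped$affected[i] == "unaffected") {
      sets <- intersect_constraint(
        sets, ped$id[i],
        if (penetrance == "complete") "0/0" else gt_called)
    }
  }
  seg_pattern(sets, max_missing)
}

#' De novo segregation pattern
#'
#' The affected individual carries a new allele absent from both parents:
#' parents homozygous reference, affected heterozygous or homozygous
#' alternative. Unaffected full siblings of the affected (same two parents)
#' cannot have inherited the allele and are constrained to `0/0`. Every
#' affected individual must have both parents in the pedigree.
#'
#' @inheritParams pattern_recessive
#' @return A `seg_pattern`.
#' @export
pattern_de_novo <- function(ped, max_missing = 0L) {
  aff <- affected_ids(ped)
  if (!length(aff)) abort("de novo model needs at least one affected individual")
  sets <- list()
  for (a in aff) {
    r <- ped[ped$id == a, ]
    if (is.na(r$father) || is.na(r$mother)) {
      abort(paste0("de novo model needs both parents of affected '", a,
                   "' in the pedigree"))
    }
    sets <- intersect_constraint(sets, a, c("0/1", "1/1"))
    sets <- intersect_constraint(sets, r$father, "0/0")
    sets <- intersect_constraint(sets, r$mother, "0/0")
    sibs <- ped$id[!is.na(ped$father) & !is.na(ped$mother) &
                     ped$father == r$father & ped$mother == r$mother &
                     ped$id != a & ped$affected == "unaffected"]
    for (s in sibs) sets <- intersect_constraint(sets, s, "0/0")
  }
  seg_pattern(sets, max_missing)
}

#' Case-control segregation pattern
#'
#' Constrains unrelated affected (cases) and unaffected (controls) samples,
#' e.g. `1/1` for cases versus `0/1` or `0/0` for controls for a recessive
#' loss-of-function mutation; the dominant variant requires cases to carry
#' at least one alternative allele and controls none.
#'
#' @param cases,controls Disjoint, non-empty character vectors of sample
#'   names.
#' @param model `"recessive"` or `"dominant"`.
#' @param max_missing Missing-call tolerance (see [seg_pattern()]).
#' @return A `seg_pattern`.
#' @export
pattern_case_control <- function(cases, controls,
                                 model = c("recessive", "dominant"),
                                 max_missing = 0L) {
  model <- match.arg(model)
  cases <- as.character(cases); controls <- as.character(controls)
  problems <- character()
  if (!length(cases)) problems <- c(problems, "no cases given")
  if (!length(controls)) problems <- c(problems, "no controls given")
  overlap <- intersect(cases, controls)
  if (length(overlap)) {
    problems <- c(problems, paste0("sample(s) in both groups: ",
                                   paste(overlap, collapse = ", ")))
  }
  if (length(problems)) abort(paste0("invalid case-control design: ",
                                     paste(problems, collapse = "; ")))
  sets <- c(
    stats::setNames(rep(list(switch(model, recessive = "1/1",
                                    dominant = c("0/1", "1/1"))),
                        length(cases)), cases),
    stats::setNames(rep(list(switch(model, recessive = c("0/0", "0/1"),
                                    dominant = "0/0")),
                        length(controls)), controls)
  )
  seg_pattern(sets, max_missing)
}

#' Validate a segregation pattern against a sample roster
#'
#' Checks that every constrained sample exists in the roster and that the
#' pattern invariants hold; all violations are reported together rather
#' than failing on the first.
#'
#' @param pattern A `seg_pattern`.
#' @param roster Character vector of sample names (e.g.
#'   `variant_samples(x)`).
#' @return A tibble with columns `sample` and `problem`; zero rows means
#'   the pattern is valid.
#' @export
validate_pattern <- function(pattern, roster) {
  out <- tibble(sample = character(), problem = character())
  if (!inherits(pattern, "seg_pattern")) {
    return(tibble(sample = NA_character_, problem = "not a seg_pattern object"))
  }
  missing_samples <- setdiff(pattern$sample, roster)
  for (s in missing_samples) {
    out <- dplyr::bind_rows(out, tibble(sample = s, problem = "sample not in VCF roster"))
  }
  empty <- vapply(pattern$allowed, length, 0L) == 0L
  for (s in pattern$sample[empty]) {
    out <- dplyr::bind_rows(out, tibble(sample = s, problem = "empty allowed set"))
  }
  bad <- vapply(pattern$allowed, function(a) !all(a %in% gt_called), TRUE)
  for (s in pattern$sample[bad & !empty]) {
    out <- dplyr::bind_rows(out, tibble(sample = s, problem = "allowed set outside {0/0, 0/1, 1/1}"))
  }
  if (max_missing(pattern) > nrow(pattern)) {
    out <- dplyr::bind_rows(out, tibble(
      sample = NA_character_,
      problem = "max_missing exceeds number of constrained samples"))
  }
  out
}
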