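#' Build and validate a pedigree
#'
#' A pedigree is a tibble with one row per individual and columns
#' `family_id`, `id`, `father_id`, `mother_id` (`NA` for founders),
#' `sex_karyotype` (`"XX"`, `"XY"` or `"XXY"`; the karyotype travels on the
#' individual so that sex-chromosome zygosity legality can be checked per
#' variant) and `affected` (`"affected"`, `"unaffected"`, `"unknown"`).
#'
#' @param members A data frame with the columns above.
#' @return A validated pedigree tibble.
#' @examples
#' trio <- pedigree(tibble::tribble(
#'   ~family_id, ~id, ~father_id, ~mother_id, ~sex_karyotype, ~affected,
#'   "F1", "father", NA, NA, "XY", "unaffected",
#'   "F1", "mother", NA, NA, "XX", "unaffected",
#'   "F1", "child", "father", "mother", "XY", "affected"
#' ))
#' @export
pedigree <- function(members) {
  ped <- as_tibble(members)
  needed <- c("family_id", "id", "father_id", "mother_id", "sex_karyotype", "affected")
  missing_cols <- setdiff(needed, names(ped))
  if (length(missing_cols)) {
    abort(paste0("pedigree is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  ped <- ped[, needed]
  if (anyDuplicated(ped$id)) abort("pedigree member ids must be unique")
  if (!all(ped$sex_karyotype %in% c("XX", "XY", "XXY"))) {
    abort("sex_karyotype must be one of XX, XY, XXY")
  }
  if (!all(ped$affected %in% c("affected", "unaffected", "unknown"))) {
    abort("affected must be affected/unaffected/unknown")
  }
  for (col in c("father_id", "mother_id")) {
    refs <- ped[[col]][!is.na(ped[[col]])]
    unknown <- setdiff(refs, ped$id)
    if (length(unknown)) {
      abort(sprintf("unknown parent id(s): %s", paste(unknown, collapse = ", ")))
    }
  }
  if (!any(ped$affected == "affected")) abort("pedigree has no affected member")
  assert_acyclic(ped)
  ped
}

# An individual may never be its own ancestor.
assert_acyclic <- function(ped) {
  parents <- setNames(
    map2(ped$father_id, ped$mother_id, function(f, m) c(f, m)[!is.na(c(f, m))]),
    ped$id
  )
  for (start in ped$id) {
    seen <- character()
    frontier <- parents[[start]]
    while (length(frontier)) {
      if (start %in% frontier) abort(sprintf("ancestry cycle involving '%s'", start))
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(parents[frontier])), seen)
    }
  }
  invisible(ped)
}

#' Read a pedigree from a PED file
#'
#' Reads a whitespace-delimited six-column PLINK PED file (family, individual,
#' father, mother, sex, phenotype). `0` parent codes mean founder. Sex code 1
#' maps to `XY`, 2 to `XX`. An optional seventh column overrides the
#' karyotype, which is how a 47,XXY individual is encoded.
#'
#' @param path Path to the PED file.
#' @return A pedigree tibble (see [pedigree()]).
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 6) abort("PED file must have at least six columns")
  sex <- raw[[5]]
  karyo <- ifelse(sex == "1", "XY", ifelse(sex == "2", "XX", NA_character_))
  if (ncol(raw) >= 7) {
    ov <- raw[[7]]
    karyo <- ifelse(!is.na(ov) & ov %in% c("XX", "XY", "XXY"), ov, karyo)
  }
  pheno <- raw[[6]]
  aff <- ifelse(pheno == "2", "affected",
         ifelse(pheno == "1", "unaffected", "unknown"))
  self_parent <- raw[[2]] == raw[[3]] | raw[[2]] == raw[[4]]
  if (any(self_parent)) {
    abort(sprintf("individual '%s' listed as its own parent",
                  raw[[2]][self_parent][1]))
  }
  pedigree(tibble(
    family_id = raw[[1]],
    id = raw[[2]],
    father_id = ifelse(raw[[3]] == "0", NA_character_, raw[[3]]),
    mother_id = ifelse(raw[[4]] == "0", NA_character_, raw[[4]]),
    sex_karyotype = karyo,
    affected = aff
  ))
}

#' Write a pedigree to a PED file
#'
#' Emits the six PLINK columns plus a seventh karyotype column so that
#' `read_pedigree(write_pedigree(ped))` round-trips 47,XXY individuals.
#'
#' @param ped A pedigree tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  ped <- pedigree(ped)
  out <- data.frame(
    fam = ped$family_id,
    id = ped$id,
    father = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mother = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = ifelse(ped$sex_karyotype == "XX", "2", "1"),
    pheno = c(affected = "2", unaffected = "1", unknown = "0")[ped$affected],
    karyo = ped$sex_karyotype
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Number of X copies implied by the karyotype.
x_copies <- function(karyotype) {
  c(XX = 2L, XY = 1L, XXY = 2L)[karyotype]
}

#' Pick the index (proband) of a pedigree
#'
#' The first affected member, unless `index_id` is given.
#'
#' @param ped A pedigree tibble.
#' @param index_id Optional explicit individual id.
#' @return An individual id.
#' @export
index_of <- function(ped, index_id = NULL) {
  if (!is.null(index_id)) {
    if (!index_id %in% ped$id) abort(sprintf("'%s' is not in the pedigree", index_id))
    return(index_id)
  }
  aff <- ped$id[ped$affected == "affected"]
  if (!length(aff)) abort("pedigree has no affected member to use as index")
  aff[[1]]
}
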