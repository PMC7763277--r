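carries_alt <- function(gt) gt %in% c("het", "hom_alt", "hem_alt")

#' Check familial co-segregation of a candidate call
#'
#' Evaluates every genotyped non-index relative against the inheritance
#' hypothesis of the call (complete penetrance assumed):
#'
#' * AR homozygous: affected relatives must be `hom_alt`; unaffected must not be.
#' * AR compound het: affected relatives must carry both variants; an
#'   unaffected relative carrying both is a violation only when parental
#'   genotypes confirm the two variants are in trans; with unknown phase it
#'   is tolerated. Phase of the index is resolved (in trans) when each parent
#'   carries exactly one of the pair.
#' * AD/XLD: affected relatives carry the variant; unaffected carry nothing.
#' * XLR: affected XY relatives are `hem_alt`, affected XX/XXY relatives are
#'   `hom_alt` (both X copies; 47,XXY males can be X-homozygous); unaffected
#'   XY must not be hemizygous; heterozygous females (and XXY het) are
#'   tolerated carriers.
#'
#' @param call One candidate call (one-row tibble from [run_cascade()]
#'   candidates, or a list with `mode`, `call_type`, `variant_ids`).
#' @param ped Pedigree tibble.
#' @param variants Variant rows for the call's members (with family genotypes).
#' @return A list: `consistent`, `affected_checked`, `healthy_checked`
#'   (counts of consistent non-index relatives, the convention of the
#'   A/H notation), `violations` tibble, `phase_resolved` (`NA` for
#'   non-compound calls), `index_id`.
#' @export
check_segregation <- function(call, ped, variants) {
  ped <- pedigree(ped)
  mode <- call$mode[[1]]
  type <- call$call_type[[1]]
  ids <- if (is.list(call$variant_ids)) call$variant_ids[[1]] else call$variant_ids
  v <- variants[match(ids, variants$variant_id), , drop = FALSE]
  if (any(is.na(v$variant_id))) abort("variants for the call's members are missing")
  fam_ids <- unique(unlist(map(v$genotypes, names)))
  unknown <- setdiff(fam_ids, ped$id)
  if (length(unknown)) {
    abort(sprintf("genotype(s) for unknown individual(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  index_id <- index_of(ped)
  gt <- function(vid, ind) {
    g <- v$genotypes[[match(vid, v$variant_id)]]
    val <- if (ind %in% names(g)) g[[ind]] else NA_character_
    if (is.na(val)) "missing" else val
  }
  relatives <- ped[ped$id != index_id & ped$affected != "unknown", , drop = FALSE]
  # under XLR the expected genotype is keyed on each relative's karyotype,
  # whether the index call was hemizygous (XY) or X-homozygous (XX/XXY)
  type <- if (mode == "XLR" && type %in% c("hom", "hem")) "hem" else type

  violations <- list()
  n_aff <- 0L
  n_healthy <- 0L
  phase_resolved <- NA

  expect_for <- function(affected, karyo) {
    switch(type,
      hom = if (affected) "hom_alt" else "not hom_alt",
      hem = , # XLR call
      het_dominant = if (mode %in% c("AD", "XLD") && type == "het_dominant") {
        if (affected) "carrier" else "non-carrier"
      } else if (affected) {
        if (karyo == "XY") "hem_alt" else "hom_alt"
      } else {
        if (karyo == "XY") "not hem_alt" else "not hom_alt (carrier het allowed)"
      },
      comphet = if (affected) "both variants" else "not both in trans"
    )
  }

  # trans check via the individual's parents: each parent carries exactly one
  trans_confirmed <- function(ind) {
    row <- ped[ped$id == ind, ]
    f <- row$father_id; m <- row$mother_id
    if (is.na(f) || is.na(m)) return(NA)
    fc <- c(carries_alt(gt(ids[1], f)), carries_alt(gt(ids[2], f)))
    mc <- c(carries_alt(gt(ids[1], m)), carries_alt(gt(ids[2], m)))
    if (any(is.na(c(fc, mc)))) return(NA)
    if ((fc[1] && !fc[2] && mc[2] && !mc[1]) ||
        (fc[2] && !fc[1] && mc[1] && !mc[2])) return(TRUE)
    if ((fc[1] && fc[2] && !mc[1] && !mc[2]) ||
        (mc[1] && mc[2] && !fc[1] && !fc[2])) return(FALSE)  # cis
    NA
  }

  if (type == "comphet") {
    tc <- trans_confirmed(index_id)
    phase_resolved <- isTRUE(tc)
    if (isFALSE(tc)) {
      # parental genotypes place both variants on one haplotype: not a
      # compound heterozygote at all
      violations[[length(violations) + 1L]] <- tibble(
        individual = index_id, expected = "variants in trans",
        observed = "in cis (single parental origin)")
    }
  }

  for (i in seq_len(nrow(relatives))) {
    ind <- relatives$id[i]
    affected <- relatives$affected[i] == "affected"
    karyo <- relatives$sex_karyotype[i]
    gts <- map_chr(ids, gt, ind = ind)
    if (any(gts == "missing")) next  # not genotyped -> not checked
    ok <- switch(type,
      hom = if (affected) all(gts == "hom_alt") else !all(gts == "hom_alt"),
      het_dominant = if (affected) all(carries_alt(gts)) else !any(carries_alt(gts)),
      hem = {
        if (affected) {
          if (karyo == "XY") all(gts == "hem_alt") else all(gts == "hom_alt")
        } else {
          if (karyo == "XY") !any(gts == "hem_alt") else !any(gts == "hom_alt")
        }
      },
      comphet = {
        both <- all(carries_alt(gts))
        if (affected) both && !isFALSE(trans_confirmed(ind))
        else if (!both) TRUE
        else !isTRUE(trans_confirmed(ind))  # both carried: violation iff in trans
      }
    )
    if (ok) {
      if (affected) n_aff <- n_aff + 1L else n_healthy <- n_healthy + 1L
    } else {
      violations[[length(violations) + 1L]] <- tibble(
        individual = ind,
        expected = expect_for(affected, karyo),
        observed = paste(gts, collapse = ",")
      )
    }
  }

  list(
    consistent = length(violations) == 0L,
    affected_checked = n_aff,
    healthy_checked = n_healthy,
    violations = if (length(violations)) bind_rows(violations) else
      tibble(individual = character(), expected = character(), observed = character()),
    phase_resolved = if (type == "comphet") phase_resolved else NA,
    index_id = index_id
  )
}

#' Format a segregation result in the A/H convention
#'
#' Produces the `"Yes(A/H)"` notation (affected/healthy relatives checked
#' and consistent, index excluded) or `"No"` when no relative was genotyped
#' or the call failed to segregate.
#'
#' @param result Output of [check_segregation()].
#' @return A string such as `"Yes(2/5)"` or `"No"`.
#' @export
count_segregants <- function(result) {
  if (!result$consistent) return("No")
  if (result$affected_checked + result$healthy_checked == 0L) return("No")
  sprintf("Yes(%d/%d)", result$affected_checked, result$healthy_checked)
}
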