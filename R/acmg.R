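ACMG_CODES <- c(
  "PVS1",
  paste0("PS", 1:4),
  paste0("PM", 1:6),
  paste0("PP", 1:5),
  "BA1",
  paste0("BS", 1:4),
  paste0("BP", 1:7)
)

#' Combine ACMG/AMP evidence criteria into a five-tier class
#'
#' Implements the standard ACMG/AMP combining rules mapping a set of evidence
#' criteria (PVS1, PS1-4, PM1-6, PP1-5, BA1, BS1-4, BP1-7) to the five-tier
#' verdict: 1 benign, 2 likely benign, 3 uncertain significance (VUS),
#' 4 likely pathogenic, 5 pathogenic. When both a pathogenic-side and a
#' benign-side combination are satisfied the evidence is contradictory and
#' the verdict is VUS.
#'
#' @param codes Character vector of criterion codes (duplicates ignored).
#' @return Integer class in 1..5.
#' @examples
#' acmg_combine(c("PVS1", "PS1"))  # 5
#' acmg_combine(character())       # 3
#' acmg_combine("BA1")             # 1
#' @export
acmg_combine <- function(codes) {
  codes <- unique(as.character(codes))
  bad <- setdiff(codes, ACMG_CODES)
  if (length(bad)) {
    abort(sprintf("unknown ACMG criterion code(s): %s", paste(bad, collapse = ", ")))
  }
  pvs <- sum(codes == "PVS1")
  ps <- sum(grepl("^PS", codes))
  pm <- sum(grepl("^PM", codes))
  pp <- sum(grepl("^PP", codes))
  ba <- sum(codes == "BA1")
  bs <- sum(grepl("^BS", codes))
  bp <- sum(grepl("^BP", codes))

  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp == 1) || pp >= 2)) ||
    (ps >= 2) ||
    (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
  likely_pathogenic <-
    (pvs == 1 && pm == 1) ||
    (ps == 1 && pm >= 1 && pm <= 2) ||
    (ps == 1 && pp >= 2) ||
    (pm >= 3) ||
    (pm == 2 && pp >= 2) ||
    (pm == 1 && pp >= 4)
  benign <- (ba >= 1) || (bs >= 2)
  likely_benign <- (bs == 1 && bp == 1) || (bp >= 2)

  path_side <- pathogenic || likely_pathogenic
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return(3L)
  if (pathogenic) return(5L)
  if (likely_pathogenic) return(4L)
  if (benign) return(1L)
  if (likely_benign) return(2L)
  3L
}

#' Discard benign and likely benign variants
#'
#' Drops variants whose ACMG class is in `config$acmg_discard_classes`
#' (default classes 1 and 2), keeping VUS, likely pathogenic and pathogenic.
#' A missing class (no evidence assessed) counts as VUS and is kept.
#'
#' @param variants Annotated variant tibble.
#' @param config A [prioritization_config()].
#' @return The retained rows.
#' @export
acmg_filter <- function(variants, config = prioritization_config()) {
  cls <- variants$acmg_class
  if (any(!is.na(cls) & !(cls %in% 1:5))) abort("acmg_class must be in 1..5")
  cls[is.na(cls)] <- 3L
  variants[!(cls %in% config$acmg_discard_classes), , drop = FALSE]
}
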