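# Shared constructors for pedigrees and variant rows used across tests.

trio_ped <- function(family_id = "T1", child_karyo = "XY") {
  pedigree(tibble::tribble(
    ~family_id, ~id, ~father_id, ~mother_id, ~sex_karyotype, ~affected,
    family_id, "father", NA, NA, "XY", "unaffected",
    family_id, "mother", NA, NA, "XX", "unaffected",
    family_id, "index", "father", "mother", child_karyo, "affected"
  ))
}

# Family-35-like structure: two affected brothers (one 47,XXY), healthy sister
family35_ped <- function() {
  pedigree(tibble::tribble(
    ~family_id, ~id, ~father_id, ~mother_id, ~sex_karyotype, ~affected,
    "F35", "I1", NA, NA, "XY", "unaffected",
    "F35", "I2", NA, NA, "XX", "unaffected",
    "F35", "II1", "I1", "I2", "XY", "affected",
    "F35", "II2", "I1", "I2", "XXY", "affected",
    "F35", "II3", "I1", "I2", "XX", "unaffected"
  ))
}

# One variant row with passing defaults; override any field.
mk_variant <- function(chrom = "1", pos = 1000L, ref = "C", alt = "T",
                       gene = "USH2A", consequence = "missense",
                       genotypes = list(c(index = "het")), ...) {
  annotated_variants(tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt, gene = gene,
    consequence = consequence, genotypes = genotypes, ...
  ))
}

# Independent transcription of the ACMG/AMP combining-rule table, written as
# a literal rule-by-rule checklist (the oracle for acmg_combine).
acmg_oracle <- function(codes) {
  codes <- unique(codes)
  n <- function(p) sum(startsWith(codes, p))
  pvs1 <- "PVS1" %in% codes
  ps <- n("PS"); pm <- n("PM"); pp <- n("PP")
  ba1 <- "BA1" %in% codes
  bs <- n("BS"); bp <- n("BP")
  patho <- FALSE
  if (pvs1 && ps >= 1) patho <- TRUE                     # Ia
  if (pvs1 && pm >= 2) patho <- TRUE                     # Ib
  if (pvs1 && pm == 1 && pp == 1) patho <- TRUE          # Ic
  if (pvs1 && pp >= 2) patho <- TRUE                     # Id
  if (ps >= 2) patho <- TRUE                             # II
  if (ps == 1 && pm >= 3) patho <- TRUE                  # IIIa
  if (ps == 1 && pm == 2 && pp >= 2) patho <- TRUE       # IIIb
  if (ps == 1 && pm == 1 && pp >= 4) patho <- TRUE       # IIIc
  lp <- FALSE
  if (pvs1 && pm == 1) lp <- TRUE                        # i
  if (ps == 1 && (pm == 1 || pm == 2)) lp <- TRUE        # ii
  if (ps == 1 && pp >= 2) lp <- TRUE                     # iii
  if (pm >= 3) lp <- TRUE                                # iv
  if (pm == 2 && pp >= 2) lp <- TRUE                     # v
  if (pm == 1 && pp >= 4) lp <- TRUE                     # vi
  ben <- ba1 || bs >= 2
  lb <- (bs == 1 && bp == 1) || bp >= 2
  if ((patho || lp) && (ben || lb)) return(3L)
  if (patho) return(5L)
  if (lp) return(4L)
  if (ben) return(1L)
  if (lb) return(2L)
  3L
}

ALL_ACMG_CODES <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6),
                    paste0("PP", 1:5), "BA1", paste0("BS", 1:4),
                    paste0("BP", 1:7))

# does this candidate call carry exactly the planted causal variants?
is_planted_call <- function(cand_row_ids, manifest) {
  setequal(cand_row_ids, manifest$causal_ids)
}
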