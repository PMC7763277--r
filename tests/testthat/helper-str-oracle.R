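# Independent brute-force oracle: enumerate all marker intervals free of a
# discordant marker, keep the maximal ones, then apply the excluder rule and
# the outer-bound convention.
oracle_shared_regions <- function(hap, affected, excluders, full_dose = TRUE) {
  asg <- hap$assignments
  mk <- hap$mother_phase
  out <- list()
  carries <- function(rows, H, fd) {
    ok <- !is.na(rows$label) & (rows$label == H | rows$label == "M1+M2")
    if (fd) ok & rows$both_copies else ok
  }
  for (H in c("M1", "M2")) {
    share <- vapply(seq_len(nrow(mk)), function(i) {
      if (!mk$informative[i]) return(NA)
      rows <- asg[asg$marker == mk$marker[i] & asg$individual %in% affected, ]
      if (nrow(rows) < length(affected) || any(!rows$informative)) return(NA)
      all(carries(rows, H, full_dose))
    }, logical(1))
    true_i <- which(!is.na(share) & share)
    if (!length(true_i)) next
    intervals <- list()
    for (i in true_i) for (j in true_i[true_i >= i]) {
      if (!any(vapply(i:j, function(k) isFALSE(share[k]), logical(1)))) {
        intervals[[length(intervals) + 1L]] <- c(i, j)
      }
    }
    # maximal = not contained in a longer discord-free interval
    keep <- Filter(function(iv) {
      !any(vapply(intervals, function(o) {
        (o[1] < iv[1] || o[2] > iv[2]) && o[1] <= iv[1] && o[2] >= iv[2]
      }, logical(1)))
    }, intervals)
    for (iv in keep) {
      falses <- which(vapply(seq_len(nrow(mk)), function(k) isFALSE(share[k]),
                             logical(1)))
      lo_flank <- falses[falses < iv[1]]
      hi_flank <- falses[falses > iv[2]]
      start_i <- if (length(lo_flank)) max(lo_flank) else 1L
      end_i <- if (length(hi_flank)) min(hi_flank) else nrow(mk)
      inside <- seq(start_i, end_i)
      ex_ok <- vapply(excluders, function(e) {
        rows <- asg[asg$individual == e & asg$marker %in% mk$marker[inside] &
                      asg$informative, ]
        nrow(rows) > 0 && any(!carries(rows, H, FALSE))
      }, logical(1))
      if (length(excluders) && !all(ex_ok)) next
      out[[length(out) + 1L]] <- tibble::tibble(
        haplotype = H, start = mk$position[start_i], end = mk$position[end_i])
    }
  }
  if (!length(out)) return(tibble::tibble(haplotype = character(),
                                          start = integer(), end = integer()))
  res <- dplyr::bind_rows(out)
  res[order(res$start, res$haplotype), ]
}

random_str_family <- function(seed) {
  set.seed(seed + 5000)
  n_kids <- sample(2:4, 1)
  karyo <- sample(c("XY", "XX"), n_kids, replace = TRUE)
  if (runif(1) < 0.3) karyo[sample.int(n_kids, 1)] <- "XXY"
  aff <- rep("unaffected", n_kids)
  aff[sample.int(n_kids, sample(1:min(2, n_kids), 1))] <- "affected"
  if (!any(aff == "affected")) aff[1] <- "affected"
  pedigree(tibble::tibble(
    family_id = "R", id = c("dad", "mum", paste0("k", seq_len(n_kids))),
    father_id = c(NA, NA, rep("dad", n_kids)),
    mother_id = c(NA, NA, rep("mum", n_kids)),
    sex_karyotype = c("XY", "XX", karyo),
    affected = c("unaffected", "unaffected", aff)))
}
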