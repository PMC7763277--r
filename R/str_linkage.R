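#' Reconstruct parental-origin X haplotypes from STR genotypes
#'
#' Takes microsatellite genotypes for one nuclear family (a genotype tibble
#' with `individual`, `marker`, `allele1`, `allele2`; `allele2` is `NA` for
#' hemizygous XY males) and labels, per child and marker, which maternal
#' haplotype (M1/M2) was transmitted:
#'
#' * XY sons carry a single allele, which is maternal.
#' * XX daughters: the paternal allele is identified from the father's
#'   hemizygous genotype; the remaining allele is maternal.
#' * XXY sons are resolved against both parents; when neither allele can be
#'   paternal at some marker the two X copies are both maternal, and markers
#'   where the son is homozygous for a maternal allele carry that haplotype
#'   on both copies.
#'
#' The mother's phase (which allele is M1 at each marker) is chosen by a
#' 2-state dynamic program minimizing the total number of recombinations
#' implied across all children. Markers with a Mendelian inconsistency are
#' flagged and dropped from inference; markers where the mother is
#' homozygous are uninformative.
#'
#' @param genotypes STR genotype tibble.
#' @param ped Pedigree tibble for the nuclear family (one father, one mother,
#'   children with both parent links).
#' @param markers Marker map (default the packaged 26-marker panel,
#'   [str_marker_map()]).
#' @return An `str_haplotypes` object: `assignments` (individual, marker,
#'   position, `label` in M1/M2/M1+M2 or `NA`, `both_copies`, `informative`),
#'   `mother_phase` (per-marker M1/M2 alleles), `dropped_markers`, and ids.
#' @export
assign_haplotypes <- function(genotypes, ped, markers = str_marker_map()) {
  ped <- pedigree(ped)
  kids <- ped$id[!is.na(ped$father_id) & !is.na(ped$mother_id)]
  if (!length(kids)) abort("no children with both parents in the pedigree")
  mother <- unique(ped$mother_id[ped$id %in% kids])
  father <- unique(ped$father_id[ped$id %in% kids])
  if (length(mother) != 1L || length(father) != 1L) {
    abort("assign_haplotypes expects a single nuclear family")
  }
  mk <- markers[order(markers$position), ]
  g <- function(ind, marker) {
    row <- genotypes[genotypes$individual == ind & genotypes$marker == marker, ]
    if (!nrow(row)) return(c(NA_integer_, NA_integer_))
    as.integer(c(row$allele1[1], row$allele2[1]))
  }
  M <- nrow(mk)
  mom <- t(vapply(mk$name, function(m) g(mother, m), integer(2)))
  dad <- vapply(mk$name, function(m) g(father, m)[1], integer(1))
  informative <- !is.na(mom[, 1]) & !is.na(mom[, 2]) & mom[, 1] != mom[, 2]

  karyo <- setNames(ped$sex_karyotype, ped$id)
  dropped <- character()

  # maternal allele(s) received by each child at each marker; NA = unknown
  received <- list()
  for (kid in kids) {
    rec <- vector("list", M)
    for (i in seq_len(M)) {
      al <- g(kid, mk$name[i])
      rec[[i]] <- switch(karyo[[kid]],
        XY = al[1],
        XX = {
          if (any(is.na(al)) || is.na(dad[i])) NA_integer_
          else if (al[1] == dad[i]) al[2]
          else if (al[2] == dad[i]) al[1]
          else { dropped <- c(dropped, mk$name[i]); NA_integer_ }
        },
        XXY = al  # resolved below
      )
    }
    received[[kid]] <- rec
  }
  # XXY origin: both-maternal when some marker has no allele matching father
  for (kid in kids[karyo[kids] == "XXY"]) {
    al_list <- received[[kid]]
    both_maternal <- any(vapply(seq_len(M), function(i) {
      al <- al_list[[i]]
      !any(is.na(al)) && !is.na(dad[i]) && !(dad[i] %in% al)
    }, logical(1)))
    received[[kid]] <- map(seq_len(M), function(i) {
      al <- al_list[[i]]
      if (any(is.na(al))) return(NA_integer_)
      if (both_maternal) al
      else if (al[1] == dad[i]) al[2]
      else if (al[2] == dad[i]) al[1]
      else al  # father allele absent here -> both maternal at this marker
    })
  }

  # indicator per single-maternal-allele child: 1 if received mother's allele1
  single_kids <- kids[karyo[kids] != "XXY"]
  ind_mat <- matrix(NA_integer_, nrow = length(kids), ncol = M,
                    dimnames = list(kids, mk$name))
  for (kid in single_kids) {
    for (i in seq_len(M)) {
      a <- received[[kid]][[i]]
      if (length(a) != 1L || is.na(a) || !informative[i]) next
      if (mk$name[i] %in% dropped) next
      if (a == mom[i, 1]) ind_mat[kid, i] <- 1L
      else if (a == mom[i, 2]) ind_mat[kid, i] <- 2L
      else dropped <- c(dropped, mk$name[i])  # Mendelian inconsistency
    }
  }
  for (d in unique(dropped)) ind_mat[, mk$name == d] <- NA_integer_

  # DP over informative markers: phase[i] = 1 keeps (M1 = mom allele1)
  inf_idx <- which(informative & !(mk$name %in% dropped))
  phase <- rep(1L, M)
  if (length(inf_idx) > 1) {
    cost <- matrix(0, nrow = 2, ncol = length(inf_idx))
    back <- matrix(1L, nrow = 2, ncol = length(inf_idx))
    for (j in 2:length(inf_idx)) {
      i_prev <- inf_idx[j - 1]; i_cur <- inf_idx[j]
      trans <- matrix(0, 2, 2)
      for (p_prev in 1:2) for (p_cur in 1:2) {
        n_switch <- 0
        for (kid in single_kids) {
          b1 <- ind_mat[kid, i_prev]; b2 <- ind_mat[kid, i_cur]
          if (is.na(b1) || is.na(b2)) next
          lab1 <- if (b1 == p_prev) 1L else 2L
          lab2 <- if (b2 == p_cur) 1L else 2L
          if (lab1 != lab2) n_switch <- n_switch + 1
        }
        trans[p_prev, p_cur] <- n_switch
      }
      for (p_cur in 1:2) {
        tot <- cost[, j - 1] + trans[, p_cur]
        back[p_cur, j] <- which.min(tot)
        cost[p_cur, j] <- min(tot)
      }
    }
    p <- which.min(cost[, length(inf_idx)])
    states <- integer(length(inf_idx))
    for (j in length(inf_idx):1) {
      states[j] <- p
      p <- back[p, j]
    }
    phase[inf_idx] <- states
  }
  m1 <- ifelse(phase == 1L, mom[, 1], mom[, 2])
  m2 <- ifelse(phase == 1L, mom[, 2], mom[, 1])

  rows <- list()
  for (kid in kids) {
    for (i in seq_len(M)) {
      a <- received[[kid]][[i]]
      lab <- NA_character_; both <- NA
      if (!informative[i] || mk$name[i] %in% dropped || any(is.na(a))) {
        # uninformative
      } else if (length(a) == 1L) {
        lab <- if (a == m1[i]) "M1" else if (a == m2[i]) "M2" else NA_character_
        both <- karyo[[kid]] == "XY"  # hemizygous: the only copy
      } else {
        hit1 <- m1[i] %in% a; hit2 <- m2[i] %in% a
        if (a[1] == a[2]) {
          lab <- if (a[1] == m1[i]) "M1" else if (a[1] == m2[i]) "M2" else NA_character_
          both <- TRUE  # homozygous across both X copies
        } else if (hit1 && hit2) {
          lab <- "M1+M2"; both <- FALSE
        } else if (hit1) { lab <- "M1"; both <- FALSE
        } else if (hit2) { lab <- "M2"; both <- FALSE }
      }
      rows[[length(rows) + 1L]] <- tibble(
        individual = kid, marker = mk$name[i], position = mk$position[i],
        label = lab, both_copies = both,
        informative = informative[i] && !(mk$name[i] %in% dropped) && !is.na(lab)
      )
    }
  }

  structure(list(
    assignments = bind_rows(rows),
    mother_phase = tibble(marker = mk$name, position = mk$position,
                          m1_allele = m1, m2_allele = m2,
                          informative = informative & !(mk$name %in% dropped)),
    dropped_markers = unique(dropped),
    mother = mother, father = father, children = kids
  ), class = "str_haplotypes")
}

#' @export
print.str_haplotypes <- function(x, ...) {
  cat(sprintf("<str_haplotypes> %d children x %d markers (%d informative, %d dropped)\n",
              length(x$children), length(unique(x$assignments$marker)),
              sum(x$mother_phase$informative), length(x$dropped_markers)))
  invisible(x)
}

# does this individual carry haplotype hap at marker row(s)? full_dose: on
# every X copy (hemizygous XY, or homozygous for the haplotype allele)
carries_hap <- function(assign_rows, hap, full_dose = FALSE) {
  lab <- assign_rows$label
  has <- !is.na(lab) & (lab == hap | lab == "M1+M2")
  if (full_dose) has & assign_rows$both_copies else has
}

#' Maximal X regions shared by all affected and absent in excluders
#'
#' Scans the informative markers for maximal runs where every affected
#' individual carries the same maternal haplotype in a disease-compatible
#' state (hemizygous in XY males; on both X copies for XX/XXY individuals
#' under the gene-dosage hypothesis, i.e. homozygous for the haplotype's
#' allele) and where each excluder lacks that haplotype at one or more
#' informative markers inside the region. Interval bounds extend outward to
#' the flanking discordant markers (the recombinant markers), the "maximum
#' common region" convention; when uninformative markers sit between the
#' last shared marker and the flank, the true breakpoint cannot be placed
#' and the boundary is flagged ambiguous.
#'
#' @param hap An `str_haplotypes` object from [assign_haplotypes()].
#' @param affected Character vector of affected children.
#' @param excluders Character vector of individuals that must not share
#'   (e.g. a healthy sibling); may be empty.
#' @param full_dose Require the haplotype on every X copy of each affected
#'   (default TRUE, the dosage hypothesis).
#' @return Tibble of shared regions: `haplotype`, `chrom`, `start`, `end`,
#'   marker bounds, carriers/excluded list-columns, ambiguity flags.
#' @export
shared_regions <- function(hap, affected, excluders = character(),
                           full_dose = TRUE) {
  asg <- hap$assignments
  mk <- hap$mother_phase
  if (!any(mk$informative)) {
    warn("no informative markers; no shared regions can be inferred")
    return(empty_shared_regions())
  }
  out <- list()
  for (H in c("M1", "M2")) {
    share <- vapply(seq_len(nrow(mk)), function(i) {
      if (!mk$informative[i]) return(NA)
      rows <- asg[asg$marker == mk$marker[i] & asg$individual %in% affected, ]
      if (nrow(rows) < length(affected) || any(!rows$informative)) return(NA)
      all(carries_hap(rows, H, full_dose))
    }, logical(1))
    runs <- true_runs(share)
    for (r in runs) {
      lo <- r[1]; hi <- r[2]
      # each excluder must lack H at >=1 informative marker inside the region
      flank_lo <- last_false_before(share, lo)
      flank_hi <- first_false_after(share, hi)
      start_i <- if (is.na(flank_lo)) 1L else flank_lo
      end_i <- if (is.na(flank_hi)) nrow(mk) else flank_hi
      inside <- seq(start_i, end_i)
      excl_ok <- vapply(excluders, function(e) {
        rows <- asg[asg$individual == e & asg$marker %in% mk$marker[inside] &
                      asg$informative, ]
        nrow(rows) > 0 && any(!carries_hap(rows, H, full_dose = FALSE))
      }, logical(1))
      if (length(excluders) && !all(excl_ok)) next
      out[[length(out) + 1L]] <- tibble(
        haplotype = H, chrom = "X",
        start = mk$position[start_i], end = mk$position[end_i],
        first_marker = mk$marker[lo], last_marker = mk$marker[hi],
        lower_flank = if (is.na(flank_lo)) NA_character_ else mk$marker[flank_lo],
        upper_flank = if (is.na(flank_hi)) NA_character_ else mk$marker[flank_hi],
        n_markers = sum(!is.na(share[lo:hi]) & share[lo:hi]),
        carriers = list(affected),
        excluded = list(excluders[excl_ok]),
        ambiguous_lower = !is.na(flank_lo) && flank_lo + 1L <= lo - 1L &&
          any(is.na(share[(flank_lo + 1L):(lo - 1L)])),
        ambiguous_upper = !is.na(flank_hi) && hi + 1L <= flank_hi - 1L &&
          any(is.na(share[(hi + 1L):(flank_hi - 1L)]))
      )
    }
  }
  if (!length(out)) return(empty_shared_regions())
  res <- bind_rows(out)
  res[order(res$start, res$haplotype), ]
}

empty_shared_regions <- function() {
  tibble(haplotype = character(), chrom = character(), start = integer(),
         end = integer(), first_marker = character(), last_marker = character(),
         lower_flank = character(), upper_flank = character(),
         n_markers = integer(), carriers = list(), excluded = list(),
         ambiguous_lower = logical(), ambiguous_upper = logical())
}

# maximal runs of TRUE, NA transparent (does not break a run)
true_runs <- function(x) {
  runs <- list()
  i <- 1L; n <- length(x)
  while (i <= n) {
    if (isTRUE(x[i])) {
      j <- i
      last_true <- i
      while (j < n && !isFALSE(x[j + 1L])) {
        j <- j + 1L
        if (isTRUE(x[j])) last_true <- j
      }
      runs[[length(runs) + 1L]] <- c(i, last_true)
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

last_false_before <- function(x, i) {
  idx <- which(vapply(seq_len(i - 1L), function(k) isFALSE(x[k]), logical(1)))
  if (length(idx)) max(idx) else NA_integer_
}

first_false_after <- function(x, i) {
  if (i >= length(x)) return(NA_integer_)
  idx <- which(vapply((i + 1L):length(x), function(k) isFALSE(x[k]), logical(1)))
  if (length(idx)) i + min(idx) else NA_integer_
}

#' List genes overlapping each shared region
#'
#' @param regions Output of [shared_regions()] (or any interval tibble).
#' @param gene_map Interval tibble with a `gene` column (default the
#'   packaged X map, [xchr_gene_map()]).
#' @return `regions` with a `genes` list-column (map order preserved).
#' @export
genes_in_region <- function(regions, gene_map = xchr_gene_map()) {
  regions$genes <- map(seq_len(nrow(regions)), function(i) {
    hit <- gene_map$chrom == regions$chrom[i] &
      gene_map$start <= regions$end[i] & gene_map$end >= regions$start[i]
    gene_map$gene[hit]
  })
  regions
}
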