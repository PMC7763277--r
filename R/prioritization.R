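INHERITANCE_MODES <- c("AR", "AD", "XLR", "XLD")

#' Cascade configuration
#'
#' Thresholds of the prioritization cascade. Defaults are the study values:
#' MAF < 0.01 for recessive and < 0.0001 for dominant hypotheses, non-coding
#' variants kept only within 10 bp of a canonical splice site, a 20-read
#' depth floor, benign/likely-benign (classes 1-2) discarded, and recovery of
#' reported-pathogenic variants up to any frequency when a family would
#' otherwise be empty-handed. The effective MAF of a variant is the maximum
#' across the four population databases (GnomAD, EVS, 1000GP, CSVS); absence
#' from all of them counts as 0.
#'
#' @param maf_recessive,maf_dominant Frequency ceilings per hypothesis.
#' @param splice_max_distance_bp Maximum distance from a canonical splice
#'   site for intronic/UTR variants.
#' @param min_depth QC depth floor (reads).
#' @param max_fs QC ceiling for the Phred-scaled strand-bias statistic.
#' @param ird_gene_list Gene symbols used for tiering (default the packaged
#'   retinal-disease snapshot, [ird_genes()]).
#' @param acmg_discard_classes ACMG classes removed by [acmg_filter()].
#' @return A `prioritization_config` list.
#' @export
prioritization_config <- function(maf_recessive = 0.01, maf_dominant = 0.0001,
                                  splice_max_distance_bp = 10L, min_depth = 20L,
                                  max_fs = 60.0,
                                  ird_gene_list = ird_genes(),
                                  acmg_discard_classes = c(1L, 2L)) {
  if (maf_dominant > maf_recessive) abort("maf_dominant must be <= maf_recessive")
  structure(list(
    maf_recessive = maf_recessive, maf_dominant = maf_dominant,
    splice_max_distance_bp = splice_max_distance_bp, min_depth = min_depth,
    max_fs = max_fs, ird_gene_list = ird_gene_list,
    acmg_discard_classes = acmg_discard_classes
  ), class = "prioritization_config")
}

mode_is_recessive <- function(mode) mode %in% c("AR", "XLR")
mode_is_x <- function(mode) mode %in% c("XLR", "XLD")

#' Population-frequency filter
#'
#' Keeps variants whose effective MAF (maximum over databases; unobserved
#' everywhere = 0) is strictly below the mode's ceiling: 0.01 for recessive
#' modes (AR, XLR), 0.0001 for dominant modes (AD, XLD).
#'
#' @param variants Annotated variant tibble.
#' @param mode One of `"AR"`, `"AD"`, `"XLR"`, `"XLD"`.
#' @param config A [prioritization_config()].
#' @return The retained rows.
#' @export
frequency_filter <- function(variants, mode, config = prioritization_config()) {
  mode <- match.arg(mode, INHERITANCE_MODES)
  thr <- if (mode_is_recessive(mode)) config$maf_recessive else config$maf_dominant
  variants[effective_maf(variants) < thr, , drop = FALSE]
}

#' Consequence filter
#'
#' Removes non-coding (intronic/UTR) variants farther than
#' `splice_max_distance_bp` from a canonical splice site. Synonymous variants
#' are kept unconditionally in genes of the IRD tier; in non-IRD genes they
#' are kept only when they fall in the first or last two bases of an exon
#' (possible splicing effect).
#'
#' @inheritParams frequency_filter
#' @return The retained rows.
#' @export
consequence_filter <- function(variants, config = prioritization_config()) {
  ird <- variants$gene %in% config$ird_gene_list
  noncoding <- variants$consequence %in% c("intronic", "UTR")
  near_splice <- variants$splice_distance_bp <= config$splice_max_distance_bp
  syn <- variants$consequence == "synonymous"
  boundary <- !is.na(variants$exon_boundary_offset) &
    variants$exon_boundary_offset %in% c(1L, 2L)
  keep <- rep(TRUE, nrow(variants))
  keep[noncoding & !near_splice] <- FALSE
  keep[syn & !ird & !boundary] <- FALSE
  variants[keep, , drop = FALSE]
}

#' Zygosity / inheritance-compatibility filter
#'
#' Keeps variants whose genotype in the index patient is compatible with the
#' inheritance hypothesis. Autosomal modes consider autosomes only, X-linked
#' modes the X chromosome only. Dominant modes keep heterozygotes and discard
#' homozygotes. AR keeps homozygotes plus heterozygotes that have at least
#' one other surviving heterozygous partner in the same gene (compound-het
#' compatibility). XLR keeps hemizygotes (XY index) or alternate homozygotes
#' (XX/XXY index, both X copies). Hemizygous genotypes recorded on an
#' autosome, or on X for a two-X-copy index, are a data error.
#'
#' @inheritParams frequency_filter
#' @param index_individual Index patient id.
#' @param karyotype Index `sex_karyotype` (`"XX"`, `"XY"`, `"XXY"`).
#' @return The retained rows.
#' @export
zygosity_filter <- function(variants, mode, index_individual, karyotype = "XY") {
  mode <- match.arg(mode, INHERITANCE_MODES)
  on_x <- is_x_chrom(variants$chrom)
  v <- if (mode_is_x(mode)) variants[on_x, , drop = FALSE]
       else variants[!on_x, , drop = FALSE]
  if (!nrow(v)) return(v)
  gt <- genotype_of(v, index_individual)
  hem_autosome <- gt == "hem_alt" & !is_x_chrom(v$chrom)
  hem_two_x <- gt == "hem_alt" & is_x_chrom(v$chrom) & karyotype %in% c("XX", "XXY")
  if (any(hem_autosome) || any(hem_two_x)) {
    abort("hem_alt genotype recorded where the index carries two chromosome copies")
  }
  keep <- switch(mode,
    AD = gt == "het",
    XLD = gt == "het",
    AR = {
      het <- gt == "het"
      paired <- het & ave_count(v$gene, het) >= 2
      gt == "hom_alt" | paired
    },
    XLR = if (karyotype == "XY") gt == "hem_alt" else gt == "hom_alt"
  )
  v[keep, , drop = FALSE]
}

# per-gene count of TRUE flags, aligned to rows
ave_count <- function(gene, flag) {
  tab <- tapply(flag, gene, sum)
  as.integer(tab[gene])
}

#' Control-genotype filter
#'
#' Uses GnomAD genotype counts as the control population. Under recessive
#' hypotheses a variant must be absent in homozygous and hemizygous state in
#' controls; dominant hypotheses additionally require absence in heterozygous
#' state. Variants already reported pathogenic (ClinVar/HGMD/LOVD) bypass
#' the filter.
#'
#' @inheritParams frequency_filter
#' @return The retained rows.
#' @export
control_genotype_filter <- function(variants, mode) {
  mode <- match.arg(mode, INHERITANCE_MODES)
  counts <- cbind(variants$gnomad_het, variants$gnomad_hem, variants$gnomad_hom)
  if (any(counts < 0, na.rm = TRUE)) abort("GnomAD genotype counts must be >= 0")
  ok <- variants$gnomad_hom == 0 & variants$gnomad_hem == 0
  if (!mode_is_recessive(mode)) ok <- ok & variants$gnomad_het == 0
  variants[variants$reported_pathogenic | ok, , drop = FALSE]
}

# Pointwise pass/fail per filter, independent of order; drives the audit
# trail and the recovery rules ("removed solely for ...").
pointwise_verdicts <- function(variants, mode, config, lax = FALSE) {
  fs <- variants$fs_phred
  fs[is.na(fs)] <- 0
  thr <- if (mode_is_recessive(mode)) config$maf_recessive else config$maf_dominant
  ird <- variants$gene %in% config$ird_gene_list
  noncoding <- variants$consequence %in% c("intronic", "UTR")
  syn <- variants$consequence == "synonymous"
  boundary <- !is.na(variants$exon_boundary_offset) &
    variants$exon_boundary_offset %in% c(1L, 2L)
  cls <- variants$acmg_class
  cls[is.na(cls)] <- 3L
  ctrl_ok <- variants$gnomad_hom == 0 & variants$gnomad_hem == 0
  if (!mode_is_recessive(mode)) ctrl_ok <- ctrl_ok & variants$gnomad_het == 0
  tibble(
    variant_id = variants$variant_id,
    depth_ok = variants$depth >= config$min_depth,
    fs_ok = fs <= config$max_fs,
    freq_ok = effective_maf(variants) < thr,
    consequence_ok = !(noncoding & variants$splice_distance_bp > config$splice_max_distance_bp) &
      !(syn & !ird & !boundary),
    control_ok = lax | variants$reported_pathogenic | ctrl_ok,
    acmg_ok = lax | !(cls %in% config$acmg_discard_classes)
  )
}

#' Recover variants for otherwise-empty analyses
#'
#' When a mode yields no candidate for a family, two removal reasons are
#' reconsidered: (a) variants removed solely for low coverage (< `min_depth`)
#' and (b) reported-pathogenic variants removed solely for exceeding the
#' frequency ceiling. A variant also failing any other filter is not
#' recovered.
#'
#' @param removed Variant tibble of removed variants.
#' @inheritParams frequency_filter
#' @param lax Whether the control-genotype and ACMG filters are switched off.
#' @return The recoverable rows of `removed`.
#' @export
recover_variants <- function(removed, mode, config = prioritization_config(),
                             lax = FALSE) {
  if (!nrow(removed)) return(removed)
  pw <- pointwise_verdicts(removed, mode, config, lax = lax)
  depth_only <- !pw$depth_ok & pw$fs_ok & pw$freq_ok & pw$consequence_ok &
    pw$control_ok & pw$acmg_ok
  maf_only <- removed$reported_pathogenic & !pw$freq_ok & pw$depth_ok &
    pw$fs_ok & pw$consequence_ok & pw$control_ok & pw$acmg_ok
  removed[depth_only | maf_only, , drop = FALSE]
}

# Build candidate calls from the surviving variants of one mode.
build_candidates <- function(kept, mode, config, index_id, recovered_ids = character()) {
  if (!nrow(kept)) return(empty_candidates())
  gt <- genotype_of(kept, index_id)
  out <- list()
  add <- function(rows, type) {
    v <- kept[rows, , drop = FALSE]
    out[[length(out) + 1L]] <<- tibble(
      mode = mode, gene = v$gene[1], call_type = type,
      variant_ids = list(sort(v$variant_id)),
      hgvs_c = paste(v$hgvs_c, collapse = ";"),
      chrom = v$chrom[1], pos = min(v$pos),
      tier = if (v$gene[1] %in% config$ird_gene_list) "IRD_gene" else "novel_candidate",
      acmg_class = max(c(v$acmg_class, 3L), na.rm = TRUE),
      maf = max(effective_maf(v)),
      recovered = any(v$variant_id %in% recovered_ids),
      modifier_flag = FALSE
    )
  }
  if (mode %in% c("AD", "XLD")) {
    for (i in which(gt == "het")) add(i, "het_dominant")
  } else if (mode == "XLR") {
    for (i in which(gt == "hem_alt")) add(i, "hem")
    for (i in which(gt == "hom_alt")) add(i, "hom")
  } else {
    for (i in which(gt == "hom_alt")) add(i, "hom")
    # compound-het pairs among surviving heterozygotes of one gene
    for (g in unique(kept$gene)) {
      idx <- which(kept$gene == g & gt == "het")
      if (length(idx) >= 2) {
        pairs <- utils::combn(idx, 2, simplify = FALSE)
        for (p in pairs) add(p, "comphet")
      }
    }
  }
  if (!length(out)) return(empty_candidates())
  bind_rows(out)
}

empty_candidates <- function() {
  tibble(mode = character(), gene = character(), call_type = character(),
         variant_ids = list(), hgvs_c = character(), chrom = character(),
         pos = integer(), tier = character(), acmg_class = integer(),
         maf = numeric(), recovered = logical(), modifier_flag = logical())
}

rank_candidates <- function(cand) {
  if (!nrow(cand)) return(cand)
  ord <- order(match(cand$tier, c("IRD_gene", "novel_candidate")),
               -cand$acmg_class, cand$maf, cand$chrom, cand$pos)
  cand[ord, , drop = FALSE]
}

#' Run the full prioritization cascade
#'
#' Executes, for each inheritance hypothesis (AR, AD, XLR, XLD), the ordered
#' filter cascade: QC (depth/strand bias) -> population frequency ->
#' consequence -> zygosity and compound-het pairing -> control genotypes ->
#' ACMG class -> candidate tiering (known IRD genes first, then novel
#' candidates) -> familial segregation (when relative genotypes are present)
#' -> recovery when a mode ends empty. With `lax = TRUE` the
#' control-genotype and ACMG steps are skipped (the re-analysis mode used to
#' revisit linked regions). A full audit trail of removals is retained.
#'
#' @param variants Annotated variant tibble (genotypes include the family).
#' @param ped Pedigree tibble; the index is its first affected member unless
#'   `index_id` is given.
#' @param config A [prioritization_config()].
#' @param design Optional [target_design()]; when given, variants are first
#'   restricted to its primary regions.
#' @param lax Skip control-genotype and ACMG filters.
#' @param modes Inheritance hypotheses to run (default all four).
#' @param index_id Optional explicit index patient.
#' @param check_segregation Whether to run co-segregation on candidates
#'   (default TRUE; needs >= 1 genotyped non-index relative).
#' @return An `ird_prioritization` object: `candidates` (ranked tibble),
#'   `removed` (audit tibble: mode, variant_id, step, reason), `flags`.
#' @export
run_cascade <- function(variants, ped, config = prioritization_config(),
                        design = NULL, lax = FALSE,
                        modes = INHERITANCE_MODES, index_id = NULL,
                        check_segregation = TRUE) {
  ped <- pedigree(ped)
  index_id <- index_of(ped, index_id)
  karyo <- ped$sex_karyotype[ped$id == index_id]
  if (!is.null(design)) variants <- intersect_with_design(variants, design, "primary")

  audit <- list()
  note <- function(mode, v, step, reason) {
    if (nrow(v)) {
      audit[[length(audit) + 1L]] <<- tibble(mode = mode, variant_id = v$variant_id,
                                             step = step, reason = reason)
    }
  }
  all_cand <- list()
  recovery_applied <- logical(0)

  for (mode in modes) {
    qc <- apply_qc_filters(variants, config$min_depth, config$max_fs)
    if (nrow(qc$removed)) {
      for (i in seq_len(nrow(qc$removed))) {
        note(mode, qc$removed[i, ], "qc", paste(qc$removed$reasons[[i]], collapse = "+"))
      }
    }
    k <- qc$kept
    k2 <- frequency_filter(k, mode, config)
    note(mode, anti_join(k, k2, by = "variant_id"), "frequency", "high_maf")
    k3 <- consequence_filter(k2, config)
    note(mode, anti_join(k2, k3, by = "variant_id"), "consequence", "consequence")

    run_tail <- function(kin, recovered_ids = character()) {
      k4 <- zygosity_filter(kin, mode, index_id, karyo)
      scope <- if (mode_is_x(mode)) kin[is_x_chrom(kin$chrom), , drop = FALSE]
               else kin[!is_x_chrom(kin$chrom), , drop = FALSE]
      note(mode, anti_join(scope, k4, by = "variant_id"), "zygosity", "zygosity")
      k5 <- if (lax) k4 else control_genotype_filter(k4, mode)
      note(mode, anti_join(k4, k5, by = "variant_id"), "control_genotypes", "control_genotypes")
      k6 <- if (lax) k5 else acmg_filter(k5, config)
      note(mode, anti_join(k5, k6, by = "variant_id"), "acmg", "benign_class")
      # AR pairing can be broken by later filters; re-check partners survive
      if (mode == "AR" && nrow(k6)) {
        gt6 <- genotype_of(k6, index_id)
        het <- gt6 == "het"
        orphan <- het & ave_count(k6$gene, het) < 2
        note(mode, k6[orphan, , drop = FALSE], "zygosity", "unpaired_het")
        k6 <- k6[!orphan, , drop = FALSE]
      }
      cand <- build_candidates(k6, mode, config, index_id, recovered_ids)
      if (check_segregation && nrow(cand)) {
        seg <- map(seq_len(nrow(cand)), function(i) {
          check_segregation(cand[i, ], ped, k6[k6$variant_id %in% cand$variant_ids[[i]], , drop = FALSE])
        })
        cand$seg_consistent <- map_lgl(seg, "consistent")
        cand$seg_affected <- map_int(seg, "affected_checked")
        cand$seg_healthy <- map_int(seg, "healthy_checked")
        cand$seg_label <- map_chr(seg, count_segregants)
        cand$phase_resolved <- map_lgl(seg, function(s) isTRUE(s$phase_resolved))
        bad <- !is.na(cand$seg_consistent) & !cand$seg_consistent
        for (i in which(bad)) {
          audit[[length(audit) + 1L]] <<- tibble(mode = mode,
            variant_id = cand$variant_ids[[i]], step = "segregation",
            reason = "non_segregating")
        }
        cand <- cand[!bad, , drop = FALSE]
      } else if (nrow(cand)) {
        cand$seg_consistent <- NA
        cand$seg_affected <- NA_integer_
        cand$seg_healthy <- NA_integer_
        cand$seg_label <- "No"
        cand$phase_resolved <- NA
      }
      cand
    }

    cand <- run_tail(k3)
    rec_applied <- FALSE
    if (!nrow(cand)) {
      removed_ids <- unique(unlist(map(audit, function(a) a$variant_id[a$mode == mode])))
      removed_v <- variants[variants$variant_id %in% removed_ids, , drop = FALSE]
      rec <- recover_variants(removed_v, mode, config, lax = lax)
      if (nrow(rec)) {
        rec_applied <- TRUE
        note(mode, rec, "recovery", "recovered")
        cand <- run_tail(bind_rows(k3, rec), recovered_ids = rec$variant_id)
      }
    }
    recovery_applied[mode] <- rec_applied
    all_cand[[mode]] <- cand
  }

  structure(list(
    candidates = rank_candidates(bind_rows(all_cand)),
    removed = if (length(audit)) bind_rows(audit) else
      tibble(mode = character(), variant_id = character(),
             step = character(), reason = character()),
    flags = list(lax = lax, recovery_applied = recovery_applied),
    index_id = index_id, modes = modes
  ), class = "ird_prioritization")
}

#' @export
print.ird_prioritization <- function(x, ...) {
  cat(sprintf("<ird_prioritization> index %s, %d candidate call(s)%s\n",
              x$index_id, nrow(x$candidates),
              if (x$flags$lax) " [lax]" else ""))
  if (nrow(x$candidates)) {
    print(x$candidates[, c("mode", "gene", "call_type", "tier", "hgvs_c", "seg_label")])
  }
  invisible(x)
}

#' Compare prioritization results across two sequencing strategies
#'
#' When two affected relatives were sequenced on different designs, a
#' candidate seen in only one of them, at a position both designs cover
#' (`common_regions`), is contradicted by its absence in the other relative:
#' with a shared phenotype it is removed; with discordant phenotypes
#' (intrafamilial variability) it is instead kept and flagged as a possible
#' second-site modifier. Candidates outside the common regions are never
#' touched (absence there is not evidence).
#'
#' @param result_a,result_b `ird_prioritization` results for the two relatives.
#' @param common_regions Interval tibble covered by both designs.
#' @param same_phenotype Do the two relatives share the phenotype?
#' @return A list with the two adjusted results (`a`, `b`).
#' @export
cross_strategy_compare <- function(result_a, result_b, common_regions,
                                   same_phenotype = TRUE) {
  key <- function(cand) paste(cand$gene, map_chr(cand$variant_ids, paste, collapse = "|"))
  adjust <- function(mine, other) {
    cand <- mine$candidates
    if (!nrow(cand)) return(mine)
    unshared <- !(key(cand) %in% key(other$candidates))
    inside <- map_lgl(seq_len(nrow(cand)), function(i) {
      ids <- cand$variant_ids[[i]]
      pos <- as.integer(sub(".*?:(\\d+):.*", "\\1", ids))
      chrom <- sub(":.*", "", ids)
      all(points_in_intervals(chrom, pos, common_regions))
    })
    hit <- unshared & inside
    if (same_phenotype) {
      mine$candidates <- cand[!hit, , drop = FALSE]
    } else {
      cand$modifier_flag[hit] <- TRUE
      mine$candidates <- cand
    }
    mine
  }
  list(a = adjust(result_a, result_b), b = adjust(result_b, result_a))
}
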