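#' Variant-level quality-control filters
#'
#' Keeps variants with sequencing depth of at least `min_depth` reads and a
#' Phred-scaled Fisher strand-bias statistic of at most `max_fs`. Values
#' exactly at a threshold are kept (removal uses the strict inequalities
#' depth < 20 and FS > 60). Missing FS is treated as 0. Removed variants are
#' returned with machine-readable reasons (`low_coverage`, `strand_bias`) so
#' the recovery step can later re-admit depth-only removals.
#'
#' @param variants Annotated variant tibble.
#' @param min_depth Minimum read depth (default 20).
#' @param max_fs Maximum FS in Phred units (default 60.0).
#' @return A list with `kept` (variant tibble) and `removed` (tibble with
#'   `variant_id` and a `reasons` list-column).
#' @export
apply_qc_filters <- function(variants, min_depth = 20, max_fs = 60.0) {
  if (any(variants$depth < 0, na.rm = TRUE)) abort("depth must be >= 0")
  fs <- variants$fs_phred
  fs[is.na(fs)] <- 0
  low <- variants$depth < min_depth
  bias <- fs > max_fs
  keep <- !low & !bias
  removed <- variants[!keep, , drop = FALSE]
  removed$reasons <- pmap(list(low[!keep], bias[!keep]), function(l, b) {
    c(if (l) "low_coverage", if (b) "strand_bias")
  })
  list(kept = variants[keep, , drop = FALSE], removed = removed)
}

#' Normalize per-target read depths to copy-number ratios
#'
#' Double-median normalization: each target's sample depth is scaled by the
#' sample-wide median, the reference likewise, and the ratio of the two
#' scaled depths is reported. Identical sample and reference profiles give
#' ratio 1 everywhere, and the ratios are invariant to rescaling either
#' profile by a constant.
#'
#' @param profile Coverage profile tibble with `chrom`, `start`, `end`,
#'   `gene`, `exon`, `sample_depth` (>= 0) and `reference_depth` (> 0).
#' @return The profile with a `ratio` column appended.
#' @export
normalize_ratios <- function(profile) {
  p <- as_tibble(profile)
  if (!nrow(p)) abort("coverage profile must have at least one target")
  if (any(p$reference_depth <= 0)) abort("reference_depth must be > 0")
  med_s <- median(p$sample_depth)
  med_r <- median(p$reference_depth)
  if (med_s == 0 || med_r == 0) abort("degenerate profile: zero median depth")
  p$ratio <- (p$sample_depth / med_s) / (p$reference_depth / med_r)
  p
}

#' Call copy-number variants from a normalized ratio table
#'
#' Flags maximal runs of at least `min_consecutive_targets` consecutive
#' targets (within a gene, in genomic order) whose ratio falls below the
#' deletion cut-off or above the duplication cut-off. Ratios exactly at a
#' cut-off are not called (the cut-offs are strict: < 0.6 and > 1.40). For
#' deletions, a zygosity hint is attached: run mean ratio near 0.5 suggests
#' a heterozygous deletion, near 0 a homozygous one.
#'
#' @param ratio_table Output of [normalize_ratios()].
#' @param deletion_cutoff Ratios strictly below are deletion evidence (0.6).
#' @param duplication_cutoff Ratios strictly above are duplication evidence (1.40).
#' @param min_consecutive_targets Minimum run length to call (default 2;
#'   use 1 to allow single-exon events).
#' @return Tibble of calls: `chrom`, `start`, `end`, `gene`, `exon_first`,
#'   `exon_last`, `n_targets`, `ratio` (run mean), `call`, `zygosity_hint`.
#' @export
call_cnvs <- function(ratio_table, deletion_cutoff = 0.6,
                      duplication_cutoff = 1.40, min_consecutive_targets = 2L) {
  if (any(!is.finite(ratio_table$ratio))) abort("ratios must be finite")
  calls <- list()
  for (g in unique(ratio_table$gene)) {
    sub <- ratio_table[ratio_table$gene == g, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    state <- ifelse(sub$ratio < deletion_cutoff, "deletion",
             ifelse(sub$ratio > duplication_cutoff, "duplication", "normal"))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] == "normal" || r$lengths[k] < min_consecutive_targets) next
      idx <- starts[k]:ends[k]
      mean_ratio <- mean(sub$ratio[idx])
      hint <- if (r$values[k] == "deletion") {
        if (mean_ratio < 0.25) "hom" else "het"
      } else "none"
      calls[[length(calls) + 1L]] <- tibble(
        chrom = sub$chrom[idx[1]], start = min(sub$start[idx]),
        end = max(sub$end[idx]), gene = g,
        exon_first = sub$exon[idx[1]], exon_last = sub$exon[idx[length(idx)]],
        n_targets = length(idx), ratio = mean_ratio,
        call = r$values[k], zygosity_hint = hint
      )
    }
  }
  if (!length(calls)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  gene = character(), exon_first = character(),
                  exon_last = character(), n_targets = integer(),
                  ratio = numeric(), call = character(),
                  zygosity_hint = character()))
  }
  bind_rows(calls)
}
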