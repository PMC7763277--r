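#' Genomic intervals
#'
#' Intervals are tibbles with `chrom`, `start`, `end` (1-based, inclusive,
#' `start <= end`). BED input is 0-based half-open and converted on read.
#'
#' @param chrom,start,end Vectors describing the intervals.
#' @param ... Further columns carried along (e.g. `gene`).
#' @return A tibble of validated intervals.
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  iv <- tibble(chrom = as.character(chrom), start = as.integer(start),
               end = as.integer(end), ...)
  if (any(iv$start > iv$end)) abort("interval start must be <= end")
  iv
}

#' Read a BED file as 1-based inclusive intervals
#'
#' @param path BED path (3+ columns; a 4th column is kept as `name`).
#' @return Interval tibble.
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  iv <- genomic_intervals(raw[[1]], as.integer(raw[[2]]) + 1L, as.integer(raw[[3]]))
  if (ncol(raw) >= 4) iv$name <- as.character(raw[[4]])
  iv
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals Interval tibble.
#' @param path Output path.
#' @param name_col Optional column to emit as the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, name_col = NULL) {
  out <- data.frame(intervals$chrom, intervals$start - 1L, intervals$end)
  if (!is.null(name_col)) out[[4]] <- intervals[[name_col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Vectorized point-in-any-interval test.
points_in_intervals <- function(chrom, pos, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(pos)))
  vapply(seq_along(pos), function(i) {
    any(intervals$chrom == chrom[i] &
        intervals$start <= pos[i] & intervals$end >= pos[i])
  }, logical(1))
}

#' Construct a sequencing target design
#'
#' A design couples its intended target regions (`primary_regions`: every
#' region meant to be analysed, probe-backed or not) with the regions actually
#' covered by capture probes (`captured_regions`), plus the gene sets they
#' imply. Keeping both matters diagnostically: a variant in a primary-only
#' region (e.g. the repetitive ORF15 of RPGR) is on-target for analysis even
#' though no probe covers it.
#'
#' @param name Design label (`"PS"`, `"CES"`, `"WES"` or free text).
#' @param primary_regions,captured_regions Interval tibbles.
#' @param gene_set Genes included in the design.
#' @param covered_gene_set Genes whose causal regions are actually
#'   sequenceable; must be a subset of `gene_set`.
#' @return A `target_design` object.
#' @export
target_design <- function(name, primary_regions, captured_regions = primary_regions,
                          gene_set = character(), covered_gene_set = gene_set) {
  if (!all(covered_gene_set %in% gene_set)) {
    abort("covered_gene_set must be a subset of gene_set")
  }
  # every captured base must lie inside some primary region
  if (nrow(captured_regions)) {
    ok <- vapply(seq_len(nrow(captured_regions)), function(i) {
      any(primary_regions$chrom == captured_regions$chrom[i] &
          primary_regions$start <= captured_regions$start[i] &
          primary_regions$end >= captured_regions$end[i])
    }, logical(1))
    if (!all(ok)) abort("captured_regions must be contained in primary_regions")
  }
  structure(
    list(name = name,
         primary_regions = as_tibble(primary_regions),
         captured_regions = as_tibble(captured_regions),
         gene_set = sort(unique(gene_set)),
         covered_gene_set = sort(unique(covered_gene_set))),
    class = "target_design"
  )
}

#' @export
print.target_design <- function(x, ...) {
  cat(sprintf("<target_design '%s'>: %d primary / %d captured regions, %d genes (%d covered)\n",
              x$name, nrow(x$primary_regions), nrow(x$captured_regions),
              length(x$gene_set), length(x$covered_gene_set)))
  invisible(x)
}

#' Keep variants on-target for a design
#'
#' Filters a variant table to positions inside the design's `primary` (default)
#' or `captured` regions. Using the primary regions retains variants in
#' probe-free target regions that a capture-dependent file would call
#' off-target.
#'
#' @param variants Annotated variant tibble.
#' @param design A [target_design()].
#' @param use `"primary"` or `"captured"`.
#' @return The retained rows of `variants`.
#' @export
intersect_with_design <- function(variants, design, use = c("primary", "captured")) {
  use <- match.arg(use)
  regions <- if (use == "primary") design$primary_regions else design$captured_regions
  keep <- points_in_intervals(variants$chrom, variants$pos, regions)
  variants[keep, , drop = FALSE]
}
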