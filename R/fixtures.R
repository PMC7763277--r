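FIXTURE_MD5 <- c(
  table1_panel_variants.tsv = "792aa1ee67b476853f6a2b7e17539164",
  table2_ces_variants.tsv   = "ea1f44e3d0f744cfabeffb9a637a929c",
  table3_candidate_variants.tsv = "e69d2aa45db038b839a790127c2cb758",
  cohort_counts.tsv = "3d3f4e807372c067316e3175b3b159fb"
)

fixture_file <- function(file, checked = TRUE) {
  path <- extdata_path(file)
  if (checked && file %in% names(FIXTURE_MD5)) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, unname(FIXTURE_MD5[[file]]))) {
      abort(sprintf("fixture '%s' failed its integrity check (md5 %s)", file, got))
    }
  }
  path
}

#' Load the packaged study-result fixtures
#'
#' Returns the packaged transcriptions of the study's result tables:
#' `table1` - candidate variants found in IRD genes by panel sequencing
#' (38 variant occurrences in 22 families), `table2` - variants found by
#' clinical exome sequencing (5 occurrences, 4 families), `table3` - novel
#' candidate-gene variants (WDFY3 and CITED1, with control genotype counts).
#' Files carry a recorded md5 checksum verified at load time.
#'
#' @param which `"table1"`, `"table2"` or `"table3"`.
#' @return A tibble of fixture records: `family_id`, `gene`, `hgvs_c`,
#'   `hgvs_p`, `status` (Het/Hom/Hem), `acmg_class`, `segregation` (printed
#'   form), `seg_affected`/`seg_healthy` (parsed counts, `NA` when
#'   segregation was not performed), `solved` (logical), `reference`.
#' @export
load_fixtures <- function(which = c("table1", "table2", "table3")) {
  which <- match.arg(which)
  file <- switch(which,
    table1 = "table1_panel_variants.tsv",
    table2 = "table2_ces_variants.tsv",
    table3 = "table3_candidate_variants.tsv"
  )
  rec <- readr::read_tsv(fixture_file(file), show_col_types = FALSE, progress = FALSE)
  rec$family_id <- as.character(rec$family_id)
  seg <- parse_segregation(rec$segregation)
  rec$seg_affected <- seg$affected
  rec$seg_healthy <- seg$healthy
  rec$solved <- rec$solved == "Yes"
  rec
}

# "Yes(2/5)" -> affected 2 / healthy 5; "No" -> NA/NA (not performed)
parse_segregation <- function(x) {
  m <- stringr::str_match(x, "^Yes\\((\\d+)/(\\d+)\\)$")
  list(affected = as.integer(m[, 2]), healthy = as.integer(m[, 3]))
}

#' Cohort composition of the study
#'
#' Family and individual counts for the 42-family cohort (66 affected
#' patients, 113 healthy relatives; 11 families escalated to clinical exome,
#' 5 to whole exome).
#'
#' @return A named numeric vector.
#' @export
cohort_counts <- function() {
  x <- readr::read_tsv(fixture_file("cohort_counts.tsv"),
                       show_col_types = FALSE, progress = FALSE)
  setNames(x$value, x$quantity)
}

#' Packaged IRD-associated gene list
#'
#' A dated snapshot of retinal-disease-associated gene symbols (RetNet-style)
#' used for candidate tiering; replaceable via
#' `prioritization_config(ird_gene_list = ...)`.
#'
#' @return Character vector of gene symbols.
#' @export
ird_genes <- function() {
  readr::read_tsv(extdata_path("ird_gene_list.tsv"),
                  show_col_types = FALSE, progress = FALSE)$gene
}

#' Packaged X-chromosome STR marker map (synthetic positions)
#'
#' The 26 microsatellite markers used for X-chromosome linkage. Marker names
#' follow the DXS nomenclature; positions are synthetic stand-ins on a
#' realistic scale, since only the ordering matters to the haplotype logic.
#'
#' @return Tibble with `name`, `chrom`, `position` (strictly increasing).
#' @export
str_marker_map <- function() {
  m <- readr::read_tsv(extdata_path("str_markers_synthetic.tsv"),
                       show_col_types = FALSE, progress = FALSE)
  stopifnot(all(diff(m$position) > 0))
  m
}

#' Packaged X-chromosome gene map (synthetic coordinates)
#'
#' The eight X-linked IRD genes flanking the mid-X linkage region (NYX, NDP,
#' RP2, CACNA1F, PGK1, CHM, TIMM8A, PRPS1) plus CITED1 and RPGR, at synthetic
#' positions preserving their relative order along the chromosome.
#'
#' @return Interval tibble with a `gene` column.
#' @export
xchr_gene_map <- function() {
  readr::read_tsv(extdata_path("xchr_genes_synthetic.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Reconstructed sequencing designs of the three strategies
#'
#' Gene-level reconstructions of the three designs compared in the study:
#' the custom IRD panel (`ps_design()`: the panel-diagnosed genes plus RPGR,
#' whose repetitive ORF15 is in the design but not sequenceable, so RPGR is
#' absent from `covered_gene_set`), the ~4800-gene clinical exome
#' (`ces_design()`: all disease-associated genes, including WDFY3 but not
#' CITED1), and the whole exome (`wes_design()`: every gene).
#'
#' @return A [target_design()].
#' @export
ps_design <- function() {
  genes <- c(sort(unique(load_fixtures("table1")$gene)), "RPGR")
  target_design("PS", genomic_intervals(character(), integer(), integer()),
                gene_set = genes, covered_gene_set = setdiff(genes, "RPGR"))
}

#' @rdname ps_design
#' @export
ces_design <- function() {
  genes <- sort(unique(c(ird_genes(), load_fixtures("table1")$gene,
                         load_fixtures("table2")$gene, "WDFY3")))
  target_design("CES", genomic_intervals(character(), integer(), integer()),
                gene_set = genes)
}

#' @rdname ps_design
#' @export
wes_design <- function() {
  genes <- sort(unique(c(ird_genes(), load_fixtures("table1")$gene,
                         load_fixtures("table2")$gene,
                         load_fixtures("table3")$gene)))
  target_design("WES", genomic_intervals(character(), integer(), integer()),
                gene_set = genes)
}
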