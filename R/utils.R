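#' @importFrom rlang %||% .data abort warn
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join anti_join distinct n row_number across pull rename
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap keep
#' @importFrom stats median rbeta rbinom rexp rnbinom rpois runif setNames
#' @importFrom utils head tail
NULL

# Consequence vocabulary used throughout the cascade.
CONSEQUENCES <- c(
  "missense", "nonsense", "frameshift", "inframe_indel", "synonymous",
  "splice_canonical", "intronic", "UTR", "other"
)

GENOTYPES <- c("hom_ref", "het", "hom_alt", "hem_alt", "missing")

MAF_DATABASES <- c("gnomad", "evs", "kg1000", "csvs")

#' Stable variant identifier
#'
#' Builds the `chrom:pos:ref>alt` key used to track variants across filters,
#' audits and genotype tables.
#'
#' @param chrom,pos,ref,alt Vectors of VCF-style coordinates (1-based).
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

# Effective MAF: maximum across population databases; unobserved everywhere -> 0.
effective_maf <- function(variants) {
  cols <- paste0("maf_", MAF_DATABASES)
  m <- as.matrix(variants[, cols])
  bad <- !is.na(m) & (m < 0 | m > 1)
  if (any(bad)) abort("MAF values must lie in [0, 1].")
  out <- apply(m, 1L, function(x) if (all(is.na(x))) 0 else max(x, na.rm = TRUE))
  as.numeric(out)
}

# Extract one individual's genotype for every variant row.
genotype_of <- function(variants, individual_id) {
  map_chr(variants$genotypes, function(g) {
    v <- if (individual_id %in% names(g)) g[[individual_id]] else NA_character_
    if (is.na(v)) "missing" else v
  })
}

is_x_chrom <- function(chrom) {
  toupper(sub("^chr", "", chrom)) == "X"
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "irdtriage")
  if (!nzchar(p)) abort(sprintf("packaged data file '%s' not found", file))
  p
}
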