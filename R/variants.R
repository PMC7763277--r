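#' Annotated variant tables
#'
#' The cascade consumes one tibble with a row per called variant and the
#' columns below. Genotypes are a list-column of named character vectors
#' (individual id -> `hom_ref`/`het`/`hom_alt`/`hem_alt`/`missing`), so a
#' variant row is self-contained for a whole family. Annotation is a sidecar
#' table joined onto the VCF, never parsed from INFO, keeping the package
#' annotator-agnostic.
#'
#' Columns: `chrom`, `pos`, `ref`, `alt` (VCF convention, 1-based), `gene`,
#' `transcript`, `hgvs_c`, `hgvs_p`, `consequence` (one of missense, nonsense,
#' frameshift, inframe_indel, synonymous, splice_canonical, intronic, UTR,
#' other), `splice_distance_bp` (bp to the nearest canonical splice site, 0
#' for exonic non-boundary positions), `exon_boundary_offset` (1 or 2 when in
#' the first/last two bases of an exon, else `NA`), `maf_gnomad`, `maf_evs`,
#' `maf_kg1000`, `maf_csvs` (allele frequencies in [0,1], `NA` = unobserved),
#' `gnomad_het`, `gnomad_hem`, `gnomad_hom` (genotype counts in controls),
#' `acmg_codes` (list-column of ACMG criterion codes), `acmg_class` (1-5,
#' derived from the codes when absent), `reported_pathogenic` (a ClinVar/
#' HGMD/LOVD assertion exists), `depth`, `fs_phred`, `genotypes`.
#'
#' @param x A data frame with the columns above (missing optional columns are
#'   filled with defaults).
#' @return A validated variant tibble with a `variant_id` column.
#' @export
annotated_variants <- function(x) {
  v <- as_tibble(x)
  required <- c("chrom", "pos", "ref", "alt", "gene")
  miss <- setdiff(required, names(v))
  if (length(miss)) abort(paste0("variant table missing: ", paste(miss, collapse = ", ")))

  defaults <- list(
    transcript = NA_character_, hgvs_c = NA_character_, hgvs_p = NA_character_,
    consequence = "other", splice_distance_bp = 0L, exon_boundary_offset = NA_integer_,
    maf_gnomad = NA_real_, maf_evs = NA_real_, maf_kg1000 = NA_real_,
    maf_csvs = NA_real_, gnomad_het = 0L, gnomad_hem = 0L, gnomad_hom = 0L,
    acmg_class = NA_integer_, reported_pathogenic = FALSE,
    depth = 0L, fs_phred = 0
  )
  for (nm in names(defaults)) if (!nm %in% names(v)) v[[nm]] <- defaults[[nm]]
  if (!"acmg_codes" %in% names(v)) v$acmg_codes <- replicate(nrow(v), character(), simplify = FALSE)
  if (!"genotypes" %in% names(v)) v$genotypes <- replicate(nrow(v), character(), simplify = FALSE)

  if (!all(v$consequence %in% CONSEQUENCES)) {
    abort(paste0("unknown consequence value(s): ",
                 paste(setdiff(v$consequence, CONSEQUENCES), collapse = ", ")))
  }
  if (any(v$depth < 0, na.rm = TRUE)) abort("depth must be >= 0")
  if (any(v$fs_phred < 0, na.rm = TRUE)) abort("fs_phred must be >= 0")
  counts <- cbind(v$gnomad_het, v$gnomad_hem, v$gnomad_hom)
  if (any(counts < 0, na.rm = TRUE)) abort("GnomAD genotype counts must be >= 0")
  effective_maf(v)  # validates MAF range
  gts <- unlist(v$genotypes)
  if (length(gts) && !all(gts %in% GENOTYPES)) {
    abort("genotype values must be hom_ref/het/hom_alt/hem_alt/missing")
  }
  # derive the five-tier class from evidence codes where absent
  needs <- is.na(v$acmg_class) & lengths(v$acmg_codes) > 0
  if (any(needs)) v$acmg_class[needs] <- map_int(v$acmg_codes[needs], acmg_combine)
  bad_class <- !is.na(v$acmg_class) & !(v$acmg_class %in% 1:5)
  if (any(bad_class)) abort("acmg_class must be in 1..5")

  v$variant_id <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  v
}

GT_TO_CODE <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                hem_alt = "1", missing = "./.")

gt_string_to_call <- function(gt) {
  gt <- sub(":.*", "", gt)
  gt[is.na(gt)] <- "./."
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    a <- a[a != ""]
    if (!length(a) || any(a == ".")) return("missing")
    if (length(a) == 1L) return(if (a == "1") "hem_alt" else "hom_ref")
    n_alt <- sum(a == "1")
    if (n_alt == 0L) "hom_ref" else if (n_alt == length(a)) "hom_alt" else "het"
  }, character(1))
}

#' Read a VCF plus its annotation sidecar into a variant table
#'
#' VCF records are joined to annotation rows by `chrom`/`pos`/`ref`/`alt`.
#' Records without an annotation are dropped and reported via the
#' `"unmatched"` attribute; duplicated annotation keys are an error.
#'
#' @param vcf_path Path to a VCF (v4.x), plain or gzipped.
#' @param annotation_path Path to a TSV with the [annotated_variants()]
#'   columns (minus genotypes); `acmg_codes` may be a comma-separated string.
#' @return An annotated variant tibble.
#' @export
read_variant_table <- function(vcf_path, annotation_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  calls <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  calls$genotypes <- map(seq_len(nrow(calls)), function(i) {
    setNames(gt_string_to_call(gt[i, ]), samples)
  })

  ann <- readr::read_tsv(annotation_path, show_col_types = FALSE, progress = FALSE)
  ann$pos <- as.integer(ann$pos)
  key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(key)) {
    abort(sprintf("ambiguous annotation: duplicated key(s) %s",
                  paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  if ("acmg_codes" %in% names(ann) && is.character(ann$acmg_codes)) {
    ann$acmg_codes <- map(ann$acmg_codes, function(s) {
      if (is.na(s) || !nzchar(s)) character() else strsplit(s, ",")[[1]]
    })
  }
  joined <- dplyr::inner_join(calls, ann, by = c("chrom", "pos", "ref", "alt"))
  unmatched <- dplyr::anti_join(calls, ann, by = c("chrom", "pos", "ref", "alt"))
  if (nrow(unmatched)) {
    warn(sprintf("%d VCF record(s) had no annotation and were dropped", nrow(unmatched)))
  }
  out <- annotated_variants(joined)
  attr(out, "unmatched") <- variant_key(unmatched$chrom, unmatched$pos,
                                        unmatched$ref, unmatched$alt)
  out
}

#' Write a variant table as VCF plus annotation TSV
#'
#' Inverse of [read_variant_table()]; used by the simulators so every
#' generated family exists on disk in standard formats.
#'
#' @param variants Annotated variant tibble.
#' @param vcf_path Output VCF path (written gzipped if it ends in `.gz`).
#' @param annotation_path Output TSV path.
#' @return Invisibly, a list of the two paths.
#' @importClassesFrom vcfR vcfR
#' @export
write_variant_table <- function(variants, vcf_path, annotation_path) {
  v <- annotated_variants(variants)
  samples <- unique(unlist(map(v$genotypes, names)))
  fix <- cbind(
    CHROM = v$chrom, POS = as.character(v$pos), ID = rep(".", nrow(v)),
    REF = v$ref, ALT = v$alt, QUAL = rep(".", nrow(v)),
    FILTER = rep("PASS", nrow(v)),
    INFO = paste0("DP=", v$depth)
  )
  gt <- cbind(
    FORMAT = rep("GT", nrow(v)),
    vapply(samples, function(s) {
      calls <- map_chr(v$genotypes, function(g) {
        val <- g[[s]]
        if (is.null(val)) "missing" else val
      })
      unname(GT_TO_CODE[calls])
    }, character(nrow(v)))
  )
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">")
  obj <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(obj, file = vcf_path)

  ann <- v
  ann$genotypes <- NULL
  ann$variant_id <- NULL
  ann$acmg_codes <- map_chr(v$acmg_codes, paste, collapse = ",")
  readr::write_tsv(ann, annotation_path, progress = FALSE)
  invisible(list(vcf = vcf_path, annotation = annotation_path))
}
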