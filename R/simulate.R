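SIM_MODES <- c("AR_hom", "AR_comphet", "AD", "XLR", "XLR_with_XXY")

AUTOSOMAL_IRD <- c("ABCA4", "USH2A", "PDE6B", "EYS", "CRB1", "PROM1",
                   "BBS10", "MFRP", "FAM161A", "RP1L1")
XLINKED_IRD <- c("RPGR", "RP2", "CHM", "CACNA1F", "NYX", "NDP",
                 "TIMM8A", "PGK1", "PRPS1")

sim_pedigree <- function(mode, family_id = "SIM1") {
  base <- function(...) pedigree(tibble::tribble(
    ~family_id, ~id, ~father_id, ~mother_id, ~sex_karyotype, ~affected, ...
  ))
  switch(mode,
    AR_hom = ,
    AR_comphet = base(
      family_id, "father", NA, NA, "XY", "unaffected",
      family_id, "mother", NA, NA, "XX", "unaffected",
      family_id, "II1", "father", "mother", "XY", "affected",
      family_id, "II2", "father", "mother", "XX", "affected",
      family_id, "II3", "father", "mother", "XY", "unaffected",
      family_id, "II4", "father", "mother", "XX", "unaffected"),
    AD = base(
      family_id, "father", NA, NA, "XY", "affected",
      family_id, "mother", NA, NA, "XX", "unaffected",
      family_id, "II1", "father", "mother", "XY", "affected",
      family_id, "II2", "father", "mother", "XX", "affected",
      family_id, "II3", "father", "mother", "XY", "unaffected",
      family_id, "II4", "father", "mother", "XX", "unaffected"),
    XLR = base(
      family_id, "father", NA, NA, "XY", "unaffected",
      family_id, "mother", NA, NA, "XX", "unaffected",
      family_id, "II1", "father", "mother", "XY", "affected",
      family_id, "II2", "father", "mother", "XY", "affected",
      family_id, "II3", "father", "mother", "XX", "unaffected"),
    XLR_with_XXY = base(
      family_id, "father", NA, NA, "XY", "unaffected",
      family_id, "mother", NA, NA, "XX", "unaffected",
      family_id, "II1", "father", "mother", "XY", "affected",
      family_id, "II2", "father", "mother", "XXY", "affected",
      family_id, "II3", "father", "mother", "XX", "unaffected")
  )
}

# founder allele copies -> per-individual genotype strings, Mendelian drop.
# copies: list(father = int vector, mother = int vector) of 0/1 alt flags;
# transmit: optional list(child -> c(paternal_copy, maternal_copy)) overrides.
drop_genotypes <- function(ped, on_x, copies, transmit = list()) {
  gts <- character(0)
  kids <- ped$id[!is.na(ped$father_id)]
  founders <- setdiff(ped$id, kids)
  enc2 <- function(a) if (sum(a) == 2L) "hom_alt" else if (sum(a) == 1L) "het" else "hom_ref"
  enc1 <- function(a) if (a == 1L) "hem_alt" else "hom_ref"
  for (id in founders) {
    k <- ped$sex_karyotype[ped$id == id]
    cp <- copies[[id]]
    gts[[id]] <- if (on_x && k == "XY") enc1(cp[1]) else enc2(cp[1:2])
  }
  for (id in kids) {
    k <- ped$sex_karyotype[ped$id == id]
    tr <- transmit[[id]] %||% c(sample(1:2, 1), sample(1:2, 1))
    pat <- copies[[ped$father_id[ped$id == id]]]
    mat <- copies[[ped$mother_id[ped$id == id]]]
    pa <- if (on_x) pat[1] else pat[tr[1]]  # X: father passes his single X
    ma <- mat[tr[2]]
    gts[[id]] <- if (!on_x) {
      enc2(c(pa, ma))
    } else if (k == "XY") {
      enc1(ma)                       # sons: maternal X only
    } else if (k == "XXY") {
      enc2(c(ma, ma))                # duplicated maternal gamete
    } else {
      enc2(c(pa, ma))
    }
  }
  gts
}

sample_background_variants <- function(n, ped, params) {
  n_genes <- max(1L, ceiling(n / 2.5))
  gene_pool <- tibble(
    gene = sprintf("BG%04d", seq_len(n_genes)),
    chrom = sample(c(as.character(1:22), "X"), n_genes, replace = TRUE,
                   prob = c(rep(0.9 / 22, 22), 0.1)),
    base = sample.int(2e8, n_genes)
  )
  # a slice of the pool sits in known IRD genes so tiering is exercised;
  # the fraction mirrors the exome-wide density of retinal-disease genes
  # (roughly 280 of 20,000 genes)
  n_ird <- min(length(AUTOSOMAL_IRD),
               max(1L, round(params$ird_gene_fraction * n_genes)))
  swap <- sample.int(n_genes, n_ird)
  gene_pool$gene[swap] <- sample(AUTOSOMAL_IRD, n_ird)
  gene_pool$chrom[swap] <- sample(as.character(1:22), n_ird, replace = TRUE)

  gi <- sample.int(n_genes, n, replace = TRUE)
  maf <- ifelse(runif(n) < params$maf_zero_weight, 0,
                pmin(rbeta(n, params$maf_beta_a, params$maf_beta_b), 1))
  obs <- function(x) ifelse(runif(n) < 0.8 & x > 0, pmin(x * runif(n, 0.8, 1.2), 1), NA)
  consequence <- sample(names(params$consequence_freq), n, replace = TRUE,
                        prob = params$consequence_freq)
  splice_dist <- ifelse(consequence %in% c("intronic", "UTR"),
                        sample.int(50, n, replace = TRUE), 0L)
  boundary <- ifelse(consequence == "synonymous" & runif(n) < 0.1,
                     sample(1:2, n, replace = TRUE), NA_integer_)
  acmg <- map(runif(n), function(u) {
    if (u < 0.10) c("BA1") else if (u < 0.18) c("BS1", "BP4")
    else if (u < 0.22) c("PM2", "PP3") else character()
  })
  v <- tibble(
    chrom = gene_pool$chrom[gi],
    pos = gene_pool$base[gi] + sample.int(5e4, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    gene = gene_pool$gene[gi],
    hgvs_c = sprintf("c.%d%s>%s", sample.int(9000, n, TRUE), "N", "N"),
    hgvs_p = NA_character_,
    consequence = consequence,
    splice_distance_bp = as.integer(splice_dist),
    exon_boundary_offset = boundary,
    maf_gnomad = obs(maf), maf_evs = obs(maf),
    maf_kg1000 = obs(maf), maf_csvs = obs(maf),
    gnomad_het = rpois(n, 2 * maf * params$control_n),
    gnomad_hom = rpois(n, maf^2 * params$control_n),
    reported_pathogenic = runif(n) < 0.02,
    depth = rnbinom(n, size = params$depth_size, mu = params$depth_mean),
    fs_phred = rexp(n, rate = params$fs_rate),
    acmg_codes = acmg
  )
  v$gnomad_hem <- ifelse(is_x_chrom(v$chrom),
                         rpois(n, maf * params$control_n / 4), 0L)
  v$.maf <- maf
  v <- v[!duplicated(variant_key(v$chrom, v$pos, v$ref, v$alt)), , drop = FALSE]
  maf <- v$.maf
  v$.maf <- NULL
  # genotypes: founder copies carry the allele at its own population
  # frequency (Hardy-Weinberg), then one random founder copy is forced to
  # alt — ascertainment: only sites called in the family enter the VCF
  founders <- ped$id[is.na(ped$father_id)]
  v$genotypes <- map(seq_len(nrow(v)), function(i) {
    on_x <- is_x_chrom(v$chrom[i])
    copies <- list()
    slots <- list()
    for (f in founders) {
      ncp <- if (on_x && ped$sex_karyotype[ped$id == f] == "XY") 1L else 2L
      copies[[f]] <- as.integer(runif(2) < maf[i])
      if (ncp == 1L) copies[[f]][2] <- 0L
      for (s in seq_len(ncp)) slots[[length(slots) + 1L]] <- c(f, s)
    }
    pick <- slots[[sample.int(length(slots), 1)]]
    copies[[pick[1]]][as.integer(pick[2])] <- 1L
    drop_genotypes(ped, on_x, copies)
  })
  v
}

planted_annotations <- function(gene, chrom, pos, ref = "C", alt = "T") {
  codes <- list(c("PVS1", "PS3"), c("PVS1", "PM2"), c("PS1", "PM2"),
                c("PS1", "PM2", "PP3"))[[sample.int(4, 1)]]
  tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
    hgvs_c = sprintf("c.%dC>T", pos %% 9000L + 1L), hgvs_p = "p.(?)",
    consequence = sample(c("nonsense", "frameshift", "missense"), 1),
    splice_distance_bp = 0L, exon_boundary_offset = NA_integer_,
    maf_gnomad = if (runif(1) < 0.3) runif(1, 0, 5e-5) else NA_real_,
    maf_evs = NA_real_, maf_kg1000 = NA_real_, maf_csvs = NA_real_,
    gnomad_het = 0L, gnomad_hom = 0L, gnomad_hem = 0L,
    reported_pathogenic = runif(1) < 0.3,
    depth = 40L + rnbinom(1, size = 5, mu = 100),
    fs_phred = runif(1, 0, 10),
    acmg_codes = list(codes)
  )
}

#' Simulate an annotated family variant table with a planted causal genotype
#'
#' Generates a nuclear family under one of five scenarios (`AR_hom`,
#' `AR_comphet`, `AD`, `XLR`, `XLR_with_XXY`), a background of variants with
#' realistic annotation draws (MAF mixture with a point mass at zero and a
#' Beta tail; categorical consequences; negative-binomial depth; exponential
#' strand bias; Poisson control-genotype counts proportional to MAF), and a
#' planted causal genotype in a known IRD gene whose annotations are drawn
#' from the passing region of every pointwise filter. Background genotypes
#' are assigned by Mendelian gene-dropping conditioned on the site being
#' called in the family; a 47,XXY child receives a duplicated maternal
#' gamete. Planted genotypes segregate perfectly by construction.
#'
#' @param mode Scenario name.
#' @param n_background Number of background variants (default 100).
#' @param seed Integer seed; the same seed reproduces identical output.
#' @param out_dir Optional directory; when given, writes `family.ped`,
#'   `family.vcf.gz`, `annotations.tsv` and `manifest.json`.
#' @param params Background-model parameters (see defaults in the source).
#' @return List with `pedigree`, `variants` (annotated variant tibble),
#'   `manifest` (seed, mode, causal ids/gene, cascade mode), and `paths`
#'   when files were written.
#' @export
simulate_family <- function(mode = SIM_MODES, n_background = 100, seed = 1,
                            out_dir = NULL,
                            params = list(maf_zero_weight = 0.3,
                                          maf_beta_a = 0.5, maf_beta_b = 50,
                                          ird_gene_fraction = 0.015,
                                          control_n = 50000,
                                          depth_mean = 150, depth_size = 3,
                                          fs_rate = 0.15,
                                          consequence_freq = c(
                                            missense = 0.48, synonymous = 0.18,
                                            intronic = 0.15, UTR = 0.06,
                                            inframe_indel = 0.03,
                                            splice_canonical = 0.02,
                                            nonsense = 0.02, frameshift = 0.02,
                                            other = 0.04))) {
  mode <- match.arg(mode)
  set.seed(seed)
  ped <- sim_pedigree(mode)
  bg <- sample_background_variants(n_background, ped, params)

  on_x <- mode %in% c("XLR", "XLR_with_XXY")
  gene <- if (on_x) sample(XLINKED_IRD, 1) else sample(AUTOSOMAL_IRD, 1)
  chrom <- if (on_x) "X" else sample(as.character(1:22), 1)
  base_pos <- sample.int(1e8, 1) + 1e6L
  bg <- bg[bg$gene != gene, , drop = FALSE]

  ids <- ped$id
  aff_kids <- ped$id[ped$affected == "affected" & !is.na(ped$father_id)]
  unaff_kids <- ped$id[ped$affected == "unaffected" & !is.na(ped$father_id)]

  plant <- switch(mode,
    AR_hom = {
      v <- planted_annotations(gene, chrom, base_pos)
      copies <- list(father = c(1L, 0L), mother = c(1L, 0L))
      tr <- c(setNames(rep(list(c(1L, 1L)), length(aff_kids)), aff_kids),
              setNames(list(c(2L, 1L), c(2L, 2L)), unaff_kids))
      v$genotypes <- list(drop_genotypes(ped, FALSE, copies, tr))
      v
    },
    AR_comphet = {
      v1 <- planted_annotations(gene, chrom, base_pos)
      v2 <- planted_annotations(gene, chrom, base_pos + 500L, ref = "G", alt = "A")
      c1 <- list(father = c(1L, 0L), mother = c(0L, 0L))
      c2 <- list(father = c(0L, 0L), mother = c(1L, 0L))
      tr_aff <- setNames(rep(list(c(1L, 1L)), length(aff_kids)), aff_kids)
      tr_un <- setNames(list(c(2L, 1L), c(2L, 2L)), unaff_kids)
      v1$genotypes <- list(drop_genotypes(ped, FALSE, c1, c(tr_aff, tr_un)))
      v2$genotypes <- list(drop_genotypes(ped, FALSE, c2, c(tr_aff, tr_un)))
      bind_rows(v1, v2)
    },
    AD = {
      v <- planted_annotations(gene, chrom, base_pos)
      copies <- list(father = c(1L, 0L), mother = c(0L, 0L))
      tr <- c(setNames(rep(list(c(1L, 1L)), length(aff_kids)), aff_kids),
              setNames(rep(list(c(2L, 1L)), length(unaff_kids)), unaff_kids))
      v$genotypes <- list(drop_genotypes(ped, FALSE, copies, tr))
      v
    },
    XLR = ,
    XLR_with_XXY = {
      v <- planted_annotations(gene, "X", base_pos)
      copies <- list(father = c(0L, 0L), mother = c(1L, 0L))
      tr <- c(setNames(rep(list(c(1L, 1L)), length(aff_kids)), aff_kids),
              setNames(rep(list(c(1L, 2L)), length(unaff_kids)), unaff_kids))
      v$genotypes <- list(drop_genotypes(ped, TRUE, copies, tr))
      v
    })

  variants <- annotated_variants(bind_rows(plant, bg))
  manifest <- list(
    seed = seed, mode = mode,
    cascade_mode = switch(mode, AR_hom = "AR", AR_comphet = "AR",
                          AD = "AD", XLR = "XLR", XLR_with_XXY = "XLR"),
    causal_gene = gene,
    causal_ids = variant_key(plant$chrom, plant$pos, plant$ref, plant$alt),
    n_background = nrow(bg)
  )
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      ped = file.path(out_dir, "family.ped"),
      vcf = file.path(out_dir, "family.vcf.gz"),
      annotation = file.path(out_dir, "annotations.tsv"),
      manifest = file.path(out_dir, "manifest.json")
    )
    write_pedigree(ped, paths$ped)
    write_variant_table(variants, paths$vcf, paths$annotation)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  }
  list(pedigree = ped, variants = variants, manifest = manifest, paths = paths)
}

gamete_labels <- function(markers, start, at) {
  lab <- rep(start, nrow(markers))
  for (x in sort(at)) {
    flip <- markers$position > x
    lab[flip] <- ifelse(lab[flip] == "M1", "M2", "M1")
  }
  lab
}

#' Simulate STR genotypes and a coverage profile with planted truth
#'
#' Drops maternal X haplotypes through a nuclear family with the requested
#' crossover positions, producing an STR genotype table (one allele for XY
#' males, two for XX/XXY), plus an exon-level coverage profile with an
#' optional planted copy-number variant (sample depth scaled by 0.5 / 0 /
#' 1.5 for het deletion / hom deletion / duplication, multiplicative noise
#' sd 0.05).
#'
#' A 47,XXY child is specified via `xxy_spec[[id]] = list(copy1 =
#' list(start =, at =), copy2 = ...)`: both X copies descend from the
#' mother, so a block where both copies carry the same haplotype is
#' homozygous by descent — the Klinefelter linkage scenario.
#'
#' @param ped Pedigree of one nuclear family.
#' @param crossovers Named list: child id -> `list(start = "M1"/"M2",
#'   at = positions)` for the maternal gamete. Missing children get a random
#'   start and Poisson(1) crossovers.
#' @param xxy_spec Named list for XXY children (see above).
#' @param cnv_spec Optional `list(gene =, exons =, type = "het_del"/
#'   "hom_del"/"dup", n_exons = 20, n_other_genes = 2)`.
#' @param seed Integer seed.
#' @param markers Marker map (default packaged panel).
#' @param n_alleles Allele count per marker (default 6).
#' @param informative_p Probability that the mother is heterozygous at a
#'   marker (default 0.9).
#' @return List with `str_genotypes`, `coverage` (NULL unless `cnv_spec`),
#'   and `manifest` containing the planted per-child haplotype labels.
#' @export
simulate_str_and_coverage <- function(ped, crossovers = list(), xxy_spec = list(),
                                      cnv_spec = NULL, seed = 1,
                                      markers = str_marker_map(),
                                      n_alleles = 6, informative_p = 0.9) {
  set.seed(seed)
  ped <- pedigree(ped)
  span <- range(markers$position)
  bad_cx <- unlist(map(crossovers, function(cx) cx$at))
  if (length(bad_cx) && any(bad_cx < span[1] | bad_cx > span[2])) {
    abort("crossover position outside the marker map")
  }
  M <- nrow(markers)
  m1 <- sample.int(n_alleles, M, replace = TRUE)
  m2 <- ifelse(runif(M) < informative_p,
               ((m1 + sample.int(n_alleles - 1, M, replace = TRUE) - 1L) %% n_alleles) + 1L,
               m1)
  dad <- sample.int(n_alleles, M, replace = TRUE)
  mom_allele <- function(lab) ifelse(lab == "M1", m1, m2)

  kids <- ped$id[!is.na(ped$father_id)]
  mother_id <- unique(ped$mother_id[ped$id %in% kids])
  father_id <- unique(ped$father_id[ped$id %in% kids])
  rows <- list(
    tibble(individual = mother_id, marker = markers$name,
           allele1 = pmin(m1, m2), allele2 = pmax(m1, m2)),
    tibble(individual = father_id, marker = markers$name,
           allele1 = dad, allele2 = NA_integer_)
  )
  truth <- list()
  for (kid in kids) {
    k <- ped$sex_karyotype[ped$id == kid]
    if (k == "XXY") {
      spec <- xxy_spec[[kid]] %||% {
        st <- sample(c("M1", "M2"), 1)
        at <- sort(runif(rpois(1, 1), span[1], span[2]))
        list(copy1 = list(start = st, at = numeric()),
             copy2 = list(start = st, at = at))
      }
      l1 <- gamete_labels(markers, spec$copy1$start, spec$copy1$at %||% numeric())
      l2 <- gamete_labels(markers, spec$copy2$start, spec$copy2$at %||% numeric())
      a1 <- mom_allele(l1); a2 <- mom_allele(l2)
      rows[[length(rows) + 1L]] <- tibble(individual = kid, marker = markers$name,
                                          allele1 = pmin(a1, a2), allele2 = pmax(a1, a2))
      truth[[kid]] <- tibble(marker = markers$name, copy1 = l1, copy2 = l2)
    } else {
      cx <- crossovers[[kid]] %||% list(start = sample(c("M1", "M2"), 1),
                                        at = sort(runif(rpois(1, 1), span[1], span[2])))
      lab <- gamete_labels(markers, cx$start, cx$at %||% numeric())
      ma <- mom_allele(lab)
      if (k == "XY") {
        rows[[length(rows) + 1L]] <- tibble(individual = kid, marker = markers$name,
                                            allele1 = ma, allele2 = NA_integer_)
      } else {
        rows[[length(rows) + 1L]] <- tibble(individual = kid, marker = markers$name,
                                            allele1 = pmin(dad, ma), allele2 = pmax(dad, ma))
      }
      truth[[kid]] <- tibble(marker = markers$name, copy1 = lab,
                             copy2 = NA_character_)
    }
  }

  coverage <- NULL
  cnv_truth <- NULL
  if (!is.null(cnv_spec)) {
    n_ex <- cnv_spec$n_exons %||% 20L
    # enough unaffected filler genes that the planted event cannot move the
    # profile-wide median, as in a real panel of hundreds of targets
    genes <- c(cnv_spec$gene,
               sprintf("CNVBG%02d", seq_len(cnv_spec$n_other_genes %||% 8L)))
    prof <- list()
    for (gi in seq_along(genes)) {
      ref_d <- runif(n_ex, 80, 400)
      f <- rep(1, n_ex)
      if (gi == 1L) {
        f[cnv_spec$exons] <- switch(cnv_spec$type,
                                    het_del = 0.5, hom_del = 0, dup = 1.5)
      }
      samp <- ref_d * f * pmax(1 + stats::rnorm(n_ex, 0, 0.05), 0)
      start <- (gi - 1L) * 1e6L + (seq_len(n_ex) - 1L) * 2000L + 1L
      prof[[gi]] <- tibble(chrom = "1", start = start, end = start + 199L,
                           gene = genes[gi], exon = sprintf("ex%02d", seq_len(n_ex)),
                           sample_depth = samp, reference_depth = ref_d)
    }
    coverage <- bind_rows(prof)
    cnv_truth <- cnv_spec
  }

  list(
    str_genotypes = bind_rows(rows),
    coverage = coverage,
    manifest = list(seed = seed, mother = mother_id, father = father_id,
                    maternal_truth = truth, cnv = cnv_truth)
  )
}
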