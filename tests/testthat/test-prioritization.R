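cfg <- prioritization_config()

test_that("frequency filter applies the mode-specific ceilings", {
  v <- mk_variant(maf_gnomad = 0.005)
  expect_equal(nrow(frequency_filter(v, "AR", cfg)), 1)
  expect_equal(nrow(frequency_filter(v, "XLR", cfg)), 1)
  expect_equal(nrow(frequency_filter(v, "AD", cfg)), 0)
  expect_equal(nrow(frequency_filter(v, "XLD", cfg)), 0)

  # absent from every database counts as frequency zero
  v0 <- mk_variant()
  for (m in c("AR", "AD", "XLR", "XLD")) {
    expect_equal(nrow(frequency_filter(v0, m, cfg)), 1)
  }
  expect_error(frequency_filter(mk_variant(maf_evs = -0.1), "AR", cfg), "MAF")
})

test_that("effective MAF is the maximum across databases (brute-force scan)", {
  set.seed(13)
  n <- 1000
  v <- annotated_variants(tibble::tibble(
    chrom = "1", pos = seq_len(n), ref = "A", alt = "G", gene = "G1",
    maf_gnomad = ifelse(runif(n) < 0.3, NA, rbeta(n, 0.4, 30)),
    maf_evs = ifelse(runif(n) < 0.5, NA, rbeta(n, 0.4, 30)),
    maf_kg1000 = ifelse(runif(n) < 0.5, NA, rbeta(n, 0.4, 30)),
    maf_csvs = ifelse(runif(n) < 0.7, NA, rbeta(n, 0.4, 30))))
  eff <- apply(cbind(v$maf_gnomad, v$maf_evs, v$maf_kg1000, v$maf_csvs), 1,
               function(x) if (all(is.na(x))) 0 else max(x, na.rm = TRUE))
  for (m in c("AR", "AD")) {
    thr <- if (m == "AR") 0.01 else 1e-4
    expect_setequal(frequency_filter(v, m, cfg)$variant_id,
                    v$variant_id[eff < thr])
  }
})

test_that("consequence filter: splice distance and synonymous boundary rules", {
  near <- mk_variant(consequence = "intronic", splice_distance_bp = 8L)
  expect_equal(nrow(consequence_filter(near, cfg)), 1)
  at_limit <- mk_variant(consequence = "intronic", splice_distance_bp = 10L)
  expect_equal(nrow(consequence_filter(at_limit, cfg)), 1)
  far <- mk_variant(consequence = "intronic", splice_distance_bp = 11L)
  expect_equal(nrow(consequence_filter(far, cfg)), 0)

  # synonymous: always kept in IRD genes, boundary-only in novel genes
  syn_ird <- mk_variant(gene = "PDE6B", consequence = "synonymous")
  expect_equal(nrow(consequence_filter(syn_ird, cfg)), 1)
  syn_novel_bound <- mk_variant(gene = "NOVEL1", consequence = "synonymous",
                                exon_boundary_offset = 1L)
  expect_equal(nrow(consequence_filter(syn_novel_bound, cfg)), 1)
  syn_novel_off <- mk_variant(gene = "NOVEL1", consequence = "synonymous")
  expect_equal(nrow(consequence_filter(syn_novel_off, cfg)), 0)
})

test_that("zygosity filter enforces mode-compatible index genotypes", {
  # lone heterozygote has no compound-het partner under AR
  lone <- mk_variant(genotypes = list(c(index = "het")))
  expect_equal(nrow(zygosity_filter(lone, "AR", "index")), 0)

  # homozygotes are discarded from the dominant pipeline
  hom <- mk_variant(genotypes = list(c(index = "hom_alt")))
  expect_equal(nrow(zygosity_filter(hom, "AD", "index")), 0)
  expect_equal(nrow(zygosity_filter(hom, "AR", "index")), 1)

  # the USH2A pair survives and is paired under AR
  pair <- annotated_variants(tibble::tibble(
    chrom = "1", pos = c(100L, 900L), ref = "G", alt = "T", gene = "USH2A",
    genotypes = list(c(index = "het"), c(index = "het"))))
  kept <- zygosity_filter(pair, "AR", "index")
  expect_equal(nrow(kept), 2)

  # X handling: hemizygous male under XLR; X-homozygous female/XXY
  xv <- mk_variant(chrom = "X", genotypes = list(c(index = "hem_alt")))
  expect_equal(nrow(zygosity_filter(xv, "XLR", "index", "XY")), 1)
  expect_equal(nrow(zygosity_filter(xv, "AR", "index", "XY")), 0)  # scope
  xxy <- mk_variant(chrom = "X", genotypes = list(c(index = "hom_alt")))
  expect_equal(nrow(zygosity_filter(xxy, "XLR", "index", "XXY")), 1)

  # hemizygous on an autosome is a data error
  bad <- mk_variant(chrom = "2", genotypes = list(c(index = "hem_alt")))
  expect_error(zygosity_filter(bad, "AR", "index"), "hem_alt")
})

test_that("control-genotype filter uses GnomAD counts per mode", {
  cited1 <- mk_variant(chrom = "X", gene = "CITED1",
                       gnomad_het = 9L, gnomad_hem = 2L, gnomad_hom = 0L,
                       genotypes = list(c(index = "hem_alt")))
  expect_equal(nrow(control_genotype_filter(cited1, "XLR")), 0)

  wdfy3 <- mk_variant(gene = "WDFY3", gnomad_het = 2L, gnomad_hem = 0L,
                      gnomad_hom = 0L)
  expect_equal(nrow(control_genotype_filter(wdfy3, "AR")), 1)
  expect_equal(nrow(control_genotype_filter(wdfy3, "AD")), 0)  # het > 0

  clean <- mk_variant()
  for (m in c("AR", "AD", "XLR", "XLD")) {
    expect_equal(nrow(control_genotype_filter(clean, m)), 1)
  }

  # reported pathogenic bypasses the control filter
  rep_path <- mk_variant(gnomad_het = 50L, reported_pathogenic = TRUE)
  expect_equal(nrow(control_genotype_filter(rep_path, "AD")), 1)
})

test_that("ACMG filter drops benign classes and keeps VUS upward", {
  expect_equal(nrow(acmg_filter(mk_variant(acmg_class = 3L), cfg)), 1)
  expect_equal(nrow(acmg_filter(mk_variant(acmg_class = 2L), cfg)), 0)
  expect_equal(nrow(acmg_filter(mk_variant(acmg_class = 1L), cfg)), 0)
  expect_equal(nrow(acmg_filter(mk_variant(), cfg)), 1)  # no class = VUS
})

test_that("recovery re-admits depth-only and reported-pathogenic MAF-only removals", {
  dep <- mk_variant(depth = 8L, reported_pathogenic = TRUE,
                    consequence = "frameshift", chrom = "X", gene = "RPGR",
                    genotypes = list(c(index = "hem_alt")))
  rec <- recover_variants(dep, "XLR", cfg)
  expect_equal(nrow(rec), 1)

  hi_maf <- mk_variant(maf_gnomad = 0.03, reported_pathogenic = TRUE,
                       depth = 50L)
  expect_equal(nrow(recover_variants(hi_maf, "AR", cfg)), 1)
  # not reported pathogenic: frequency removal is final
  hi_maf_np <- mk_variant(maf_gnomad = 0.03, depth = 50L)
  expect_equal(nrow(recover_variants(hi_maf_np, "AR", cfg)), 0)

  # removed for two reasons at once (frequency + synonymous off-boundary)
  both <- mk_variant(maf_gnomad = 0.03, reported_pathogenic = TRUE,
                     gene = "NOVEL1", consequence = "synonymous")
  expect_equal(nrow(recover_variants(both, "AR", cfg)), 0)
})

test_that("every cascade filter returns a subset of its input", {
  sim <- simulate_family("AR_hom", n_background = 120, seed = 31)
  v <- sim$variants
  for (m in c("AR", "AD", "XLR", "XLD")) {
    for (f in list(function(x) frequency_filter(x, m, cfg),
                   function(x) consequence_filter(x, cfg),
                   function(x) control_genotype_filter(x, m),
                   function(x) acmg_filter(x, cfg),
                   function(x) zygosity_filter(x, m, "II1", "XY"))) {
      expect_true(all(f(v)$variant_id %in% v$variant_id))
    }
  }
})

test_that("cascade finds a planted compound het as the sole tier-1 pair", {
  sim <- simulate_family("AR_comphet", n_background = 100, seed = 101)
  res <- run_cascade(sim$variants, sim$pedigree)
  ar <- res$candidates[res$candidates$mode == "AR" &
                       res$candidates$tier == "IRD_gene", ]
  expect_equal(nrow(ar), 1)
  expect_equal(ar$call_type, "comphet")
  expect_setequal(ar$variant_ids[[1]], sim$manifest$causal_ids)
  expect_false(ar$recovered)
  expect_false(res$flags$recovery_applied[["AR"]])
  # audit trail: removed + candidates account for every variant (per mode)
  rem_ar <- unique(res$removed$variant_id[res$removed$mode == "AR"])
  expect_true(all(sim$manifest$causal_ids %in%
                  setdiff(sim$variants$variant_id, rem_ar)))
})

test_that("empty input yields an empty result with no recovery", {
  ped <- trio_ped()
  empty <- mk_variant()[0, ]
  res <- run_cascade(empty, ped)
  expect_equal(nrow(res$candidates), 0)
  expect_false(any(res$flags$recovery_applied))
})

test_that("lax mode output is a superset of strict mode output", {
  for (s in c(5, 17, 29)) {
    sim <- simulate_family("XLR", n_background = 100, seed = s)
    strict <- run_cascade(sim$variants, sim$pedigree, lax = FALSE)
    lax <- run_cascade(sim$variants, sim$pedigree, lax = TRUE)
    key <- function(r) paste(r$candidates$mode, r$candidates$gene,
                             vapply(r$candidates$variant_ids, paste,
                                    character(1), collapse = "|"))
    expect_true(all(key(strict) %in% key(lax)))
  }
})

test_that("cross-strategy comparison removes or flags unshared candidates", {
  common <- genomic_intervals("1", 1L, 10000L)
  sim <- simulate_family("AR_hom", n_background = 0, seed = 1)
  base <- run_cascade(sim$variants, sim$pedigree)
  shifted <- base
  shifted$candidates <- base$candidates[0, ]

  # candidate inside common regions, found in A only, same phenotype: removed
  a <- base; a$candidates$chrom <- "1"; a$candidates$pos <- 500L
  a$candidates$variant_ids <- list("1:500:C>T")
  cmp <- cross_strategy_compare(a, shifted, common, same_phenotype = TRUE)
  expect_equal(nrow(cmp$a$candidates), 0)

  # discordant phenotype: kept with a modifier flag
  cmp2 <- cross_strategy_compare(a, shifted, common, same_phenotype = FALSE)
  expect_equal(nrow(cmp2$a$candidates), 1)
  expect_true(cmp2$a$candidates$modifier_flag)

  # outside the common regions: untouched, unflagged
  b <- base; b$candidates$chrom <- "2"; b$candidates$pos <- 99999L
  b$candidates$variant_ids <- list("2:99999:C>T")
  cmp3 <- cross_strategy_compare(b, shifted, common, same_phenotype = TRUE)
  expect_equal(nrow(cmp3$a$candidates), 1)
  expect_false(cmp3$a$candidates$modifier_flag)
})

test_that("tidy and glance expose candidates and counts", {
  sim <- simulate_family("AD", n_background = 50, seed = 2)
  res <- run_cascade(sim$variants, sim$pedigree)
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(g$n_candidates, nrow(res$candidates))
  expect_false(g$lax)
})
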