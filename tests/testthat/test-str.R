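test_that("fully informative family without recombination has constant labels", {
  ped <- trio_ped()
  sim <- simulate_str_and_coverage(
    ped, crossovers = list(index = list(start = "M1", at = numeric())),
    seed = 2, informative_p = 1)
  hap <- assign_haplotypes(sim$str_genotypes, ped)
  labs <- hap$assignments$label[hap$assignments$individual == "index"]
  expect_true(all(labs == labs[1]))
})

test_that("planted crossovers are recovered within one marker interval", {
  # four sons: three without recombination pin the maternal phase, so the
  # single planted crossover is identifiable (with only two informative
  # children the labelling is a parsimony tie)
  ped <- pedigree(tibble::tibble(
    family_id = "CX", id = c("dad", "mum", paste0("s", 1:4)),
    father_id = c(NA, NA, rep("dad", 4)),
    mother_id = c(NA, NA, rep("mum", 4)),
    sex_karyotype = c("XY", "XX", rep("XY", 4)),
    affected = c("unaffected", "unaffected", "affected",
                 rep("unaffected", 3))))
  cx_pos <- 80e6
  sim <- simulate_str_and_coverage(
    ped, crossovers = list(s1 = list(start = "M1", at = cx_pos),
                           s2 = list(start = "M1", at = numeric()),
                           s3 = list(start = "M1", at = numeric()),
                           s4 = list(start = "M2", at = numeric())),
    seed = 8, informative_p = 1)
  hap <- assign_haplotypes(sim$str_genotypes, ped)
  a <- hap$assignments[hap$assignments$individual == "s1", ]
  a <- a[order(a$position), ]
  switch_at <- which(a$label[-1] != a$label[-nrow(a)])
  expect_length(switch_at, 1)
  # breakpoint bracketed by the flanking markers of the true position
  expect_true(a$position[switch_at] < cx_pos && a$position[switch_at + 1] > cx_pos)

  # total inferred recombinations never exceed the planted total
  truth <- sim$manifest$maternal_truth
  n_inf <- n_pl <- 0
  for (kid in paste0("s", 1:4)) {
    k <- hap$assignments[hap$assignments$individual == kid &
                           hap$assignments$informative, ]
    k <- k[order(k$position), ]
    n_inf <- n_inf + sum(k$label[-1] != k$label[-nrow(k)])
    n_pl <- n_pl + sum(truth[[kid]]$copy1[-1] != truth[[kid]]$copy1[-26])
  }
  expect_lte(n_inf, n_pl)
})

test_that("an XXY child carrying both maternal haplotypes is labelled M1+M2", {
  ped <- family35_ped()
  sim <- simulate_str_and_coverage(
    ped,
    crossovers = list(II1 = list(start = "M1", at = numeric()),
                      II3 = list(start = "M2", at = numeric())),
    xxy_spec = list(II2 = list(copy1 = list(start = "M1", at = numeric()),
                               copy2 = list(start = "M2", at = numeric()))),
    seed = 12, informative_p = 1)
  hap <- assign_haplotypes(sim$str_genotypes, ped)
  labs <- hap$assignments$label[hap$assignments$individual == "II2"]
  expect_true(all(labs == "M1+M2"))
})

test_that("Klinefelter linkage scenario recovers the planted mid-X block", {
  ped <- family35_ped()
  sim <- simulate_str_and_coverage(
    ped,
    crossovers = list(II1 = list(start = "M2", at = c(39e6, 112e6)),
                      II3 = list(start = "M2", at = numeric())),
    xxy_spec = list(II2 = list(copy1 = list(start = "M1", at = numeric()),
                               copy2 = list(start = "M2", at = c(39e6, 112e6)))),
    seed = 3)
  hap <- assign_haplotypes(sim$str_genotypes, ped)
  sr <- shared_regions(hap, affected = c("II1", "II2"), excluders = "II3")
  expect_gte(nrow(sr), 1)
  main <- sr[which.max(sr$end - sr$start), ]
  # the planted block (41-110 Mb of shared markers) sits inside the region
  expect_lte(main$start, 41e6)
  expect_gte(main$end, 110e6)
  # XXY member is homozygous for the risk haplotype inside the block
  ii2 <- hap$assignments[hap$assignments$individual == "II2" &
                           hap$assignments$position >= 41e6 &
                           hap$assignments$position <= 110e6 &
                           hap$assignments$informative, ]
  expect_true(all(ii2$both_copies))
})

test_that("a single affected individual shares the whole chromosome (vacuous)", {
  ped <- trio_ped()
  sim <- simulate_str_and_coverage(
    ped, crossovers = list(index = list(start = "M1", at = numeric())),
    seed = 4, informative_p = 1)
  hap <- assign_haplotypes(sim$str_genotypes, ped)
  sr <- shared_regions(hap, affected = "index")
  mk <- str_marker_map()
  # with one child the M1/M2 labelling is an arbitrary tie; whichever
  # haplotype the child carries must span the whole marker map
  expect_equal(nrow(sr), 1)
  expect_equal(sr$start, min(mk$position))
  expect_equal(sr$end, max(mk$position))
})

test_that("shared regions equal the brute-force interval scan on random families", {
  for (s in 1:30) {
    ped <- random_str_family(s)
    sim <- simulate_str_and_coverage(ped, seed = s)
    hap <- assign_haplotypes(sim$str_genotypes, ped)
    aff <- ped$id[ped$affected == "affected"]
    exc <- ped$id[ped$affected == "unaffected" & !is.na(ped$father_id)]
    got <- shared_regions(hap, aff, exc)
    want <- oracle_shared_regions(hap, aff, exc)
    expect_equal(got[, c("haplotype", "start", "end")], want,
                 ignore_attr = TRUE)
  }
})

test_that("adding an excluder never enlarges any shared region", {
  for (s in 31:40) {
    ped <- random_str_family(s)
    exc_pool <- ped$id[ped$affected == "unaffected" & !is.na(ped$father_id)]
    if (!length(exc_pool)) next
    sim <- simulate_str_and_coverage(ped, seed = s)
    hap <- assign_haplotypes(sim$str_genotypes, ped)
    aff <- ped$id[ped$affected == "affected"]
    before <- shared_regions(hap, aff, character())
    after <- shared_regions(hap, aff, exc_pool[1])
    # every region surviving the excluder existed already with the same span
    for (j in seq_len(nrow(after))) {
      expect_true(any(before$haplotype == after$haplotype[j] &
                      before$start <= after$start[j] &
                      before$end >= after$end[j]))
    }
    expect_lte(nrow(after), nrow(before))
  }
})

test_that("genes_in_region matches a brute-force overlap scan", {
  gm <- xchr_gene_map()
  # mid-X block: the eight IRD genes plus CITED1, not RPGR
  mid <- tibble::tibble(chrom = "X", start = 40e6, end = 110e6)
  got <- genes_in_region(mid, gm)$genes[[1]]
  expect_setequal(got, c("NYX", "NDP", "RP2", "CACNA1F", "PGK1", "CHM",
                         "TIMM8A", "PRPS1", "CITED1"))
  expect_false("RPGR" %in% got)

  expect_equal(nrow(genes_in_region(mid[0, ], gm)), 0)

  set.seed(77)
  for (i in 1:25) {
    r <- tibble::tibble(chrom = "X", start = s <- sample.int(1.5e8, 1),
                        end = s + sample.int(5e7, 1))
    want <- gm$gene[gm$start <= r$end & gm$end >= r$start]
    expect_equal(genes_in_region(r, gm)$genes[[1]], want)
  }
})

test_that("Mendelian-inconsistent markers are flagged and dropped", {
  ped <- trio_ped(child_karyo = "XX")
  sim <- simulate_str_and_coverage(
    ped, crossovers = list(index = list(start = "M1", at = numeric())),
    seed = 6, informative_p = 1)
  g <- sim$str_genotypes
  # corrupt the daughter's genotype at one marker: neither allele paternal
  dad_row <- g[g$individual == "father" & g$marker == "DXS990", ]
  idx <- which(g$individual == "index" & g$marker == "DXS990")
  bad <- dad_row$allele1 + 1L
  g$allele1[idx] <- bad; g$allele2[idx] <- bad
  mum <- g[g$individual == "mother" & g$marker == "DXS990", ]
  if (bad %in% c(mum$allele1, mum$allele2)) {
    g$allele1[idx] <- max(mum$allele1, mum$allele2, dad_row$allele1) + 1L
    g$allele2[idx] <- g$allele1[idx]
  }
  hap <- assign_haplotypes(g, ped)
  expect_true("DXS990" %in% hap$dropped_markers)
})
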