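# helper: candidate row + variants for a single-variant call
single_call <- function(mode, call_type, vid) {
  tibble::tibble(mode = mode, call_type = call_type, variant_ids = list(vid))
}

test_that("XLR hemizygous call tolerates carrier females (Family-36 pattern)", {
  ped <- pedigree(tibble::tribble(
    ~family_id, ~id, ~father_id, ~mother_id, ~sex_karyotype, ~affected,
    "F36", "mother", NA, NA, "XX", "unaffected",
    "F36", "father", NA, NA, "XY", "unaffected",
    "F36", "index", "father", "mother", "XY", "affected",
    "F36", "sister1", "father", "mother", "XX", "unaffected",
    "F36", "sister2", "father", "mother", "XX", "unaffected",
    "F36", "nephew", NA, "sister1", "XY", "affected"
  ))
  v <- mk_variant(chrom = "X", gene = "RPGR", consequence = "frameshift",
                  genotypes = list(c(index = "hem_alt", mother = "het",
                                     sister1 = "het", sister2 = "het",
                                     nephew = "hem_alt")))
  res <- check_segregation(single_call("XLR", "hem", v$variant_id), ped, v)
  expect_true(res$consistent)
  expect_equal(res$affected_checked, 1L)  # nephew
  expect_equal(res$healthy_checked, 3L)   # mother + both sisters
  expect_equal(count_segregants(res), "Yes(1/3)")
})

test_that("unaffected XY hemizygote breaks XLR segregation", {
  ped <- family35_ped()
  v <- mk_variant(chrom = "X", gene = "CHM",
                  genotypes = list(c(II1 = "hem_alt", II2 = "hom_alt",
                                     I1 = "hem_alt", I2 = "het", II3 = "hom_ref")))
  res <- check_segregation(single_call("XLR", "hem", v$variant_id), ped, v)
  expect_false(res$consistent)
  expect_equal(res$violations$individual, "I1")
})

test_that("47,XXY affected may be X-homozygous under XLR", {
  ped <- family35_ped()
  v <- mk_variant(chrom = "X", gene = "CITED1",
                  genotypes = list(c(II1 = "hem_alt", II2 = "hom_alt",
                                     I2 = "het", II3 = "hom_ref")))
  res <- check_segregation(single_call("XLR", "hem", v$variant_id), ped, v)
  expect_true(res$consistent)
  expect_equal(res$affected_checked, 1L)
  expect_equal(res$healthy_checked, 2L)
})

comphet_setup <- function(sib_gt1, sib_gt2, father_gt = c("het", "hom_ref"),
                          mother_gt = c("hom_ref", "het"),
                          sib_affected = "unaffected") {
  ped <- pedigree(tibble::tribble(
    ~family_id, ~id, ~father_id, ~mother_id, ~sex_karyotype, ~affected,
    "F", "father", NA, NA, "XY", "unaffected",
    "F", "mother", NA, NA, "XX", "unaffected",
    "F", "index", "father", "mother", "XY", "affected",
    "F", "sib", "father", "mother", "XX", sib_affected
  ))
  v <- annotated_variants(tibble::tibble(
    chrom = "1", pos = c(100L, 900L), ref = "G", alt = "T", gene = "USH2A",
    genotypes = list(
      c(index = "het", father = father_gt[1], mother = mother_gt[1], sib = sib_gt1),
      c(index = "het", father = father_gt[2], mother = mother_gt[2], sib = sib_gt2))))
  list(ped = ped, v = v,
       call = tibble::tibble(mode = "AR", call_type = "comphet",
                             variant_ids = list(v$variant_id)))
}

test_that("compound het: parents resolve phase; trans-carrying unaffected sib violates", {
  s <- comphet_setup("het", "het")
  res <- check_segregation(s$call, s$ped, s$v)
  expect_true(res$phase_resolved)   # one variant per parent: trans confirmed
  expect_false(res$consistent)      # unaffected sib carries both in trans
  expect_equal(res$violations$individual, "sib")

  # sib carrying only one variant is a consistent carrier
  s2 <- comphet_setup("het", "hom_ref")
  res2 <- check_segregation(s2$call, s2$ped, s2$v)
  expect_true(res2$consistent)
  expect_equal(count_segregants(res2), "Yes(0/3)")

  # affected sib must carry both
  s3 <- comphet_setup("hom_ref", "het", sib_affected = "affected")
  res3 <- check_segregation(s3$call, s3$ped, s3$v)
  expect_false(res3$consistent)
})

test_that("a cis pair proven by parental genotypes is rejected as compound het", {
  s <- comphet_setup("hom_ref", "hom_ref",
                     father_gt = c("het", "het"),
                     mother_gt = c("hom_ref", "hom_ref"))
  res <- check_segregation(s$call, s$ped, s$v)
  expect_false(res$consistent)
  expect_false(res$phase_resolved)
  expect_true("index" %in% res$violations$individual)
})

test_that("AR homozygous and AD calls check carriers with complete penetrance", {
  ped <- family35_ped()
  v_hom <- mk_variant(gene = "BBS10",
                      genotypes = list(c(II1 = "hom_alt", II2 = "hom_alt",
                                         I1 = "het", I2 = "het", II3 = "het")))
  res <- check_segregation(single_call("AR", "hom", v_hom$variant_id), ped, v_hom)
  expect_true(res$consistent)
  expect_equal(count_segregants(res), "Yes(1/3)")

  # unaffected homozygote violates
  v_bad <- mk_variant(gene = "BBS10",
                      genotypes = list(c(II1 = "hom_alt", II2 = "hom_alt",
                                         I1 = "het", I2 = "het", II3 = "hom_alt")))
  res_bad <- check_segregation(single_call("AR", "hom", v_bad$variant_id), ped, v_bad)
  expect_false(res_bad$consistent)
  expect_equal(count_segregants(res_bad), "No")

  # AD: an unaffected carrier is a violation
  v_ad <- mk_variant(gene = "PRPH2",
                     genotypes = list(c(II1 = "het", II2 = "het",
                                        I1 = "het", I2 = "hom_ref", II3 = "hom_ref")))
  res_ad <- check_segregation(single_call("AD", "het_dominant", v_ad$variant_id),
                              ped, v_ad)
  expect_false(res_ad$consistent)  # unaffected father I1 carries it
})

test_that("ungenotyped relatives are not checked; none checked formats as No", {
  ped <- trio_ped()
  v <- mk_variant(genotypes = list(c(index = "hom_alt")))
  res <- check_segregation(single_call("AR", "hom", v$variant_id), ped, v)
  expect_equal(res$affected_checked + res$healthy_checked, 0L)
  expect_equal(count_segregants(res), "No")
})

test_that("genotypes for unknown individuals raise a reference error", {
  ped <- trio_ped()
  v <- mk_variant(genotypes = list(c(index = "hom_alt", stranger = "het")))
  expect_error(check_segregation(single_call("AR", "hom", v$variant_id), ped, v),
               "unknown individual")
})

test_that("adding a relative can break but never repair consistency", {
  # base: inconsistent because of the unaffected carrier
  ped4 <- pedigree(tibble::tribble(
    ~family_id, ~id, ~father_id, ~mother_id, ~sex_karyotype, ~affected,
    "F", "father", NA, NA, "XY", "unaffected",
    "F", "mother", NA, NA, "XX", "unaffected",
    "F", "index", "father", "mother", "XY", "affected",
    "F", "sib", "father", "mother", "XX", "unaffected"
  ))
  gts_bad <- c(index = "het", sib = "het")
  gts_more <- c(gts_bad, father = "hom_ref", mother = "het")
  v1 <- mk_variant(gene = "PRPH2", genotypes = list(gts_bad))
  v2 <- mk_variant(gene = "PRPH2", genotypes = list(gts_more))
  call <- single_call("AD", "het_dominant", v1$variant_id)
  r1 <- check_segregation(call, ped4, v1)
  r2 <- check_segregation(call, ped4, v2)
  expect_false(r1$consistent)
  expect_false(r2$consistent)  # extra relatives cannot repair the violation
})
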