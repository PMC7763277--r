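stage_visible_variants <- function(variants, design) {
  if (nrow(design$primary_regions)) {
    intersect_with_design(variants, design, "primary")
  } else {
    # gene-level designs: a variant is callable when its gene is sequenceable
    variants[variants$gene %in% design$covered_gene_set, , drop = FALSE]
  }
}

solved_verdict <- function(result) {
  cand <- result$candidates
  if (!nrow(cand)) return(FALSE)
  tier1 <- cand$tier == "IRD_gene"
  seg_ok <- is.na(cand$seg_consistent) | cand$seg_consistent
  any(tier1 & seg_ok)
}

#' Run the escalating multi-strategy workflow for one family
#'
#' Applies the prioritization cascade stage by stage (panel, then clinical
#' exome, then whole exome by default), restricting each stage to the
#' variants its design can call, and stops at the first stage that yields a
#' solved verdict: at least one candidate in a known IRD gene whose
#' segregation, when checkable, is consistent.
#'
#' @param variants Annotated variant tibble for the family.
#' @param ped Pedigree tibble.
#' @param stages Named list of [target_design()]s in escalation order
#'   (default `ps_design()`, `ces_design()`, `wes_design()`).
#' @param config A [prioritization_config()].
#' @param ... Passed to [run_cascade()].
#' @return An `ird_workflow` object: per-stage results, `solved_stage`
#'   (name or `NA`), and a Table-style `report` tibble (ID, Gene, Variants,
#'   Status, ACMG, Segr., Solved).
#' @export
run_family_workflow <- function(variants, ped,
                                stages = list(PS = ps_design(),
                                              CES = ces_design(),
                                              WES = wes_design()),
                                config = prioritization_config(), ...) {
  if (!length(stages)) abort("at least one stage design must be configured")
  if (is.null(names(stages)) || any(!nzchar(names(stages)))) {
    names(stages) <- map_chr(stages, function(d) d$name)
  }
  ped <- pedigree(ped)
  results <- list()
  solved_stage <- NA_character_
  for (nm in names(stages)) {
    vis <- stage_visible_variants(variants, stages[[nm]])
    res <- run_cascade(vis, ped, config, ...)
    results[[nm]] <- res
    if (solved_verdict(res)) {
      solved_stage <- nm
      break
    }
  }
  final <- results[[length(results)]]
  cand <- final$candidates
  status_of <- function(i) {
    switch(cand$call_type[i], hom = "Hom", hem = "Hem",
           comphet = "Het", het_dominant = "Het")
  }
  report <- if (nrow(cand)) tibble(
    ID = ped$family_id[1], Gene = cand$gene, Variants = cand$hgvs_c,
    Status = map_chr(seq_len(nrow(cand)), status_of),
    ACMG = cand$acmg_class, Segr. = cand$seg_label,
    Solved = ifelse(rep(!is.na(solved_stage), nrow(cand)), "Yes", "No"),
    Stage = names(results)[length(results)]
  ) else tibble(ID = ped$family_id[1], Gene = NA_character_,
                Variants = NA_character_, Status = NA_character_,
                ACMG = NA_integer_, Segr. = NA_character_, Solved = "No",
                Stage = names(results)[length(results)])
  structure(list(stage_results = results, solved_stage = solved_stage,
                 report = report, family_id = ped$family_id[1]),
            class = "ird_workflow")
}

#' @export
print.ird_workflow <- function(x, ...) {
  cat(sprintf("<ird_workflow> family %s: %s\n", x$family_id,
              if (is.na(x$solved_stage)) "unsolved"
              else paste("solved at stage", x$solved_stage)))
  print(x$report)
  invisible(x)
}

#' Summarize a cohort of fixture records
#'
#' Computes the cohort-level arithmetic over variant-occurrence records
#' (e.g. the packaged tables): solved family counts, unique variants
#' (deduplicated by gene + cDNA change, so recurrent alleles across
#' families count once), and novel variants (reference `"This study"`).
#' Duplicated family blocks are dropped first, making the summary
#' idempotent under repeated reports.
#'
#' @param records Fixture-record tibble ([load_fixtures()] format), or
#'   several row-bound together.
#' @return A one-row tibble: `families`, `solved_families`,
#'   `unsolved_families`, `variant_occurrences`, `unique_variants`,
#'   `novel_variants`.
#' @export
summarize_cohort <- function(records) {
  if (!nrow(records)) abort("no reports to summarize")
  records <- distinct(records, .data$family_id, .data$gene, .data$hgvs_c,
                      .keep_all = TRUE)
  fam <- distinct(records, .data$family_id, .keep_all = TRUE)
  tibble(
    families = nrow(fam),
    solved_families = sum(fam$solved),
    unsolved_families = sum(!fam$solved),
    variant_occurrences = nrow(records),
    unique_variants = nrow(distinct(records, .data$gene, .data$hgvs_c)),
    novel_variants = nrow(distinct(
      filter(records, .data$reference == "This study"), .data$gene, .data$hgvs_c))
  )
}

#' Study-level summary across all packaged fixtures
#'
#' Combines the packaged tables and cohort counts into the headline numbers
#' of the study: panel-solved families, families left for escalation,
#' clinical-exome diagnoses, families with candidate variants, and cohort
#' size.
#'
#' @return A named list of counts.
#' @export
study_summary <- function() {
  t1 <- load_fixtures("table1")
  t2 <- load_fixtures("table2")
  cc <- cohort_counts()
  s1 <- summarize_cohort(t1)
  s2 <- summarize_cohort(t2)
  list(
    families_total = unname(cc[["families_total"]]),
    table1_families = s1$families,
    table1_variant_occurrences = s1$variant_occurrences,
    table1_unique_variants = s1$unique_variants,
    table1_novel_variants = s1$novel_variants,
    ps_solved = s1$solved_families,
    unsolved_after_ps = unname(cc[["families_total"]]) - s1$solved_families,
    ces_tested = unname(cc[["ces_tested_families"]]),
    ces_solved = s2$solved_families,
    families_with_candidates = s1$families + s2$families,
    total_individuals = unname(cc[["affected_individuals"]]) +
      unname(cc[["healthy_relatives"]])
  )
}
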