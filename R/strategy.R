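#' Sequencing-strategy parameters
#'
#' Bundles the quantities driving the strategy comparator: target size,
#' required mean coverage, on-target read fraction, duplicate fraction,
#' sequencer run output, and reagent costs. Defaults for the three compared
#' strategies are exposed by [default_strategy_params()]: a ~0.8 Mb custom
#' IRD panel at 200x, a 12 Mb clinical exome and a 47 Mb whole exome at
#' 100x, with on-target fractions 0.966, 0.753 and 0.74 and 10% duplicates.
#'
#' @param name Strategy label.
#' @param target_size_bp Design footprint in bases.
#' @param mean_coverage Required mean depth (fold).
#' @param on_target_fraction Fraction of reads mapping on target, in (0, 1].
#' @param duplicate_fraction Fraction of duplicate reads, in \[0, 1).
#' @param run_output_bp Bases yielded by one sequencing run.
#' @param reagent_cost_per_run Sequencing reagent cost for one run (any
#'   currency; `NA` to compare relative costs only).
#' @param library_cost_per_sample Library-preparation cost per sample.
#' @param design Optional [target_design()] attached for yield estimation.
#' @return A `strategy_params` list.
#' @export
strategy_params <- function(name, target_size_bp, mean_coverage,
                            on_target_fraction, duplicate_fraction = 0.10,
                            run_output_bp = NA_real_,
                            reagent_cost_per_run = NA_real_,
                            library_cost_per_sample = 0,
                            design = NULL) {
  if (on_target_fraction <= 0 || on_target_fraction > 1) {
    abort("on_target_fraction must be in (0, 1]")
  }
  if (duplicate_fraction < 0 || duplicate_fraction >= 1) {
    abort("duplicate_fraction must be in [0, 1)")
  }
  if (mean_coverage <= 0) abort("mean_coverage must be > 0")
  structure(list(name = name, target_size_bp = target_size_bp,
                 mean_coverage = mean_coverage,
                 on_target_fraction = on_target_fraction,
                 duplicate_fraction = duplicate_fraction,
                 run_output_bp = run_output_bp,
                 reagent_cost_per_run = reagent_cost_per_run,
                 library_cost_per_sample = library_cost_per_sample,
                 design = design),
            class = "strategy_params")
}

#' @rdname strategy_params
#' @export
default_strategy_params <- function() {
  list(
    PS = strategy_params("PS", 0.8e6, 200, 0.966, design = ps_design()),
    CES = strategy_params("CES", 12e6, 100, 0.753, design = ces_design()),
    WES = strategy_params("WES", 47e6, 100, 0.74, design = wes_design())
  )
}

#' Sequencing output required per sample
#'
#' The standard coverage identity: bases that must be sequenced so that,
#' after discarding duplicates and off-target reads, the target is covered
#' at the required mean depth:
#' `target_size * coverage / (on_target * (1 - duplicates))`.
#'
#' @param params A [strategy_params()].
#' @return Bases per sample.
#' @export
per_sample_output <- function(params) {
  with(params, target_size_bp * mean_coverage /
         (on_target_fraction * (1 - duplicate_fraction)))
}

#' Samples per run and cost per sample
#'
#' The maximum number of samples multiplexed on one run is
#' `floor(run_output / per_sample_output)`; the per-sample cost spreads the
#' run reagent cost over those samples and adds the per-sample library cost.
#'
#' @param params A [strategy_params()] with `run_output_bp` set.
#' @return A list with `samples` and `cost_per_sample` (`NA` when no costs
#'   are configured).
#' @export
samples_per_run_and_cost <- function(params) {
  need <- per_sample_output(params)
  if (is.na(params$run_output_bp)) abort("run_output_bp is not set")
  if (params$run_output_bp < need) {
    abort("run output is below the per-sample requirement (capacity error)")
  }
  samples <- floor(params$run_output_bp / need)
  cost <- if (is.na(params$reagent_cost_per_run)) NA_real_ else {
    (params$reagent_cost_per_run + params$library_cost_per_sample * samples) / samples
  }
  list(samples = as.integer(samples), cost_per_sample = cost)
}

#' First-line diagnostic yield of each strategy
#'
#' Estimates, for each sequencing design, the fraction of the cohort's
#' diagnosed cases whose causal gene the design includes — the diagnostic
#' rate the strategy would have achieved as the first-line test.
#'
#' @param solved_cases Tibble with one row per diagnosed family: `family_id`
#'   and the causal `gene` (default the packaged study cohort,
#'   [study_solved_cases()]).
#' @param designs List of [target_design()]s (default PS/CES/WES).
#' @return Tibble: `strategy`, `diagnosable`, `diagnosed_total`, `fraction`.
#' @export
estimate_first_line_yield <- function(solved_cases = study_solved_cases(),
                                      designs = list(ps_design(), ces_design(),
                                                     wes_design())) {
  if (!nrow(solved_cases)) abort("solved_cases is empty; yield is undefined")
  bind_rows(map(designs, function(d) {
    tibble(strategy = d$name,
           diagnosable = sum(solved_cases$gene %in% d$gene_set),
           diagnosed_total = nrow(solved_cases),
           fraction = sum(solved_cases$gene %in% d$gene_set) / nrow(solved_cases))
  }))
}

#' Diagnosed families of the study cohort with their causal genes
#'
#' One row per family solved by panel or clinical-exome sequencing (24
#' families), from the packaged fixtures.
#'
#' @return Tibble with `family_id`, `gene`, `stage`.
#' @export
study_solved_cases <- function() {
  t1 <- load_fixtures("table1")
  t2 <- load_fixtures("table2")
  bind_rows(
    distinct(filter(t1, .data$solved), .data$family_id, .data$gene) |>
      mutate(stage = "PS"),
    distinct(filter(t2, .data$solved), .data$family_id, .data$gene) |>
      mutate(stage = "CES")
  )
}
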