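#' Turn a result object into a tidy tibble
#'
#' @param x A result object (`ird_prioritization`, `ird_workflow`).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of a result object
#'
#' @inheritParams tidy
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
tidy.ird_prioritization <- function(x, ...) x$candidates

#' @rdname glance
#' @export
glance.ird_prioritization <- function(x, ...) {
  cand <- x$candidates
  tibble(
    n_candidates = nrow(cand),
    n_tier1 = sum(cand$tier == "IRD_gene"),
    n_novel = sum(cand$tier == "novel_candidate"),
    n_recovered = sum(cand$recovered),
    n_removed = length(unique(x$removed$variant_id)),
    lax = x$flags$lax
  )
}

#' @rdname tidy
#' @export
tidy.ird_workflow <- function(x, ...) x$report

#' @rdname glance
#' @export
glance.ird_workflow <- function(x, ...) {
  tibble(family_id = x$family_id,
         solved = !is.na(x$solved_stage),
         solved_stage = x$solved_stage,
         stages_run = length(x$stage_results))
}

#' Plot candidate calls per mode and tier
#'
#' @param object An `ird_prioritization` result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ird_prioritization
#' @export
autoplot.ird_prioritization <- function(object, ...) {
  cand <- object$candidates
  ggplot2::ggplot(cand, ggplot2::aes(x = .data$mode, fill = .data$tier)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "inheritance mode", y = "candidate calls",
                  fill = "tier") +
    ggplot2::theme_minimal()
}

#' Plot a coverage-ratio profile with CNV cut-offs
#'
#' Per-target copy-number ratios along each gene with the deletion and
#' duplication cut-offs; called CNV spans are shaded.
#'
#' @param ratio_table Output of [normalize_ratios()].
#' @param calls Optional output of [call_cnvs()].
#' @param deletion_cutoff,duplication_cutoff Cut-offs to draw.
#' @return A ggplot.
#' @export
plot_cnv_ratios <- function(ratio_table, calls = NULL,
                            deletion_cutoff = 0.6, duplication_cutoff = 1.40) {
  p <- ggplot2::ggplot(ratio_table,
                       ggplot2::aes(x = .data$start, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(deletion_cutoff, duplication_cutoff),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~gene, scales = "free_x") +
    ggplot2::labs(x = "target start (bp)", y = "normalized depth ratio") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls)) {
    p <- p + ggplot2::geom_rect(
      data = calls, inherit.aes = FALSE, alpha = 0.2,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$call))
  }
  p
}

#' Plot reconstructed maternal haplotypes along the X chromosome
#'
#' @param hap An `str_haplotypes` object.
#' @return A ggplot tile map of per-marker maternal labels per child.
#' @export
plot_str_haplotypes <- function(hap) {
  asg <- hap$assignments
  ggplot2::ggplot(asg, ggplot2::aes(x = .data$position / 1e6,
                                    y = .data$individual,
                                    fill = .data$label)) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::labs(x = "X position (Mb)", y = NULL,
                  fill = "maternal haplotype") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
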