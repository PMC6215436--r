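# Enrichment summary statistics: observed count O, empirical p-value,
# enrichment ratio O / mean(R), capped per-DMI FDR, and the normalized-D
# distribution D_i = (O - R_i) / mean(R). Full precision is kept internally;
# rounding (enrichment 3 s.f., FDR 4 d.p.) is display-only.

r_counts <- function(R) {
  if (inherits(R, "random_dmi_distribution")) R$counts else as.numeric(R)
}

#' Empirical enrichment p-value
#'
#' The probability of seeing at least as many predicted DMIs in randomized
#' PPI data: `p = |{i : R_i >= O}| / n_shuffles`. Ties count toward the
#' numerator. No add-one correction is applied, so zero exceedances give a
#' numeric 0, displayed as the bound `"<1/n"` (see
#' [format_empirical_pvalue()]).
#'
#' @param O Observed predicted-DMI count.
#' @param R Random counts: numeric vector or `random_dmi_distribution`.
#' @return Numeric p-value in `[0, 1]`.
#' @export
empirical_pvalue <- function(O, R) {
  R <- r_counts(R)
  if (length(R) == 0L) stop_config("empirical_pvalue: empty random distribution")
  sum(R >= O) / length(R)
}

#' Display string for an empirical p-value
#'
#' @param p Numeric p-value from [empirical_pvalue()].
#' @param n_shuffles Number of shuffles behind `p`.
#' @return `"<1/n_shuffles"` (e.g. `"<0.001"` for 1000 shuffles) when `p`
#'   is 0, otherwise the value formatted at the resolution of the null.
#' @export
format_empirical_pvalue <- function(p, n_shuffles) {
  digits <- max(1L, ceiling(log10(n_shuffles)))
  if (p == 0) paste0("<", format(1 / n_shuffles, scientific = FALSE))
  else format(round(p, digits), scientific = FALSE)
}

#' Enrichment ratio
#'
#' Observed predicted-DMI count over the mean random count, `O / mean(R)`.
#' Reported to 3 significant figures in summaries; full precision returned.
#'
#' @param O Observed count.
#' @param R_bar Mean of the random distribution (or a
#'   `random_dmi_distribution`).
#' @return Numeric ratio; `Inf` with a warning when `R_bar` is 0.
#' @export
enrichment_ratio <- function(O, R_bar) {
  if (inherits(R_bar, "random_dmi_distribution")) R_bar <- R_bar$mean
  if (R_bar == 0) {
    warning("enrichment_ratio: mean random count is 0; enrichment is infinite")
    return(Inf)
  }
  O / R_bar
}

#' Per-DMI false discovery rate
#'
#' The expected fraction of the predicted DMIs explained by random
#' association: the mean random count capped at the observed count, divided
#' by the observed count, `min(R_bar, O) / O`. Defined as 0 when nothing is
#' predicted.
#'
#' @inheritParams enrichment_ratio
#' @return Numeric FDR in `[0, 1]`.
#' @export
dmi_fdr <- function(O, R_bar) {
  if (inherits(R_bar, "random_dmi_distribution")) R_bar <- R_bar$mean
  if (O < 0) stop_config("dmi_fdr: O must be non-negative")
  if (O == 0) return(0)
  min(R_bar, O) / O
}

#' Normalized predicted-DMI distribution
#'
#' `D_i = (O - R_i) / mean(R)`: the distribution of expected true-positive
#' predicted DMIs in units of the mean random count. `mean(D) + 1` equals
#' the enrichment ratio; `D = 1` corresponds to a 50% per-DMI FDR.
#'
#' @inheritParams empirical_pvalue
#' @return Numeric vector of the same length as `R`.
#' @export
normalized_D <- function(O, R) {
  R <- r_counts(R)
  R_bar <- mean(R)
  if (!length(R) || R_bar == 0) {
    stop_config("normalized_D: undefined when the mean random count is 0")
  }
  (O - R) / R_bar
}

#' Run the full DMI enrichment analysis
#'
#' End-to-end composition: build the potential-DMI pool under the strategy,
#' extract the predicted DMIs realized by the PPI data, generate the
#' degree-preserving permutation null, and bundle all statistics.
#'
#' @param ppi A [ppi_dataset()].
#' @param motifs A [motif_table()] (`NULL` allowed for `ELMi-Protein`).
#' @param dmi_defs A [dmi_table()] matching the strategy schema.
#' @param domains A [domain_table()] (`NULL` allowed except `ELMc-Domain`).
#' @param strategy A [dmi_strategy()].
#' @param cfg A [shuffle_config()]; its seed makes the run reproducible.
#' @return Object of class `enrichment_result`: `O`, `R`
#'   (`random_dmi_distribution`), `p_value`, `p_display`, `enrichment`,
#'   `fdr`, `D`, `n_shuffles`, `seed`, `strategy`, `potential`
#'   (`potential_dmis`), `predicted` (`predicted_dmis`), `counts`
#'   (unique-entity counts of the predicted set).
#' @export
run_enrichment <- function(ppi, motifs, dmi_defs, domains, strategy,
                           cfg = shuffle_config()) {
  if (!is.null(motifs) && inherits(motifs, "motif_table") &&
      motifs$occurrence_source != strategy$occurrence_source) {
    message("run_enrichment: motif table is tagged '", motifs$occurrence_source,
            "' but strategy expects '", strategy$occurrence_source, "'")
  }
  potential <- build_potential_dmis(ppi, motifs, dmi_defs, domains, strategy)
  predicted <- extract_predicted_dmis(potential, ppi)
  O <- nrow(predicted)
  R <- random_dmi_distribution(ppi, potential, cfg)
  p <- empirical_pvalue(O, R)
  enr <- if (R$mean > 0) O / R$mean else {
    if (O > 0) Inf else NA_real_
  }
  D <- if (R$mean > 0) (O - R$counts) / R$mean else rep(NA_real_, length(R$counts))
  structure(list(O = O, R = R, p_value = p,
                 p_display = format_empirical_pvalue(p, R$n_shuffles),
                 enrichment = enr, fdr = dmi_fdr(O, R$mean), D = D,
                 n_shuffles = R$n_shuffles, seed = cfg$seed,
                 strategy = strategy, potential = potential,
                 predicted = predicted, counts = attr(predicted, "counts")),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  fmt_na <- function(v, f) if (is.null(v) || is.na(v)) "N/A" else f(v)
  cat("DMI enrichment [", strategy_label(x$strategy), "]\n", sep = "")
  cat("  Potential DMI (NR):   ", nrow(x$potential), "\n", sep = "")
  cat("  Predicted DMI (NR):   ", x$O, "\n", sep = "")
  cat("  Mean random DMI:      ", signif(x$R$mean, 3), "\n", sep = "")
  cat("  p-value:              ", x$p_display, "\n", sep = "")
  cat("  Enrichment:           ",
      if (is.na(x$enrichment)) "N/A" else signif(x$enrichment, 3), "\n", sep = "")
  cat("  FDR:                  ", round(x$fdr, 4), "\n", sep = "")
  cat("  Unique mProteins:     ", fmt_na(x$counts$mProteins, identity), "\n", sep = "")
  cat("  Unique motif classes: ", fmt_na(x$counts$motifs, identity), "\n", sep = "")
  cat("  Unique domains:       ", fmt_na(x$counts$domains, identity), "\n", sep = "")
  cat("  Unique dProteins:     ", fmt_na(x$counts$dProteins, identity), "\n", sep = "")
  invisible(x)
}
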