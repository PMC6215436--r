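# Robustness-to-noise analysis: replace increasing proportions of the
# motif-carrying proteins with proteins drawn at random from a background
# pool, re-run the enrichment analysis, and collect the normalized-D
# distribution per noise level.

#' Noise-injection configuration
#'
#' @param fractions Proportions of motif-carrying proteins to replace
#'   (default `c(0.25, 0.50, 0.75, 1.00)`); must lie in `[0, 1]` and be
#'   sorted increasing.
#' @param pool Background protein IDs replacements are drawn from;
#'   `NULL` (default) uses all proteins of the PPI dataset
#'   (mProteins and dProteins).
#' @param seed Optional integer seed for the replacement draws.
#' @param n_shuffles Shuffles per enrichment run (default 1000).
#' @return Object of class `noise_config`.
#' @export
noise_config <- function(fractions = c(0.25, 0.50, 0.75, 1.00), pool = NULL,
                         seed = NULL, n_shuffles = 1000L) {
  if (any(fractions < 0 | fractions > 1)) {
    stop_config("noise_config: fractions must lie in [0, 1]")
  }
  if (is.unsorted(fractions)) stop_config("noise_config: fractions must be sorted")
  structure(list(fractions = fractions, pool = pool, seed = seed,
                 n_shuffles = as.integer(n_shuffles)),
            class = "noise_config")
}

#' Replace a fraction of motif-carrying proteins with pool proteins
#'
#' `round(fraction * n_carriers)` distinct carrier proteins (rounding half
#' away from zero) are selected without replacement; each selected carrier
#' is renamed — in all of its occurrence rows — to a protein sampled without
#' replacement from the background pool, so its motif-class assignments are
#' carried over unchanged. Replacement proteins may coincidentally exist in
#' the PPI network; that is the point of the simulation — they can realize
#' potential DMIs only by chance. Overlap between the pool draw and the
#' surviving carriers is logged.
#'
#' @param motifs A [motif_table()].
#' @param fraction Proportion of carriers to replace, in `[0, 1]`.
#' @param pool Character vector of candidate replacement protein IDs.
#' @return A perturbed [motif_table()] (same `occurrence_source` tag).
#' @export
perturb_motif_table <- function(motifs, fraction, pool) {
  stopifnot(inherits(motifs, "motif_table"))
  if (fraction < 0 || fraction > 1) {
    stop_config("perturb_motif_table: fraction must lie in [0, 1]")
  }
  carriers <- unique(motifs$occurrences$mProtein)
  n_rep <- as.integer(round_half_up(fraction * length(carriers)))
  if (n_rep == 0L) return(motifs)
  pool <- unique(as.character(pool))
  if (length(pool) < n_rep) {
    stop_config("perturb_motif_table: background pool (", length(pool),
                ") smaller than the number of carriers to replace (", n_rep, ")")
  }
  victims <- sample(carriers, n_rep)
  replacements <- sample(pool, n_rep)
  survivors <- setdiff(carriers, victims)
  overlap <- intersect(replacements, survivors)
  if (length(overlap)) {
    message("perturb_motif_table: ", length(overlap),
            " replacement protein(s) coincide with surviving carriers")
  }
  occ <- motifs$occurrences
  idx <- match(occ$mProtein, victims)
  occ$mProtein[!is.na(idx)] <- replacements[idx[!is.na(idx)]]
  motif_table(occ, motifs$occurrence_source)
}

#' Noise-injection sweep
#'
#' For each replacement fraction, perturbs the motif table and re-runs the
#' full enrichment analysis against the same PPI data and annotation
#' tables. The shuffle seed is shared across fractions (so the
#' fraction-0 run reproduces the unperturbed analysis), while each
#' fraction's replacement draw uses its own derived seed. Deterministic
#' given `noise_cfg$seed`.
#'
#' @inheritParams run_enrichment
#' @param noise_cfg A [noise_config()].
#' @return List of class `noise_sweep` whose elements (class `noise_run`)
#'   carry `fraction`, `motifs` (the perturbed table) and `result`
#'   (an `enrichment_result`).
#' @export
noise_sweep <- function(ppi, motifs, dmi_defs, domains, strategy,
                        noise_cfg = noise_config()) {
  stopifnot(inherits(noise_cfg, "noise_config"))
  pool <- noise_cfg$pool
  if (is.null(pool)) pool <- unique(c(ppi$pairs$mProtein, ppi$pairs$dProtein))
  runs <- vector("list", length(noise_cfg$fractions))
  for (i in seq_along(noise_cfg$fractions)) {
    f <- noise_cfg$fractions[i]
    if (!is.null(noise_cfg$seed)) set.seed(noise_cfg$seed + i)
    pert <- perturb_motif_table(motifs, f, pool)
    cfg <- shuffle_config(n_shuffles = noise_cfg$n_shuffles,
                          seed = noise_cfg$seed)
    res <- run_enrichment(ppi, pert, dmi_defs, domains, strategy, cfg)
    runs[[i]] <- structure(list(fraction = f, motifs = pert, result = res),
                           class = "noise_run")
  }
  structure(runs, class = "noise_sweep")
}

#' @export
print.noise_sweep <- function(x, ...) {
  cat("Noise sweep over", length(x), "replacement fractions:\n")
  for (r in x) {
    cat(sprintf("  fraction %.2f: O = %d, mean random = %s, p = %s\n",
                r$fraction, r$result$O, signif(r$result$R$mean, 3),
                r$result$p_display))
  }
  invisible(x)
}
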