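# Synthetic input generator: self-contained quadruples of PPI, motif
# occurrence, DMI definition and domain composition tables with a
# controllable fraction of PPI pairs planted onto realizable DMIs, so
# every pipeline stage is testable without external downloads.
#
# Planting operates on the most permissive (ELMc-Domain) potential set;
# the stricter strategies' tables are derived consistently from the same
# motif-domain ground truth so they see nested subsets.

#' Specification for a synthetic fixture
#'
#' @param n_mProteins,n_dProteins Numbers of motif-side / domain-side
#'   proteins (IDs `M1..`, `D1..`).
#' @param n_motif_classes,n_domain_classes Sizes of the motif / domain
#'   vocabularies (IDs `LIG_1..`, `PF1..`).
#' @param ppi_density Fraction of the `n_mProteins * n_dProteins` pair grid
#'   realized as PPIs, in `(0, 1]`.
#' @param planted_fraction Share of PPI pairs wired to realize at least one
#'   potential DMI under the `ELMc-Domain` strategy, in `[0, 1]`; the
#'   remainder is wired uniformly at random.
#' @param motif_per_protein,domain_per_protein Motif classes per mProtein /
#'   domains per dProtein.
#' @param seed Integer seed; fixtures are byte-identical given the seed.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_mProteins = 20L, n_dProteins = 20L,
                         n_motif_classes = 12L, n_domain_classes = 8L,
                         ppi_density = 0.1, planted_fraction = 0,
                         motif_per_protein = 2L, domain_per_protein = 2L,
                         seed = 1L) {
  counts <- c(n_mProteins, n_dProteins, n_motif_classes, n_domain_classes,
              motif_per_protein, domain_per_protein)
  if (any(counts < 1)) stop_config("fixture_spec: all counts must be >= 1")
  if (ppi_density <= 0 || ppi_density > 1) {
    stop_config("fixture_spec: ppi_density must be in (0, 1]")
  }
  if (planted_fraction < 0 || planted_fraction > 1) {
    stop_config("fixture_spec: planted_fraction must be in [0, 1]")
  }
  if (motif_per_protein > n_motif_classes || domain_per_protein > n_domain_classes) {
    stop_config("fixture_spec: per-protein counts exceed vocabulary size")
  }
  structure(list(n_mProteins = as.integer(n_mProteins),
                 n_dProteins = as.integer(n_dProteins),
                 n_motif_classes = as.integer(n_motif_classes),
                 n_domain_classes = as.integer(n_domain_classes),
                 ppi_density = ppi_density,
                 planted_fraction = planted_fraction,
                 motif_per_protein = as.integer(motif_per_protein),
                 domain_per_protein = as.integer(domain_per_protein),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic input quadruple
#'
#' Draws motif occurrences, motif-domain interaction links and domain
#' compositions uniformly under the spec, derives consistent DMI definition
#' tables for all three schemas from the same ground truth, and wires a PPI
#' network in which a `planted_fraction` share of pairs realizes at least
#' one potential DMI (under `ELMc-Domain`) and the rest are uniform random
#' pairs. The planted pair list is returned as ground truth for recovery
#' tests.
#'
#' @param spec A [fixture_spec()].
#' @return List of class `dmi_fixture`: `ppi` ([ppi_dataset()]), `motifs`
#'   ([motif_table()], known), `dmi_protein` / `dmi_motif_protein` /
#'   `dmi_motif_domain` ([dmi_table()]s, one per schema), `domains`
#'   ([domain_table()]), `planted` (data.frame of planted pairs), `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  mprot <- paste0("M", seq_len(spec$n_mProteins))
  dprot <- paste0("D", seq_len(spec$n_dProteins))
  motif_ids <- paste0("LIG_", seq_len(spec$n_motif_classes))
  domain_ids <- paste0("PF", seq_len(spec$n_domain_classes))

  occ <- data.frame(
    mProtein = rep(mprot, each = spec$motif_per_protein),
    Motif = as.vector(vapply(mprot, function(p)
      sample(motif_ids, spec$motif_per_protein), character(spec$motif_per_protein))),
    stringsAsFactors = FALSE)
  comp <- data.frame(
    dProtein = rep(dprot, each = spec$domain_per_protein),
    Domain = as.vector(vapply(dprot, function(p)
      sample(domain_ids, spec$domain_per_protein), character(spec$domain_per_protein))),
    stringsAsFactors = FALSE)
  # each motif class binds one domain
  md <- data.frame(Motif = motif_ids,
                   Domain = sample(domain_ids, spec$n_motif_classes, replace = TRUE),
                   stringsAsFactors = FALSE)

  motifs <- motif_table(occ, "known")
  domains <- domain_table(comp)
  dmi_md <- dmi_table(md, "motif-domain")
  # motif -> dProtein links implied by the ground truth
  mp <- merge(md, comp, by = "Domain")[, c("Motif", "dProtein")]
  dmi_mp <- dmi_table(mp, "motif-protein")
  # ground-truth realizable (mProtein, dProtein) pairs under ELMc-Domain
  gt <- merge(merge(occ, md, by = "Motif"), comp,
              by = "Domain")[, c("mProtein", "dProtein")]
  gt <- gt[!duplicated(gt), , drop = FALSE]
  # curated protein-level interactions: a fixed 25% subsample of the
  # realizable pairs, so the ELMi potential set nests inside the others
  n_elmi <- max(1L, as.integer(round_half_up(0.25 * nrow(gt))))
  pp <- gt[sample.int(nrow(gt), min(n_elmi, nrow(gt))), , drop = FALSE]
  dmi_pp <- dmi_table(pp, "protein-protein")

  n_grid <- spec$n_mProteins * spec$n_dProteins
  n_pairs <- max(1L, as.integer(round_half_up(spec$ppi_density * n_grid)))
  if (n_pairs > n_grid) {
    stop_infeasible("generate_fixture: density requires more pairs than exist")
  }
  n_plant <- as.integer(round_half_up(spec$planted_fraction * n_pairs))
  if (n_plant > nrow(gt)) {
    stop_infeasible("generate_fixture: planted_fraction requires ", n_plant,
                    " DMI-realizing pairs but only ", nrow(gt), " exist")
  }
  gt_key <- pair_key(gt$mProtein, gt$dProtein)
  planted <- gt[sample.int(nrow(gt), n_plant), , drop = FALSE]
  n_rand <- n_pairs - n_plant
  grid_m <- rep(mprot, times = spec$n_dProteins)
  grid_d <- rep(dprot, each = spec$n_mProteins)
  grid_key <- pair_key(grid_m, grid_d)
  avail <- which(!(grid_key %in% pair_key(planted$mProtein, planted$dProtein)))
  if (n_rand > length(avail)) {
    stop_infeasible("generate_fixture: density requires more pairs than exist")
  }
  ridx <- sample(avail, n_rand)
  pairs <- rbind(planted,
                 data.frame(mProtein = grid_m[ridx], dProtein = grid_d[ridx],
                            stringsAsFactors = FALSE))
  pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
  ppi <- suppressMessages(ppi_dataset(pairs, source_label = "synthetic"))
  rownames(planted) <- NULL

  structure(list(ppi = ppi, motifs = motifs, dmi_protein = dmi_pp,
                 dmi_motif_protein = dmi_mp, dmi_motif_domain = dmi_md,
                 domains = domains, planted = planted, spec = spec),
            class = "dmi_fixture")
}

#' Write a fixture to delimited files
#'
#' Writes the four input files in the default field-map dialect
#' (comma-separated, header row, UTF-8, LF) plus a ground-truth CSV of
#' planted pairs. File names: `ppi.csv`, `motifs.csv`, `dmi_protein.csv`,
#' `dmi_motif_protein.csv`, `dmi_motif_domain.csv`, `domains.csv`,
#' `planted.csv`.
#'
#' @param fixture A `dmi_fixture` from [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "dmi_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ppi = file.path(dir, "ppi.csv"),
             motifs = file.path(dir, "motifs.csv"),
             dmi_protein = file.path(dir, "dmi_protein.csv"),
             dmi_motif_protein = file.path(dir, "dmi_motif_protein.csv"),
             dmi_motif_domain = file.path(dir, "dmi_motif_domain.csv"),
             domains = file.path(dir, "domains.csv"),
             planted = file.path(dir, "planted.csv"))
  wf <- function(df, p) fwrite(df, p, sep = ",", eol = "\n")
  wf(fixture$ppi$pairs, paths[["ppi"]])
  wf(fixture$motifs$occurrences, paths[["motifs"]])
  wf(fixture$dmi_protein$links, paths[["dmi_protein"]])
  wf(fixture$dmi_motif_protein$links, paths[["dmi_motif_protein"]])
  wf(fixture$dmi_motif_domain$links, paths[["dmi_motif_domain"]])
  wf(fixture$domains$composition, paths[["domains"]])
  wf(fixture$planted, paths[["planted"]])
  invisible(paths)
}
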