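# Strategy-dependent mapping of potential DMIs onto a PPI network and
# extraction of the predicted DMIs realized by observed pairs.
#
# A "DMI" is the fully-populated tuple for the active strategy —
# (mProtein, dProtein) for ELMi-Protein, (mProtein, Motif, dProtein) for
# ELMc-Protein and (mProtein, Motif, Domain, dProtein) for ELMc-Domain —
# deduplicated, so one interacting protein pair can account for several
# DMIs (distinct motifs and/or domains). This tuple-level counting is what
# the unique-entity summary counts are computed over.

DMI_MODES <- c("ELMc-Protein", "ELMi-Protein", "ELMc-Domain")

#' DMI mapping strategy
#'
#' Chooses the stringency of DMI mapping and the provenance of the motif
#' occurrences.
#'
#' * `ELMi-Protein` (highest stringency): the DMI definition file links
#'   mProteins directly to known dProtein interaction partners; the motif
#'   and domain tables are not used.
#' * `ELMc-Protein` (medium): motif occurrences are joined to
#'   motif-class-to-dProtein links; the domain table is not used.
#' * `ELMc-Domain` (lowest): motif occurrences are joined to
#'   motif-class-to-domain links and then to dProtein domain composition.
#'
#' @param mode One of `"ELMi-Protein"`, `"ELMc-Protein"`, `"ELMc-Domain"`.
#' @param occurrence_source `"known"` (curated instances) or `"predicted"`
#'   (motif-scan predictions); a label checked against the motif table.
#' @return Object of class `dmi_strategy`.
#' @export
dmi_strategy <- function(mode = DMI_MODES,
                         occurrence_source = c("known", "predicted")) {
  mode <- match.arg(mode, DMI_MODES)
  occurrence_source <- match.arg(occurrence_source)
  structure(list(mode = mode, occurrence_source = occurrence_source),
            class = "dmi_strategy")
}

#' DMI definition schema required by a strategy mode
#' @param mode A strategy mode string.
#' @return The matching `schema_kind` string.
#' @export
schema_for_mode <- function(mode) {
  switch(mode,
         "ELMi-Protein" = "protein-protein",
         "ELMc-Protein" = "motif-protein",
         "ELMc-Domain"  = "motif-domain",
         stop_config("unknown strategy mode: ", mode))
}

strategy_label <- function(strategy) {
  paste0(if (strategy$occurrence_source == "known") "Known" else "Predicted",
         ": ", strategy$mode)
}

empty_dmi_frame <- function() {
  data.frame(mProtein = character(), Motif = character(),
             Domain = character(), dProtein = character(),
             stringsAsFactors = FALSE)
}

pair_key <- function(m, d) paste(m, d, sep = "\x1f")

#' Enumerate the potential DMIs of a PPI dataset
#'
#' Builds the pool of all plausible motif-mediated links between mProteins
#' and dProteins present in the PPI data, under the selected strategy. The
#' restriction is asymmetric: the tuple's mProtein must occur in the PPI
#' mProtein column and its dProtein in the dProtein column. The result is
#' deduplicated at the tuple level; unused fields are `NA`.
#'
#' @param ppi A [ppi_dataset()].
#' @param motifs A [motif_table()] (ignored for `ELMi-Protein`; may be `NULL`).
#' @param dmi_defs A [dmi_table()] whose `schema_kind` matches the strategy.
#' @param domains A [domain_table()] (used only by `ELMc-Domain`; may be `NULL`).
#' @param strategy A [dmi_strategy()].
#' @return data.frame of class `potential_dmis` with columns
#'   `mProtein`, `Motif`, `Domain`, `dProtein`.
#' @export
build_potential_dmis <- function(ppi, motifs, dmi_defs, domains, strategy) {
  stopifnot(inherits(ppi, "ppi_dataset"), inherits(strategy, "dmi_strategy"),
            inherits(dmi_defs, "dmi_table"))
  need <- schema_for_mode(strategy$mode)
  if (dmi_defs$schema_kind != need) {
    stop_config("strategy ", strategy$mode, " requires a '", need,
                "' DMI definition file, got '", dmi_defs$schema_kind, "'")
  }
  m_set <- unique(ppi$pairs$mProtein)
  d_set <- unique(ppi$pairs$dProtein)

  res <- switch(strategy$mode,
    "ELMi-Protein" = {
      lk <- dmi_defs$links
      lk <- lk[lk$mProtein %in% m_set & lk$dProtein %in% d_set, , drop = FALSE]
      if (nrow(lk)) data.frame(mProtein = lk$mProtein, Motif = NA_character_,
                               Domain = NA_character_, dProtein = lk$dProtein,
                               stringsAsFactors = FALSE)
      else empty_dmi_frame()
    },
    "ELMc-Protein" = {
      stopifnot(inherits(motifs, "motif_table"))
      occ <- motifs$occurrences
      occ <- occ[occ$mProtein %in% m_set, , drop = FALSE]
      lk <- dmi_defs$links
      lk <- lk[lk$dProtein %in% d_set, , drop = FALSE]
      j <- merge(occ, lk, by = "Motif")
      if (nrow(j)) data.frame(mProtein = j$mProtein, Motif = j$Motif,
                              Domain = NA_character_, dProtein = j$dProtein,
                              stringsAsFactors = FALSE)
      else empty_dmi_frame()
    },
    "ELMc-Domain" = {
      stopifnot(inherits(motifs, "motif_table"), inherits(domains, "domain_table"))
      occ <- motifs$occurrences
      occ <- occ[occ$mProtein %in% m_set, , drop = FALSE]
      comp <- domains$composition
      comp <- comp[comp$dProtein %in% d_set, , drop = FALSE]
      j <- merge(merge(occ, dmi_defs$links, by = "Motif"), comp, by = "Domain")
      if (nrow(j)) data.frame(mProtein = j$mProtein, Motif = j$Motif,
                              Domain = j$Domain, dProtein = j$dProtein,
                              stringsAsFactors = FALSE)
      else empty_dmi_frame()
    })

  res <- res[!duplicated(res), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("potential_dmis", "data.frame"), strategy = strategy)
}

#' Unique-entity counts of a DMI table
#'
#' @param dmis A data.frame with columns mProtein/Motif/Domain/dProtein.
#' @return Named list: `n_dmi`, `mProteins`, `motifs`, `domains`,
#'   `dProteins` (`NA` for fields the strategy does not populate).
#' @export
dmi_unique_counts <- function(dmis) {
  nun <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) NA_integer_ else length(unique(x))
  }
  list(n_dmi = nrow(dmis),
       mProteins = nun(dmis$mProtein), motifs = nun(dmis$Motif),
       domains = nun(dmis$Domain), dProteins = nun(dmis$dProtein))
}

#' Extract the predicted DMIs realized by observed PPI pairs
#'
#' The predicted set is the subset of potential DMI tuples whose
#' (mProtein, dProtein) pair is actually observed in the PPI data,
#' respecting pair orientation.
#'
#' @param potential A `potential_dmis` data.frame.
#' @param ppi A [ppi_dataset()].
#' @return data.frame of class `predicted_dmis`, with attribute `counts`
#'   (see [dmi_unique_counts()]).
#' @export
extract_predicted_dmis <- function(potential, ppi) {
  stopifnot(inherits(ppi, "ppi_dataset"))
  obs <- pair_key(ppi$pairs$mProtein, ppi$pairs$dProtein)
  keep <- pair_key(potential$mProtein, potential$dProtein) %in% obs
  res <- as.data.frame(potential)[keep, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("predicted_dmis", "data.frame"),
            strategy = attr(potential, "strategy"),
            counts = dmi_unique_counts(res))
}
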