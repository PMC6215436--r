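# Core record types and delimited-file IO for DMI enrichment analysis.
#
# All tables are plain data.frames wrapped in light S3 classes; identifiers
# are matched by exact, case-sensitive string equality after trimming
# surrounding whitespace (case-folding is left to upstream preprocessing to
# avoid silent ID collisions).

#' @importFrom data.table fread fwrite as.data.table setDF :=
#' @importFrom stats setNames
NULL

# ---- condition helpers -------------------------------------------------

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("dmi_schema_error", "dmi_error")))
}
stop_empty <- function(...) {
  stop(errorCondition(paste0(...), class = c("dmi_empty_error", "dmi_error")))
}
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("dmi_config_error", "dmi_error")))
}
stop_infeasible <- function(...) {
  stop(errorCondition(paste0(...), class = c("dmi_infeasible_error", "dmi_error")))
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Column-name mapping for delimited input files
#'
#' Input files use the default headers `mProtein`, `dProtein`, `Motif` and
#' `Domain`; a field map renames them for files produced with other
#' conventions and optionally fixes the delimiter.
#'
#' @param mProtein,dProtein,Motif,Domain Column names in the user's files for
#'   the motif-side protein, domain-side protein, motif class and domain
#'   identifiers. Must be four distinct names.
#' @param delim Field delimiter; `NULL` (default) auto-detects among
#'   comma/tab.
#' @param header Logical; files carry a header row (default `TRUE`).
#' @return An object of class `field_map`.
#' @export
#' @examples
#' field_map(mProtein = "bait", dProtein = "prey")
field_map <- function(mProtein = "mProtein", dProtein = "dProtein",
                      Motif = "Motif", Domain = "Domain",
                      delim = NULL, header = TRUE) {
  nms <- c(mProtein, dProtein, Motif, Domain)
  if (!all(nzchar(nms)) || anyDuplicated(nms)) {
    stop_config("field_map: mProtein/dProtein/Motif/Domain names must be non-empty and distinct")
  }
  structure(list(mProtein = mProtein, dProtein = dProtein,
                 Motif = Motif, Domain = Domain,
                 delim = delim, header = isTRUE(header)),
            class = "field_map")
}

as_field_map <- function(x) {
  if (inherits(x, "field_map")) return(x)
  if (is.null(x)) return(field_map())
  do.call(field_map, as.list(x))
}

# ---- generic delimited reader ------------------------------------------

# Read a delimited file, select and rename `want` (named: internal -> file
# header), trim whitespace, drop rows with missing/empty cells (logged),
# deduplicate keeping first occurrence.
read_two_cols <- function(path, fm, want, what) {
  if (!file.exists(path)) stop_config(what, ": file not found: ", path)
  sep <- if (is.null(fm$delim)) "auto" else fm$delim
  dt <- tryCatch(
    fread(path, sep = sep, header = fm$header, colClasses = "character",
          data.table = TRUE, showProgress = FALSE),
    error = function(e) stop_empty(what, ": could not parse ", path, ": ", conditionMessage(e))
  )
  if (nrow(dt) == 0L && ncol(dt) == 0L) stop_empty(what, ": empty input file: ", path)
  missing_cols <- setdiff(unname(want), names(dt))
  if (length(missing_cols)) {
    stop_schema(what, ": missing column(s) ", paste(missing_cols, collapse = ", "),
                "; found headers: ", paste(names(dt), collapse = ", "))
  }
  df <- as.data.frame(dt)[, unname(want), drop = FALSE]
  names(df) <- names(want)
  for (j in seq_along(df)) df[[j]] <- trimws(df[[j]])
  bad <- Reduce(`|`, lapply(df, function(x) is.na(x) | !nzchar(x)))
  if (any(bad)) {
    message(what, ": dropped ", sum(bad), " row(s) with missing/empty cells")
    df <- df[!bad, , drop = FALSE]
  }
  ndup <- sum(duplicated(df))
  if (ndup > 0L) message(what, ": dropped ", ndup, " duplicate row(s)")
  df <- df[!duplicated(df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ---- PPIDataset --------------------------------------------------------

#' Construct a PPI dataset
#'
#' A PPI dataset is an ordered, non-redundant list of asymmetric
#' (mProtein, dProtein) pairs: the first column holds the putative
#' motif-containing proteins, the second their domain-containing partners.
#' `(A,B)` and `(B,A)` are distinct records; self-pairs `(A,A)` are retained
#' (and flagged). Duplicates are dropped keeping first occurrence.
#'
#' @param pairs data.frame with columns `mProtein` and `dProtein`.
#' @param source_label Free-text provenance label.
#' @return Object of class `ppi_dataset` with elements `pairs` and
#'   `source_label`.
#' @export
ppi_dataset <- function(pairs, source_label = "") {
  pairs <- as.data.frame(pairs)[, c("mProtein", "dProtein")]
  pairs$mProtein <- trimws(as.character(pairs$mProtein))
  pairs$dProtein <- trimws(as.character(pairs$dProtein))
  if (any(!nzchar(pairs$mProtein)) || any(!nzchar(pairs$dProtein))) {
    stop_schema("ppi_dataset: empty protein IDs are not allowed")
  }
  pairs <- pairs[!duplicated(pairs), , drop = FALSE]
  rownames(pairs) <- NULL
  nself <- sum(pairs$mProtein == pairs$dProtein)
  if (nself > 0L) message("ppi_dataset: ", nself, " self-interaction(s) retained")
  structure(list(pairs = pairs, source_label = source_label),
            class = "ppi_dataset")
}

#' @export
print.ppi_dataset <- function(x, ...) {
  cat("PPI dataset", if (nzchar(x$source_label)) paste0("[", x$source_label, "]"),
      ":", nrow(x$pairs), "non-redundant pairs,",
      length(unique(x$pairs$mProtein)), "mProteins,",
      length(unique(x$pairs$dProtein)), "dProteins\n")
  invisible(x)
}

#' Read a pairwise PPI file
#'
#' Reads a delimited file of mProtein/dProtein pairs and canonicalizes it to
#' an asymmetric non-redundant pair list (duplicate rows dropped with a
#' logged count, first-occurrence order preserved).
#'
#' @param path Path to the delimited file.
#' @param fm A [field_map()].
#' @param source_label Provenance label stored on the result.
#' @return A [ppi_dataset()].
#' @export
read_ppi <- function(path, fm = field_map(), source_label = basename(path)) {
  fm <- as_field_map(fm)
  df <- read_two_cols(path, fm,
                      c(mProtein = fm$mProtein, dProtein = fm$dProtein), "read_ppi")
  if (nrow(df) == 0L) stop_empty("read_ppi: no usable PPI rows in ", path)
  ppi_dataset(df, source_label = source_label)
}

#' Symmetrize a PPI dataset
#'
#' Ensures every non-self pair is present in both orientations exactly once
#' (self-pairs once), e.g. to emulate an undirected interactome where every
#' protein is considered in both the motif and the domain role. Idempotent.
#'
#' @param ppi A [ppi_dataset()].
#' @return A [ppi_dataset()] with `2 * n_non_self + n_self` pairs.
#' @export
symmetrize_ppi <- function(ppi) {
  stopifnot(inherits(ppi, "ppi_dataset"))
  p <- ppi$pairs
  flipped <- data.frame(mProtein = p$dProtein, dProtein = p$mProtein,
                        stringsAsFactors = FALSE)
  suppressMessages(ppi_dataset(rbind(p, flipped), source_label = ppi$source_label))
}

# ---- MotifOccurrenceTable ----------------------------------------------

#' Construct a motif occurrence table
#'
#' Links mProteins to the motif classes they carry (known ELM instances or
#' predictions from a motif-scanning tool). Positional duplicates collapse:
#' occurrences are counted at the (protein, motif class) level.
#'
#' @param occurrences data.frame with columns `mProtein` and `Motif`.
#' @param occurrence_source `"known"` or `"predicted"`.
#' @return Object of class `motif_table`.
#' @export
motif_table <- function(occurrences, occurrence_source = c("known", "predicted")) {
  occurrence_source <- match.arg(occurrence_source)
  occ <- as.data.frame(occurrences)[, c("mProtein", "Motif")]
  occ$mProtein <- trimws(as.character(occ$mProtein))
  occ$Motif <- trimws(as.character(occ$Motif))
  occ <- occ[!duplicated(occ), , drop = FALSE]
  rownames(occ) <- NULL
  structure(list(occurrences = occ, occurrence_source = occurrence_source),
            class = "motif_table")
}

#' Read a motif occurrence file
#'
#' Extra columns (positions, scores from a prediction tool) are ignored; only
#' the mapped mProtein and Motif columns are kept. An empty table is legal
#' (warned about), e.g. when no motif survives prediction filtering.
#'
#' @inheritParams read_ppi
#' @param occurrence_source `"known"` or `"predicted"`; tag carried on the
#'   result and on the strategy labelling of downstream outputs.
#' @return A [motif_table()].
#' @export
read_motifs <- function(path, fm = field_map(),
                        occurrence_source = c("known", "predicted")) {
  occurrence_source <- match.arg(occurrence_source)
  fm <- as_field_map(fm)
  df <- read_two_cols(path, fm,
                      c(mProtein = fm$mProtein, Motif = fm$Motif), "read_motifs")
  if (nrow(df) == 0L) warning("read_motifs: no motif occurrences in ", path)
  motif_table(df, occurrence_source)
}

# ---- DMIDefinitionTable ------------------------------------------------

DMI_SCHEMAS <- c("protein-protein", "motif-protein", "motif-domain")

dmi_schema_cols <- function(schema_kind) {
  switch(schema_kind,
         "protein-protein" = c("mProtein", "dProtein"),
         "motif-protein"   = c("Motif", "dProtein"),
         "motif-domain"    = c("Motif", "Domain"),
         stop_config("unknown DMI schema kind: ", schema_kind))
}

#' Construct a DMI definition table
#'
#' Two-column link table whose schema depends on the mapping strategy:
#' direct mProtein-dProtein interactions (`protein-protein`), motif classes
#' linked to known binding partner proteins (`motif-protein`), or motif
#' classes linked to binding domains (`motif-domain`).
#'
#' @param links data.frame with the two columns required by `schema_kind`.
#' @param schema_kind One of `"protein-protein"`, `"motif-protein"`,
#'   `"motif-domain"`.
#' @return Object of class `dmi_table`.
#' @export
dmi_table <- function(links, schema_kind = DMI_SCHEMAS) {
  schema_kind <- match.arg(schema_kind, DMI_SCHEMAS)
  cols <- dmi_schema_cols(schema_kind)
  links <- as.data.frame(links)
  if (!all(cols %in% names(links))) {
    stop_schema("dmi_table (", schema_kind, "): need columns ",
                paste(cols, collapse = ", "))
  }
  links <- links[, cols]
  for (j in seq_along(links)) links[[j]] <- trimws(as.character(links[[j]]))
  links <- links[!duplicated(links), , drop = FALSE]
  rownames(links) <- NULL
  structure(list(links = links, schema_kind = schema_kind), class = "dmi_table")
}

#' Read a DMI definition file
#'
#' `schema_kind` selects which two mapped columns are required; other
#' columns are ignored.
#'
#' @inheritParams read_ppi
#' @param schema_kind See [dmi_table()].
#' @return A [dmi_table()].
#' @export
read_dmi_definitions <- function(path, fm = field_map(),
                                 schema_kind = DMI_SCHEMAS) {
  schema_kind <- match.arg(schema_kind, DMI_SCHEMAS)
  fm <- as_field_map(fm)
  cols <- dmi_schema_cols(schema_kind)
  want <- setNames(unlist(fm[cols]), cols)
  df <- read_two_cols(path, fm, want, paste0("read_dmi_definitions[", schema_kind, "]"))
  dmi_table(df, schema_kind)
}

# ---- DomainCompositionTable --------------------------------------------

#' Construct a domain composition table
#'
#' Links dProteins to their domain identifiers (e.g. Pfam accessions).
#'
#' @param composition data.frame with columns `dProtein` and `Domain`.
#' @return Object of class `domain_table`.
#' @export
domain_table <- function(composition) {
  comp <- as.data.frame(composition)[, c("dProtein", "Domain")]
  comp$dProtein <- trimws(as.character(comp$dProtein))
  comp$Domain <- trimws(as.character(comp$Domain))
  comp <- comp[!duplicated(comp), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(composition = comp), class = "domain_table")
}

#' Read a domain composition file
#'
#' @inheritParams read_ppi
#' @return A [domain_table()].
#' @export
read_domains <- function(path, fm = field_map()) {
  fm <- as_field_map(fm)
  df <- read_two_cols(path, fm,
                      c(dProtein = fm$dProtein, Domain = fm$Domain), "read_domains")
  domain_table(df)
}
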