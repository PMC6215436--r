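# Output rendering and command-line entry point: summary and DMI tables as
# CSV, random-count histogram (CSV + PNG), GraphML/edge-list network export,
# and the noise-sweep long table.

#' @importFrom utils modifyList
NULL

fmt_dmi_frame <- function(dmis) {
  out <- as.data.frame(dmis)[, c("mProtein", "Motif", "Domain", "dProtein")]
  for (j in seq_along(out)) out[[j]][is.na(out[[j]])] <- ""
  out
}

#' Write potential or predicted DMI tables
#'
#' Columns `[mProtein, Motif, Domain, dProtein]`; fields the strategy does
#' not populate are left empty.
#'
#' @param dmis A `potential_dmis` or `predicted_dmis` data.frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_dmi_table <- function(dmis, path) {
  fwrite(fmt_dmi_frame(dmis), path, sep = ",", eol = "\n")
  invisible(path)
}

#' Write the one-row machine-readable summary
#'
#' Full-precision values plus display columns rounded by the reporting
#' conventions (mean random and enrichment 3 s.f., FDR 4 d.p.).
#'
#' @param result An `enrichment_result`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(result, path) {
  x <- result
  df <- data.frame(
    strategy = strategy_label(x$strategy),
    potential_dmi = nrow(x$potential),
    predicted_dmi = x$O,
    mean_random_dmi = x$R$mean,
    p_value = x$p_value,
    p_display = x$p_display,
    enrichment = x$enrichment,
    enrichment_display = signif(x$enrichment, 3),
    fdr = x$fdr,
    fdr_display = round(x$fdr, 4),
    unique_mProteins = x$counts$mProteins,
    unique_motifs = x$counts$motifs,
    unique_domains = x$counts$domains,
    unique_dProteins = x$counts$dProteins,
    n_shuffles = x$n_shuffles,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed,
    stringsAsFactors = FALSE)
  fwrite(df, path, sep = ",", eol = "\n")
  invisible(path)
}

#' Write the per-shuffle random DMI counts
#'
#' One-column CSV of the raw data behind the enrichment histogram.
#'
#' @param R A `random_dmi_distribution`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_random_counts <- function(R, path) {
  fwrite(data.frame(random_dmi_count = R$counts), path, sep = ",", eol = "\n")
  invisible(path)
}

#' Histogram of the random DMI distribution
#'
#' Writes integer-binned (bin width 1) frequencies of the random
#' predicted-DMI counts as CSV and, unless `png_path` is `NULL`, a static
#' plot with the observed count marked by a dashed line.
#'
#' @param R A `random_dmi_distribution` or numeric count vector.
#' @param O Observed predicted-DMI count.
#' @param csv_path Output CSV path (columns `count`, `frequency`).
#' @param png_path Optional PNG path.
#' @return Invisibly, the binned data.frame.
#' @export
write_histogram <- function(R, O, csv_path, png_path = NULL) {
  counts <- r_counts(R)
  lo <- min(counts, O, 0)
  hi <- max(counts, O)
  bins <- seq(lo, hi)
  freq <- as.integer(table(factor(counts, levels = bins)))
  df <- data.frame(count = bins, frequency = freq)
  fwrite(df, csv_path, sep = ",", eol = "\n")
  if (!is.null(png_path)) {
    tryCatch({
      grDevices::png(png_path, width = 900, height = 600)
      on.exit(grDevices::dev.off(), add = TRUE)
      graphics::barplot(df$frequency, names.arg = df$count, space = 0,
                        col = "grey70", border = "grey40",
                        xlab = "Predicted DMIs in randomized PPI data",
                        ylab = "Frequency",
                        main = "Random DMI distribution")
      graphics::abline(v = O - lo + 0.5, lty = 2, lwd = 2, col = "red")
      graphics::mtext(paste("observed =", O), side = 3, col = "red")
    }, error = function(e) {
      warning("write_histogram: PNG device unavailable (", conditionMessage(e),
              "); CSV written")
    })
  }
  invisible(df)
}

#' Export the predicted DMI network
#'
#' Builds a layered bipartite-style graph whose node `type` attribute is one
#' of `mProtein`, `motif`, `domain`, `dProtein`, with edges
#' mProtein-motif, motif-domain and domain-dProtein (or mProtein-dProtein
#' directly under `ELMi-Protein`), and writes it as GraphML plus a
#' typed edge-list CSV.
#'
#' @param predicted A `predicted_dmis` data.frame.
#' @param graphml_path Output GraphML path.
#' @param edges_path Optional edge-list CSV path (columns `from`, `to`,
#'   `from_type`, `to_type`).
#' @return Invisibly, the `igraph` graph.
#' @export
export_network <- function(predicted, graphml_path, edges_path = NULL) {
  df <- as.data.frame(predicted)
  seg <- function(a, ta, b, tb) {
    keep <- !is.na(a) & !is.na(b)
    data.frame(from = paste0(ta, ":", a[keep]), to = paste0(tb, ":", b[keep]),
               from_type = ta, to_type = tb,
               from_id = a[keep], to_id = b[keep], stringsAsFactors = FALSE)
  }
  edges <- if (nrow(df) == 0L) {
    data.frame(from = character(), to = character(), from_type = character(),
               to_type = character(), from_id = character(),
               to_id = character(), stringsAsFactors = FALSE)
  } else if (all(is.na(df$Motif))) {
    seg(df$mProtein, "mProtein", df$dProtein, "dProtein")
  } else if (all(is.na(df$Domain))) {
    rbind(seg(df$mProtein, "mProtein", df$Motif, "motif"),
          seg(df$Motif, "motif", df$dProtein, "dProtein"))
  } else {
    rbind(seg(df$mProtein, "mProtein", df$Motif, "motif"),
          seg(df$Motif, "motif", df$Domain, "domain"),
          seg(df$Domain, "domain", df$dProtein, "dProtein"))
  }
  edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
  verts <- unique(rbind(
    data.frame(name = edges$from, type = edges$from_type, id = edges$from_id,
               stringsAsFactors = FALSE),
    data.frame(name = edges$to, type = edges$to_type, id = edges$to_id,
               stringsAsFactors = FALSE)))
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE, vertices = verts)
  igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edges_path)) {
    fwrite(edges[, c("from_id", "to_id", "from_type", "to_type")],
           edges_path, sep = ",", eol = "\n")
  }
  invisible(g)
}

#' Write the noise-sweep normalized-D long table
#'
#' Long format `[fraction, shuffle_index, D]` — one row per shuffle per
#' noise fraction, the raw data behind per-fraction normalized-D curves.
#'
#' @param sweep A `noise_sweep` from [noise_sweep()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_noise_sweep <- function(sweep, path) {
  rows <- lapply(sweep, function(r) {
    data.frame(fraction = r$fraction,
               shuffle_index = seq_along(r$result$D),
               D = r$result$D)
  })
  fwrite(do.call(rbind, rows), path, sep = ",", eol = "\n")
  invisible(path)
}
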