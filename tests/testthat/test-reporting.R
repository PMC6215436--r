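# CSV/histogram/network rendering and the CLI entry point.

test_that("histogram bins at width 1, conserves frequencies, marks observed", {
  df <- write_histogram(c(0, 0, 1), O = 2, csv_path = withr::local_tempfile())
  expect_equal(df$count, 0:2)
  expect_equal(df$frequency, c(2L, 1L, 0L))
  dfc <- write_histogram(rep(4L, 10), O = 4, csv_path = withr::local_tempfile())
  expect_equal(sum(dfc$frequency), 10L)
  expect_equal(dfc$frequency[dfc$count == 4], 10L)
})

test_that("network export has the right node taxonomy and counts", {
  pred3 <- structure(
    data.frame(mProtein = "A", Motif = "m", Domain = "d", dProtein = "X",
               stringsAsFactors = FALSE),
    class = c("predicted_dmis", "data.frame"))
  gpath <- withr::local_tempfile(fileext = ".graphml")
  epath <- withr::local_tempfile(fileext = ".csv")
  g <- export_network(pred3, gpath, epath)
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
  expect_setequal(igraph::V(g)$type, c("mProtein", "motif", "domain", "dProtein"))
  expect_true(file.exists(gpath))
  expect_equal(nrow(data.table::fread(epath)), 3L)
  # ELMi-Protein: direct protein-protein edge
  pred1 <- structure(
    data.frame(mProtein = "A", Motif = NA_character_, Domain = NA_character_,
               dProtein = "X", stringsAsFactors = FALSE),
    class = c("predicted_dmis", "data.frame"))
  g1 <- export_network(pred1, withr::local_tempfile(fileext = ".graphml"))
  expect_equal(c(igraph::vcount(g1), igraph::ecount(g1)), c(2, 1))
  # node counts match the unique-entity counts of a composite predicted set
  fx <- generate_fixture(fixture_spec(planted_fraction = 0.5, seed = 6))
  pred <- extract_predicted_dmis(
    build_potential_dmis(fx$ppi, fx$motifs, fx$dmi_motif_domain, fx$domains,
                         dmi_strategy("ELMc-Domain", "known")), fx$ppi)
  gg <- export_network(pred, withr::local_tempfile(fileext = ".graphml"))
  cnt <- attr(pred, "counts")
  expect_equal(igraph::vcount(gg),
               cnt$mProteins + cnt$motifs + cnt$domains + cnt$dProteins)
})

test_that("summary CSV re-parses to the full-precision result values", {
  fx <- generate_fixture(fixture_spec(planted_fraction = 0.4, seed = 12))
  res <- run_enrichment(fx$ppi, fx$motifs, fx$dmi_motif_domain, fx$domains,
                        dmi_strategy("ELMc-Domain", "known"),
                        shuffle_config(n_shuffles = 60, seed = 3))
  p <- withr::local_tempfile(fileext = ".csv")
  write_summary(res, p)
  row <- as.data.frame(data.table::fread(p))
  expect_equal(row$mean_random_dmi, res$R$mean)
  expect_equal(row$enrichment, res$enrichment)
  expect_equal(row$fdr, res$fdr)
  expect_equal(row$predicted_dmi, res$O)
  expect_equal(row$enrichment_display, signif(res$enrichment, 3))
})

test_that("CLI runs end to end, deterministically, with all outputs", {
  fx <- generate_fixture(fixture_spec(planted_fraction = 0.5, seed = 19))
  d <- withr::local_tempdir()
  paths <- write_fixture(fx, d)
  run <- function(outdir) {
    suppressMessages(cli_main(c(
      "--ppi", paths[["ppi"]], "--motifs", paths[["motifs"]],
      "--dmi", paths[["dmi_motif_domain"]], "--domains", paths[["domains"]],
      "--strategy", "elmc-domain", "--shuffles", "40", "--seed", "5",
      "--dump-random-counts", "--outdir", outdir)))
  }
  o1 <- file.path(d, "o1"); o2 <- file.path(d, "o2")
  expect_equal(run(o1), 0L)
  expect_equal(run(o2), 0L)
  expected <- c("summary.csv", "potential_dmis.csv", "predicted_dmis.csv",
                "histogram.csv", "network.graphml", "network_edges.csv",
                "random_counts.csv")
  expect_true(all(expected %in% list.files(o1)))
  for (f in c("summary.csv", "predicted_dmis.csv", "random_counts.csv")) {
    expect_identical(readLines(file.path(o1, f)), readLines(file.path(o2, f)),
                     info = f)
  }
  # predicted count in the summary matches an in-R rerun
  row <- as.data.frame(data.table::fread(file.path(o1, "summary.csv")))
  res <- run_enrichment(fx$ppi, fx$motifs, fx$dmi_motif_domain, fx$domains,
                        dmi_strategy("ELMc-Domain", "known"),
                        shuffle_config(40, seed = 5))
  expect_equal(row$predicted_dmi, res$O)
})

test_that("CLI exit codes: 2 for schema/usage errors, 1 for data errors", {
  fx <- generate_fixture(fixture_spec(seed = 19))
  d <- withr::local_tempdir()
  paths <- write_fixture(fx, d)
  # strategy/schema mismatch: elmi-protein with a motif-domain DMI file
  expect_equal(suppressMessages(cli_main(c(
    "--ppi", paths[["ppi"]], "--dmi", paths[["dmi_motif_domain"]],
    "--strategy", "elmi-protein", "--outdir", file.path(d, "x")))), 2L)
  # missing required flags
  expect_equal(suppressMessages(cli_main(c("--ppi", paths[["ppi"]]))), 2L)
  # nonexistent input file
  expect_equal(suppressMessages(cli_main(c(
    "--ppi", file.path(d, "nope.csv"), "--dmi", paths[["dmi_protein"]],
    "--strategy", "elmi-protein", "--outdir", file.path(d, "y")))), 2L)
})

test_that("config file supplies defaults and CLI flags override it", {
  fx <- generate_fixture(fixture_spec(planted_fraction = 0.3, seed = 23))
  d <- withr::local_tempdir()
  paths <- write_fixture(fx, d)
  cfgf <- file.path(d, "run.cfg")
  writeLines(c("# run configuration",
               paste0("ppi=", paths[["ppi"]]),
               paste0("dmi=", paths[["dmi_protein"]]),
               "strategy=elmi-protein",
               "shuffles=10",
               "seed=4",
               paste0("outdir=", file.path(d, "cfg_out"))), cfgf)
  expect_equal(suppressMessages(cli_main(c("--config", cfgf))), 0L)
  expect_true(file.exists(file.path(d, "cfg_out", "summary.csv")))
  # CLI overrides the file's outdir
  expect_equal(suppressMessages(cli_main(c("--config", cfgf, "--outdir",
                                           file.path(d, "cli_out")))), 0L)
  expect_true(file.exists(file.path(d, "cli_out", "summary.csv")))
})
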