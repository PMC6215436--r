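# Potential-DMI enumeration and predicted-DMI extraction.

test_that("toy cross-products across strategies: 2 / 4 / 8 / 16", {
  w <- toy_dmi_world()
  n_pot <- function(motifs, dmi, st) {
    nrow(build_potential_dmis(w$ppi, motifs, dmi, w$domains, st))
  }
  expect_equal(n_pot(NULL, w$dmi_pp, dmi_strategy("ELMi-Protein", "known")), 2L)
  expect_equal(n_pot(w$motifs_known, w$dmi_mp, dmi_strategy("ELMc-Protein", "known")), 4L)
  expect_equal(n_pot(w$motifs_known, w$dmi_md, dmi_strategy("ELMc-Domain", "known")), 8L)
  expect_equal(n_pot(w$motifs_predicted, w$dmi_md, dmi_strategy("ELMc-Domain", "predicted")), 16L)
})

test_that("PPI restriction is asymmetric and drops absent proteins", {
  ppi <- quiet_ppi(c("A", "B"), c("X", "Y"))
  motifs <- motif_table(data.frame(mProtein = c("A", "Z", "X"), Motif = "m1"), "known")
  dmi <- dmi_table(data.frame(Motif = "m1", Domain = "d1"), "motif-domain")
  doms <- domain_table(data.frame(dProtein = c("X", "Y", "A"), Domain = "d1"))
  pot <- build_potential_dmis(ppi, motifs, dmi, doms, dmi_strategy("ELMc-Domain", "known"))
  # Z is absent from the PPI data; X and A carry annotation but only in the
  # wrong role, so only A (mProtein side) x {X, Y} (dProtein side) survives
  expect_setequal(paste(pot$mProtein, pot$dProtein), c("A X", "A Y"))
  # empty motif table -> empty potential set
  pot0 <- build_potential_dmis(ppi, motif_table(data.frame(mProtein = character(),
                                                           Motif = character()), "known"),
                               dmi, doms, dmi_strategy("ELMc-Domain", "known"))
  expect_equal(nrow(pot0), 0L)
})

test_that("strategy/schema mismatch raises a configuration error", {
  w <- toy_dmi_world()
  expect_error(
    build_potential_dmis(w$ppi, w$motifs_known, w$dmi_md, w$domains,
                         dmi_strategy("ELMi-Protein", "known")),
    class = "dmi_config_error")
})

test_that("extract_predicted_dmis respects pair orientation and counts tuples", {
  pot <- structure(
    data.frame(mProtein = "A", Motif = "m1", Domain = "d1", dProtein = "X",
               stringsAsFactors = FALSE),
    class = c("potential_dmis", "data.frame"))
  expect_equal(nrow(extract_predicted_dmis(pot, quiet_ppi("A", "X"))), 1L)
  expect_equal(nrow(extract_predicted_dmis(pot, quiet_ppi("X", "A"))), 0L)
  # tuple-level counting: one interacting pair can carry several DMIs
  ppi <- quiet_ppi("A", "X")
  motifs <- motif_table(data.frame(mProtein = "A", Motif = c("m1", "m2")), "known")
  dmi <- dmi_table(data.frame(Motif = c("m1", "m2"), Domain = c("d1", "d2")),
                   "motif-domain")
  doms <- domain_table(data.frame(dProtein = "X", Domain = c("d1", "d2")))
  pred <- extract_predicted_dmis(
    build_potential_dmis(ppi, motifs, dmi, doms, dmi_strategy("ELMc-Domain", "known")),
    ppi)
  expect_equal(nrow(pred), 2L)
  cnt <- attr(pred, "counts")
  expect_equal(cnt[c("n_dmi", "mProteins", "motifs", "domains", "dProteins")],
               list(n_dmi = 2L, mProteins = 1L, motifs = 2L, domains = 2L,
                    dProteins = 1L))
})

test_that("predicted counts match the brute-force loop oracle on random fixtures", {
  for (seed in 1:5) {
    fx <- generate_fixture(fixture_spec(n_mProteins = 8, n_dProteins = 8,
                                        n_motif_classes = 5, n_domain_classes = 4,
                                        ppi_density = 0.25,
                                        planted_fraction = 0.4, seed = seed))
    cases <- list(
      list(st = dmi_strategy("ELMi-Protein", "known"), dmi = fx$dmi_protein,
           motifs = NULL),
      list(st = dmi_strategy("ELMc-Protein", "known"), dmi = fx$dmi_motif_protein,
           motifs = fx$motifs),
      list(st = dmi_strategy("ELMc-Domain", "known"), dmi = fx$dmi_motif_domain,
           motifs = fx$motifs))
    for (cs in cases) {
      pot <- build_potential_dmis(fx$ppi, cs$motifs, cs$dmi, fx$domains, cs$st)
      pred <- extract_predicted_dmis(pot, fx$ppi)
      expect_equal(nrow(pred),
                   oracle_predicted_count(fx$ppi, cs$motifs, cs$dmi,
                                          fx$domains, cs$st$mode),
                   info = paste("seed", seed, cs$st$mode))
      # predicted is always a subset of potential
      expect_true(all(do.call(paste, as.data.frame(pred)) %in%
                        do.call(paste, as.data.frame(pot))))
    }
  }
})

test_that("potential counts grow monotonically with decreasing stringency", {
  for (seed in 6:9) {
    fx <- generate_fixture(fixture_spec(planted_fraction = 0.3, seed = seed))
    n <- vapply(list(
      build_potential_dmis(fx$ppi, NULL, fx$dmi_protein, NULL,
                           dmi_strategy("ELMi-Protein", "known")),
      build_potential_dmis(fx$ppi, fx$motifs, fx$dmi_motif_protein, NULL,
                           dmi_strategy("ELMc-Protein", "known")),
      build_potential_dmis(fx$ppi, fx$motifs, fx$dmi_motif_domain, fx$domains,
                           dmi_strategy("ELMc-Domain", "known"))), nrow, 1L)
    expect_true(n[1] <= n[2] && n[2] <= n[3])
  }
})

test_that("removing a PPI pair never increases the predicted count", {
  fx <- generate_fixture(fixture_spec(planted_fraction = 0.5, seed = 21))
  st <- dmi_strategy("ELMc-Domain", "known")
  pot <- build_potential_dmis(fx$ppi, fx$motifs, fx$dmi_motif_domain, fx$domains, st)
  full <- nrow(extract_predicted_dmis(pot, fx$ppi))
  for (i in c(1L, 5L, nrow(fx$ppi$pairs))) {
    sub <- quiet_ppi(fx$ppi$pairs$mProtein[-i], fx$ppi$pairs$dProtein[-i])
    expect_lte(nrow(extract_predicted_dmis(pot, sub)), full)
  }
})
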