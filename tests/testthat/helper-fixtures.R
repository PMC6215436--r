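# Shared builders and independent oracles for the test suite.

pairs_df <- function(m, d) data.frame(mProtein = m, dProtein = d,
                                      stringsAsFactors = FALSE)

quiet_ppi <- function(m, d, ...) suppressMessages(ppi_dataset(pairs_df(m, d), ...))

# Toy configuration with one motif class bound by one domain: 2 known
# carrier proteins (K1, K2) plus 2 predicted-only carriers (P1, P2); the
# domain occurs in 4 proteins (D1..D4), 2 of which (D1, D2) have annotated
# protein-level interactions with the known carriers. The PPI network is the
# complete 4x4 carrier-by-domain-protein grid so the restriction to PPI
# proteins never removes anything.
toy_dmi_world <- function() {
  carriers <- c("K1", "K2", "P1", "P2")
  dprots <- c("D1", "D2", "D3", "D4")
  grid <- expand.grid(mProtein = carriers, dProtein = dprots,
                      stringsAsFactors = FALSE)
  list(
    ppi = quiet_ppi(grid$mProtein, grid$dProtein, source_label = "toy"),
    motifs_known = motif_table(
      data.frame(mProtein = c("K1", "K2"), Motif = "MotifA"), "known"),
    motifs_predicted = motif_table(
      data.frame(mProtein = carriers, Motif = "MotifA"), "predicted"),
    dmi_pp = dmi_table(
      data.frame(mProtein = c("K1", "K2"), dProtein = c("D1", "D2")),
      "protein-protein"),
    dmi_mp = dmi_table(
      data.frame(Motif = "MotifA", dProtein = c("D1", "D2")), "motif-protein"),
    dmi_md = dmi_table(
      data.frame(Motif = "MotifA", Domain = "DomainB"), "motif-domain"),
    domains = domain_table(
      data.frame(dProtein = dprots, Domain = "DomainB")))
}

# Brute-force predicted-DMI count: explicit nested loops over all table
# rows, independent of the merge-based implementation.
oracle_predicted_count <- function(ppi, motifs, dmi_defs, domains, mode) {
  seen <- character()
  obs <- paste(ppi$pairs$mProtein, ppi$pairs$dProtein)
  m_set <- unique(ppi$pairs$mProtein)
  d_set <- unique(ppi$pairs$dProtein)
  add <- function(key) if (!(key %in% seen)) seen[[length(seen) + 1L]] <<- key
  if (mode == "ELMi-Protein") {
    lk <- dmi_defs$links
    for (i in seq_len(nrow(lk))) {
      if (lk$mProtein[i] %in% m_set && lk$dProtein[i] %in% d_set &&
          paste(lk$mProtein[i], lk$dProtein[i]) %in% obs) {
        add(paste(lk$mProtein[i], lk$dProtein[i]))
      }
    }
  } else if (mode == "ELMc-Protein") {
    occ <- motifs$occurrences; lk <- dmi_defs$links
    for (i in seq_len(nrow(occ))) for (j in seq_len(nrow(lk))) {
      if (occ$Motif[i] == lk$Motif[j] &&
          occ$mProtein[i] %in% m_set && lk$dProtein[j] %in% d_set &&
          paste(occ$mProtein[i], lk$dProtein[j]) %in% obs) {
        add(paste(occ$mProtein[i], occ$Motif[i], lk$dProtein[j]))
      }
    }
  } else {
    occ <- motifs$occurrences; lk <- dmi_defs$links; comp <- domains$composition
    for (i in seq_len(nrow(occ))) for (j in seq_len(nrow(lk))) {
      if (occ$Motif[i] != lk$Motif[j]) next
      for (k in seq_len(nrow(comp))) {
        if (comp$Domain[k] == lk$Domain[j] &&
            occ$mProtein[i] %in% m_set && comp$dProtein[k] %in% d_set &&
            paste(occ$mProtein[i], comp$dProtein[k]) %in% obs) {
          add(paste(occ$mProtein[i], occ$Motif[i], lk$Domain[j], comp$dProtein[k]))
        }
      }
    }
  }
  length(seen)
}

# All permutations of 1..n (n small) as a list of integer vectors.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

# Exact null distribution of predicted-DMI counts: enumerate every
# permutation of the dProtein column, keep the duplicate-free ones, and
# tabulate the count of potential tuples realized by each.
exact_null_counts <- function(ppi, potential) {
  m <- ppi$pairs$mProtein
  d <- ppi$pairs$dProtein
  pot_keys <- paste(potential$mProtein, potential$dProtein)
  res <- integer()
  for (p in all_perms(length(d))) {
    dp <- d[p]
    if (anyDuplicated(paste(m, dp))) next
    res <- c(res, sum(pot_keys %in% paste(m, dp)))
  }
  res
}

# Degree conservation + non-redundancy assertions for a shuffled dataset.
expect_valid_shuffle <- function(orig, shuf) {
  expect_identical(shuf$pairs$mProtein, orig$pairs$mProtein)
  expect_identical(sort(shuf$pairs$dProtein), sort(orig$pairs$dProtein))
  expect_false(any(duplicated(shuf$pairs)))
}
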