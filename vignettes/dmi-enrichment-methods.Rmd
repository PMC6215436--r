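---
title: "Assessing domain-motif interaction enrichment in PPI data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing domain-motif interaction enrichment in PPI data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmienrich)
```

## The problem

Many protein-protein interactions (PPIs) are mediated by a short linear
motif (SLiM) in a disordered region of one protein binding a globular
domain of its partner — a domain-motif interaction (DMI). DMIs are low
affinity and tend to be filtered out of high-throughput interaction screens
(yeast two-hybrid, affinity pulldown), so before using a PPI dataset for
SLiM discovery it is worth asking: does this dataset capture DMIs at all,
beyond what random wiring of the same network would produce?

`dmienrich` answers that question. It maps known or predicted DMIs onto a
PPI dataset, compares the observed number against a degree-preserving
permutation null, and reports an empirical p-value, an enrichment ratio and
a per-DMI false discovery rate.

## Data model

PPI data is treated **asymmetrically**: each pair `(mProtein, dProtein)`
designates a putative motif-carrying protein and a putative domain-carrying
partner. `(A,B)` and `(B,A)` are distinct records; `symmetrize_ppi()`
produces the both-orientations version used when every protein should be
considered in both roles. Three annotation tables complete the inputs: motif
occurrences (`mProtein`-`Motif`), DMI definitions (schema depends on the
strategy) and domain composition (`dProtein`-`Domain`, e.g. Pfam
accessions). IDs are matched by exact, case-sensitive string equality after
whitespace trimming — case-folding is deliberately left upstream, because
silently merging `Abc1` and `ABC1` would be worse than missing a join.

## Mapping strategies

Three strategies of decreasing stringency control how the pool of
**potential DMIs** is built:

* **ELMi-Protein** — only curated protein-level DMI pairs
  (`mProtein`-`dProtein`); motif and domain tables unused.
* **ELMc-Protein** — motif occurrences joined to motif-class-to-partner
  links (`Motif`-`dProtein`); domain table unused.
* **ELMc-Domain** — motif occurrences joined to motif-to-domain links and
  then to domain composition: the most permissive pool.

Each may use `known` (curated) or `predicted` (motif-scan) occurrences,
giving the five usual analysis configurations. A DMI is the fully-populated
tuple for the active strategy, deduplicated — so a single interacting pair
can account for several DMIs through distinct motifs or domains. Tuples are
restricted to proteins present in the PPI data, using the mProtein and
dProtein columns separately. **Predicted DMIs** are the potential tuples
whose protein pair is actually observed, respecting orientation.

## The permutation null

The null model asks how many DMIs the same potential pool would realize if
partners were assigned at random while every protein keeps its number of
interactions. Each of `n_shuffles` (default 1000) randomizations keeps the
mProtein column fixed and permutes the dProtein column, rejecting any
permutation that introduces a duplicate pair. Rejection sampling draws a
uniform permutation and redraws on collision (up to `max_retries`, default
100), which is exactly uniform over duplicate-free permutations; if
rejection keeps failing, a bounded random pair-swap repair guarantees
termination on feasible inputs at the cost of exact uniformity in that
(rare, pathological) regime, and an infeasible-shuffle error is raised if
repair also fails. Original pairs may reappear in a shuffle — only
within-dataset redundancy is forbidden. All shuffles are driven by one
seeded generator, so a run is reproducible given `shuffle_config(seed=)`.

## Statistics

With observed count $O$ and random counts $R_1,\dots,R_n$ (mean $\bar R$):

* empirical p-value $p = \#\{i : R_i \ge O\}/n$. Ties count toward the
  numerator ("at least as many"). No add-one correction is applied: zero
  exceedances yield a numeric 0 displayed as the bound `"<1/n"`, which is
  the convention the published summary format implies.
* enrichment $= O/\bar R$ (3 significant figures in displays);
* per-DMI FDR $= \min(\bar R, O)/O$, the expected share of the predicted
  DMIs explained by chance, capped at 1; defined as 0 when $O=0$;
* normalized counts $D_i = (O - R_i)/\bar R$, so that
  $\mathrm{enrichment} = 1 + \mathrm{mean}(D)$ and $D = 1$ corresponds to a
  50% per-DMI FDR.

Full precision is kept internally; rounding is display-only. When
$\bar R = 0$ the enrichment is reported as infinite with a warning and $D$
is undefined (error) — degenerate cases the statistics cannot normalise.

## Noise simulation

`noise_sweep()` probes robustness to poor-quality motif data: for each
replacement fraction (default 0.25, 0.50, 0.75, 1.00),
`round(fraction * n_carriers)` distinct motif-carrying proteins are drawn
without replacement and renamed — all their occurrence rows at once — to
proteins sampled without replacement from a background pool. Replacement is
at the protein level, not the row level, because the question is what
happens when the *proteins* believed to carry motifs are wrong. Rounding is
half-away-from-zero. The pool defaults to all proteins of the PPI dataset;
replacements may coincidentally be real network proteins — that is the
point, they can realize DMIs only by chance — and any collision with a
surviving carrier is logged rather than forbidden. The shuffle seed is
shared across fractions so the fraction-0 run reproduces the unperturbed
analysis; each fraction's replacement draw has its own derived seed.

## The synthetic-data generator

`generate_fixture()` emulates all four input files with a controllable
planted-DMI fraction. Motif occurrences, motif-domain links (one binding
domain per motif class) and domain compositions are drawn uniformly;
`planted_fraction` of the PPI pairs are sampled from pairs that realize at
least one potential DMI under the most permissive (ELMc-Domain) strategy,
the remainder uniformly from the rest of the pair grid. The three DMI
definition schemas are derived from the same ground truth so the stricter
strategies see nested subsets; the curated protein-level table is a fixed
25% subsample of the realizable pairs, mirroring the reality that curated
instances are a sparse sample of true DMIs. Defaults (20x20 proteins,
density 0.1, two motifs/domains per protein, vocabularies of 12 motif and 8
domain classes) give networks of ~40 pairs, the smallest scale at which the
statistics are non-degenerate and tests stay fast.

What a green test on fixtures does *not* establish: real interactomes have
heavy-tailed degree distributions, promiscuous domains (e.g. kinase
domains) that inflate the random expectation, and motif class frequencies
far from uniform. The generator makes no attempt to match those; fixture
results validate the machinery, not biological effect sizes.

## Numerical and design choices

* p-value convention `count/n` rather than `(count+1)/(n+1)`: the published
  summary format reports a `<1/n` bound at zero exceedances, which the
  add-one convention cannot produce.
* Self-interactions `(A,A)` are legal pairs, counted once and flagged.
* Rows with missing cells are dropped with a logged count, not fatal.
* Delimiters auto-detected (comma/tab) unless fixed in the `field_map`.
* The potential pool is restricted to PPI proteins before tuple
  deduplication; restrict-then-deduplicate and the reverse give identical
  counts.
* The per-DMI FDR of the two most permissive published configurations is
  reproducible only from unrounded mean random counts; the package never
  rounds internally for this reason.
* The config file accepted by the CLI is flat `key=value` text (one pair
  per line, `#` comments); CLI flags take precedence.

## Limitations

No motif regular-expression scanning, no sequence handling, no remote
resource fetching and no isoform mapping: motif occurrence and annotation
tables are assumed to be prepared upstream. The null model is a
column-shuffle null; stub-rewiring/edge-swap nulls are out of scope. The
interactive network view of the original application is replaced by a
static GraphML + edge-list export loadable into any graph viewer.
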