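# Degree-preserving permutation null for DMI enrichment.
#
# Each randomized dataset keeps the mProtein column fixed (every mProtein
# retains its number of partners) and permutes the dProtein column, rejecting
# permutations that introduce duplicate (mProtein, dProtein) pairs. Rejection
# sampling is uniform over duplicate-free permutations; a targeted pair-swap
# repair is used as a fallback so feasible inputs always terminate.

#' Shuffle configuration
#'
#' @param n_shuffles Number of randomized datasets (default 1000).
#' @param seed Optional integer seed; when given, results are reproducible.
#' @param max_retries Rejection-sampling attempts per shuffle before falling
#'   back to pair-swap repair (default 100).
#' @return Object of class `shuffle_config`.
#' @export
shuffle_config <- function(n_shuffles = 1000L, seed = NULL, max_retries = 100L) {
  n_shuffles <- as.integer(n_shuffles)
  if (is.na(n_shuffles) || n_shuffles < 1L) {
    stop_config("shuffle_config: n_shuffles must be a positive integer")
  }
  if (max_retries < 1L) stop_config("shuffle_config: max_retries must be >= 1")
  structure(list(n_shuffles = n_shuffles, seed = seed,
                 max_retries = as.integer(max_retries)),
            class = "shuffle_config")
}

# One duplicate-free permutation of the integer-coded dProtein column.
# m, d: integer codes; K: stride for the pair key m*K + d. Draws a uniform
# permutation and rejects on duplicate pairs; after max_retries failures,
# repairs collisions by random pair swaps (bounded), erroring if the input
# admits no duplicate-free assignment it can reach.
shuffle_dcol <- function(m, d, K, max_retries = 100L) {
  n <- length(d)
  if (n == 1L) return(d)
  for (i in seq_len(max_retries)) {
    dp <- d[sample.int(n)]
    if (!anyDuplicated(m * K + dp)) return(dp)
  }
  # repair fallback: random pair swaps between a colliding row and a random
  # row, accepted when they do not increase the number of duplicate pairs
  dp <- d[sample.int(n)]
  for (i in seq_len(200L * n)) {
    keys <- m * K + dp
    ndup <- sum(duplicated(keys))
    if (ndup == 0L) return(dp)
    dup <- which(duplicated(keys))
    a <- dup[sample.int(length(dup), 1L)]
    b <- sample.int(n, 1L)
    if (a == b) next
    cand <- dp
    cand[c(a, b)] <- dp[c(b, a)]
    if (sum(duplicated(m * K + cand)) <= ndup) dp <- cand
  }
  stop_infeasible("shuffle_ppi: no duplicate-free dProtein assignment found ",
                  "within retry budget; the network is too constrained ",
                  "(an mProtein's partner multiset cannot be rewired without ",
                  "creating redundant pairs)")
}

# integer-code the PPI columns once; reused across shuffles
code_ppi <- function(ppi) {
  m_lv <- unique(ppi$pairs$mProtein)
  d_lv <- unique(ppi$pairs$dProtein)
  list(m = match(ppi$pairs$mProtein, m_lv),
       d = match(ppi$pairs$dProtein, d_lv),
       m_lv = m_lv, d_lv = d_lv, K = length(d_lv) + 1)
}

#' Degree-preserving shuffle of a PPI dataset
#'
#' Returns a randomized dataset with an identical mProtein column, a
#' dProtein column that is a permutation of the original dProtein multiset,
#' and no duplicate pairs. Original pairs may reappear by chance; only
#' within-dataset redundancy is forbidden.
#'
#' @param ppi A canonical [ppi_dataset()].
#' @param max_retries Rejection attempts before repair fallback.
#' @return A [ppi_dataset()].
#' @export
shuffle_ppi <- function(ppi, max_retries = 100L) {
  stopifnot(inherits(ppi, "ppi_dataset"))
  cd <- code_ppi(ppi)
  dp <- shuffle_dcol(cd$m, cd$d, cd$K, max_retries)
  suppressMessages(ppi_dataset(
    data.frame(mProtein = ppi$pairs$mProtein, dProtein = cd$d_lv[dp],
               stringsAsFactors = FALSE),
    source_label = paste0(ppi$source_label, " [shuffled]")))
}

#' Random predicted-DMI count distribution
#'
#' Generates `n_shuffles` degree-preserving randomizations of the PPI data
#' and maps each onto the same potential-DMI pool, returning the count of
#' realized DMI tuples per shuffle — the permutation null for the observed
#' predicted-DMI count.
#'
#' @param ppi A [ppi_dataset()].
#' @param potential A `potential_dmis` data.frame (see
#'   [build_potential_dmis()]).
#' @param cfg A [shuffle_config()].
#' @return Object of class `random_dmi_distribution` with elements
#'   `counts` (length `n_shuffles`), `mean`, `n_shuffles`, `seed`.
#' @export
random_dmi_distribution <- function(ppi, potential, cfg = shuffle_config()) {
  stopifnot(inherits(ppi, "ppi_dataset"), inherits(cfg, "shuffle_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cd <- code_ppi(ppi)
  # potential tuples grouped by pair: weight = number of tuples per pair
  pm <- match(potential$mProtein, cd$m_lv)
  pd <- match(potential$dProtein, cd$d_lv)
  ok <- !is.na(pm) & !is.na(pd)
  counts <- integer(cfg$n_shuffles)
  if (any(ok)) {
    pk <- pm[ok] * cd$K + pd[ok]
    w <- as.integer(table(pk))
    upk <- as.numeric(names(table(pk)))
    for (i in seq_len(cfg$n_shuffles)) {
      dp <- shuffle_dcol(cd$m, cd$d, cd$K, cfg$max_retries)
      counts[i] <- sum(w[upk %in% (cd$m * cd$K + dp)])
    }
  }
  structure(list(counts = counts, mean = mean(counts),
                 n_shuffles = cfg$n_shuffles, seed = cfg$seed),
            class = "random_dmi_distribution")
}

#' @export
print.random_dmi_distribution <- function(x, ...) {
  cat("Random DMI distribution:", x$n_shuffles, "shuffles, mean",
      signif(x$mean, 3), "\n")
  invisible(x)
}
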