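# Deterministic synthetic inputs and a demo pool optimizer.
#
# The library enumerates decorated drug-like scaffolds (alkanes,
# substituted benzenes, piperazines, fused bicyclics) with seeded
# decoration; "invalid" entries are systematic syntactic corruptions
# (unclosed branches/rings) that are guaranteed unparseable. The optimizer
# is resampling-based: it exercises the three-line generative-model loop
# contract (sample, score, update) without any neural model.

.fixture_cores <- c(
  alkane = "CC{R1}CCC{R2}",
  benzene = "c1ccc{R1}cc1{R2}",
  piperazine = "C1CN{R1}CCN1{R2}",
  naphthalene = "c1ccc2ccccc2c1{R1}",
  indole = "c1ccc2c(c1)cc[nH]2",
  quinoline = "c1ccc2ncccc2c1{R1}",
  cyclohexyl = "C1CCCCC1{R1}",
  pyridine = "c1ccnc{R1}c1",
  morpholine = "C1COCCN1{R1}",
  tetralin = "c1ccc2c(c1{R1})CCCC2"
)
.fixture_subs <- c("C", "CC", "CCC", "O", "OC", "N", "NC", "F", "Cl", "Br",
                   "C(=O)O", "C(=O)N", "C#N", "S(=O)(=O)N", "C(F)(F)F",
                   "OCC", "NCC", "C(C)C", "", "")

#' Deterministic synthetic SMILES library
#'
#' Builds `n` SMILES from enumerated scaffold templates with seeded
#' decoration. Exactly `round(n * invalid_fraction)` entries are made
#' syntactically invalid by appending an unclosed branch/ring token, a
#' corruption OpenBabel is guaranteed to reject. Reproducible for a given
#' `(n, seed, invalid_fraction)`.
#'
#' @param n number of entries (>= 1).
#' @param seed RNG seed.
#' @param invalid_fraction fraction of syntactically invalid entries.
#' @return object of class `fixture_library`: list with `smiles`, `valid`
#'   (intended validity flags), `seed`, `invalid_fraction`.
#' @export
make_library <- function(n, seed = 1L, invalid_fraction = 0) {
  stopifnot(n >= 1)
  if (invalid_fraction < 0 || invalid_fraction > 1)
    stop("invalid_fraction must be in [0,1]", call. = FALSE)
  rng <- .seeded_rng(seed)
  smiles <- character(n)
  for (i in seq_len(n)) {
    core <- .fixture_cores[[1 + (rng() %% length(.fixture_cores))]]
    s <- core
    for (slot in c("{R1}", "{R2}")) {
      dec <- .fixture_subs[[1 + (rng() %% length(.fixture_subs))]]
      s <- sub(slot, if (nzchar(dec)) paste0("(", dec, ")") else "",
               s, fixed = TRUE)
    }
    smiles[i] <- s
  }
  n_bad <- round(n * invalid_fraction)
  bad_idx <- integer()
  if (n_bad > 0) {
    # deterministic spread of corrupted entries
    bad_idx <- unique(floor(seq(1, n, length.out = n_bad)))
    while (length(bad_idx) < n_bad)
      bad_idx <- unique(c(bad_idx, (max(bad_idx) %% n) + 1L))
    bad_idx <- sort(bad_idx[seq_len(n_bad)])
    # unmatched ring-opening or dangling bracket: rejected by any parser
    smiles[bad_idx] <- paste0(smiles[bad_idx],
                              c("(C1", "([", "(C1")[1 + (bad_idx %% 3)])
  }
  structure(list(smiles = smiles,
                 valid = !(seq_len(n) %in% bad_idx),
                 seed = seed, invalid_fraction = invalid_fraction),
            class = "fixture_library")
}

#' @export
print.fixture_library <- function(x, ...) {
  cat("<fixture_library> ", length(x$smiles), " entries (",
      sum(!x$valid), " corrupted), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# small deterministic integer stream (LCG, 31-bit), independent of R's RNG
# so that fixture construction never disturbs user RNG state
.seeded_rng <- function(seed) {
  state <- (as.numeric(seed) %% 2147483647) + 1
  function() {
    state <<- (state * 48271) %% 2147483647
    as.integer(state %% 1e9)
  }
}

#' Demo pool optimizer
#'
#' A minimal stand-in for a generative model: it holds a pool of valid
#' molecules, samples batches with probability proportional to
#' `exp(score / temperature)` of each member's last known score, and feeds
#' them through the scoring pipeline for a fixed number of batches. Over a
#' run this hill-climbs towards high-scoring pool members, exercising the
#' iterative loop (including caching and diversity penalties) end to end.
#'
#' @param config an [objective_config()] or JSON path.
#' @param pool_size size of the sampling pool (drawn from [make_library()]).
#' @param batches number of scoring iterations.
#' @param batch_size molecules per iteration.
#' @param seed RNG seed (sampling and pool construction).
#' @param temperature softmax temperature; large values approach uniform
#'   sampling.
#' @param output_dir passed to [scoring_run()].
#' @return list with `run` (the [scoring_run()]), `records`, and
#'   `batch_means` (mean score per batch).
#' @export
demo_optimize <- function(config, pool_size = 200L, batches = 20L,
                          batch_size = 32L, seed = 1L, temperature = 0.1,
                          output_dir = NULL) {
  stopifnot(temperature > 0, batches >= 0, batch_size >= 1)
  lib <- make_library(pool_size * 2L, seed = seed, invalid_fraction = 0)
  parsed <- parse_smiles(lib$smiles)
  pool <- unique(parsed$canonical_smiles[parsed$valid])
  if (length(pool) > pool_size) pool <- pool[seq_len(pool_size)]
  run <- scoring_run(config, output_dir = output_dir)
  last_score <- rep(0, length(pool))
  set.seed(seed)
  batch_means <- numeric(batches)
  for (b in seq_len(batches)) {
    w <- exp(last_score / temperature)
    idx <- sample.int(length(pool), batch_size, replace = TRUE, prob = w)
    sc <- score_batch(run, pool[idx])
    # remember the best observed score per pool member (diversity filters
    # make repeat evaluations non-stationary)
    for (k in seq_along(idx)) {
      last_score[idx[k]] <- max(last_score[idx[k]], sc[k])
    }
    batch_means[b] <- mean(sc)
  }
  list(run = run, records = run_records(run), batch_means = batch_means)
}
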