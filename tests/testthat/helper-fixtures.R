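# Shared helpers for the test suite. Everything is generated in code; no
# binary fixtures.

# a small, diverse set of drug-like SMILES used across tests
fixture_smiles <- function() {
  c(
    ethanol = "CCO",
    benzene = "c1ccccc1",
    toluene = "Cc1ccccc1",
    ethylbenzene = "CCc1ccccc1",
    paracetamol = "CC(=O)Nc1ccc(O)cc1",
    naphthalene = "c1ccc2ccccc2c1",
    pyridine = "c1ccncc1",
    piperazine_ph = "C1CN(c2ccccc2)CCN1",
    cyclohexanone = "O=C1CCCCC1",
    octane = "CCCCCCCC",
    biphenyl = "c1ccccc1-c1ccccc1",
    quinoline = "c1ccc2ncccc2c1"
  )
}

# hand-rolled bit vector for similarity algebra tests
bitvec <- function(on, n_bits = 2048L) genscore:::.new_bitfp(on, n_bits)

# a minimal descriptor-window objective used by several manager tests
toy_window_config <- function(output_dir = NULL, diversity_filter = NULL,
                              filters = character()) {
  objective_config(
    "toy_window",
    scorers = list(
      scorer_spec("d", "descriptors", names = c("MW", "TPSA", "HBD", "logP"))
    ),
    parameters = list(
      list(source = "d_TPSA",
           transform = list(kind = "step_threshold", direction = "minimize",
                            threshold = 70)),
      list(source = "d_HBD",
           transform = list(kind = "step_threshold", direction = "minimize",
                            threshold = 2)),
      list(source = "d_logP",
           transform = list(kind = "step_threshold", direction = "range",
                            low = 2, high = 4)),
      list(source = "d_MW",
           transform = list(kind = "step_threshold", direction = "minimize",
                            threshold = 400))
    ),
    aggregation = "amean",
    diversity_filter = diversity_filter,
    filters = filters,
    output_dir = output_dir
  )
}

# a scorer that counts its invocations through an environment, for cache
# accounting tests
counting_scorer <- function(counter_env) {
  counter_env$calls <- 0L
  scorer_spec("count", "custom", fn = function(smi) {
    counter_env$calls <- counter_env$calls + 1L
    c(score = 0.75)
  })
}

# brute-force longest path over rotatable bonds: independent oracle for
# max_consecutive_rotatable_bonds (enumerates every simple path)
brute_force_longest_path <- function(edges) {
  if (!nrow(edges)) return(0L)
  nodes <- unique(c(edges$i, edges$j))
  best <- 0L
  extend <- function(path, used) {
    best <<- max(best, sum(used))
    last <- path[length(path)]
    for (k in seq_len(nrow(edges))) {
      if (used[k]) next
      nxt <- if (edges$i[k] == last) edges$j[k]
             else if (edges$j[k] == last) edges$i[k] else NA
      if (is.na(nxt) || nxt %in% path) next
      used[k] <- TRUE
      extend(c(path, nxt), used)
      used[k] <- FALSE
    }
  }
  for (v in nodes) extend(v, rep(FALSE, nrow(edges)))
  best
}

# naive O(n^2) sphere exclusion: independent oracle for se_div
naive_se_div <- function(fps, threshold = 0.65) {
  centres <- list()
  for (fp in fps) {
    excluded <- FALSE
    for (ct in centres) {
      if (similarity(fp, ct, "Tanimoto") >= threshold) excluded <- TRUE
    }
    if (!excluded) centres[[length(centres) + 1]] <- fp
  }
  length(centres) / length(fps)
}

# brute-force dominance front ranks: independent oracle for the
# non-dominated sort (peels maximal fronts by direct pairwise comparison)
naive_pareto_ranks <- function(mat) {
  n <- nrow(mat)
  rank <- rep(NA_integer_, n)
  r <- 0L
  remaining <- seq_len(n)
  while (length(remaining)) {
    r <- r + 1L
    front <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        j != i && all(mat[j, ] >= mat[i, ]) && any(mat[j, ] > mat[i, ])
      }, logical(1)))
    }, logical(1))]
    rank[front] <- r
    remaining <- setdiff(remaining, front)
  }
  rank
}
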