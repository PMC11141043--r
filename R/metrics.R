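# Evaluation metrics over generated molecule sets: intrinsic (set-only)
# and extrinsic (against a compiled reference set), plus chunked statistics
# over run records.

.metric_fp_spec <- function() fp_spec("ECFP", 2L, 2048L) # "ECFP4"

#' Compile a reference set for extrinsic metrics
#'
#' Precomputes canonical SMILES, ECFP4 fingerprints and their bit union,
#' scaffold / fragment / functional-group / ring-system count vectors and
#' property samples (logP, SA, QED, MW; the natural-product likeness score
#' has no offline implementation here and is reported as an undefined
#' marker downstream).
#'
#' @param smiles reference SMILES (invalid entries are dropped).
#' @param name label used in reports.
#' @return object of class `reference_set`.
#' @export
reference_set <- function(smiles, name = "reference") {
  parsed <- parse_smiles(smiles)
  can <- unique(parsed$canonical_smiles[parsed$valid])
  if (!length(can)) stop("reference set has no valid molecules", call. = FALSE)
  fps <- lapply(can, fingerprint, spec = .metric_fp_spec())
  props <- t(vapply(can, function(s)
    calc_descriptors(s, c("logP", "SA", "QED", "MW")), numeric(4)))
  structure(list(
    name = name,
    canonical_set = can,
    fps = fps,
    bit_union = sort(unique(unlist(lapply(fps, `[[`, "on")))),
    scaffold_counts = .count_table(vapply(can, murcko_scaffold, character(1))),
    fragment_counts = .count_table(unlist(lapply(can, fragments))),
    fg_counts = .count_table(unlist(lapply(can, functional_groups))),
    ring_counts = .count_table(unlist(lapply(can, ring_systems))),
    property_samples = list(
      LogP = props[, "logP"], SA = props[, "SA"], NP = NULL,
      QED = props[, "QED"], Weight = props[, "MW"])
  ), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set> '", x$name, "': ", length(x$canonical_set),
      " molecules, ", length(x$bit_union), " distinct ECFP4 bits\n", sep = "")
  invisible(x)
}

.count_table <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(table(character()))
  table(x)
}

# cosine similarity between two count vectors over the union vocabulary
.cosine_counts <- function(a, b) {
  keys <- union(names(a), names(b))
  if (!length(keys)) return(NA_real_)
  va <- as.numeric(a[keys]); va[is.na(va)] <- 0
  vb <- as.numeric(b[keys]); vb[is.na(vb)] <- 0
  den <- sqrt(sum(va^2)) * sqrt(sum(vb^2))
  if (den == 0) return(NA_real_)
  sum(va * vb) / den
}

#' Intrinsic evaluation metrics
#'
#' Computes validity, uniqueness, scaffold uniqueness, internal diversity
#' (orders 1 and 2, ECFP4 Tanimoto over ordered pairs, self-pairs
#' excluded), scaffold / functional-group / ring-system diversity, the
#' alert-filter pass fraction (shipped MCF + PAINS-like lists), sphere
#' exclusion diversity at the 0.65 Tanimoto threshold and Solow-Polasky
#' diversity, the latter two on a seeded sample of at most `sample_n`
#' unique molecules. With no valid molecules every downstream metric is the
#' undefined marker `NA`.
#'
#' @param gen character vector of generated SMILES.
#' @param sample_n sample cap for SEDiv / Solow-Polasky.
#' @param seed sampling seed.
#' @param include_self_pairs include i = j pairs in internal diversity
#'   means (some published implementations do); default FALSE.
#' @return named list of metric values.
#' @export
intrinsic_metrics <- function(gen, sample_n = 1000L, seed = 42L,
                              include_self_pairs = FALSE) {
  stopifnot(length(gen) >= 1)
  parsed <- parse_smiles(gen)
  n_total <- nrow(parsed)
  valid_smi <- parsed$canonical_smiles[parsed$valid]
  n_valid <- length(valid_smi)
  out <- list(n_total = n_total, n_valid = n_valid,
              Validity = n_valid / n_total)
  und <- c("Uniqueness", "ScaffoldUniqueness", "IntDiv1", "IntDiv2",
           "ScaffoldDiversity", "FGDiversity", "RingSystemDiversity",
           "Filters", "SEDiv", "SolowPolasky", "n_unique")
  if (n_valid == 0) {
    out[und] <- NA_real_
    return(out)
  }
  uni <- unique(valid_smi)
  n_unique <- length(uni)
  out$n_unique <- n_unique
  out$Uniqueness <- n_unique / n_valid
  scaffs <- vapply(uni, murcko_scaffold, character(1))
  out$ScaffoldUniqueness <- length(unique(scaffs)) / n_unique
  out$ScaffoldDiversity <- length(unique(scaffs)) / n_unique
  fgs <- unlist(lapply(uni, functional_groups))
  out$FGDiversity <- if (length(fgs)) length(unique(fgs)) / length(fgs) else NA_real_
  rsys <- unlist(lapply(uni, ring_systems))
  out$RingSystemDiversity <-
    if (length(rsys)) length(unique(rsys)) / length(rsys) else NA_real_
  alerts <- c(.alert_catalog("mcf"), .alert_catalog("pains"))
  out$Filters <- mean(vapply(uni, function(s)
    .alert_hits(s, alerts) == 0, logical(1)))
  fps <- lapply(uni, fingerprint, spec = .metric_fp_spec())
  idv <- .internal_diversity(fps, include_self_pairs)
  out$IntDiv1 <- idv[1]
  out$IntDiv2 <- idv[2]
  # SEDiv / Solow-Polasky sample the valid stream *with* duplicates: a set
  # of k copies of one molecule must score 1/k, so deduplication would
  # hide exactly the redundancy these metrics measure.
  fps_valid <- fps[match(valid_smi, uni)]
  smp <- .seeded_sample(fps_valid, min(sample_n, n_valid), seed)
  out$SEDiv <- se_div(smp)
  out$SolowPolasky <- solow_polasky(smp)
  out
}

.seeded_sample <- function(x, k, seed) {
  if (k >= length(x)) {
    idx <- seq_along(x)
  } else {
    idx <- withr_seed_sample(length(x), k, seed)
  }
  # seeded shuffle so greedy sphere exclusion has a deterministic order
  x[idx]
}

# sample/shuffle without clobbering the caller's RNG state
withr_seed_sample <- function(n, k, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(n, k)
}

# mean pairwise similarity power means; ordered pairs i != j unless
# include_self requests the self-inclusive convention
.internal_diversity <- function(fps, include_self = FALSE) {
  n <- length(fps)
  if (n == 1 && !include_self) return(c(0, 0))
  sims <- numeric(0)
  if (n > 1) {
    sims <- unlist(lapply(seq_len(n - 1), function(i) {
      vapply(seq(i + 1, n), function(j)
        similarity(fps[[i]], fps[[j]], "Tanimoto"), numeric(1))
    }))
    sims <- c(sims, sims) # ordered pairs: each unordered pair twice
  }
  if (include_self) sims <- c(sims, rep(1, n))
  c(1 - mean(sims), 1 - sqrt(mean(sims^2)))
}

#' Sphere exclusion diversity
#'
#' Greedy sphere exclusion in input order: a molecule becomes a new sphere
#' centre iff its Tanimoto similarity to every previously accepted centre
#' is below `threshold`; the metric is centres / n. For meaningful values
#' the caller supplies a (seeded) shuffled sample, as
#' [intrinsic_metrics()] does.
#'
#' @param fps list of `bitfp` fingerprints.
#' @param threshold Tanimoto exclusion radius (default 0.65).
#' @return value in (0, 1].
#' @export
se_div <- function(fps, threshold = 0.65) {
  stopifnot(length(fps) >= 1)
  centres <- list()
  for (fp in fps) {
    ok <- TRUE
    for (ct in centres) {
      if (similarity(fp, ct, "Tanimoto") >= threshold) { ok <- FALSE; break }
    }
    if (ok) centres[[length(centres) + 1]] <- fp
  }
  length(centres) / length(fps)
}

#' Solow-Polasky diversity
#'
#' `D = 1' F^-1 1` with `F_ij = exp(-theta * d_ij)` and
#' `d = 1 - Tanimoto`, reported normalised as `D / n` in (0, 1] so values
#' are comparable across set sizes. A ridge of 1e-10 regularises
#' near-singular F (e.g. duplicated fingerprints).
#'
#' @param fps list of `bitfp` fingerprints.
#' @param theta distance-decay rate (default 1).
#' @return normalised effective number of species, in (0, 1].
#' @export
solow_polasky <- function(fps, theta = 1) {
  n <- length(fps)
  stopifnot(n >= 1)
  if (n == 1) return(1)
  f <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- 1 - similarity(fps[[i]], fps[[j]], "Tanimoto")
      f[i, j] <- f[j, i] <- exp(-theta * d)
    }
  }
  sol <- solve(f + diag(1e-10, n), rep(1, n))
  min(1, sum(sol) / n)
}

#' Extrinsic evaluation metrics against a reference set
#'
#' Novelty (unique generated molecules absent from the reference), single
#' nearest-neighbour similarity, analogue similarity and coverage at the
#' `analogue_threshold`, cosine similarities of scaffold / fragment /
#' functional-group / ring-system count vectors, outlier-bit "silliness"
#' (mean fraction of a molecule's ECFP4 bits missing from the reference
#' bit union) and 1-D Wasserstein distances for LogP, SA, NP, QED and
#' Weight. NP has no offline implementation and is reported `NA`; the FCD
#' and purchasability entries are likewise emitted as `NA` markers so
#' report schemas stay stable.
#'
#' @param gen character vector of generated SMILES.
#' @param ref a [reference_set()].
#' @param analogue_threshold Tanimoto threshold defining an analogue.
#' @return named list of metric values.
#' @export
extrinsic_metrics <- function(gen, ref, analogue_threshold = 0.4) {
  stopifnot(length(gen) >= 1, inherits(ref, "reference_set"))
  parsed <- parse_smiles(gen)
  uni <- unique(parsed$canonical_smiles[parsed$valid])
  if (!length(uni)) {
    nm <- c("Novelty", "SNN", "AnalogueSimilarity", "AnalogueCoverage",
            "ScaffoldSimilarity", "FragmentSimilarity", "FGSimilarity",
            "RingSystemSimilarity", "Silliness", "FCD", "Purchasability",
            paste0("Wasserstein_", c("LogP", "SA", "NP", "QED", "Weight")))
    out <- stats::setNames(as.list(rep(NA_real_, length(nm))), nm)
    return(out)
  }
  fps <- lapply(uni, fingerprint, spec = .metric_fp_spec())
  max_sims <- vapply(fps, function(fp)
    max(vapply(ref$fps, function(r) similarity(fp, r, "Tanimoto"),
               numeric(1))), numeric(1))
  ref_max <- vapply(ref$fps, function(r)
    max(vapply(fps, function(fp) similarity(fp, r, "Tanimoto"),
               numeric(1))), numeric(1))
  props <- t(vapply(uni, function(s)
    calc_descriptors(s, c("logP", "SA", "QED", "MW")), numeric(4)))
  silliness <- vapply(fps, function(fp) {
    if (!length(fp$on)) return(0)
    mean(!(fp$on %in% ref$bit_union))
  }, numeric(1))
  list(
    Novelty = mean(!(uni %in% ref$canonical_set)),
    SNN = mean(max_sims),
    AnalogueSimilarity = mean(max_sims >= analogue_threshold),
    AnalogueCoverage = mean(ref_max >= analogue_threshold),
    ScaffoldSimilarity = .cosine_counts(
      .count_table(vapply(uni, murcko_scaffold, character(1))),
      ref$scaffold_counts),
    FragmentSimilarity = .cosine_counts(
      .count_table(unlist(lapply(uni, fragments))), ref$fragment_counts),
    FGSimilarity = .cosine_counts(
      .count_table(unlist(lapply(uni, functional_groups))), ref$fg_counts),
    RingSystemSimilarity = .cosine_counts(
      .count_table(unlist(lapply(uni, ring_systems))), ref$ring_counts),
    Silliness = mean(silliness),
    FCD = NA_real_,            # needs a trained network: undefined marker
    Purchasability = NA_real_, # needs an external catalogue: undefined marker
    Wasserstein_LogP = wasserstein_1d(props[, "logP"], ref$property_samples$LogP),
    Wasserstein_SA = wasserstein_1d(props[, "SA"], ref$property_samples$SA),
    Wasserstein_NP = NA_real_, # no offline NP-likeness implementation
    Wasserstein_QED = wasserstein_1d(props[, "QED"], ref$property_samples$QED),
    Wasserstein_Weight = wasserstein_1d(props[, "MW"], ref$property_samples$Weight)
  )
}

#' Exact 1-D Wasserstein distance
#'
#' Earth-mover distance between two empirical distributions, computed
#' exactly as the integral of |Q_x(u) - Q_y(u)| over the merged quantile
#' breakpoints (sample sizes need not match).
#'
#' @param x,y numeric samples.
#' @return nonnegative distance, in the units of the samples.
#' @export
wasserstein_1d <- function(x, y) {
  x <- sort(x); y <- sort(y)
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 1, ny >= 1)
  breaks <- sort(unique(c(seq_len(nx) / nx, seq_len(ny) / ny)))
  lo <- c(0, breaks[-length(breaks)])
  qx <- x[pmin(nx, floor(lo * nx) + 1)]
  qy <- y[pmin(ny, floor(lo * ny) + 1)]
  sum((breaks - lo) * abs(qx - qy))
}

#' Full metrics report
#'
#' Intrinsic metrics plus extrinsic metrics for each supplied reference
#' set, flattened to a one-row data.frame (reference metrics prefixed with
#' the reference name).
#'
#' @param gen generated SMILES.
#' @param references list of [reference_set()] objects (possibly empty).
#' @param sample_n,seed,analogue_threshold passed through.
#' @return one-row data.frame.
#' @export
metrics_report <- function(gen, references = list(), sample_n = 1000L,
                           seed = 42L, analogue_threshold = 0.4) {
  out <- intrinsic_metrics(gen, sample_n = sample_n, seed = seed)
  for (ref in references) {
    ex <- extrinsic_metrics(gen, ref, analogue_threshold)
    names(ex) <- paste0(ref$name, "_", names(ex))
    out <- c(out, ex)
  }
  as.data.frame(out)
}

#' Chunked statistics over a run record
#'
#' Groups a [run_records()] table (or the `scores.csv` it is written to)
#' into consecutive chunks of `n` molecules, or by the distinct values of
#' a named column (e.g. `"step"`), and per chunk computes the intrinsic
#' metrics plus mean / median / standard deviation of every numeric
#' column.
#'
#' @param records data.frame or CSV path with the manager's column
#'   contract (needs at least `input_smiles`).
#' @param n chunk size (ignored when `column` is given).
#' @param column group by this column instead of fixed-size chunks.
#' @param sample_n,seed passed to [intrinsic_metrics()].
#' @return data.frame, one row per chunk.
#' @export
statistics_by_n <- function(records, n = 100L, column = NULL,
                            sample_n = 1000L, seed = 42L) {
  if (is.character(records)) records <- utils::read.csv(records,
                                                        stringsAsFactors = FALSE)
  if (!"input_smiles" %in% names(records))
    stop("records lack an 'input_smiles' column", call. = FALSE)
  if (!is.null(column)) {
    if (!column %in% names(records))
      stop("unknown column '", column, "'; available: ",
           paste(names(records), collapse = ", "), call. = FALSE)
    groups <- split(seq_len(nrow(records)), records[[column]])
  } else {
    stopifnot(n >= 1)
    groups <- split(seq_len(nrow(records)),
                    (seq_len(nrow(records)) - 1) %/% n)
  }
  num_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  rows <- lapply(names(groups), function(gname) {
    idx <- groups[[gname]]
    chunk <- records[idx, , drop = FALSE]
    im <- intrinsic_metrics(chunk$input_smiles, sample_n = sample_n,
                            seed = seed)
    stats <- unlist(lapply(num_cols, function(cl) {
      v <- chunk[[cl]]
      stats::setNames(c(mean(v), stats::median(v), stats::sd(v)),
                      paste0(cl, c("_mean", "_median", "_sd")))
    }))
    cbind(data.frame(chunk = gname, n_molecules = length(idx),
                     stringsAsFactors = FALSE),
          as.data.frame(im), t(as.data.frame(stats)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
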