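# Diversity filters: stateful memories that penalise over-exploited
# chemotypes across a run. Bucket-overflow kinds zero the score once a
# cluster is full; the Occurrence kind decays gradually with repeat count.

#' Diversity filter specification
#'
#' @param kind one of `"Unique"`, `"Occurrence"`,
#'   `"IdenticalMurckoScaffold"`, `"IdenticalTopologicalScaffold"`,
#'   `"CompoundSimilarity"`, `"ScaffoldSimilarityAtomPair"`,
#'   `"ScaffoldSimilarityECFP"`.
#' @param nbmax cluster capacity; once a cluster holds `nbmax` members,
#'   further members score 0. May be `Inf` (neutral filter).
#' @param minscore only molecules scoring at least this much enter memory;
#'   sub-threshold molecules are never penalised.
#' @param minsimilarity Tanimoto threshold for joining an existing cluster
#'   (similarity kinds only).
#' @param occurrence_tolerance,occurrence_buffer Occurrence kind: repeats
#'   beyond `tolerance` decay the score linearly, reaching 0 after
#'   `buffer` further repeats.
#' @return object of class `div_filter_spec`.
#' @export
div_filter_spec <- function(kind, nbmax = 25, minscore = 0.5,
                            minsimilarity = 0.6, occurrence_tolerance = 5L,
                            occurrence_buffer = 5L) {
  kinds <- c("Unique", "Occurrence", "IdenticalMurckoScaffold",
             "IdenticalTopologicalScaffold", "CompoundSimilarity",
             "ScaffoldSimilarityAtomPair", "ScaffoldSimilarityECFP")
  if (!kind %in% kinds)
    stop("unknown diversity filter kind '", kind, "'; use one of: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  stopifnot(nbmax >= 1, minscore >= 0, minscore <= 1,
            minsimilarity >= 0, minsimilarity <= 1,
            occurrence_tolerance >= 0, occurrence_buffer >= 1)
  structure(list(kind = kind, nbmax = nbmax, minscore = minscore,
                 minsimilarity = minsimilarity,
                 occurrence_tolerance = as.integer(occurrence_tolerance),
                 occurrence_buffer = as.integer(occurrence_buffer)),
            class = "div_filter_spec")
}

#' Diversity memory
#'
#' Mutable clustering state shared across the batches of a run: cluster
#' key -> members and occupancy, plus per-SMILES seen counts for the
#' Unique/Occurrence kinds.
#' @return environment of class `div_memory`.
#' @export
new_div_memory <- function() {
  e <- new.env(parent = emptyenv())
  e$clusters <- list()     # key -> list(fp, members, occupancy)
  e$order <- character()   # creation order, for deterministic ties
  e$seen <- new.env(parent = emptyenv()) # canonical smiles -> count
  class(e) <- "div_memory"
  e
}

#' @export
print.div_memory <- function(x, ...) {
  cat("<div_memory> ", length(x$clusters), " clusters, ",
      length(ls(x$seen)), " molecules seen\n", sep = "")
  invisible(x)
}

# fingerprint used by each similarity kind
.div_fp <- function(smi, kind) {
  switch(kind,
    CompoundSimilarity = fingerprint(smi, fp_spec("ECFP", 2L, 2048L)),
    ScaffoldSimilarityAtomPair = fingerprint(smi, fp_spec("AtomPair", n_bits = 2048L)),
    ScaffoldSimilarityECFP = fingerprint(smi, fp_spec("ECFP", 2L, 2048L))
  )
}

#' Assign a molecule to a diversity cluster
#'
#' Key rules: Unique/Occurrence cluster by canonical SMILES;
#' IdenticalMurckoScaffold / IdenticalTopologicalScaffold by scaffold
#' (acyclic molecules share the `""` cluster); the similarity kinds join
#' the nearest existing centroid with Tanimoto at or above
#' `minsimilarity` (earliest-created cluster on ties) or open a new one.
#' Assignment never mutates `memory`.
#'
#' @param canonical_smiles canonical SMILES of a valid molecule.
#' @param spec a [div_filter_spec()].
#' @param memory a [new_div_memory()].
#' @return the cluster key (character).
#' @export
assign_cluster <- function(canonical_smiles, spec, memory) {
  stopifnot(inherits(spec, "div_filter_spec"), inherits(memory, "div_memory"))
  kind <- spec$kind
  if (kind %in% c("Unique", "Occurrence")) return(canonical_smiles)
  if (kind == "IdenticalMurckoScaffold") return(murcko_scaffold(canonical_smiles))
  if (kind == "IdenticalTopologicalScaffold") return(topological_scaffold(canonical_smiles))
  # similarity kinds
  probe_smi <- if (kind == "CompoundSimilarity") canonical_smiles
               else murcko_scaffold(canonical_smiles)
  if (!nzchar(probe_smi)) return("") # acyclic under scaffold-similarity kinds
  fp <- .div_fp(probe_smi, kind)
  best_key <- NULL
  best_sim <- -1
  for (key in memory$order) {
    cl <- memory$clusters[[key]]
    if (is.null(cl$fp)) next
    s <- similarity(fp, cl$fp, "Tanimoto")
    if (s > best_sim + 1e-12) { # strict improvement: earliest wins ties
      best_sim <- s
      best_key <- key
    }
  }
  if (!is.null(best_key) && best_sim >= spec$minsimilarity) best_key else probe_smi
}

# occurrence decay: full score within tolerance, then linear to 0
.occurrence_scale <- function(seen, tol, buffer) {
  max(0, 1 - max(0, seen - tol) / buffer)
}

#' Apply a diversity filter to a batch of scored molecules
#'
#' Processes records in order, penalising and updating memory as it goes:
#' \itemize{
#' \item `Unique`: a repeat of any canonical SMILES already in memory
#'   scores 0.
#' \item `Occurrence`: the score is scaled by
#'   `max(0, 1 - max(0, seen - tolerance) / buffer)` where `seen` counts
#'   prior memory entries of the same SMILES.
#' \item all other kinds: a molecule whose cluster already holds `nbmax`
#'   members scores 0.
#' }
#' Only molecules with incoming score at least `minscore` enter memory;
#' sub-threshold molecules pass through unpenalised and leave the memory
#' untouched.
#'
#' @param canonical_smiles character vector (NA for invalid molecules,
#'   which pass through untouched).
#' @param scores numeric desirabilities in [0,1], same length.
#' @param spec a [div_filter_spec()].
#' @param memory a [new_div_memory()]; mutated in place.
#' @return list with `scores` (penalised) and `scale` (applied factor,
#'   0/1 for the hard kinds).
#' @export
apply_diversity_filter <- function(canonical_smiles, scores, spec, memory) {
  stopifnot(length(canonical_smiles) == length(scores))
  out <- numeric(length(scores))
  scale <- rep(1, length(scores))
  for (r in seq_along(scores)) {
    smi <- canonical_smiles[r]
    s <- scores[r]
    if (is.na(smi)) { out[r] <- s; next }
    if (s < spec$minscore) { out[r] <- s; next } # gate: no penalty, no memory
    if (spec$kind == "Unique") {
      seen <- .seen_count(memory, smi)
      if (seen > 0) scale[r] <- 0
      .seen_bump(memory, smi)
    } else if (spec$kind == "Occurrence") {
      seen <- .seen_count(memory, smi)
      scale[r] <- .occurrence_scale(seen, spec$occurrence_tolerance,
                                    spec$occurrence_buffer)
      .seen_bump(memory, smi)
    } else {
      key <- assign_cluster(smi, spec, memory)
      occ <- if (is.null(memory$clusters[[key]])) 0L
             else memory$clusters[[key]]$occupancy
      if (occ >= spec$nbmax) scale[r] <- 0
      if (occ < spec$nbmax) {
        if (is.null(memory$clusters[[key]])) {
          probe_smi <- if (spec$kind %in% c("CompoundSimilarity")) smi
                       else if (spec$kind %in% c("ScaffoldSimilarityAtomPair",
                                                 "ScaffoldSimilarityECFP"))
                         murcko_scaffold(smi)
                       else NULL
          fp <- if (!is.null(probe_smi) && nzchar(probe_smi))
            .div_fp(probe_smi, spec$kind) else NULL
          memory$clusters[[key]] <- list(fp = fp, members = character(),
                                         occupancy = 0L)
          memory$order <- c(memory$order, key)
        }
        cl <- memory$clusters[[key]]
        cl$members <- c(cl$members, smi)
        cl$occupancy <- cl$occupancy + 1L
        memory$clusters[[key]] <- cl
      }
    }
    out[r] <- s * scale[r]
  }
  list(scores = .clamp01(out), scale = scale)
}

.seen_count <- function(memory, smi) {
  if (exists(smi, envir = memory$seen, inherits = FALSE))
    get(smi, envir = memory$seen, inherits = FALSE) else 0L
}
.seen_bump <- function(memory, smi) {
  assign(smi, .seen_count(memory, smi) + 1L, envir = memory$seen)
}

#' Dump a diversity memory to CSV
#'
#' One row per cluster: key, occupancy and the member SMILES
#' (semicolon-separated), in creation order.
#'
#' @param memory a [new_div_memory()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_div_memory <- function(memory, path) {
  rows <- data.frame(
    cluster_key = memory$order,
    occupancy = vapply(memory$order, function(k)
      memory$clusters[[k]]$occupancy, integer(1)),
    members = vapply(memory$order, function(k)
      paste(memory$clusters[[k]]$members, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
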