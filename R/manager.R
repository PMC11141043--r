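# The scoring orchestrator: configuration loading and validation, the
# per-batch pipeline (parse -> dedupe/cache -> score -> transform ->
# aggregate -> diversity/filters), run records and CSV output.

#' Objective configuration
#'
#' Declarative description of a scoring objective: which scorers to run,
#' how each produced column is transformed into a desirability, how the
#' desirabilities are aggregated, an optional diversity filter, and which
#' parameters act as multiplicative filters.
#'
#' @param task_name short task identifier (used in output paths).
#' @param scorers list of [scorer_spec()].
#' @param parameters list of parameter definitions, each a list with
#'   `source` (a raw column name, see [scorer_columns()]), `transform`
#'   (a [transform_spec()] or list of its arguments) and optional `weight`
#'   (default 1).
#' @param aggregation an [aggregation_spec()] or kind string.
#' @param diversity_filter optional [div_filter_spec()].
#' @param filters character vector of parameter names whose transformed
#'   scores multiply the aggregate ("any scoring function can be used as a
#'   filter").
#' @param output_dir where per-iteration and final CSVs go; `NULL`
#'   disables file output.
#' @return object of class `objective_config`.
#' @export
objective_config <- function(task_name, scorers, parameters,
                             aggregation = "amean", diversity_filter = NULL,
                             filters = character(), output_dir = NULL) {
  if (is.character(aggregation))
    aggregation <- aggregation_spec(aggregation)
  cfg <- structure(list(
    task_name = task_name, scorers = scorers, parameters = parameters,
    aggregation = aggregation, diversity_filter = diversity_filter,
    filters = filters, output_dir = output_dir
  ), class = "objective_config")
  errs <- .config_errors(cfg)
  if (length(errs))
    stop("invalid objective configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  # normalise parameter transforms to transform_spec objects
  cfg$parameters <- lapply(cfg$parameters, function(pr) {
    if (!inherits(pr$transform, "transform_spec"))
      pr$transform <- do.call(transform_spec, pr$transform)
    pr$weight <- pr$weight %||% 1
    pr$name <- pr$name %||% pr$source
    pr
  })
  cfg
}

# every problem reported at once, with JSON-ish paths
.config_errors <- function(cfg) {
  errs <- character()
  if (!is.character(cfg$task_name) || !nzchar(cfg$task_name))
    errs <- c(errs, "task_name: must be a nonempty string")
  if (!length(cfg$scorers))
    errs <- c(errs, "scorers: at least one scorer is required")
  nm <- vapply(cfg$scorers, function(s) s$name, character(1))
  if (anyDuplicated(nm))
    errs <- c(errs, paste0("scorers: duplicated name(s) ",
                           paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  produced <- unlist(lapply(cfg$scorers, scorer_columns))
  if (!length(cfg$parameters))
    errs <- c(errs, "parameters: at least one parameter is required")
  for (i in seq_along(cfg$parameters)) {
    pr <- cfg$parameters[[i]]
    where <- paste0("parameters[", i, "]")
    if (is.null(pr$source)) {
      errs <- c(errs, paste0(where, ".source: missing"))
      next
    }
    if (!pr$source %in% produced)
      errs <- c(errs, paste0(where, ".source: '", pr$source,
                             "' is not produced by any scorer (available: ",
                             paste(produced, collapse = ", "), ")"))
    if (is.null(pr$transform)) {
      errs <- c(errs, paste0(where, ".transform: missing"))
    } else if (!inherits(pr$transform, "transform_spec")) {
      tr <- tryCatch(do.call(transform_spec, pr$transform),
                     error = function(e) conditionMessage(e))
      if (is.character(tr))
        errs <- c(errs, paste0(where, ".transform: ", tr))
    }
    if (!is.null(pr$weight) && (!is.numeric(pr$weight) || pr$weight < 0))
      errs <- c(errs, paste0(where, ".weight: must be a nonnegative number"))
  }
  pnames <- vapply(cfg$parameters, function(pr)
    (pr$name %||% pr$source) %||% "", character(1))
  if (inherits(cfg$aggregation, "aggregation_spec") &&
      cfg$aggregation$kind %in% c("wsum", "wprod")) {
    missing_w <- setdiff(setdiff(pnames, cfg$filters),
                         names(cfg$aggregation$weights))
    if (length(missing_w))
      errs <- c(errs, paste0("aggregation.weights: missing for parameter(s) ",
                             paste(missing_w, collapse = ", ")))
  }
  bad_f <- setdiff(cfg$filters, pnames)
  if (length(bad_f))
    errs <- c(errs, paste0("filters: unknown parameter(s) ",
                           paste(bad_f, collapse = ", ")))
  if (!is.null(cfg$diversity_filter) &&
      !inherits(cfg$diversity_filter, "div_filter_spec"))
    errs <- c(errs, "diversity_filter: not a div_filter_spec")
  errs
}

#' Load an objective configuration from JSON
#'
#' The JSON mirrors [objective_config()]: `task_name`, `scorers` (each with
#' `name`, `kind` and kind-specific params), `parameters` (each with
#' `source`, `transform`, `weight`), `aggregation` (`kind` + optional
#' `weights`), optional `diversity_filter` and `filters`. All SMARTS are
#' compiled and referenced files resolved at load time; every problem is
#' reported at once.
#'
#' @param path JSON file path.
#' @param output_dir overrides the config's `output_dir` when given.
#' @return an `objective_config`.
#' @export
load_config <- function(path, output_dir = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  known <- c("task_name", "output_dir", "scorers", "parameters",
             "aggregation", "diversity_filter", "filters")
  unknown <- setdiff(names(obj), known)
  if (length(unknown))
    stop("invalid objective configuration:\n  - unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  scorers <- lapply(obj$scorers, function(s) {
    args <- c(list(name = s$name, kind = s$kind),
              s[setdiff(names(s), c("name", "kind"))])
    # JSON lists -> vectors where scorers expect them
    for (f in c("names", "smarts", "ref_smiles", "training_smiles",
                "descriptors")) {
      if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
    }
    if (!is.null(args$coefficients)) args$coefficients <- unlist(args$coefficients)
    do.call(scorer_spec, args)
  })
  parameters <- lapply(obj$parameters, function(pr) {
    pr$transform <- lapply(pr$transform, function(x) x)
    pr
  })
  agg <- if (is.null(obj$aggregation)) "amean"
         else aggregation_spec(obj$aggregation$kind %||% "amean",
                               unlist(obj$aggregation$weights))
  dfilter <- if (!is.null(obj$diversity_filter))
    do.call(div_filter_spec, obj$diversity_filter) else NULL
  objective_config(
    task_name = obj$task_name,
    scorers = scorers,
    parameters = parameters,
    aggregation = agg,
    diversity_filter = dfilter,
    filters = unlist(obj$filters) %||% character(),
    output_dir = output_dir %||% obj$output_dir
  )
}

#' Write an objective configuration to JSON
#' @param cfg an [objective_config()] (must not contain `custom` scorers).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  if (any(vapply(cfg$scorers, function(s) s$kind == "custom", logical(1))))
    stop("custom scorers are not JSON-serialisable", call. = FALSE)
  obj <- list(
    task_name = cfg$task_name,
    output_dir = cfg$output_dir,
    scorers = lapply(cfg$scorers, function(s) c(list(name = s$name, kind = s$kind),
                                                s$params)),
    parameters = lapply(cfg$parameters, function(pr) list(
      source = pr$source, name = pr$name, weight = pr$weight,
      transform = Filter(Negate(is.null), unclass(pr$transform)))),
    aggregation = list(kind = cfg$aggregation$kind,
                       weights = as.list(cfg$aggregation$weights)),
    diversity_filter = if (!is.null(cfg$diversity_filter))
      unclass(cfg$diversity_filter),
    filters = cfg$filters
  )
  jsonlite::write_json(Filter(Negate(is.null), obj), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# ---- the run object -------------------------------------------------------

#' Create a scoring run
#'
#' The stateful orchestrator: holds the score cache, the running
#' normalisation ranges, the diversity memory and the run record. Score
#' batches with [score_batch()] and finish with [finalize_run()].
#'
#' @param config an [objective_config()] or a JSON config path.
#' @param output_dir overrides the config's output directory; `NULL` keeps
#'   it; `NA` disables file output.
#' @param parallel_map an optional `lapply`-compatible function used to map
#'   scorers over molecules (e.g. a wrapper over
#'   `parallel::mclapply`); must be order-preserving. Default `lapply`.
#' @return environment of class `scoring_run`.
#' @export
scoring_run <- function(config, output_dir = NULL, parallel_map = lapply) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "objective_config"))
  if (!is.null(output_dir) && !is.na(output_dir)) config$output_dir <- output_dir
  if (length(output_dir) == 1 && is.na(output_dir)) config$output_dir <- NULL
  run <- new.env(parent = emptyenv())
  run$config <- config
  run$cache <- new.env(parent = emptyenv()) # canonical smiles -> cached record row
  run$range_states <- lapply(config$parameters, function(pr) new_running_range())
  names(run$range_states) <- vapply(config$parameters, `[[`, character(1), "name")
  run$memory <- if (!is.null(config$diversity_filter)) new_div_memory() else NULL
  run$records <- list()
  run$step <- 0L
  run$n_scored <- 0L
  run$scorer_calls <- 0L
  run$parallel_map <- parallel_map
  if (!is.null(config$output_dir)) {
    dir.create(file.path(config$output_dir, "iterations"),
               recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(config$output_dir))
      stop("cannot create output directory: ", config$output_dir, call. = FALSE)
  }
  class(run) <- "scoring_run"
  run
}

#' @export
print.scoring_run <- function(x, ...) {
  cat("<scoring_run> task '", x$config$task_name, "': ", x$step,
      " step(s), ", x$n_scored, " molecules scored, ",
      length(ls(x$cache)), " unique in cache\n", sep = "")
  invisible(x)
}

#' @export
summary.scoring_run <- function(object, ...) {
  rec <- run_records(object)
  cat("Scoring run '", object$config$task_name, "'\n", sep = "")
  cat("  steps:            ", object$step, "\n")
  cat("  molecules scored: ", nrow(rec), "\n")
  if (nrow(rec)) {
    cat("  valid fraction:   ", round(mean(rec$valid), 4), "\n")
    cat("  mean score:       ", round(mean(rec$score), 4), "\n")
    cat("  best score:       ", round(max(rec$score), 4), "\n")
    cat("  best molecule:    ", rec$canonical_smiles[which.max(rec$score)], "\n")
  }
  invisible(rec)
}

# raw columns produced by the config's scorers, in declaration order
.raw_columns <- function(config) {
  unlist(lapply(config$scorers, scorer_columns))
}

#' Score a batch of SMILES
#'
#' The per-iteration pipeline: parse and canonicalize; check intra-batch
#' uniqueness (duplicates are scored once and share the value);
#' cross-reference inter-batch uniqueness against the run cache and reuse
#' previous scores without re-invoking scorers; run scorers only for valid,
#' unseen molecules; transform, aggregate, apply multiplicative filters and
#' the diversity filter; append to the run record and write the
#' per-iteration CSV. Invalid molecules score 0. A scorer error on a
#' molecule fails that molecule (score 0, warning), never the batch.
#'
#' @param run a [scoring_run()].
#' @param smiles character vector.
#' @param step optional explicit step number; defaults to counting up
#'   from 1.
#' @return numeric scores, same length and order as `smiles`.
#' @export
score_batch <- function(run, smiles, step = NULL) {
  stopifnot(inherits(run, "scoring_run"))
  config <- run$config
  step <- if (is.null(step)) run$step + 1L else as.integer(step)
  run$step <- step
  n <- length(smiles)
  if (n == 0) return(numeric(0))

  parsed <- parse_smiles(smiles)
  can <- parsed$canonical_smiles
  valid <- parsed$valid
  unique_in_batch <- unname(!duplicated(can, incomparables = NA) & valid)
  seen_before <- unname(valid & vapply(can, function(s)
    !is.na(s) && exists(s, envir = run$cache, inherits = FALSE), logical(1)))

  raw_cols <- .raw_columns(config)
  pnames <- vapply(config$parameters, `[[`, character(1), "name")
  tr_cols <- paste0(pnames, "_transformed")

  # molecules that actually need scoring: valid, first occurrence in batch,
  # not in cache
  todo <- which(valid & unique_in_batch & !seen_before)
  todo_smi <- can[todo]
  raw_new <- run$parallel_map(todo_smi, function(s) {
    out <- rep(NA_real_, length(raw_cols))
    names(out) <- raw_cols
    for (sc in config$scorers) {
      vals <- tryCatch(run_scorer(sc, s), error = function(e) {
        warning("scorer '", sc$name, "' failed on ", s, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(vals)) {
        out[scorer_columns(sc)] <- NA_real_
      } else {
        out[names(vals)] <- vals
      }
    }
    out
  })
  run$scorer_calls <- run$scorer_calls + length(todo)

  # assemble per-input rows
  raw_mat <- matrix(NA_real_, nrow = n, ncol = length(raw_cols),
                    dimnames = list(NULL, raw_cols))
  tr_mat <- matrix(0, nrow = n, ncol = length(tr_cols),
                   dimnames = list(NULL, tr_cols))
  dscore <- numeric(n)
  filter_product <- rep(1, n)
  failed <- logical(n)

  # transform + aggregate the newly scored molecules (in input order so the
  # running ranges see a deterministic stream)
  new_rows <- list()
  for (idx in seq_along(todo)) {
    i <- todo[idx]
    rv <- raw_new[[idx]]
    fail <- FALSE
    tr <- numeric(length(config$parameters))
    for (k in seq_along(config$parameters)) {
      pr <- config$parameters[[k]]
      x <- rv[[pr$source]]
      tr[k] <- if (is.na(x)) { fail <- TRUE; 0 }
               else transform_score(x, pr$transform, run$range_states[[pr$name]])
    }
    names(tr) <- pnames
    agg_names <- setdiff(pnames, config$filters)
    ds <- if (fail) 0 else if (length(agg_names))
      aggregate_scores(tr[agg_names], config$aggregation,
                       batch_context = NULL) else 1
    fp_val <- if (length(config$filters)) prod(tr[config$filters]) else 1
    raw_mat[i, ] <- rv
    tr_mat[i, ] <- tr
    dscore[i] <- ds
    filter_product[i] <- fp_val
    failed[i] <- fail
    new_rows[[as.character(can[i])]] <- list(raw = rv, tr = tr, dscore = ds,
                                             filter_product = fp_val,
                                             failed = fail)
  }
  # pareto aggregation is batch-wise: recompute dscores over the batch
  if (config$aggregation$kind == "pareto" && length(todo)) {
    agg_names <- setdiff(pnames, config$filters)
    ctx <- lapply(todo, function(i) tr_mat[i, paste0(agg_names, "_transformed")])
    ctx <- lapply(ctx, function(v) { names(v) <- agg_names; v })
    ranks <- pareto_front_ranks(do.call(rbind, ctx))
    for (idx in seq_along(todo)) {
      i <- todo[idx]
      if (!failed[i]) dscore[i] <- 1 - (ranks[idx] - 1) / max(ranks)
      new_rows[[as.character(can[i])]]$dscore <- dscore[i]
    }
  }
  # fill cache
  for (key in names(new_rows)) assign(key, new_rows[[key]], envir = run$cache)

  # resolve intra-batch duplicates and cache hits
  for (i in seq_len(n)) {
    if (!valid[i]) next
    if (i %in% todo) next
    hit <- get(can[i], envir = run$cache, inherits = FALSE)
    raw_mat[i, ] <- hit$raw
    tr_mat[i, ] <- hit$tr
    dscore[i] <- hit$dscore
    filter_product[i] <- hit$filter_product
    failed[i] <- hit$failed
  }

  pre_div <- ifelse(valid & !failed, dscore * filter_product, 0)
  div_scale <- rep(1, n)
  if (!is.null(config$diversity_filter)) {
    dd <- apply_diversity_filter(ifelse(valid, can, NA_character_),
                                 .clamp01(pre_div),
                                 config$diversity_filter, run$memory)
    score <- dd$scores
    div_scale <- dd$scale
  } else {
    score <- .clamp01(pre_div)
  }
  score[!valid] <- 0

  rec <- data.frame(
    step = rep(step, n),
    batch_idx = seq_len(n) - 1L,
    input_smiles = parsed$input_smiles,
    canonical_smiles = can,
    valid = valid,
    unique_in_batch = unique_in_batch,
    seen_before = seen_before,
    stringsAsFactors = FALSE
  )
  rec <- cbind(rec, as.data.frame(raw_mat), as.data.frame(tr_mat))
  rec$dscore <- ifelse(valid & !failed, dscore, 0)
  rec$filter_product <- ifelse(valid, filter_product, 1)
  rec$passes_diversity <- div_scale > 0
  rec$score <- score
  run$records[[length(run$records) + 1]] <- rec
  run$n_scored <- run$n_scored + n
  if (!is.null(config$output_dir)) {
    utils::write.csv(rec, file.path(config$output_dir, "iterations",
                                    sprintf("step_%06d.csv", step)),
                     row.names = FALSE)
  }
  score
}

#' Full run record
#' @param run a [scoring_run()].
#' @return data.frame with one row per scored input across all batches.
#' @export
run_records <- function(run) {
  stopifnot(inherits(run, "scoring_run"))
  if (!length(run$records)) {
    cols <- c("step", "batch_idx", "input_smiles", "canonical_smiles",
              "valid", "unique_in_batch", "seen_before",
              .raw_columns(run$config),
              paste0(vapply(run$config$parameters, `[[`, character(1), "name"),
                     "_transformed"),
              "dscore", "filter_product", "passes_diversity", "score")
    df <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(df) <- cols
    return(df)
  }
  do.call(rbind, run$records)
}

#' Finish a run and write the final CSV
#'
#' Writes `scores.csv` (all records, in scoring order) to the run's output
#' directory, plus the diversity-memory dump when a diversity filter was
#' active.
#'
#' @param run a [scoring_run()].
#' @return the path of the written CSV (or the records invisibly when file
#'   output is disabled).
#' @export
finalize_run <- function(run) {
  stopifnot(inherits(run, "scoring_run"))
  rec <- run_records(run)
  if (is.null(run$config$output_dir)) return(invisible(rec))
  path <- file.path(run$config$output_dir, "scores.csv")
  utils::write.csv(rec, path, row.names = FALSE)
  if (!is.null(run$memory))
    write_div_memory(run$memory, file.path(run$config$output_dir,
                                           "diversity_memory.csv"))
  path
}
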