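# Benchmark mode: iterate a generator over several objectives under an
# evaluation budget and compute metrics on exit.

#' Built-in benchmark presets
#'
#' Each preset is a list of [objective_config()] objects built from the
#' package's fixture generators, so benchmarks run with no external data.
#' `"demo"` pairs a drug-likeness window objective (TPSA, HBD, logP, MW)
#' with a fingerprint-similarity rediscovery objective.
#'
#' @param name preset name.
#' @return list of `objective_config` objects.
#' @export
benchmark_preset <- function(name = "demo") {
  presets <- list(
    demo = function() {
      lib <- make_library(50, seed = 97L, invalid_fraction = 0)
      target <- parse_smiles(lib$smiles[1])$canonical_smiles
      list(
        objective_config(
          "physchem_window",
          scorers = list(scorer_spec("d", "descriptors",
                                     names = c("TPSA", "HBD", "logP", "MW"))),
          parameters = list(
            list(source = "d_TPSA", transform = list(kind = "step_threshold",
                                                     direction = "minimize",
                                                     threshold = 70)),
            list(source = "d_HBD", transform = list(kind = "step_threshold",
                                                    direction = "minimize",
                                                    threshold = 2)),
            list(source = "d_logP", transform = list(kind = "step_threshold",
                                                     direction = "range",
                                                     low = 2, high = 4)),
            list(source = "d_MW", transform = list(kind = "step_threshold",
                                                   direction = "minimize",
                                                   threshold = 400))
          ),
          aggregation = "amean"
        ),
        objective_config(
          "similarity_rediscovery",
          scorers = list(scorer_spec("sim", "fingerprint_similarity",
                                     ref_smiles = target)),
          parameters = list(
            list(source = "sim_similarity",
                 transform = list(kind = "identity"))
          ),
          aggregation = "amean"
        )
      )
    }
  )
  if (!name %in% names(presets))
    stop("unknown benchmark preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  presets[[name]]()
}

#' Run a benchmark
#'
#' Iterates over the objectives, scoring generator batches against each
#' until the evaluation budget is reached (`finished` flips once the
#' number of evaluated molecules is at least `budget`; the batch that
#' crosses the budget is completed, not truncated). On exit the metrics
#' suite runs over each objective's records and a summary CSV is written.
#'
#' @param objectives a preset name, or a list of [objective_config()] /
#'   JSON config paths.
#' @param budget molecules to evaluate per objective (>= 1).
#' @param generator a function `(batch_size, last_scores, last_smiles)`
#'   returning a character vector of SMILES; `NULL` uses the demo pool
#'   sampler ([make_pool_generator()]).
#' @param batch_size molecules per generator call.
#' @param seed seed for the default generator.
#' @param output_dir root output directory; each objective writes to
#'   `<output_dir>/<task_name>`. `NULL` disables file output.
#' @param sample_n,metric_seed passed to [intrinsic_metrics()].
#' @return object of class `benchmark_result`: list with `summary`
#'   (one row per objective) and `runs`.
#' @export
run_benchmark <- function(objectives, budget, generator = NULL,
                          batch_size = 32L, seed = 1L, output_dir = NULL,
                          sample_n = 1000L, metric_seed = 42L) {
  stopifnot(budget >= 1, batch_size >= 1)
  if (is.character(objectives) && length(objectives) == 1 &&
      !file.exists(objectives)) {
    objectives <- benchmark_preset(objectives)
  }
  if (inherits(objectives, "objective_config")) objectives <- list(objectives)
  if (!length(objectives)) stop("empty objective list", call. = FALSE)
  objectives <- lapply(objectives, function(o)
    if (is.character(o)) load_config(o) else o)

  runs <- list()
  rows <- list()
  for (obj in objectives) {
    gen_fn <- generator %||% make_pool_generator(seed = seed)
    odir <- if (!is.null(output_dir))
      file.path(output_dir, obj$task_name) else NULL
    run <- scoring_run(obj, output_dir = odir)
    n_eval <- 0L
    finished <- FALSE
    last_scores <- numeric(0)
    last_smiles <- character(0)
    while (!finished) {
      batch <- gen_fn(batch_size, last_scores, last_smiles)
      sc <- score_batch(run, batch)
      last_scores <- sc
      last_smiles <- batch
      n_eval <- n_eval + length(batch)
      finished <- n_eval >= budget
    }
    run$finished <- finished
    finalize_run(run)
    rec <- run_records(run)
    im <- intrinsic_metrics(rec$input_smiles, sample_n = sample_n,
                            seed = metric_seed)
    rows[[obj$task_name]] <- cbind(
      data.frame(task = obj$task_name, n_evaluated = n_eval,
                 batches = run$step, budget = budget, finished = finished,
                 mean_score = mean(rec$score),
                 top_score = max(rec$score), stringsAsFactors = FALSE),
      as.data.frame(im))
    runs[[obj$task_name]] <- run
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary_df,
                     file.path(output_dir, "benchmark_summary.csv"),
                     row.names = FALSE)
  }
  structure(list(summary = summary_df, runs = runs),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> ", nrow(x$summary), " objective(s)\n", sep = "")
  print(x$summary[, c("task", "n_evaluated", "finished", "mean_score",
                      "top_score")])
  invisible(x)
}

#' Score-weighted pool generator
#'
#' The default benchmark generator: samples from a fixed fixture pool with
#' weights `exp(score / temperature)` of each member's best score so far
#' (uniform before any feedback). Returns a closure with the
#' `(batch_size, last_scores, last_smiles)` generator signature.
#'
#' @param pool character vector of SMILES; `NULL` builds one from
#'   [make_library()].
#' @param temperature softmax temperature.
#' @param seed RNG seed for sampling.
#' @return generator function.
#' @export
make_pool_generator <- function(pool = NULL, temperature = 0.1, seed = 1L) {
  if (is.null(pool)) {
    lib <- make_library(300, seed = seed, invalid_fraction = 0)
    parsed <- parse_smiles(lib$smiles)
    pool <- unique(parsed$canonical_smiles[parsed$valid])
  }
  best <- stats::setNames(rep(0, length(pool)), pool)
  rng_env <- new.env(parent = emptyenv())
  rng_env$counter <- 0L
  function(batch_size, last_scores, last_smiles) {
    # fold feedback into the per-member best scores
    if (length(last_scores) && length(last_smiles)) {
      for (k in seq_along(last_smiles)) {
        s <- last_smiles[k]
        if (!is.na(s) && s %in% names(best))
          best[s] <<- max(best[s], last_scores[k])
      }
    }
    rng_env$counter <- rng_env$counter + 1L
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed + rng_env$counter)
    idx <- sample.int(length(pool), batch_size, replace = TRUE,
                      prob = exp(best / temperature))
    pool[idx]
  }
}
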