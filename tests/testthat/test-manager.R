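# The scoring orchestrator: config validation, pipeline contract, caching,
# filters, CSV output.

test_that("configs validate eagerly and report every problem at once", {
  expect_error(
    objective_config("t",
                     scorers = list(scorer_spec("d", "descriptors",
                                                names = "MW")),
                     parameters = list(
                       list(source = "d_nope",
                            transform = list(kind = "identity")),
                       list(transform = list(kind = "identity"))
                     )),
    "d_nope.*parameters\\[2\\]|parameters\\[2\\].*d_nope")
  expect_error(
    objective_config("", scorers = list(), parameters = list()),
    "task_name")
})

test_that("JSON configs round trip through load_config", {
  cfg <- toy_window_config()
  path <- tempfile(fileext = ".json")
  write_config(cfg, path)
  cfg2 <- load_config(path)
  expect_equal(cfg2$task_name, cfg$task_name)
  expect_equal(length(cfg2$parameters), 4L)
  run <- scoring_run(cfg2, output_dir = NA)
  s <- score_batch(run, c("CCO", "c1ccccc1CCCC"))
  run_ref <- scoring_run(cfg, output_dir = NA)
  expect_equal(s, score_batch(run_ref, c("CCO", "c1ccccc1CCCC")))
  expect_error(load_config(tempfile()), "not found")
})

test_that("unknown JSON keys and bad parameters are configuration errors", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(task_name = "x", bogus_key = 1), path,
                       auto_unbox = TRUE)
  expect_error(load_config(path), "unknown key")
})

test_that("scoring preserves length/order and zeroes invalid molecules", {
  run <- scoring_run(toy_window_config(), output_dir = NA)
  smi <- c("CCO", "not_a_smiles", "c1ccccc1CCCC", "", "C1CC")
  s <- score_batch(run, smi)
  expect_length(s, length(smi))
  expect_equal(s[c(2, 4, 5)], c(0, 0, 0))
  expect_true(all(s >= 0 & s <= 1))
  rec <- run_records(run)
  expect_equal(nrow(rec), length(smi))
  expect_equal(rec$input_smiles, smi)
})

test_that("intra-batch duplicates are scored once and share the value", {
  env <- new.env()
  cfg <- objective_config(
    "count", scorers = list(counting_scorer(env)),
    parameters = list(list(source = "count_score",
                           transform = list(kind = "identity"))))
  run <- scoring_run(cfg, output_dir = NA)
  s <- score_batch(run, c("CCO", "CCO", "OCC"))
  expect_equal(env$calls, 1L) # one distinct canonical molecule
  expect_equal(s, rep(0.75, 3))
})

test_that("cross-batch repeats reuse the cache without re-invoking scorers", {
  env <- new.env()
  cfg <- objective_config(
    "count", scorers = list(counting_scorer(env)),
    parameters = list(list(source = "count_score",
                           transform = list(kind = "identity"))))
  run <- scoring_run(cfg, output_dir = NA)
  s1 <- score_batch(run, c("CCO", "CCC"))
  expect_equal(env$calls, 2L)
  s2 <- score_batch(run, c("CCO", "OCC", "CCC"))
  expect_equal(env$calls, 2L) # nothing new to score
  expect_equal(s2, c(s1[1], s1[1], s1[2]))
  rec <- run_records(run)
  expect_true(all(rec$seen_before[rec$step == 2]))
  # cache hit rate 1 on all-repeats: scorer call count equals the number
  # of distinct valid unseen molecules for the whole run
  expect_equal(env$calls, length(unique(rec$canonical_smiles[rec$valid])))
})

test_that("steps auto-increment from one; explicit steps are honoured", {
  run <- scoring_run(toy_window_config(), output_dir = NA)
  score_batch(run, "CCO")
  score_batch(run, "CCC")
  rec <- run_records(run)
  expect_equal(unique(rec$step), c(1L, 2L))
  score_batch(run, "CCCC", step = 10)
  expect_equal(max(run_records(run)$step), 10L)
})

test_that("a failing scorer fails the molecule, not the batch", {
  flaky <- scorer_spec("flaky", "custom", fn = function(smi) {
    if (smi == "CCO") stop("boom")
    c(score = 0.5)
  })
  cfg <- objective_config(
    "flaky", scorers = list(flaky),
    parameters = list(list(source = "flaky_score",
                           transform = list(kind = "identity"))))
  run <- scoring_run(cfg, output_dir = NA)
  expect_warning(s <- score_batch(run, c("CCO", "CCC")), "flaky")
  expect_equal(s, c(0, 0.5))
})

test_that("filter parameters multiply the aggregate", {
  cfg <- objective_config(
    "filtered",
    scorers = list(
      scorer_spec("d", "descriptors", names = "MW"),
      scorer_spec("alert", "substructure_filter", smarts = "[OX2H]")
    ),
    parameters = list(
      list(source = "d_MW",
           transform = list(kind = "step_threshold", direction = "minimize",
                            threshold = 400)),
      list(source = "alert_filter", transform = list(kind = "identity"))
    ),
    aggregation = "amean",
    filters = "alert_filter"
  )
  run <- scoring_run(cfg, output_dir = NA)
  s <- score_batch(run, c("CCO", "CCC"))
  # ethanol hits the hydroxyl alert: aggregate multiplied to zero
  expect_equal(s, c(0, 1))
  rec <- run_records(run)
  expect_equal(rec$filter_product, c(0, 1))
  expect_equal(rec$dscore, c(1, 1))
})

test_that("per-iteration and final CSVs land with conserved row counts", {
  out <- tempfile()
  cfg <- toy_window_config(output_dir = out)
  run <- scoring_run(cfg)
  score_batch(run, c("CCO", "CCC", "bad("))
  score_batch(run, c("c1ccccc1", "CCO"))
  expect_true(file.exists(file.path(out, "iterations", "step_000001.csv")))
  expect_true(file.exists(file.path(out, "iterations", "step_000002.csv")))
  path <- finalize_run(run)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 5L)
  expect_true(all(c("step", "batch_idx", "input_smiles", "canonical_smiles",
                    "valid", "dscore", "filter_product", "passes_diversity",
                    "score") %in% names(tab)))
})

test_that("an empty run finalizes to a header-only record", {
  out <- tempfile()
  run <- scoring_run(toy_window_config(output_dir = out))
  path <- finalize_run(run)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 0L)
  expect_true("score" %in% names(tab))
})

test_that("serial and parallel scorer maps produce identical records", {
  cfg <- toy_window_config()
  smi <- make_library(30, seed = 19, invalid_fraction = 0.1)$smiles
  serial <- scoring_run(cfg, output_dir = NA)
  s1 <- score_batch(serial, smi)
  chunked_map <- function(x, f) {
    # deliberately different evaluation strategy, same contract
    unlist(lapply(split(x, ceiling(seq_along(x) / 7)), function(ch)
      lapply(ch, f)), recursive = FALSE, use.names = FALSE)
  }
  par <- scoring_run(cfg, output_dir = NA, parallel_map = chunked_map)
  s2 <- score_batch(par, smi)
  expect_identical(s1, s2)
  expect_identical(run_records(serial)$score, run_records(par)$score)
})

test_that("diversity penalties are re-applied to cached repeats", {
  cfg <- toy_window_config(
    diversity_filter = div_filter_spec("Unique", minscore = 0.1))
  run <- scoring_run(cfg, output_dir = NA)
  s1 <- score_batch(run, "c1ccccc1CCCC")
  expect_gt(s1, 0)
  s2 <- score_batch(run, "c1ccccc1CCCC") # cached, but a repeat by definition
  expect_equal(s2, 0)
})

test_that("normalise transforms interact with the cache deterministically", {
  cfg <- objective_config(
    "norm",
    scorers = list(scorer_spec("d", "descriptors", names = "MW")),
    parameters = list(list(source = "d_MW",
                           transform = list(kind = "normalise"))))
  replay <- function() {
    run <- scoring_run(cfg, output_dir = NA)
    c(score_batch(run, c("CCO", "CCCCCCCC")),
      score_batch(run, c("CCO", "CCCC")))
  }
  expect_identical(replay(), replay())
})
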