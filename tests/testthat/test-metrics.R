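# Evaluation metrics: identities, oracles, closed forms, chunking.

test_that("degenerate sets hit the exact intrinsic identities", {
  k <- 5
  im <- intrinsic_metrics(rep("CCO", k))
  expect_equal(im$Validity, 1)
  expect_equal(im$Uniqueness, 1 / k)
  expect_equal(im$IntDiv1, 0)
  expect_equal(im$IntDiv2, 0)
  im2 <- intrinsic_metrics(c("CCO", "bad_smiles"))
  expect_equal(im2$Validity, 0.5)
  im3 <- intrinsic_metrics(c("C1CC", "(["))
  expect_equal(im3$Validity, 0)
  expect_true(is.na(im3$IntDiv1)) # undefined marker, not an exception
})

test_that("two-molecule internal diversity follows the definition", {
  a <- fingerprint("CCO")
  b <- fingerprint("CCC")
  t <- similarity(a, b, "Tanimoto")
  im <- intrinsic_metrics(c("CCO", "CCC"))
  expect_equal(im$IntDiv1, 1 - t, tolerance = 1e-12)
  expect_equal(im$IntDiv2, 1 - t, tolerance = 1e-12) # only one distinct pair
})

test_that("IntDiv2 <= IntDiv1 over random fingerprint subsets", {
  lib <- make_library(60, seed = 23, invalid_fraction = 0)
  can <- unique(parse_smiles(lib$smiles)$canonical_smiles)
  fps <- lapply(can, fingerprint)
  set.seed(31)
  for (rep in 1:50) {
    idx <- sample(seq_along(fps), sample(3:12, 1))
    idv <- genscore:::.internal_diversity(fps[idx])
    expect_lte(idv[2], idv[1] + 1e-12)
  }
})

test_that("sphere exclusion diversity matches the naive oracle", {
  n <- 6
  same <- replicate(n, fingerprint("CCO"), simplify = FALSE)
  expect_equal(se_div(same), 1 / n)
  lib <- make_library(50, seed = 29, invalid_fraction = 0)
  can <- unique(parse_smiles(lib$smiles)$canonical_smiles)
  fps <- lapply(can, fingerprint)
  expect_equal(se_div(fps), naive_se_div(fps))
  expect_equal(se_div(fps, threshold = 0.3), naive_se_div(fps, 0.3))
  # every molecule its own sphere when all pairs are distant
  far <- lapply(c("CCO", "c1ccc2ncccc2c1", "C1CN(CCN1)C"), fingerprint)
  expect_equal(se_div(far), 1)
  # adding a duplicate of an existing centre cannot raise the value
  expect_lte(se_div(c(fps, fps[1])), se_div(fps))
})

test_that("Solow-Polasky matches the n=2 closed form on a (d, theta) grid", {
  mk <- function(n_shared, n_only) {
    # construct two fingerprints with controlled Tanimoto
    a <- bitvec(0:(n_shared + n_only - 1), 512L)
    b <- bitvec(c(0:(n_shared - 1), (n_shared + n_only):(n_shared + 2 * n_only - 1)),
                512L)
    list(a, b)
  }
  expect_equal(solow_polasky(list(fingerprint("CCO"))), 1)
  for (n_only in c(2, 5, 9)) {
    pair <- mk(4, n_only)
    d <- 1 - similarity(pair[[1]], pair[[2]], "Tanimoto")
    for (theta in c(0.5, 1, 2, 5)) {
      got <- solow_polasky(pair, theta = theta)
      want <- (2 / (1 + exp(-theta * d))) / 2
      expect_equal(got, want, tolerance = 1e-9,
                   info = paste(n_only, theta))
    }
  }
  # two maximally distant molecules, large theta -> D/n -> 1
  far <- list(bitvec(1:8, 64L), bitvec(9:16, 64L))
  expect_equal(solow_polasky(far, theta = 50), 1, tolerance = 1e-6)
})

test_that("self-comparison extrinsic metrics hit their identities", {
  lib <- make_library(25, seed = 37, invalid_fraction = 0)
  ref <- reference_set(lib$smiles, "self")
  ex <- extrinsic_metrics(lib$smiles, ref)
  expect_equal(ex$Novelty, 0)
  expect_equal(ex$SNN, 1)
  expect_equal(ex$AnalogueSimilarity, 1)
  expect_equal(ex$AnalogueCoverage, 1)
  expect_equal(ex$Silliness, 0)
  expect_equal(ex$Wasserstein_LogP, 0, tolerance = 1e-9)
  expect_equal(ex$Wasserstein_Weight, 0, tolerance = 1e-9)
  expect_equal(ex$ScaffoldSimilarity, 1, tolerance = 1e-12)
  expect_true(is.na(ex$FCD)) # stable schema: unavailable, not omitted
  expect_true(is.na(ex$Wasserstein_NP))
})

test_that("fully disjoint fingerprint bits give silliness 1", {
  ref <- reference_set(c("CCCCC", "CCCCCC"), "alkanes")
  ex <- extrinsic_metrics("FC(F)(F)F", ref)
  expect_equal(ex$Silliness, 1)
  expect_equal(ex$Novelty, 1)
})

test_that("1-D Wasserstein distance translates and scales correctly", {
  set.seed(3)
  x <- stats::rnorm(40)
  expect_equal(wasserstein_1d(x, x + 2.5), 2.5, tolerance = 1e-9)
  expect_equal(wasserstein_1d(x, x), 0)
  # unequal sample sizes against a known quantile integral
  expect_equal(wasserstein_1d(c(0, 1), c(0.5)), 0.5)
})

test_that("statistics_by_n chunks records and computes moments", {
  lib <- make_library(30, seed = 41, invalid_fraction = 0)
  cfg <- toy_window_config()
  run <- scoring_run(cfg, output_dir = NA)
  for (batch in split(lib$smiles, (seq_along(lib$smiles) - 1) %/% 10))
    score_batch(run, batch)
  rec <- run_records(run)
  tab <- statistics_by_n(rec, n = 10, sample_n = 20)
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("Validity", "score_mean", "score_median", "score_sd")
                  %in% names(tab)))
  by_step <- statistics_by_n(rec, column = "step", sample_n = 20)
  expect_equal(nrow(by_step), 3L)
  expect_equal(by_step$chunk, as.character(1:3))
  # constant column has zero spread in every chunk
  rec$const <- 1
  tab2 <- statistics_by_n(rec, n = 10, sample_n = 20)
  expect_true(all(tab2$const_sd == 0))
  expect_error(statistics_by_n(rec, column = "nope"), "available")
})

test_that("metrics are deterministic given inputs and seed", {
  lib <- make_library(40, seed = 43, invalid_fraction = 0.1)
  a <- intrinsic_metrics(lib$smiles, sample_n = 20, seed = 7)
  b <- intrinsic_metrics(lib$smiles, sample_n = 20, seed = 7)
  expect_identical(a, b)
})
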