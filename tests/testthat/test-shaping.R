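# Transformation and aggregation algebra.

test_that("gaussian transform hits its closed-form landmarks", {
  sp <- transform_spec("gaussian_threshold", direction = "range",
                       mu = 3, sigma = 2)
  expect_equal(transform_score(3, sp), 1)
  expect_equal(transform_score(5, sp), exp(-0.5), tolerance = 1e-12)
  expect_equal(transform_score(1, sp), exp(-0.5), tolerance = 1e-12)
  # one-sided variants return 1 past mu in the preferred direction
  up <- transform_spec("gaussian_threshold", direction = "maximize",
                       mu = 3, sigma = 2)
  expect_equal(transform_score(10, up), 1)
  expect_lt(transform_score(1, up), 1)
  dn <- transform_spec("gaussian_threshold", direction = "minimize",
                       mu = 3, sigma = 2)
  expect_equal(transform_score(-10, dn), 1)
})

test_that("linear ramp is piecewise linear with midpoint 0.5", {
  lt <- transform_spec("linear_threshold", threshold = 10, buffer = 4)
  expect_equal(transform_score(10, lt), 1)
  expect_equal(transform_score(6, lt), 0)
  expect_equal(transform_score(8, lt), 0.5)
  # monotone nondecreasing for maximize
  xs <- seq(0, 15, by = 0.25)
  vals <- vapply(xs, transform_score, numeric(1), spec = lt)
  expect_true(all(diff(vals) >= -1e-12))
  mn <- transform_spec("linear_threshold", direction = "minimize",
                       threshold = 10, buffer = 4)
  vals <- vapply(xs, transform_score, numeric(1), spec = mn)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("step window accepts inside and rejects outside", {
  st <- transform_spec("step_threshold", direction = "range",
                       low = 2, high = 4)
  expect_equal(transform_score(3, st), 1)
  expect_equal(transform_score(5, st), 0)
  expect_equal(transform_score(2, st), 1)
  expect_equal(transform_score(4, st), 1)
})

test_that("running normalisation rescales within the observed range", {
  rr <- new_running_range()
  ns <- transform_spec("normalise")
  expect_equal(transform_score(7, ns, rr), 0.5) # no range yet
  expect_equal(transform_score(10, ns, rr), 1)  # new maximum
  expect_equal(transform_score(8.5, ns, rr), 0.5)
  reset_range(rr)
  expect_equal(rr$count, 0L)
  expect_equal(transform_score(2, ns, rr), 0.5)
  expect_equal(transform_score(4, ns, rr), 1)
  # inversion for minimize
  rr2 <- new_running_range()
  mn <- transform_spec("normalise", direction = "minimize")
  transform_score(4, mn, rr2)
  expect_equal(transform_score(2, mn, rr2), 1)
})

test_that("normalisation replays identically over the same sequence", {
  xs <- c(3, -1, 7, 7, 0, 12, 5)
  run_once <- function() {
    rr <- new_running_range()
    ns <- transform_spec("normalise")
    vapply(xs, transform_score, numeric(1), spec = ns, range_state = rr)
  }
  expect_identical(run_once(), run_once())
})

test_that("non-finite raw scores become 0 with a warning", {
  sp <- transform_spec("identity")
  expect_warning(v <- transform_score(NaN, sp), "non-finite")
  expect_equal(v, 0)
  expect_warning(transform_score(Inf, sp))
})

test_that("all transforms map a wide input range into [0,1]", {
  specs <- list(
    transform_spec("identity"),
    transform_spec("linear_threshold", threshold = 2, buffer = 1),
    transform_spec("linear_threshold", direction = "minimize",
                   threshold = -3, buffer = 0.5),
    transform_spec("gaussian_threshold", direction = "range", mu = 0,
                   sigma = 0.3),
    transform_spec("step_threshold", direction = "range", low = -1, high = 1)
  )
  set.seed(42)
  xs <- c(stats::rnorm(300, sd = 50), stats::rcauchy(100))
  for (sp in specs) {
    vals <- vapply(xs, transform_score, numeric(1), spec = sp)
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("weighted sum matches the hand formula and AM-GM holds", {
  sc <- c(a = 0.5, b = 1.0, c = 0.0)
  expect_equal(aggregate_scores(sc, aggregation_spec("wsum",
                                                     c(a = 2, b = 1, c = 1))),
               0.5)
  expect_equal(aggregate_scores(sc, aggregation_spec("amean")), 0.5)
  set.seed(7)
  for (rep in 1:200) {
    k <- sample(2:6, 1)
    s <- stats::setNames(stats::runif(k), paste0("p", seq_len(k)))
    g <- aggregate_scores(s, aggregation_spec("gmean"))
    a <- aggregate_scores(s, aggregation_spec("amean"))
    expect_lte(g, a + 1e-12)
  }
})

test_that("products annihilate at zero and are permutation invariant", {
  s <- c(a = 0.8, b = 0.0, c = 0.9)
  expect_equal(aggregate_scores(s, aggregation_spec("prod")), 0)
  expect_equal(aggregate_scores(s, aggregation_spec("gmean")), 0)
  s2 <- c(x = 0.3, y = 0.9, z = 0.6)
  for (kind in c("prod", "gmean", "amean", "auto_wsum", "auto_wprod")) {
    sp <- aggregation_spec(kind)
    perm <- s2[c(3, 1, 2)]
    expect_equal(aggregate_scores(s2, sp), aggregate_scores(perm, sp),
                 info = kind)
  }
})

test_that("auto-weighting emphasises the least satisfied objective", {
  s <- c(a = 0.9, b = 0.2)
  auto <- aggregate_scores(s, aggregation_spec("auto_wsum"))
  expect_lt(auto, mean(s)) # pulled towards the weak objective
})

test_that("pareto ranks agree with the brute-force dominance oracle", {
  bc <- list(c(x = 1, y = 0), c(x = 0, y = 1), c(x = 0.5, y = 0.5),
             c(x = 0.2, y = 0.2))
  mat <- do.call(rbind, bc)
  expect_equal(pareto_front_ranks(mat), c(1L, 1L, 1L, 2L))
  expect_equal(aggregate_scores(bc[[4]], aggregation_spec("pareto"), bc), 0.5)
  expect_equal(aggregate_scores(bc[[1]], aggregation_spec("pareto"), bc), 1)
  set.seed(9)
  for (rep in 1:20) {
    m <- matrix(stats::runif(sample(20:120, 1) * 3), ncol = 3)
    expect_identical(pareto_front_ranks(m), naive_pareto_ranks(m))
  }
  expect_error(aggregate_scores(bc[[1]], aggregation_spec("pareto")),
               "batch_context")
})

test_that("aggregation rejects bad inputs loudly", {
  expect_error(aggregate_scores(numeric(), aggregation_spec("amean")),
               "empty")
  expect_error(aggregate_scores(c(a = 1.4), aggregation_spec("amean")),
               "\\[0,1\\]")
  expect_error(aggregation_spec("wsum"), "weights")
  expect_error(aggregation_spec("nope"), "unknown aggregation")
})
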