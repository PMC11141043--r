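# Score transformation (raw value -> desirability in [0,1]) and
# aggregation (vector of desirabilities -> one score).

#' Transformation specification
#'
#' @param kind one of `"normalise"` (running max-min over the values seen
#'   so far in the run), `"linear_threshold"` (linear ramp of width
#'   `buffer` ending at `threshold`), `"gaussian_threshold"` (Gaussian bump
#'   around `mu` with width `sigma`; one-sided for maximize/minimize,
#'   symmetric for `direction = "range"`), `"step_threshold"` (hard window)
#'   or `"identity"` (clamp to [0,1]).
#' @param direction `"maximize"`, `"minimize"` or `"range"`.
#' @param threshold,buffer linear/step parameters; `buffer > 0`.
#' @param mu,sigma Gaussian parameters; `sigma > 0`.
#' @param low,high window bounds for `step_threshold` with
#'   `direction = "range"`; `low <= high`.
#' @return object of class `transform_spec`.
#' @export
transform_spec <- function(kind, direction = "maximize", threshold = NULL,
                           buffer = NULL, mu = NULL, sigma = NULL,
                           low = NULL, high = NULL) {
  kinds <- c("normalise", "linear_threshold", "gaussian_threshold",
             "step_threshold", "identity")
  if (!kind %in% kinds)
    stop("unknown transform kind '", kind, "'; use one of: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  if (!direction %in% c("maximize", "minimize", "range"))
    stop("direction must be maximize, minimize or range", call. = FALSE)
  if (kind == "linear_threshold") {
    if (is.null(threshold) || is.null(buffer))
      stop("linear_threshold requires 'threshold' and 'buffer'", call. = FALSE)
    if (buffer <= 0) stop("'buffer' must be > 0", call. = FALSE)
  }
  if (kind == "gaussian_threshold") {
    if (is.null(mu) || is.null(sigma))
      stop("gaussian_threshold requires 'mu' and 'sigma'", call. = FALSE)
    if (sigma <= 0) stop("'sigma' must be > 0", call. = FALSE)
  }
  if (kind == "step_threshold") {
    if (direction == "range") {
      if (is.null(low) && is.null(high))
        stop("step_threshold with direction 'range' requires 'low' and/or 'high'",
             call. = FALSE)
      low <- if (is.null(low)) -Inf else low
      high <- if (is.null(high)) Inf else high
      if (low > high) stop("'low' must be <= 'high'", call. = FALSE)
    } else if (is.null(threshold)) {
      stop("step_threshold requires 'threshold' (or direction 'range' with low/high)",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, direction = direction, threshold = threshold,
                 buffer = buffer, mu = mu, sigma = sigma, low = low,
                 high = high), class = "transform_spec")
}

#' Running min/max range state
#'
#' Mutable state for the `normalise` transform: the minimum and maximum
#' raw value observed so far in a run ("moving goal post" normalisation).
#' @return environment of class `running_range` with `min_seen`,
#'   `max_seen`, `count`.
#' @export
new_running_range <- function() {
  e <- new.env(parent = emptyenv())
  e$min_seen <- NA_real_
  e$max_seen <- NA_real_
  e$count <- 0L
  class(e) <- "running_range"
  e
}

#' @rdname new_running_range
#' @param range_state a `running_range` to clear in place.
#' @export
reset_range <- function(range_state) {
  stopifnot(inherits(range_state, "running_range"))
  range_state$min_seen <- NA_real_
  range_state$max_seen <- NA_real_
  range_state$count <- 0L
  invisible(range_state)
}

.clamp01 <- function(x) {
  # tolerate tiny floating error, then hard-clamp
  x[x > 1 & x < 1 + 1e-9] <- 1
  x[x < 0 & x > -1e-9] <- 0
  pmin(1, pmax(0, x))
}

#' Transform a raw score to a desirability
#'
#' Maps any finite raw value to [0,1] according to `spec`. Non-finite
#' values score 0 with a warning. The `normalise` kind first updates
#' `range_state` with `x`, then rescales within the observed range;
#' before a range exists (first observation, or a constant stream) the
#' neutral value 0.5 is returned.
#'
#' @param x raw value.
#' @param spec a [transform_spec()].
#' @param range_state a [new_running_range()]; required for `normalise`.
#' @return value in [0,1].
#' @export
transform_score <- function(x, spec, range_state = NULL) {
  stopifnot(inherits(spec, "transform_spec"))
  if (!is.finite(x)) {
    warning("non-finite raw score treated as 0 desirability", call. = FALSE)
    return(0)
  }
  v <- switch(spec$kind,
    identity = x,
    normalise = {
      if (is.null(range_state))
        stop("'normalise' requires a range_state", call. = FALSE)
      if (range_state$count == 0L) {
        range_state$min_seen <- x
        range_state$max_seen <- x
      } else {
        range_state$min_seen <- min(range_state$min_seen, x)
        range_state$max_seen <- max(range_state$max_seen, x)
      }
      range_state$count <- range_state$count + 1L
      span <- range_state$max_seen - range_state$min_seen
      u <- if (span == 0) 0.5 else (x - range_state$min_seen) / span
      if (spec$direction == "minimize") 1 - u else u
    },
    linear_threshold = {
      th <- spec$threshold; bu <- spec$buffer
      if (spec$direction == "minimize") {
        if (x <= th) 1 else if (x >= th + bu) 0 else (th + bu - x) / bu
      } else {
        if (x >= th) 1 else if (x <= th - bu) 0 else (x - (th - bu)) / bu
      }
    },
    gaussian_threshold = {
      gauss <- exp(-(x - spec$mu)^2 / (2 * spec$sigma^2))
      if (spec$direction == "maximize" && x >= spec$mu) 1
      else if (spec$direction == "minimize" && x <= spec$mu) 1
      else gauss
    },
    step_threshold = {
      if (spec$direction == "range") {
        as.numeric(x >= spec$low && x <= spec$high)
      } else if (spec$direction == "minimize") {
        as.numeric(x <= spec$threshold)
      } else {
        as.numeric(x >= spec$threshold)
      }
    }
  )
  .clamp01(v)
}

#' Aggregation specification
#'
#' @param kind one of `"wsum"`, `"auto_wsum"`, `"prod"`, `"wprod"`,
#'   `"auto_wprod"`, `"gmean"`, `"amean"`, `"pareto"`.
#' @param weights named non-negative weights (parameter name -> weight) for
#'   the weighted kinds; normalised internally, so they need not sum to 1.
#' @return object of class `aggregation_spec`.
#' @export
aggregation_spec <- function(kind = "amean", weights = NULL) {
  kinds <- c("wsum", "auto_wsum", "prod", "wprod", "auto_wprod", "gmean",
             "amean", "pareto")
  if (!kind %in% kinds)
    stop("unknown aggregation kind '", kind, "'; use one of: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  if (kind %in% c("wsum", "wprod")) {
    if (is.null(weights) || !length(weights) || is.null(names(weights)))
      stop("'", kind, "' requires named weights", call. = FALSE)
    if (any(weights < 0) || all(weights == 0))
      stop("weights must be >= 0 with at least one positive", call. = FALSE)
  }
  structure(list(kind = kind, weights = weights), class = "aggregation_spec")
}

# dynamic weights emphasising the least-satisfied objectives:
# w_i = (1 - s_i) + eps, normalised per molecule (eps = 0.01). This is the
# package's reading of auto-weighting; documented as such.
.auto_weights <- function(scores, eps = 0.01) {
  w <- (1 - scores) + eps
  w / sum(w)
}

#' Aggregate desirabilities into one score
#'
#' All inputs must already lie in [0,1]. `wsum` is the weight-normalised
#' weighted mean; `amean` the unweighted mean; `prod` the plain product;
#' `wprod` the geometric weighted product `prod(s_i ^ (w_i / sum w))`;
#' `gmean` the geometric mean; `auto_wsum`/`auto_wprod` use per-molecule
#' dynamic weights proportional to `(1 - s_i) + 0.01`, emphasising the
#' least-satisfied objectives; `pareto` scores by non-dominated front rank
#' within `batch_context` (rank 1 = non-dominated), scaled to
#' `1 - (rank - 1) / n_fronts`, ties within a front sharing a value.
#'
#' @param scores named numeric vector of desirabilities in [0,1].
#' @param spec an [aggregation_spec()].
#' @param batch_context for `pareto`: list of score vectors for the whole
#'   batch, one of which is `scores`.
#' @return aggregate desirability in [0,1].
#' @export
aggregate_scores <- function(scores, spec, batch_context = NULL) {
  stopifnot(inherits(spec, "aggregation_spec"))
  if (!length(scores)) stop("empty score vector", call. = FALSE)
  if (any(scores < 0 | scores > 1))
    stop("aggregate_scores() inputs must be in [0,1]", call. = FALSE)
  v <- switch(spec$kind,
    amean = mean(scores),
    wsum = {
      w <- spec$weights[names(scores)]
      if (anyNA(w))
        stop("weights missing for: ",
             paste(names(scores)[is.na(w)], collapse = ", "), call. = FALSE)
      sum(w * scores) / sum(w)
    },
    auto_wsum = sum(.auto_weights(scores) * scores),
    prod = prod(scores),
    wprod = {
      w <- spec$weights[names(scores)]
      if (anyNA(w))
        stop("weights missing for: ",
             paste(names(scores)[is.na(w)], collapse = ", "), call. = FALSE)
      prod(scores ^ (w / sum(w)))
    },
    auto_wprod = prod(scores ^ .auto_weights(scores)),
    gmean = prod(scores) ^ (1 / length(scores)),
    pareto = {
      if (is.null(batch_context))
        stop("'pareto' aggregation requires a batch_context", call. = FALSE)
      mat <- do.call(rbind, batch_context)
      ranks <- pareto_front_ranks(mat)
      idx <- which(vapply(batch_context, function(s)
        isTRUE(all.equal(unname(s), unname(scores))), logical(1)))[1]
      if (is.na(idx))
        stop("'scores' must be one of the rows of batch_context", call. = FALSE)
      1 - (ranks[idx] - 1) / max(ranks)
    }
  )
  .clamp01(v)
}

#' Non-dominated sorting front ranks
#'
#' Fast non-dominated sort (dominance-count / dominated-set peeling) over a
#' score matrix where larger is better in every column. Rank 1 is the
#' non-dominated front.
#'
#' @param mat numeric matrix, one row per point.
#' @return integer vector of front ranks.
#' @export
pareto_front_ranks <- function(mat) {
  n <- nrow(mat)
  if (n == 1) return(1L)
  dominates <- function(i, j) {
    all(mat[i, ] >= mat[j, ]) && any(mat[i, ] > mat[j, ])
  }
  dom_count <- integer(n)
  dominated_by <- vector("list", n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (dominates(i, j)) {
        dom_count[j] <- dom_count[j] + 1L
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (dominates(j, i)) {
        dom_count[i] <- dom_count[i] + 1L
        dominated_by[[j]] <- c(dominated_by[[j]], i)
      }
    }
  }
  rank <- integer(n)
  front <- which(dom_count == 0L)
  r <- 1L
  while (length(front)) {
    rank[front] <- r
    nxt <- integer()
    for (i in front) {
      for (j in dominated_by[[i]]) {
        dom_count[j] <- dom_count[j] - 1L
        if (dom_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    front <- nxt
    r <- r + 1L
  }
  rank
}
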