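# Gaussian-process Bayesian optimization over a bounded hyperparameter
# box: Latin-hypercube initial design, Matern 5/2 surrogate on the
# transformed (unit-cube) space, expected-improvement acquisition, stopping
# on an evaluation or wall-time budget. Generic over any objective
# callable; the training objective it drives at full scale (validation
# error of a trained network) is out of scope here, and a shipped analytic
# demo objective stands in for it in examples and tests.

#' Hyperparameter search space
#'
#' A bounded box of named dimensions. Each dimension has lower/upper
#' bounds, an optional log10 transform (used for ranges spanning several
#' decades) and an optional integrality constraint (continuous relaxation +
#' rounding).
#'
#' @param dims A list of dimensions, each created by `space_dim()`.
#' @return A `hyperparameter_space` object.
#' @export
hyperparameter_space <- function(dims) {
  nms <- vapply(dims, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stopf("dimension names must be unique")
  for (d in dims)
    if (!(d$lower < d$upper)) stopf("lower < upper required for `%s`", d$name)
  structure(stats::setNames(dims, nms), class = "hyperparameter_space")
}

#' @rdname hyperparameter_space
#' @param name Dimension name.
#' @param lower,upper Bounds (inclusive).
#' @param log Sample/model this dimension in log10 space.
#' @param integer Round sampled values to integers.
#' @export
space_dim <- function(name, lower, upper, log = FALSE, integer = FALSE) {
  list(name = name, lower = lower, upper = upper, log = log, integer = integer)
}

#' Default network-training hyperparameter box
#'
#' The four-dimensional box used for tuning the feature-extraction network:
#' L2 regularization in `(1e-10, 1e-2)` (log scale), section depth in
#' `{1,2,3}`, momentum in `(0.7, 0.98)`, and learning rate in `(0.0001, 1)`
#' (log scale).
#'
#' @return A [hyperparameter_space()].
#' @export
default_hyperparameter_space <- function() {
  hyperparameter_space(list(
    space_dim("l2", 1e-10, 1e-2, log = TRUE),
    space_dim("depth", 1, 3, integer = TRUE),
    space_dim("momentum", 0.7, 0.98),
    space_dim("lr", 1e-4, 1, log = TRUE)))
}

# --- transforms between native and unit-cube coordinates ----------------

#' @noRd
to_unit <- function(space, X) {
  U <- X
  for (i in seq_along(space)) {
    d <- space[[i]]
    x <- X[, i]
    if (d$log) U[, i] <- (log10(x) - log10(d$lower)) / (log10(d$upper) - log10(d$lower))
    else U[, i] <- (x - d$lower) / (d$upper - d$lower)
  }
  U
}

#' @noRd
from_unit <- function(space, U) {
  X <- U
  for (i in seq_along(space)) {
    d <- space[[i]]
    u <- U[, i]
    x <- if (d$log) 10^(log10(d$lower) + u * (log10(d$upper) - log10(d$lower)))
         else d$lower + u * (d$upper - d$lower)
    if (d$integer) x <- pmin(d$upper, pmax(d$lower, round(x)))
    X[, i] <- x
  }
  colnames(X) <- names(space)
  X
}

#' Latin-hypercube sample of a hyperparameter space
#'
#' Draws `n` points with `lhs::randomLHS` in the transformed space: log
#' dimensions are sampled uniformly in log10, integer dimensions rounded.
#' All points respect the box bounds.
#'
#' @param space A [hyperparameter_space()].
#' @param n Number of points (>= 1).
#' @param seed Integer seed; the design is deterministic given it.
#' @return A numeric matrix `n x length(space)` with named columns.
#' @export
sample_space <- function(space, n, seed = 1L) {
  n <- assert_scalar_int(n, "n", min = 1)
  U <- with_seed_or_stream(seed, lhs::randomLHS(n, length(space)))
  from_unit(space, U)
}

# --- Matern 5/2 GP ------------------------------------------------------

#' @noRd
matern52 <- function(U1, U2, lengthscale) {
  r2 <- outer(rowSums(U1^2), rowSums(U2^2), "+") - 2 * U1 %*% t(U2)
  r <- sqrt(pmax(r2, 0)) / lengthscale
  (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
}

# Fit a zero-mean GP on standardized y; lengthscale chosen from a small
# grid by marginal likelihood. Returns a predictor of (mean, sd).
#' @noRd
gp_fit <- function(U, y, nugget = 1e-8) {
  mu <- mean(y); sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  z <- (y - mu) / sdy
  n <- length(z)
  best <- NULL
  for (ls in c(0.05, 0.1, 0.2, 0.5, 1, 2)) {
    K <- matern52(U, U, ls) + diag(nugget, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), z))
    loglik <- -0.5 * sum(z * alpha) - sum(log(diag(ch))) - 0.5 * n * log(2 * pi)
    if (is.null(best) || loglik > best$loglik)
      best <- list(ls = ls, ch = ch, alpha = alpha, loglik = loglik)
  }
  if (is.null(best)) stopf("GP fit failed (singular kernel)")
  function(Unew) {
    Ks <- matern52(Unew, U, best$ls)
    m <- drop(Ks %*% best$alpha)
    vs <- forwardsolve(t(best$ch), t(Ks))  # L^{-1} k*
    v <- pmax(1 - colSums(vs^2), 1e-12)   # 1 - k*' K^{-1} k*
    list(mean = mu + sdy * m, sd = sdy * sqrt(v))
  }
}

#' @noRd
expected_improvement <- function(pred, y_best) {
  imp <- y_best - pred$mean
  z <- imp / pred$sd
  pred$sd * (z * stats::pnorm(z) + stats::dnorm(z))
}

#' Run Gaussian-process Bayesian optimization
#'
#' Minimizes `objective` over the box: `n_init` Latin-hypercube seeds, then
#' sequential evaluations at the expected-improvement maximizer of a Matern
#' 5/2 GP fitted to all finite observations (in the transformed space).
#' Stops at `max_evals` evaluations or when `max_time_s` of wall time is
#' exceeded, whichever comes first. An objective returning `NaN`/`NA` is
#' recorded as `+Inf` and optimization continues. Deterministic under
#' `seed` for a deterministic objective (unless the time budget binds).
#'
#' @param objective Function taking a named list/vector of hyperparameter
#'   values and returning a single number to minimize.
#' @param space A [hyperparameter_space()].
#' @param max_evals Total evaluation budget (>= `n_init`).
#' @param max_time_s Wall-time budget in seconds; default 54000 (the
#'   full-scale tuning budget; tests and examples always override this with
#'   seconds-scale budgets).
#' @param seed Integer seed.
#' @param n_init Latin-hypercube initialization size; default 5.
#' @param n_candidates Random candidate pool size for maximizing EI;
#'   default 1000.
#' @return A `bo_trace` list: `points` (data frame of evaluated points),
#'   `values`, `best_point` (named list), `best_value`, `stop_reason`
#'   (`"max_evals"` or `"max_time"`).
#' @examples
#' space <- hyperparameter_space(list(space_dim("lr", 1e-4, 1, log = TRUE)))
#' tr <- run_bo(function(p) (log10(p$lr) + 2)^2, space,
#'              max_evals = 15, max_time_s = 60, seed = 1)
#' tr$best_point$lr
#' @export
run_bo <- function(objective, space, max_evals, max_time_s = 54000,
                   seed = 1L, n_init = 5L, n_candidates = 1000L) {
  if (!inherits(space, "hyperparameter_space"))
    stopf("`space` must be a hyperparameter_space")
  max_evals <- assert_scalar_int(max_evals, "max_evals", min = 1)
  n_init <- assert_scalar_int(n_init, "n_init", min = 1)
  if (max_evals < n_init) stopf("`max_evals` must be >= n_init")
  t0 <- proc.time()[["elapsed"]]
  over_time <- function() proc.time()[["elapsed"]] - t0 > max_time_s

  with_seed_or_stream(seed, {
    U <- lhs::randomLHS(n_init, length(space))
    X <- from_unit(space, U)
    eval_point <- function(xrow) {
      v <- tryCatch(objective(as.list(xrow)), error = function(e) NaN)
      if (length(v) != 1 || is.na(v) || is.nan(v)) Inf else as.numeric(v)
    }
    y <- numeric(0)
    stop_reason <- "max_evals"
    for (i in seq_len(n_init)) {
      y <- c(y, eval_point(X[i, ]))
      if (over_time()) { stop_reason <- "max_time"; break }
    }
    X <- X[seq_along(y), , drop = FALSE]
    U <- U[seq_along(y), , drop = FALSE]

    while (length(y) < max_evals && stop_reason == "max_evals") {
      ok <- is.finite(y)
      Ucand <- matrix(stats::runif(n_candidates * length(space)),
                      n_candidates, length(space))
      if (sum(ok) >= 2) {
        pred_fun <- gp_fit(U[ok, , drop = FALSE], y[ok])
        ei <- expected_improvement(pred_fun(Ucand), min(y[ok]))
        unext <- Ucand[which.max(ei), , drop = FALSE]
      } else {
        unext <- Ucand[1, , drop = FALSE]  # fall back to random search
      }
      xnext <- from_unit(space, unext)
      y <- c(y, eval_point(xnext[1, ]))
      U <- rbind(U, unext)
      X <- rbind(X, xnext)
      if (over_time()) stop_reason <- "max_time"
    }

    best <- which.min(y)
    structure(list(points = as.data.frame(X),
                   values = y,
                   best_point = as.list(X[best, ]),
                   best_value = y[best],
                   stop_reason = stop_reason),
              class = "bo_trace")
  })
}

#' Analytic demo objective for the tuner
#'
#' A smooth surrogate objective over the default box, minimized at
#' `lr = 0.01` along the learning-rate axis:
#' `(log10(lr) + 2)^2` plus small quadratic penalties on the other
#' dimensions when present. Used to exercise and sanity-check [run_bo()]
#' without any network training.
#'
#' @param point Named list of hyperparameter values (needs at least `lr`).
#' @return Objective value.
#' @export
demo_quadratic_objective <- function(point) {
  v <- (log10(point$lr) + 2)^2
  if (!is.null(point$momentum)) v <- v + (point$momentum - 0.9)^2
  if (!is.null(point$l2)) v <- v + 0.01 * (log10(point$l2) + 6)^2
  v
}
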