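# Pathfinder algorithm (PFA) specialized to wrapper feature selection.
# A swarm of continuous positions in [0,1]^d is thresholded to binary
# feature masks; each mask is scored by a KNN cost that trades
# classification error against the selected-feature fraction
# (cost = 0.94 * error + 0.014 * n_sel/d). The lowest-cost member is the
# pathfinder (leader); followers move toward the leader and a random
# neighbour with a decaying random vibration, and roles can swap every
# iteration as costs change. Elitism keeps the best mask ever seen.

#' PFA configuration
#'
#' @param swarm_size Number of swarm members `m` (>= 2).
#' @param max_iter Number of iterations `k_max` (>= 1).
#' @param phi_alpha Weight of the classification error in the cost;
#'   default 0.94.
#' @param phi_beta Weight of the selected-feature fraction; default 0.014.
#' @param knn_k Neighbours for the KNN fitness classifier; default 5.
#' @param eval_scheme `"holdout_50_50"` (one seeded stratified 50:50 split,
#'   the full-scale protocol) or `"cv5"` (stratified 5-fold CV).
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return A `pfa_config` object.
#' @export
pfa_config <- function(swarm_size = 20L, max_iter = 30L,
                       phi_alpha = 0.94, phi_beta = 0.014,
                       knn_k = 5L, eval_scheme = c("holdout_50_50", "cv5"),
                       seed = 1L) {
  swarm_size <- assert_scalar_int(swarm_size, "swarm_size", min = 2)
  max_iter <- assert_scalar_int(max_iter, "max_iter", min = 1)
  knn_k <- assert_scalar_int(knn_k, "knn_k", min = 1)
  if (phi_alpha < 0 || phi_beta < 0) stopf("cost weights must be >= 0")
  structure(list(swarm_size = swarm_size, max_iter = max_iter,
                 phi_alpha = phi_alpha, phi_beta = phi_beta,
                 knn_k = knn_k, eval_scheme = match.arg(eval_scheme),
                 seed = as.integer(seed)),
            class = "pfa_config")
}

#' Threshold a continuous position into a selection mask
#'
#' A feature is selected when its coordinate exceeds 0.5 (strict). If no
#' coordinate exceeds 0.5 the single largest coordinate is selected (ties
#' broken toward the lowest index), so the mask is never empty.
#'
#' @param position Numeric vector with entries in `[0,1]`.
#' @return Logical selection mask of the same length.
#' @export
binarize <- function(position) {
  if (anyNA(position) || any(position < 0 | position > 1))
    stopf("`position` entries must lie in [0,1]")
  sel <- position > 0.5
  if (!any(sel)) sel[which.max(position)] <- TRUE
  sel
}

# KNN classification error of the masked columns under the configured
# evaluation scheme. Assumes the RNG stream is already positioned (called
# inside a seeded run); `split` is the precomputed train indicator for the
# holdout scheme.
#' @noRd
knn_error_masked <- function(values, labels, mask, cfg, split = NULL) {
  x <- values[, mask, drop = FALSE]
  y <- factor(labels)
  if (cfg$eval_scheme == "holdout_50_50") {
    if (is.null(split)) split <- stratified_holdout(labels)
    pred <- class::knn(x[split, , drop = FALSE], x[!split, , drop = FALSE],
                       y[split], k = cfg$knn_k)
    mean(pred != y[!split])
  } else {
    fold <- stratified_folds(labels, 5L)
    err <- 0
    for (f in 1:5) {
      te <- fold == f
      pred <- class::knn(x[!te, , drop = FALSE], x[te, , drop = FALSE],
                         y[!te], k = cfg$knn_k)
      err <- err + sum(pred != y[te])
    }
    err / length(y)
  }
}

#' KNN wrapper fitness of a feature mask
#'
#' Evaluates a seeded KNN classifier on the masked feature columns and
#' composes the selection cost
#' `cost = phi_alpha * error + phi_beta * (n_selected / d)` with
#' `error = 1 - accuracy`. With the default weights (0.94, 0.014) a mask of
#' all `d` features and perfect accuracy costs exactly 0.014.
#'
#' @param mask Logical mask with at least one `TRUE`.
#' @param data A [feature_matrix()].
#' @param cfg A [pfa_config()]; `cfg$seed` fixes the data split and KNN
#'   tie-breaking.
#' @return A `fitness_record` list: `cost`, `error`, `accuracy`,
#'   `n_selected`.
#' @export
fitness <- function(mask, data, cfg = pfa_config()) {
  if (!inherits(data, "feature_matrix")) stopf("`data` must be a feature_matrix")
  mask <- as.logical(mask)
  if (length(mask) != ncol(data$values)) stopf("mask length must equal d")
  if (!any(mask)) stopf("mask must select at least one feature")
  err <- with_seed_or_stream(cfg$seed,
    knn_error_masked(data$values, data$labels, mask, cfg))
  fitness_record(err, sum(mask), ncol(data$values), cfg)
}

#' @noRd
fitness_record <- function(error, n_selected, d, cfg) {
  structure(list(cost = cfg$phi_alpha * error + cfg$phi_beta * (n_selected / d),
                 error = error, accuracy = 1 - error,
                 n_selected = as.integer(n_selected)),
            class = "fitness_record")
}

#' Leader (pathfinder) position update
#'
#' `x_p^{k+1} = x_p^k + 2 r3 * (x_p^k - x_p^{k-1}) + A` with
#' `r3 ~ U[0,1]^d` and fluctuation `A = u2 * exp(-2k/k_max)`,
#' `u2 ~ U[-1,1]^d`; the result is clipped to `[0,1]^d`. The random draws
#' can be injected for testing.
#'
#' @param leader Current leader position.
#' @param leader_prev Leader position at the previous iteration.
#' @param k,k_max Current iteration and iteration budget.
#' @param r3,u2 Optional injected random vectors (drawn from the ambient
#'   RNG stream when `NULL`).
#' @return The updated, clipped leader position.
#' @export
pathfinder_update <- function(leader, leader_prev, k, k_max,
                              r3 = NULL, u2 = NULL) {
  d <- length(leader)
  if (is.null(r3)) r3 <- stats::runif(d)
  if (is.null(u2)) u2 <- stats::runif(d, -1, 1)
  A <- u2 * exp(-2 * k / k_max)
  clip01(leader + 2 * r3 * (leader - leader_prev) + A)
}

#' Follower position update
#'
#' `x_i^{k+1} = x_i^k + R1*(x_j^k - x_i^k) + R2*(x_p^k - x_i^k) + eps`
#' with `R1 = alpha * r1`, `R2 = beta * r2`, `r1, r2 ~ U[0,1]^d`,
#' interaction/attraction coefficients `alpha, beta ~ U[1,2]` (drawn once
#' per iteration and shared across followers), and vibration
#' `eps = (1 - k/k_max) * u1 * D_ij` where `u1 ~ U[-1,1]^d` and `D_ij` is
#' the componentwise gap `x_i - x_j` between the member and its neighbour
#' (the form used in reference PFA implementations; a scalar norm would be
#' out of scale with the unit box in high dimension). The vibration
#' vanishes at the final iteration, and coincident `x_i = x_j = x_p` is a
#' fixed point. Result clipped to `[0,1]^d`.
#'
#' @param xi Follower position.
#' @param xj A randomly chosen other member's position.
#' @param xp Leader position (pre-update, `x_p^k`).
#' @param k,k_max Current iteration and iteration budget.
#' @param alpha,beta Interaction and attraction coefficients.
#' @param r1,r2,u1 Optional injected random vectors.
#' @return The updated, clipped follower position.
#' @export
follower_update <- function(xi, xj, xp, k, k_max, alpha, beta,
                            r1 = NULL, r2 = NULL, u1 = NULL) {
  d <- length(xi)
  if (is.null(r1)) r1 <- stats::runif(d)
  if (is.null(r2)) r2 <- stats::runif(d)
  if (is.null(u1)) u1 <- stats::runif(d, -1, 1)
  eps <- (1 - k / k_max) * u1 * (xi - xj)
  clip01(xi + alpha * r1 * (xj - xi) + beta * r2 * (xp - xi) + eps)
}

#' Run the pathfinder feature-selection algorithm
#'
#' Initializes `m` positions uniformly in `[0,1]^d`, scores every member's
#' thresholded mask with the KNN cost, and iterates: the minimum-cost
#' member is (re-)elected leader, the leader moves by
#' [pathfinder_update()], every other member moves by [follower_update()]
#' toward the pre-update leader, and the best mask ever evaluated is
#' retained (elitism), so the best-cost history is non-increasing. One
#' stratified 50:50 split (or 5-fold CV) fixed by `cfg$seed` is reused for
#' every evaluation so that costs are comparable across masks.
#'
#' @param data A [feature_matrix()] with at least 2 classes.
#' @param cfg A [pfa_config()].
#' @return A list of class `pfa_result`: `mask` (logical), `record` (the
#'   best `fitness_record`), `history` (best cost after initialization and
#'   after each iteration, length `max_iter + 1`), `leader_trace`
#'   (leader index per iteration), `n_evals`.
#' @examples
#' sim <- make_gaussian_feature_data(15, 3, 12, 4, effect_size = 3, seed = 1)
#' res <- run_pfa(sim$data, pfa_config(swarm_size = 6, max_iter = 5, seed = 1))
#' res$record$cost <= res$history[1]
#' @export
run_pfa <- function(data, cfg = pfa_config()) {
  if (!inherits(data, "feature_matrix")) stopf("`data` must be a feature_matrix")
  d <- ncol(data$values)
  if (d == 0) stopf("no features to select from")
  if (length(unique(data$labels)) < 2) stopf("need at least two classes")
  m <- cfg$swarm_size; k_max <- cfg$max_iter

  with_seed_or_stream(cfg$seed, {
    split <- if (cfg$eval_scheme == "holdout_50_50") stratified_holdout(data$labels)
    eval_cost <- function(pos) {
      msk <- binarize(pos)
      err <- knn_error_masked(data$values, data$labels, msk, cfg, split)
      fitness_record(err, sum(msk), d, cfg)
    }

    pos <- matrix(stats::runif(m * d), m, d)
    recs <- apply(pos, 1, eval_cost, simplify = FALSE)
    costs <- vapply(recs, `[[`, numeric(1), "cost")
    leader_idx <- which.min(costs)
    best_i <- leader_idx
    best_mask <- binarize(pos[best_i, ])
    best_rec <- recs[[best_i]]
    leader_prev <- pos[leader_idx, ]  # no earlier position yet
    history <- best_rec$cost
    leader_trace <- integer(0)
    n_evals <- m

    for (k in seq_len(k_max)) {
      xp <- pos[leader_idx, ]
      new_leader <- pathfinder_update(xp, leader_prev, k, k_max)
      alpha <- stats::runif(1, 1, 2); beta <- stats::runif(1, 1, 2)
      new_pos <- pos
      new_pos[leader_idx, ] <- new_leader
      for (i in seq_len(m)[-leader_idx]) {
        j <- sample(seq_len(m)[-i], 1L)
        new_pos[i, ] <- follower_update(pos[i, ], pos[j, ], xp, k, k_max,
                                        alpha, beta)
      }
      leader_prev <- xp
      pos <- new_pos
      recs <- apply(pos, 1, eval_cost, simplify = FALSE)
      costs <- vapply(recs, `[[`, numeric(1), "cost")
      n_evals <- n_evals + m
      leader_idx <- which.min(costs)  # roles may swap
      if (costs[leader_idx] < best_rec$cost) {
        best_rec <- recs[[leader_idx]]
        best_mask <- binarize(pos[leader_idx, ])
      }
      history <- c(history, best_rec$cost)
      leader_trace <- c(leader_trace, leader_idx)
    }

    structure(list(mask = best_mask, record = best_rec, history = history,
                   leader_trace = leader_trace, n_evals = n_evals),
              class = "pfa_result")
  })
}

#' @export
print.pfa_result <- function(x, ...) {
  cat(sprintf("<pfa_result> %d/%d features, cost %.4f (accuracy %.4f)\n",
              x$record$n_selected, length(x$mask), x$record$cost,
              x$record$accuracy))
  invisible(x)
}
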