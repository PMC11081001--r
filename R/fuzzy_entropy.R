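# Second stage of the FEcPFA selector: each PFA-selected feature is scored
# by running one-dimensional fuzzy C-means over its values (C = number of
# classes) and summarizing the membership matrix by a fuzzy entropy; crisp,
# well-clustered features are retained, uncertain ones dropped.

#' Shannon entropy of a probability vector
#'
#' `H = -sum(p * log(p))` in natural log units, with the convention
#' `0 * log 0 = 0`.
#'
#' @param p Nonnegative vector summing to 1 (within 1e-9).
#' @return Entropy in nats; 0 for a degenerate distribution, `log(length(p))`
#'   for the uniform one.
#' @export
shannon_entropy <- function(p) {
  if (anyNA(p) || any(p < 0)) stopf("`p` must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stopf("`p` must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' One-dimensional fuzzy C-means
#'
#' Alternates the center update `C_j = sum(mu_ij^e u_i) / sum(mu_ij^e)` and
#' the membership update `mu_ij = 1 / sum_m (D_ij / D_im)^(2/(e-1))` with
#' Euclidean distances `D_ij = |u_i - C_j|`, starting from seeded random
#' memberships, until the largest membership change falls below `tol` or
#' `max_iter` is reached. A point coinciding with a center receives
#' membership 1 there. The fuzzy objective `sum(mu^e D^2)` is non-increasing
#' across iterations. A constant input cannot support `C` distinct centers;
#' it is returned flagged `degenerate` (single effective cluster), not an
#' error.
#'
#' @param values Numeric vector of length `N >= C`.
#' @param C Number of clusters (>= 2).
#' @param e Fuzziness exponent (> 1); default 2.
#' @param tol Convergence tolerance on max membership change; default 1e-6.
#' @param max_iter Iteration cap; default 200.
#' @param seed Seed for the membership initialization.
#' @return An `fcm_result` list: `centers` (length `C`), `memberships`
#'   (`N x C`, rows summing to 1), `n_iter`, `converged`, `degenerate`,
#'   `objective` (trace of the fuzzy objective, one value per iteration).
#' @export
fcm_1d <- function(values, C, e = 2, tol = 1e-6, max_iter = 200L, seed = 1L) {
  if (anyNA(values) || any(!is.finite(values))) stopf("`values` must be finite")
  C <- assert_scalar_int(C, "C", min = 2)
  N <- length(values)
  if (N < C) stopf("need at least C data points")
  if (!(e > 1)) stopf("fuzziness `e` must be > 1")

  if (diff(range(values)) == 0) {
    return(structure(list(centers = rep(values[1], C),
                          memberships = matrix(1 / C, N, C),
                          n_iter = 0L, converged = TRUE, degenerate = TRUE,
                          objective = numeric(0)),
                     class = "fcm_result"))
  }

  with_seed_or_stream(seed, {
    mu <- matrix(stats::runif(N * C), N, C)
    mu <- mu / rowSums(mu)
    expo <- 2 / (e - 1)
    objective <- numeric(0)
    converged <- FALSE
    it <- 0L
    centers <- rep(NA_real_, C)
    while (it < max_iter) {
      it <- it + 1L
      mue <- mu^e
      centers <- colSums(mue * values) / colSums(mue)
      D <- abs(outer(values, centers, "-"))
      objective <- c(objective, sum(mue * D^2))
      mu_new <- matrix(0, N, C)
      zero <- D < .Machine$double.eps
      exact <- rowSums(zero) > 0
      if (any(exact))  # membership 1 split across coinciding centers
        mu_new[exact, ] <- zero[exact, , drop = FALSE] /
          rowSums(zero[exact, , drop = FALSE])
      if (any(!exact)) {
        Dn <- D[!exact, , drop = FALSE]
        inv <- Dn^(-expo)
        mu_new[!exact, ] <- inv / rowSums(inv)
      }
      delta <- max(abs(mu_new - mu))
      mu <- mu_new
      if (delta < tol) { converged <- TRUE; break }
    }
    structure(list(centers = centers, memberships = mu, n_iter = it,
                   converged = converged, degenerate = FALSE,
                   objective = objective),
              class = "fcm_result")
  })
}

#' Fuzzy-entropy score of a single feature
#'
#' Clusters the feature's values with [fcm_1d()] (one cluster per class),
#' forms the cluster mass distribution `lambda_c` as the normalized mean
#' membership of each cluster over all samples, and returns the fuzzy
#' entropy `Fe = -sum(lambda_c log lambda_c)` together with the crispness
#' (mean maximum membership), which measures how decisively samples commit
#' to a cluster. Degenerate (constant) features score `Fe = log(C)` --
#' maximal uncertainty -- with crispness `1/C`.
#'
#' @param feature_values Numeric vector of length `N`.
#' @param labels Integer class labels (used only for the class count `C`).
#' @param e Fuzziness exponent; default 2.
#' @param seed Seed passed to [fcm_1d()].
#' @return An `entropy_score` list: `Fe` (in `[0, log C]`), `crispness`
#'   (in `[1/C, 1]`), `degenerate`.
#' @export
fuzzy_entropy_score <- function(feature_values, labels, e = 2, seed = 1L) {
  C <- length(unique(labels))
  if (C < 2) stopf("need at least two classes present")
  if (length(feature_values) != length(labels))
    stopf("`feature_values` and `labels` lengths differ")
  fit <- fcm_1d(feature_values, C = C, e = e, seed = seed)
  if (fit$degenerate) {
    return(structure(list(Fe = log(C), crispness = 1 / C, degenerate = TRUE),
                     class = "entropy_score"))
  }
  lambda <- colMeans(fit$memberships)
  lambda <- lambda / sum(lambda)
  structure(list(Fe = shannon_entropy(lambda),
                 crispness = mean(apply(fit$memberships, 1, max)),
                 degenerate = FALSE),
            class = "entropy_score")
}

#' Refine a PFA-selected mask by fuzzy entropy
#'
#' Scores every selected feature with [fuzzy_entropy_score()] and keeps the
#' `ceiling(rho * n_selected)` best-ranked ones: features are ranked by
#' crispness (descending) with fuzzy entropy (ascending) as tie-break, so
#' crisply clustered features survive and diffuse ones are dropped. The
#' output mask is always a subset of the input mask and never empty;
#' `rho = 1` returns the input unchanged. The default
#' `rho = 1467/2048` reproduces the full-scale reduction from 2,048
#' extracted deep features to 1,467 retained ones.
#'
#' @param data A [feature_matrix()].
#' @param mask Logical input mask (at least one `TRUE`).
#' @param rho Retain fraction in `(0, 1]`; default `1467/2048`.
#' @param e Fuzziness exponent; default 2.
#' @param seed Seed forwarded to the per-feature FCM runs.
#' @return A list of class `refine_result`: `mask` (the refined logical
#'   mask), `scores` (data frame with one row per input-selected feature:
#'   `feature`, `Fe`, `crispness`, `kept`).
#' @export
refine_selection <- function(data, mask, rho = 1467 / 2048, e = 2, seed = 1L) {
  if (!inherits(data, "feature_matrix")) stopf("`data` must be a feature_matrix")
  mask <- as.logical(mask)
  if (length(mask) != ncol(data$values)) stopf("mask length must equal d")
  if (!any(mask)) stopf("input mask must select at least one feature")
  if (!(rho > 0 && rho <= 1)) stopf("`rho` must lie in (0, 1]")

  sel <- which(mask)
  scores <- lapply(sel, function(j)
    fuzzy_entropy_score(data$values[, j], data$labels, e = e, seed = seed))
  Fe <- vapply(scores, `[[`, numeric(1), "Fe")
  crisp <- vapply(scores, `[[`, numeric(1), "crispness")
  n_keep <- max(1L, as.integer(ceiling(rho * length(sel))))
  ord <- order(-crisp, Fe, sel)  # crispness desc, Fe asc, index as final tie-break
  keep <- sel[ord[seq_len(n_keep)]]
  out <- logical(length(mask))
  out[keep] <- TRUE
  structure(list(mask = out,
                 scores = data.frame(feature = sel, Fe = Fe, crispness = crisp,
                                     kept = sel %in% keep)),
            class = "refine_result")
}

#' Run the full two-stage FEcPFA selector
#'
#' Stage one selects features with [run_pfa()]; stage two refines the mask
#' with [refine_selection()].
#'
#' @param data A [feature_matrix()].
#' @param cfg A [pfa_config()].
#' @param rho Retain fraction for the refinement stage.
#' @param e Fuzziness exponent.
#' @return A list with `pfa` (the `pfa_result`), `refined` (the
#'   `refine_result`) and `mask` (the final logical mask).
#' @export
run_fecpfa <- function(data, cfg = pfa_config(), rho = 1467 / 2048, e = 2) {
  pfa <- run_pfa(data, cfg)
  refined <- refine_selection(data, pfa$mask, rho = rho, e = e, seed = cfg$seed)
  list(pfa = pfa, refined = refined, mask = refined$mask)
}
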