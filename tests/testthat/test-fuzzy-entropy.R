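test_that("Shannon entropy matches closed forms and validates input", {
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), log(4))
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2))
  expect_error(shannon_entropy(c(-0.1, 1.1)), "nonnegative")
  expect_error(shannon_entropy(c(0.3, 0.3)), "sum to 1")
})

test_that("1-D fuzzy C-means recovers well-separated clusters and keeps its guarantees", {
  fit <- fcm_1d(c(0, 0, 10, 10), C = 2, e = 2, seed = 1)
  expect_equal(sort(fit$centers), c(0, 10), tolerance = 1e-3)
  expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
  own <- apply(fit$memberships, 1, max)
  expect_true(all(own > 0.99))
  expect_true(all(diff(fit$objective) <= 1e-9))     # alternating minimization
  expect_true(fit$converged)

  # independent oracles: exhaustive grid on the closed-form e=2 objective,
  # and e1071's fuzzy clustering on the same input
  vals <- c(0, 0.5, 4.5, 5, 6, 10)
  fit2 <- fcm_1d(vals, C = 2, e = 2, seed = 2)
  grid <- fcm2_grid_oracle(vals)
  expect_equal(sort(fit2$centers), sort(grid$centers), tolerance = 0.05)
  cm <- e1071::cmeans(matrix(c(0, 0, 10, 10)), centers = 2, m = 2)
  expect_equal(sort(fit$centers), sort(as.numeric(cm$centers)), tolerance = 1e-2)

  # a point equidistant from both converged centers splits its membership
  fit3 <- fcm_1d(c(0, 0, 5, 10, 10), C = 2, e = 2, seed = 3)
  mid <- which.min(abs(c(0, 0, 5, 10, 10) - 5))
  expect_equal(fit3$memberships[mid, 1], 0.5, tolerance = 0.05)

  # a point sitting exactly on a center gets full membership there
  fit4 <- fcm_1d(c(0, 0, 0, 10, 10, 10), C = 2, e = 2, seed = 4)
  expect_true(max(fit4$memberships[1, ]) > 0.999)

  # constant input: degenerate flag, no exception
  fit5 <- fcm_1d(rep(3, 8), C = 2, seed = 5)
  expect_true(fit5$degenerate)
  expect_true(all(abs(rowSums(fit5$memberships) - 1) < 1e-9))

  expect_error(fcm_1d(c(1, 2), C = 3), "at least C")
  expect_error(fcm_1d(1:5, C = 2, e = 1), "fuzziness")
})

test_that("fuzzy entropy scores are bounded and rank crisp structure above noise", {
  withr::with_seed(11, {
    labels <- rep(0:1, each = 40)
    for (i in 1:10) {
      s <- fuzzy_entropy_score(rnorm(80), labels, seed = i)
      expect_gte(s$Fe, 0)
      expect_lte(s$Fe, log(2) + 1e-12)
    }
    # strongly bimodal features are crisper than pure-noise ones on average
    crisp_bi <- replicate(15, {
      x <- c(rnorm(40, -3), rnorm(40, 3))
      fuzzy_entropy_score(x, labels, seed = 1)$crispness
    })
    crisp_noise <- replicate(15, fuzzy_entropy_score(rnorm(80), labels,
                                                     seed = 1)$crispness)
    expect_gt(mean(crisp_bi), mean(crisp_noise))
  })

  # degenerate feature scores maximal uncertainty by convention
  s <- fuzzy_entropy_score(rep(1, 30), rep(0:2, 10), seed = 1)
  expect_equal(s$Fe, log(3))
  expect_true(s$degenerate)
})

test_that("refinement keeps the requested fraction, subsets the input, never empties", {
  sim <- study_data(seed = 1)
  full <- rep(TRUE, 200)

  same <- refine_selection(sim$data, full, rho = 1, seed = 1)
  expect_identical(same$mask, full)                 # rho = 1 is the identity
  again <- refine_selection(sim$data, same$mask, rho = 1, seed = 1)
  expect_identical(again$mask, same$mask)           # idempotent at rho = 1

  half <- refine_selection(sim$data, full, rho = 0.5, seed = 1)
  expect_equal(sum(half$mask), 100)
  expect_true(all(which(half$mask) %in% which(full)))

  sparse <- logical(200); sparse[c(3, 17, 99)] <- TRUE
  one <- refine_selection(sim$data, sparse, rho = 0.01, seed = 1)
  expect_equal(sum(one$mask), 1)                    # never empty
  expect_true(all(which(one$mask) %in% which(sparse)))

  expect_equal(nrow(half$scores), 200)
  expect_identical(half$scores$kept, half$mask[half$scores$feature])

  expect_error(refine_selection(sim$data, full, rho = 0), "rho")
  expect_error(refine_selection(sim$data, logical(200)), "at least one")
})
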