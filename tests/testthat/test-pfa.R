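test_that("binarize thresholds at 0.5 strictly with a non-empty fallback", {
  expect_equal(binarize(rep(0.9, 4)), rep(TRUE, 4))
  low <- binarize(c(0.1, 0.3, 0.2))
  expect_equal(low, c(FALSE, TRUE, FALSE))        # argmax fallback
  expect_equal(binarize(c(0.4, 0.6, 0.5)), c(FALSE, TRUE, FALSE))  # strict >
  expect_equal(sum(binarize(rep(0.1, 5))), 1)
  expect_equal(binarize(c(0.2, 0.2, 0.2)), c(TRUE, FALSE, FALSE))  # tie -> lowest index
  expect_error(binarize(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("the cost decomposes exactly as weighted error plus feature fraction", {
  sim <- tiny_data()
  cfg <- pfa_config(seed = 2)
  d <- ncol(sim$data$values)
  withr::with_seed(3, {
    for (i in 1:25) {
      mask <- runif(d) > runif(1, 0.2, 0.8)
      if (!any(mask)) mask[1] <- TRUE
      rec <- fitness(mask, sim$data, cfg)
      expect_lt(abs(rec$cost - 0.94 * rec$error - 0.014 * sum(mask) / d), 1e-12)
      expect_equal(rec$error, 1 - rec$accuracy)
      expect_equal(rec$n_selected, sum(mask))
    }
  })
  # perfectly separable data with every feature: error 0, cost = 0.014
  sep <- feature_matrix(rbind(matrix(0, 10, 3), matrix(100, 10, 3)),
                        rep(0:1, each = 10))
  rec <- fitness(rep(TRUE, 3), sep, cfg)
  expect_equal(rec$accuracy, 1)
  expect_equal(rec$cost, 0.014)
  expect_error(fitness(rep(FALSE, 3), sep, cfg), "at least one")
})

test_that("leader and follower updates degenerate exactly as the equations dictate", {
  d <- 8
  leader <- seq(0.1, 0.8, length.out = d)
  prev <- rev(leader)
  # zeroed randomness: leader is stationary
  expect_equal(pathfinder_update(leader, prev, k = 3, k_max = 10,
                                 r3 = rep(0, d), u2 = rep(0, d)), leader)
  # forced u2 = 1 at k = k_max: fluctuation is exactly e^{-2}
  moved <- pathfinder_update(leader, leader, k = 10, k_max = 10,
                             r3 = rep(0, d), u2 = rep(1, d))
  expect_equal(moved, pmin(1, leader + exp(-2)))

  xi <- seq(0.2, 0.9, length.out = d); xj <- rev(xi); xp <- rep(0.5, d)
  # zeroed randomness: follower is stationary
  expect_equal(follower_update(xi, xj, xp, k = 2, k_max = 10, alpha = 1.5,
                               beta = 1.5, r1 = rep(0, d), r2 = rep(0, d),
                               u1 = rep(0, d)), xi)
  # vibration vanishes at the last iteration whatever u1 is
  a <- follower_update(xi, xj, xp, k = 10, k_max = 10, alpha = 1.2, beta = 1.8,
                       r1 = rep(0.3, d), r2 = rep(0.4, d), u1 = rep(1, d))
  b <- follower_update(xi, xj, xp, k = 10, k_max = 10, alpha = 1.2, beta = 1.8,
                       r1 = rep(0.3, d), r2 = rep(0.4, d), u1 = rep(0, d))
  expect_equal(a, b)
  # coincident member, neighbour and leader: fixed point
  z <- rep(0.4, d)
  expect_equal(follower_update(z, z, z, k = 2, k_max = 10, alpha = 2, beta = 2),
               z)

  # positions stay inside the unit box under arbitrary updates
  withr::with_seed(9, {
    for (i in 1:1000) {
      lead <- runif(5); prv <- runif(5)
      out <- pathfinder_update(lead, prv, k = sample(10, 1), k_max = 10)
      expect_true(all(out >= 0 & out <= 1))
      out2 <- follower_update(runif(5), runif(5), runif(5), k = sample(10, 1),
                              k_max = 10, alpha = runif(1, 1, 2),
                              beta = runif(1, 1, 2))
      expect_true(all(out2 >= 0 & out2 <= 1))
    }
  })
})

test_that("the full PFA run is elitist, deterministic, and validates its inputs", {
  sim <- tiny_data()
  cfg <- pfa_config(swarm_size = 8, max_iter = 10, seed = 4)
  res <- run_pfa(sim$data, cfg)
  expect_s3_class(res, "pfa_result")
  expect_length(res$history, 11)                 # initial evaluation + 10 iterations
  expect_true(all(diff(res$history) <= 0))       # elitist best-so-far
  expect_true(any(res$mask))
  expect_lt(abs(res$record$cost -
                0.94 * res$record$error -
                0.014 * res$record$n_selected / ncol(sim$data$values)), 1e-12)

  res2 <- run_pfa(sim$data, cfg)
  expect_identical(res$mask, res2$mask)
  expect_identical(res$history, res2$history)

  # different seeds explore differently
  res3 <- run_pfa(sim$data, pfa_config(swarm_size = 8, max_iter = 10, seed = 5))
  expect_false(identical(res$history, res3$history))

  one_class <- feature_matrix(matrix(rnorm(40), 10, 4), rep(0L, 10))
  expect_error(run_pfa(one_class, cfg), "two classes")
})

test_that("PFA recovers planted features and beats the all-features baseline", {
  sim <- study_data(seed = 1)
  cfg <- pfa_config(swarm_size = 12, max_iter = 15, seed = 1)
  res <- run_pfa(sim$data, cfg)
  recall <- sum(res$mask & sim$truth$informative_mask) /
    sum(sim$truth$informative_mask)
  expect_gt(recall, 0.5)   # scaled-down run; the acceptance suite runs full scale
  all_cost <- fitness(rep(TRUE, 200), sim$data, cfg)$cost
  expect_lte(res$record$cost, all_cost)
  expect_lt(res$record$n_selected, 200)
})
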