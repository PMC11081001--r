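test_that("row softmax matches closed forms and is shift-invariant and stable", {
  expect_equal(row_softmax(matrix(0, 2, 2)), matrix(0.5, 2, 2))
  expect_equal(row_softmax(matrix(c(log(2), 0), 1, 2)),
               matrix(c(2 / 3, 1 / 3), 1, 2))
  withr::with_seed(1, {
    for (i in 1:20) {
      P <- matrix(runif(30, -50, 50), 5, 6)
      S <- row_softmax(P)
      expect_true(all(abs(rowSums(S) - 1) < 1e-9))
      # entries live in (0,1); the upper end may round to 1 in double
      # precision when one score dominates a row by ~700 nats
      expect_true(all(S > 0 & S <= 1))
      P2 <- P; P2[3, ] <- P2[3, ] + 123.4   # shift one row by a constant
      expect_equal(row_softmax(P2)[3, ], S[3, ], tolerance = 1e-12)
    }
  })
  expect_error(row_softmax(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(row_softmax(matrix(c(1, Inf), 1, 2)), "finite")
})

test_that("self-attention agrees with brute-force loops and behaves at the limits", {
  withr::with_seed(2, {
    for (i in 1:50) {
      X <- matrix(rnorm(25), 5, 5); Y <- matrix(rnorm(25), 5, 5)
      V <- matrix(rnorm(15), 5, 3)
      got <- self_attention(X, Y, V)
      want <- brute_attention(X, Y, V)
      expect_lt(max(abs(got$AM - want$AM)), 1e-10)
      expect_lt(max(abs(got$SMP - want$SMP)), 1e-10)
      # convex-combination bounds: AM rows within column ranges of V
      expect_true(all(got$AM <= matrix(apply(V, 2, max), 5, 3, byrow = TRUE) + 1e-12))
      expect_true(all(got$AM >= matrix(apply(V, 2, min), 5, 3, byrow = TRUE) - 1e-12))
      # permutation equivariance in V's columns
      perm <- sample(3)
      expect_equal(self_attention(X, Y, V[, perm])$AM, got$AM[, perm])
    }
  })

  # uniform attention: zero scores average the value rows
  V <- matrix(1:12, 4, 3) * 0.1
  am0 <- self_attention(matrix(0, 4, 4), matrix(0, 4, 4), V)$AM
  expect_equal(am0, matrix(colMeans(V), 4, 3, byrow = TRUE))

  # saturated diagonal: each row attends to its own value row
  P_big <- diag(1000, 4)
  amI <- row_softmax(P_big) %*% V
  expect_lt(max(abs(amI - V)), 1e-6)

  expect_error(self_attention(matrix(0, 3, 3), matrix(0, 2, 2), V), "equal size")
  expect_error(self_attention(matrix(0, 4, 4), matrix(0, 4, 4), matrix(0, 3, 2)),
               "T rows")
})

test_that("attention head honours the 2,048-feature contract and its degeneracies", {
  cfg <- attention_config(input_dim = 64, feature_dim = 2048, seq_len = 32, seed = 3)
  x <- withr::with_seed(4, rnorm(64))
  out <- attention_head(x, cfg)
  expect_length(out, 2048)
  expect_identical(out, attention_head(x, cfg))  # deterministic given weights

  cfg2 <- attention_config(input_dim = 64, feature_dim = 2048, seq_len = 32, seed = 3)
  expect_identical(attention_head(x, cfg2), out) # same seed, same weights

  zero_cfg <- attention_config(64, 2048, 32,
                               Wq = matrix(0, 64, 1024),
                               Wk = matrix(0, 64, 1024),
                               Wv = matrix(0, 64, 2048))
  expect_equal(attention_head(x, zero_cfg), rep(0, 2048))

  X <- withr::with_seed(5, matrix(rnorm(3 * 64), 3, 64))
  M <- attention_head(X, cfg)
  expect_equal(dim(M), c(3, 2048))
  expect_equal(M[2, ], attention_head(X[2, ], cfg))

  expect_error(attention_head(rnorm(10), cfg), "input_dim")
  expect_error(attention_config(64, feature_dim = 100, seq_len = 32), "divide")
})

test_that("ResNet-Self forward pass is deterministic and emits 2,048 features", {
  model <- build_resnet_self(seed = 1)
  imgs <- withr::with_seed(6, replicate(2, array(runif(64 * 64 * 3), c(64, 64, 3)),
                                        simplify = FALSE))
  f1 <- extract_features(model, imgs)
  expect_equal(dim(f1), c(2, 2048))
  expect_true(all(is.finite(f1)))
  f2 <- extract_features(model, imgs, batch_size = 1)  # chunking must not matter
  expect_identical(f1, f2)
  # grayscale input goes through channel replication
  g <- extract_features(model, list(matrix(0.5, 64, 64)))
  expect_equal(dim(g), c(1, 2048))
  expect_error(extract_features(model, list(matrix(0.5, 8, 8))), "at least 32")
})
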