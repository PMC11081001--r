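# Shared fixtures and independent oracles for the test suite.

# Small labeled dataset used across selector tests (4 classes, planted
# signal). Built once; tests must not mutate it.
study_data <- function(seed = 1) {
  make_gaussian_feature_data(n_per_class = 50, n_classes = 4, d = 200,
                             d_informative = 20, effect_size = 3, seed = seed)
}

tiny_data <- function(seed = 1) {
  make_gaussian_feature_data(n_per_class = 15, n_classes = 3, d = 20,
                             d_informative = 6, effect_size = 3, seed = seed)
}

random_image <- function(h, w, rgb = FALSE, seed = 1) {
  withr::with_seed(seed, {
    if (rgb) as_image_grid(array(runif(h * w * 3), c(h, w, 3)))
    else as_image_grid(matrix(runif(h * w), h, w))
  })
}

# Brute-force self-attention: explicit double loops, independent of the
# vectorized implementation.
brute_attention <- function(X, Y, V) {
  Tn <- nrow(X); J <- ncol(V)
  P <- matrix(0, Tn, Tn)
  for (i in seq_len(Tn)) for (j in seq_len(Tn))
    P[i, j] <- sum(X[i, ] * Y[j, ])
  SMP <- matrix(0, Tn, Tn)
  for (i in seq_len(Tn)) {
    e <- exp(P[i, ] - max(P[i, ]))
    SMP[i, ] <- e / sum(e)
  }
  AM <- matrix(0, Tn, J)
  for (i in seq_len(Tn)) for (j in seq_len(J))
    AM[i, j] <- sum(SMP[i, ] * V[, j])
  list(P = P, SMP = SMP, AM = AM)
}

# Textbook-formula metrics oracle, computed by a different route than the
# package: per-class tallies via explicit loops, kappa via e1071's
# agreement coefficient, MCC as the Pearson correlation between the
# flattened one-hot true/predicted indicator matrices (the definition the
# Gorodkin form generalizes).
oracle_report <- function(cm) {
  C <- nrow(cm); s <- sum(cm)
  acc <- sum(diag(cm)) / s
  prec <- rec <- f1 <- numeric(C)
  for (k in seq_len(C)) {
    tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
    prec[k] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[k] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[k] <- if (prec[k] + rec[k] == 0) 0 else 2 * prec[k] * rec[k] / (prec[k] + rec[k])
  }
  kappa <- e1071::classAgreement(cm)$kappa
  # reconstruct label pairs and correlate indicator matrices
  yt <- rep(rep(seq_len(C), C), times = as.vector(t(cm)))
  yp <- rep(rep(seq_len(C), each = C), times = as.vector(t(cm)))
  It <- diag(C)[yt, , drop = FALSE]
  Ip <- diag(C)[yp, , drop = FALSE]
  num <- sum((It - matrix(colMeans(It), s, C, byrow = TRUE)) *
               (Ip - matrix(colMeans(Ip), s, C, byrow = TRUE)))
  vt <- sum(scale(It, scale = FALSE)^2)
  vp <- sum(scale(Ip, scale = FALSE)^2)
  mcc <- if (vt == 0 || vp == 0) 0 else num / sqrt(vt * vp)
  list(accuracy = acc, precision_macro = mean(prec), recall_macro = mean(rec),
       f1_macro = mean(f1), kappa = kappa, mcc = mcc)
}

# Closed-form fuzzy C-means objective for e = 2 with fixed centers: the
# optimal memberships give J(centers) = sum_i 1 / sum_j D_ij^{-2}. Grid
# search over center pairs is an independent oracle for fcm_1d at C = 2.
fcm2_grid_oracle <- function(values, grid_n = 201) {
  grid <- seq(min(values), max(values), length.out = grid_n)
  best <- list(J = Inf)
  for (a in grid) for (b in grid) {
    if (a >= b) next
    D2 <- cbind((values - a)^2, (values - b)^2)
    D2 <- pmax(D2, 1e-300)
    J <- sum(1 / (1 / D2[, 1] + 1 / D2[, 2]))
    if (J < best$J) best <- list(J = J, centers = c(a, b))
  }
  best
}

# Stratified 5-fold KNN CV accuracy, written directly in the test suite
# (independent of the package's fitness path).
cv_knn_accuracy <- function(values, labels, k = 5, seed = 1) {
  withr::with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(1:5, length(idx))
    }
    correct <- 0
    for (f in 1:5) {
      te <- fold == f
      pred <- class::knn(values[!te, , drop = FALSE], values[te, , drop = FALSE],
                         factor(labels[!te]), k = k)
      correct <- correct + sum(pred == factor(labels[te]))
    }
    correct / length(labels)
  })
}
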