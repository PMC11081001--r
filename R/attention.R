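# Query/key/value self-attention head. A flattened feature vector is
# projected into a square query matrix X, a square key matrix Y and a value
# matrix V; correlation scores P = X Y^T are converted to a row-stochastic
# attention map by softmax and applied to V. The attended map, flattened,
# is the extracted feature vector (2,048 long by default).

#' Numerically stable row-wise softmax
#'
#' `SM(P)[i,j] = exp(P[i,j]) / sum_j exp(P[i,j])`, computed with per-row
#' maximum subtraction so that large scores do not overflow. Every output
#' row sums to 1.
#'
#' @param P Numeric matrix with finite entries.
#' @return A row-stochastic matrix of the same shape.
#' @examples
#' row_softmax(matrix(0, 2, 2))  # uniform rows
#' @export
row_softmax <- function(P) {
  if (!is.matrix(P) || length(P) == 0) stopf("`P` must be a non-empty matrix")
  if (anyNA(P) || any(!is.finite(P))) stopf("`P` must be finite")
  z <- exp(P - apply(P, 1, max))
  z / rowSums(z)
}

#' Self-attention map
#'
#' Computes correlation scores `P = X %*% t(Y)`, the row-stochastic softmax
#' `SMP`, and the attended output `AM = SMP %*% V`. Each row of `AM` is a
#' convex combination of the rows of `V`.
#'
#' @param X,Y Square `T x T` query/key matrices of equal size.
#' @param V `T x J` value matrix.
#' @return A list of class `attention_map` with elements `P`, `SMP`, `AM`.
#' @export
self_attention <- function(X, Y, V) {
  if (!is.matrix(X) || !is.matrix(Y) || !is.matrix(V))
    stopf("X, Y, V must be matrices")
  if (nrow(X) != ncol(X) || !all(dim(X) == dim(Y)))
    stopf("X and Y must be square and of equal size")
  if (nrow(V) != nrow(X)) stopf("V must have T rows")
  if (anyNA(c(X, Y, V)) || any(!is.finite(c(X, Y, V))))
    stopf("attention inputs must be finite")
  P <- X %*% t(Y)
  SMP <- row_softmax(P)
  structure(list(P = P, SMP = SMP, AM = SMP %*% V), class = "attention_map")
}

#' Self-attention head configuration
#'
#' Defines the three linear projections that turn a flattened input vector
#' of length `input_dim` into the query (`T x T`), key (`T x T`) and value
#' (`T x J`) matrices, with `J = feature_dim / seq_len`. Projection weights
#' may be supplied; otherwise they are drawn `N(0, 1/input_dim)` under
#' `seed`. The head is used untrained: it is a fixed random feature
#' projection whose output length honours the `feature_dim` contract.
#'
#' @param input_dim Length of the flattened input vector.
#' @param feature_dim Output feature length; default 2048.
#' @param seq_len Attention sequence length `T`; default 32. Must divide
#'   `feature_dim`.
#' @param Wq,Wk Optional `input_dim x seq_len^2` projection matrices.
#' @param Wv Optional `input_dim x feature_dim` projection matrix.
#' @param seed Seed for randomly drawn projections.
#' @return An `attention_config` object.
#' @export
attention_config <- function(input_dim, feature_dim = 2048L, seq_len = 32L,
                             Wq = NULL, Wk = NULL, Wv = NULL, seed = 1L) {
  input_dim <- assert_scalar_int(input_dim, "input_dim", min = 1)
  feature_dim <- assert_scalar_int(feature_dim, "feature_dim", min = 1)
  seq_len <- assert_scalar_int(seq_len, "seq_len", min = 1)
  if (feature_dim %% seq_len != 0) stopf("`seq_len` must divide `feature_dim`")
  J <- feature_dim %/% seq_len
  draw <- function(nc) matrix(stats::rnorm(input_dim * nc, sd = 1 / sqrt(input_dim)),
                              input_dim, nc)
  if (is.null(Wq) || is.null(Wk) || is.null(Wv)) {
    rand <- with_seed_or_stream(seed, list(q = draw(seq_len^2), k = draw(seq_len^2),
                                           v = draw(seq_len * J)))
    if (is.null(Wq)) Wq <- rand$q
    if (is.null(Wk)) Wk <- rand$k
    if (is.null(Wv)) Wv <- rand$v
  }
  chk <- function(W, nc, nm) {
    if (!is.matrix(W) || nrow(W) != input_dim || ncol(W) != nc)
      stopf("`%s` must be %d x %d", nm, input_dim, nc)
    W
  }
  structure(list(input_dim = input_dim, feature_dim = feature_dim,
                 seq_len = seq_len, J = J,
                 Wq = chk(Wq, seq_len^2, "Wq"), Wk = chk(Wk, seq_len^2, "Wk"),
                 Wv = chk(Wv, seq_len * J, "Wv")),
            class = "attention_config")
}

#' Extract attended features from a flattened input
#'
#' Projects the input through the configured query/key/value maps, applies
#' [self_attention()], and flattens the attended map to a vector of length
#' `cfg$feature_dim`. Deterministic given the configuration's weights.
#'
#' @param features Numeric vector of length `cfg$input_dim`, or a matrix
#'   with that many columns (one sample per row).
#' @param cfg An [attention_config()].
#' @return A feature vector of length `cfg$feature_dim`, or a matrix
#'   `n x feature_dim` for matrix input.
#' @export
attention_head <- function(features, cfg) {
  if (!inherits(cfg, "attention_config")) stopf("`cfg` must be an attention_config")
  if (is.matrix(features)) {
    out <- t(apply(features, 1, attention_head, cfg = cfg))
    dimnames(out) <- NULL
    return(out)
  }
  if (length(features) != cfg$input_dim)
    stopf("input length %d != input_dim %d", length(features), cfg$input_dim)
  Tn <- cfg$seq_len
  f <- as.numeric(features)
  X <- matrix(drop(f %*% cfg$Wq), Tn, Tn)
  Y <- matrix(drop(f %*% cfg$Wk), Tn, Tn)
  V <- matrix(drop(f %*% cfg$Wv), Tn, cfg$J)
  as.numeric(self_attention(X, Y, V)$AM)
}
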