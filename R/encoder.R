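softmax_rows <- function(s) {
  mx <- apply(s, 1L, max)
  e <- exp(s - mx)
  e / rowSums(e)
}

layernorm_rows <- function(x, gain, bias, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd_ <- sqrt(rowMeans(xc^2) + eps)
  sweep(sweep(xc / sd_, 2L, as.vector(gain), "*"), 2L, as.vector(bias), "+")
}

relu <- function(x) x * (x > 0)

NEG_INF <- -1e30

#' Multi-head self-attention
#'
#' Per head, queries/keys/values are affine maps of the input rows
#' (q = W_Q x + b_Q etc.); scaled dot-product scores are softmaxed per row
#' and applied to the values; head outputs are concatenated and mixed by
#' W_o. The scaling factor is `1/sqrt(d_k)` by default, with `1/d_k`
#' selectable.
#'
#' Padding: positions with `mask = FALSE` neither attend nor are attended to
#' (their score columns are driven to -Inf); their output rows are zeroed,
#' so a padded-and-masked sequence gives the same unpadded rows as the
#' unpadded forward pass.
#'
#' @param x n x d_e input matrix (rows are positions).
#' @param layer layer parameters: `heads` (list of `W_Q,b_Q,W_K,b_K,W_V,b_V`,
#'   each map d_e x d_k applied as `x %*% W`), and `W_o` ((h*d_k) x d_e).
#' @param scale_mode `"sqrt"` for 1/sqrt(d_k) (default) or `"linear"` for
#'   1/d_k.
#' @param mask optional logical vector, FALSE marking padded positions.
#' @return n x d_e matrix of attended representations.
#' @export
self_attention <- function(x, layer, scale_mode = c("sqrt", "linear"),
                           mask = NULL) {
  scale_mode <- match.arg(scale_mode)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite values in input")
  n <- nrow(x)
  d_k <- ncol(layer$heads[[1L]]$W_Q)
  scale <- if (scale_mode == "sqrt") 1 / sqrt(d_k) else 1 / d_k
  heads <- lapply(layer$heads, function(h) {
    q <- sweep(x %*% h$W_Q, 2L, as.vector(h$b_Q), "+")
    k <- sweep(x %*% h$W_K, 2L, as.vector(h$b_K), "+")
    v <- sweep(x %*% h$W_V, 2L, as.vector(h$b_V), "+")
    s <- (q %*% t(k)) * scale
    if (!is.null(mask)) s[, !mask] <- NEG_INF
    softmax_rows(s) %*% v
  })
  out <- do.call(cbind, heads) %*% layer$W_o
  if (!is.null(mask)) out[!mask, ] <- 0
  out
}

#' Encoder block: self-attention, feed-forward, layer normalisation
#'
#' Computes `A = self_attention(x)`, the position-wise feed-forward
#' `FFN(A) = relu(A W_F1 + b_F1) W_F2 + b_F2`, and returns
#' `LayerNorm(A + FFN(A))` — a single residual around the feed-forward, the
#' form the model defines. `residual = "standard"` selects the conventional
#' two-residual variant `LayerNorm(LayerNorm(x + A) + FFN(.))`.
#'
#' @inheritParams self_attention
#' @param layer adds `W_F1` (d_e x d_f), `b_F1`, `W_F2` (d_f x d_e), `b_F2`,
#'   `ln_gain`, `ln_bias` (and `ln2_gain`, `ln2_bias` for the standard form).
#' @param residual `"as_printed"` (default) or `"standard"`.
#' @return n x d_e matrix of hidden vectors.
#' @export
encoder_block <- function(x, layer, scale_mode = c("sqrt", "linear"),
                          residual = c("as_printed", "standard"),
                          mask = NULL) {
  residual <- match.arg(residual)
  a <- self_attention(x, layer, scale_mode = scale_mode, mask = mask)
  if (residual == "standard")
    a <- layernorm_rows(x + a, layer$ln2_gain, layer$ln2_bias)
  ffn <- sweep(relu(sweep(a %*% layer$W_F1, 2L, as.vector(layer$b_F1), "+")) %*%
                 layer$W_F2, 2L, as.vector(layer$b_F2), "+")
  h <- layernorm_rows(a + ffn, layer$ln_gain, layer$ln_bias)
  if (!is.null(mask)) h[!mask, ] <- 0
  h
}

day_agg_scores <- function(h, params, mask = NULL) {
  n <- nrow(h)
  last <- if (is.null(mask)) n else max(which(mask))
  hk <- h[rep(last, n), , drop = FALSE]
  z <- cbind(h, hk)
  hid <- relu(sweep(z %*% params$W1, 2L, as.vector(params$b1), "+"))
  as.vector(sweep(hid %*% params$W2, 2L, as.vector(params$b2), "+"))
}

#' Attention-weighted aggregation of the day sequence
#'
#' Scores every day's hidden vector against the last day's with a small MLP
#' on the concatenated pair, converts scores to weights, and returns the
#' weighted sum. Weights are a softmax over the MLP scores by default (the
#' exponentiate-then-normalise realisation of the score-ratio definition);
#' `literal_ratio = TRUE` uses the raw ratio e_k / sum(e_i) instead.
#'
#' @param h K x d_e matrix of per-day hidden vectors.
#' @param params list with `W1` (2 d_e x d_e), `b1`, `W2` (d_e x 1), `b2`.
#' @param literal_ratio use raw score ratios instead of softmax.
#' @param mask optional logical vector, FALSE marking padded days (excluded
#'   from the weights; the "last day" is the last unmasked one).
#' @return list with `z` (length-d_e vector) and `weights` (length-K, zeros
#'   at padded positions).
#' @export
aggregate_days <- function(h, params, literal_ratio = FALSE, mask = NULL) {
  if (!is.matrix(h)) h <- matrix(h, nrow = 1L)
  e <- day_agg_scores(h, params, mask = mask)
  keep <- if (is.null(mask)) rep(TRUE, nrow(h)) else mask
  w <- numeric(nrow(h))
  if (literal_ratio) {
    w[keep] <- e[keep] / sum(e[keep])
  } else {
    ex <- exp(e[keep] - max(e[keep]))
    w[keep] <- ex / sum(ex)
  }
  list(z = as.vector(t(w) %*% h), weights = w)
}

#' Average-pooled aggregation of history hidden states
#'
#' Arithmetic mean of the non-padding hidden vectors of the history
#' encoder.
#'
#' @param h n x d_e matrix of per-word hidden vectors.
#' @param mask optional logical vector, FALSE marking padding.
#' @return length-d_e numeric vector.
#' @export
aggregate_history <- function(h, mask = NULL) {
  if (!is.matrix(h)) h <- matrix(h, nrow = 1L)
  if (!is.null(mask)) h <- h[mask, , drop = FALSE]
  if (nrow(h) == 0L) stop("history has no non-padding positions")
  colMeans(h)
}
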