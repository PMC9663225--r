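#' Frequency vector of observed activities
#'
#' Counts, per activity, the number of observed days containing it (days are
#' sets, so each day contributes at most one), together with the 0/1
#' indicator of having occurred at all. This is the statistic that carries
#' long-term orders — activities issued daily regardless of condition
#' changes — into the final recommendation.
#'
#' @param observed_days nonempty list of activity-id sets.
#' @param n_activities vocabulary size M.
#' @return list with `counts` (length-M integer), `beta` (length-M 0/1), and
#'   `n_days`.
#' @export
frequency_vector <- function(observed_days, n_activities) {
  if (length(observed_days) == 0L) stop("need at least one observed day")
  counts <- integer(n_activities)
  for (d in observed_days) {
    ids <- unique(as.integer(d))
    counts[ids] <- counts[ids] + 1L
  }
  list(counts = counts, beta = as.integer(counts > 0L),
       n_days = length(observed_days))
}

#' Frequency gate
#'
#' Per-activity weight \eqn{\alpha = \sigma(W_p l^p + b_p)} balancing the
#' learned day-branch score against the raw frequency evidence. `W_p` is a
#' per-activity (diagonal) map by default; a full M x M matrix is accepted
#' too.
#'
#' @param l length-M (optionally normalised) frequency vector.
#' @param W_p either a length-M vector (diagonal gate) or an M x M matrix.
#' @param b_p length-M bias.
#' @return length-M vector strictly in (0, 1).
#' @export
gate <- function(l, W_p, b_p) {
  pre <- if (is.matrix(W_p)) as.vector(matrix(l, 1L) %*% W_p) else W_p * l
  as.vector(sigmoid(pre + b_p))
}

#' Gated additive fusion of day, history and frequency information
#'
#' Produces the final per-activity recommendation scores
#' \deqn{\hat y = \sigma\big((1-\alpha)\odot\beta\odot(W_d z^d + b_d)
#'   + \alpha\odot \tilde l^p + \lambda (W_{txt} z^w + b_{txt})\big)}
#' where \eqn{\alpha} is the frequency gate, \eqn{\beta} masks the
#' day-branch scores of never-observed activities, and \eqn{\tilde l^p} is
#' the frequency vector normalised by the number of observed days (raw
#' counts selectable). With `beta_mode = "all_ones"` the day branch reaches
#' every activity regardless of observation.
#'
#' @param z_d length-d_e aggregated day representation.
#' @param z_w length-d_e aggregated history representation, or `NULL` to
#'   omit the history term (the no-history ablation).
#' @param freq output of [frequency_vector()].
#' @param params list with `W_d` (d_e x M), `b_d`, `W_txt` (d_e x M),
#'   `b_txt`, `W_p`, `b_p`.
#' @param lambda weight of the history term.
#' @param counts `"normalized"` (default; counts / n_days, in [0,1]) or
#'   `"raw"`.
#' @param beta_mode `"as_printed"` (default) or `"all_ones"`.
#' @return list with `scores` (length-M, strictly in (0,1)) and `alpha`
#'   (gate values).
#' @export
fuse <- function(z_d, z_w, freq, params, lambda = 0.5,
                 counts = c("normalized", "raw"),
                 beta_mode = c("as_printed", "all_ones")) {
  counts <- match.arg(counts)
  beta_mode <- match.arg(beta_mode)
  l <- if (counts == "normalized") freq$counts / freq$n_days else freq$counts
  alpha <- gate(l, params$W_p, params$b_p)
  beta <- if (beta_mode == "all_ones") rep(1, length(freq$beta)) else freq$beta
  day_term <- as.vector(matrix(z_d, 1L) %*% params$W_d) + as.vector(params$b_d)
  pre <- (1 - alpha) * beta * day_term + alpha * l
  if (!is.null(z_w)) {
    txt <- as.vector(matrix(z_w, 1L) %*% params$W_txt) + as.vector(params$b_txt)
    pre <- pre + lambda * txt
  }
  list(scores = as.vector(sigmoid(pre)), alpha = alpha)
}

#' Total training loss
#'
#' Squared-error recommendation loss plus the weighted generator
#' cross-entropy:
#' \deqn{L = \frac{1}{N}\sum_{i} \lVert y_i - \hat y_i\rVert^2 + \gamma L_g}
#' where the norm is the per-instance sum of squared errors and N is the
#' batch size.
#'
#' @param y multi-hot targets: length-M vector or N x M matrix.
#' @param y_hat matching scores.
#' @param l_g generator cross-entropy loss (scalar; 0 if unused).
#' @param gamma weight of the generator term.
#' @return scalar loss.
#' @export
total_loss <- function(y, y_hat, l_g = 0, gamma = 0.5) {
  if (is.matrix(y) != is.matrix(y_hat) ||
      (is.matrix(y) && !all(dim(y) == dim(y_hat))) ||
      (!is.matrix(y) && length(y) != length(y_hat)))
    stop("shape mismatch between y and y_hat")
  if (!is.matrix(y)) {
    y <- matrix(y, nrow = 1L)
    y_hat <- matrix(y_hat, nrow = 1L)
  }
  mean(rowSums((y - y_hat)^2)) + gamma * l_g
}

#' Top-K recommendation list
#'
#' Ids of the K largest scores, ties broken deterministically by ascending
#' id.
#'
#' @param scores length-M numeric score vector.
#' @param k number of items to return (capped at M).
#' @return integer vector of length min(K, M).
#' @export
top_k <- function(scores, k) {
  if (k < 1L) stop("k must be >= 1")
  ord <- order(-scores, seq_along(scores))
  ord[seq_len(min(k, length(scores)))]
}
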