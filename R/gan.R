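LOG_EPS <- 1e-7

clamp01 <- function(p, eps = LOG_EPS) pmin(pmax(p, eps), 1 - eps)

#' Generator forward pass
#'
#' Maps the aggregated day representation z^d through two linear layers with
#' a ReLU between them and a final fully connected layer with sigmoid
#' output, producing a probability vector over the activity vocabulary (the
#' "generated" next-day activities).
#'
#' @param z length-d_e numeric vector (or 1 x d_e matrix).
#' @param params list with `W1` (d_e x d_e), `b1`, `W2` (d_e x d_e), `b2`,
#'   `W3` (d_e x M), `b3`.
#' @return length-M numeric vector with entries strictly in (0, 1).
#' @export
generator_forward <- function(z, params) {
  z <- matrix(as.numeric(z), nrow = 1L)
  h1 <- relu(z %*% params$W1 + matrix(params$b1, 1L))
  h2 <- h1 %*% params$W2 + matrix(params$b2, 1L)
  as.vector(sigmoid(h2 %*% params$W3 + matrix(params$b3, 1L)))
}

#' Generator cross-entropy loss
#'
#' Mean binary cross-entropy between the generated probability vector and
#' the multi-hot ground truth over the M activities:
#' \deqn{L_g = -\frac{1}{M}\sum_i p_i \log \hat p_i + (1-p_i)\log(1-\hat p_i).}
#' Probabilities are clamped to [eps, 1-eps] so the loss is always finite.
#'
#' @param p_hat length-M vector of generated probabilities.
#' @param y length-M 0/1 multi-hot target.
#' @return scalar loss.
#' @export
generator_ce_loss <- function(p_hat, y) {
  if (length(p_hat) != length(y)) stop("length mismatch between p_hat and y")
  p <- clamp01(p_hat)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Discriminator forward pass
#'
#' Scores an activity vector (a multi-hot ground truth or a generated
#' probability vector) with two ReLU linear layers and a final sigmoid
#' scalar: the estimated probability that the input is real.
#'
#' @param v length-M numeric vector (or a batch as an N x M matrix).
#' @param params list with `W1` (M x H), `b1`, `W2` (H x H), `b2`, `W3`
#'   (H x 1), `b3`.
#' @return numeric vector of realness scores in (0, 1), one per input row.
#' @export
discriminator_forward <- function(v, params) {
  v <- if (is.matrix(v)) v else matrix(as.numeric(v), nrow = 1L)
  h1 <- relu(sweep(v %*% params$W1, 2L, as.vector(params$b1), "+"))
  h2 <- relu(sweep(h1 %*% params$W2, 2L, as.vector(params$b2), "+"))
  as.vector(sigmoid(sweep(h2 %*% params$W3, 2L, as.vector(params$b3), "+")))
}

#' Discriminator loss
#'
#' \deqn{L_D = -\frac{1}{N}\sum_i \log D(V_{T_i}) + \log(1 - D(V_{G_i}))}
#' over a batch of real targets and generated vectors (the latter treated as
#' fixed inputs, no gradient into the generator).
#'
#' @param real N x M matrix (rows are multi-hot ground truths).
#' @param fake N x M matrix (rows are generated probability vectors).
#' @param params discriminator parameters.
#' @return scalar loss.
#' @export
discriminator_loss <- function(real, fake, params) {
  if (!is.matrix(real)) real <- matrix(real, nrow = 1L)
  if (!is.matrix(fake)) fake <- matrix(fake, nrow = 1L)
  if (nrow(real) == 0L || nrow(fake) == 0L) stop("batches must be nonempty")
  dr <- clamp01(discriminator_forward(real, params))
  df <- clamp01(discriminator_forward(fake, params))
  -(mean(log(dr)) + mean(log(1 - df)))
}

#' Adversarial generator loss
#'
#' \deqn{L_{\mathcal G} = \frac{1}{N}\sum_i \log(1 - D(G(z_i^d)))}
#' — minimised by the generator (and, end to end, by the encoder feeding it)
#' to push generated vectors toward ones the discriminator scores as real.
#'
#' @param fake N x M matrix of generated probability vectors.
#' @param params discriminator parameters.
#' @return scalar loss (negative when the discriminator is undecided).
#' @export
generator_adv_loss <- function(fake, params) {
  if (!is.matrix(fake)) fake <- matrix(fake, nrow = 1L)
  if (nrow(fake) == 0L) stop("batch must be nonempty")
  df <- clamp01(discriminator_forward(fake, params))
  mean(log(1 - df))
}
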