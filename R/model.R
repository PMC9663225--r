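#' Model configuration
#'
#' All architectural and training hyperparameters of the recommender. The
#' defaults follow the published configuration where one is stated
#' (embedding dimension 32, one self-attention layer over inpatient days and
#' two over the medical history, lambda = gamma = 0.5, Adam) and documented
#' package choices elsewhere (4 heads, feed-forward width 4 d_e, 1/sqrt(d_k)
#' scaling, learning rate 5e-3).
#'
#' @param n_activities activity vocabulary size M.
#' @param n_words word vocabulary size J.
#' @param d_e embedding dimension (even).
#' @param heads number of self-attention heads (must divide d_e).
#' @param day_layers,hist_layers encoder depths for the day and history
#'   sequences.
#' @param d_f feed-forward width.
#' @param lambda weight of the history term in the fusion head.
#' @param gamma weight of the generator cross-entropy in the total loss.
#' @param pooling day-set embedding mode: `"soft_attention"` (default) or the
#'   `"average"` / `"max"` pooling ablations.
#' @param use_history include the medical-history branch (FALSE is the
#'   no-history ablation).
#' @param use_adversarial train with the generator/discriminator pair (FALSE
#'   is the no-adversarial ablation).
#' @param scale_mode attention scaling, `"sqrt"` or `"linear"`.
#' @param residual encoder residual form, `"as_printed"` (single residual
#'   around the feed-forward) or `"standard"`.
#' @param day_attention_activation inner nonlinearity of the day-set
#'   attention, `"sigmoid"` or `"tanh"`.
#' @param normalize_day_attention softmax-normalise day-set attention weights.
#' @param counts feed `"normalized"` (counts / observed days) or `"raw"`
#'   frequency counts to the gate and fusion.
#' @param beta_mode `"as_printed"` (day branch masked to observed activities)
#'   or `"all_ones"`.
#' @param literal_day_aggregation use raw score ratios instead of softmax in
#'   the day aggregator.
#' @param adv_stop_gradient detach the aggregated day vector before the
#'   generator so adversarial gradients do not reach the encoder.
#' @param d_hidden discriminator hidden width (default ceiling(M / 2)).
#' @param d_steps discriminator updates per recommendation-network update.
#' @param dropout dropout rate applied inside encoder blocks during training.
#' @param lr Adam learning rate.
#' @return list of class `ndm_config`.
#' @export
model_config <- function(n_activities, n_words, d_e = 32L, heads = 4L,
                         day_layers = 1L, hist_layers = 2L, d_f = 4L * d_e,
                         lambda = 0.5, gamma = 0.5,
                         pooling = c("soft_attention", "average", "max"),
                         use_history = TRUE, use_adversarial = TRUE,
                         scale_mode = c("sqrt", "linear"),
                         residual = c("as_printed", "standard"),
                         day_attention_activation = c("sigmoid", "tanh"),
                         normalize_day_attention = FALSE,
                         counts = c("normalized", "raw"),
                         beta_mode = c("as_printed", "all_ones"),
                         literal_day_aggregation = FALSE,
                         adv_stop_gradient = FALSE,
                         d_hidden = NULL, d_steps = 1L, dropout = 0,
                         lr = 5e-3) {
  if (d_e %% 2L != 0L) stop("d_e must be even")
  if (d_e %% heads != 0L) stop("heads must divide d_e")
  structure(list(n_activities = as.integer(n_activities),
                 n_words = as.integer(n_words),
                 d_e = as.integer(d_e), heads = as.integer(heads),
                 d_k = as.integer(d_e / heads),
                 day_layers = as.integer(day_layers),
                 hist_layers = as.integer(hist_layers),
                 d_f = as.integer(d_f),
                 lambda = lambda, gamma = gamma,
                 pooling = match.arg(pooling),
                 use_history = use_history,
                 use_adversarial = use_adversarial,
                 scale_mode = match.arg(scale_mode),
                 residual = match.arg(residual),
                 day_attention_activation = match.arg(day_attention_activation),
                 normalize_day_attention = normalize_day_attention,
                 counts = match.arg(counts),
                 beta_mode = match.arg(beta_mode),
                 literal_day_aggregation = literal_day_aggregation,
                 adv_stop_gradient = adv_stop_gradient,
                 d_hidden = as.integer(if (is.null(d_hidden))
                   ceiling(n_activities / 2) else d_hidden),
                 d_steps = as.integer(d_steps),
                 dropout = dropout, lr = lr),
            class = "ndm_config")
}

rmat <- function(nr, nc, sd = 0.1) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

init_encoder_layer <- function(params, base, cfg) {
  d_e <- cfg$d_e; d_k <- cfg$d_k; d_f <- cfg$d_f
  for (h in seq_len(cfg$heads)) {
    hb <- paste0(base, "h", h, "_")
    params[[paste0(hb, "WQ")]] <- rmat(d_e, d_k)
    params[[paste0(hb, "bQ")]] <- matrix(0, 1L, d_k)
    params[[paste0(hb, "WK")]] <- rmat(d_e, d_k)
    params[[paste0(hb, "bK")]] <- matrix(0, 1L, d_k)
    params[[paste0(hb, "WV")]] <- rmat(d_e, d_k)
    params[[paste0(hb, "bV")]] <- matrix(0, 1L, d_k)
  }
  params[[paste0(base, "WO")]] <- rmat(cfg$heads * d_k, d_e)
  params[[paste0(base, "WF1")]] <- rmat(d_e, d_f)
  params[[paste0(base, "bF1")]] <- matrix(0, 1L, d_f)
  params[[paste0(base, "WF2")]] <- rmat(d_f, d_e)
  params[[paste0(base, "bF2")]] <- matrix(0, 1L, d_e)
  params[[paste0(base, "ln_g")]] <- matrix(1, 1L, d_e)
  params[[paste0(base, "ln_b")]] <- matrix(0, 1L, d_e)
  params[[paste0(base, "ln2_g")]] <- matrix(1, 1L, d_e)
  params[[paste0(base, "ln2_b")]] <- matrix(0, 1L, d_e)
  params
}

layer_from <- function(p, base, heads_n) {
  list(heads = lapply(seq_len(heads_n), function(h) {
         hb <- paste0(base, "h", h, "_")
         list(W_Q = p[[paste0(hb, "WQ")]], b_Q = p[[paste0(hb, "bQ")]],
              W_K = p[[paste0(hb, "WK")]], b_K = p[[paste0(hb, "bK")]],
              W_V = p[[paste0(hb, "WV")]], b_V = p[[paste0(hb, "bV")]])
       }),
       W_o = p[[paste0(base, "WO")]],
       W_F1 = p[[paste0(base, "WF1")]], b_F1 = p[[paste0(base, "bF1")]],
       W_F2 = p[[paste0(base, "WF2")]], b_F2 = p[[paste0(base, "bF2")]],
       ln_gain = p[[paste0(base, "ln_g")]], ln_bias = p[[paste0(base, "ln_b")]],
       ln2_gain = p[[paste0(base, "ln2_g")]],
       ln2_bias = p[[paste0(base, "ln2_b")]])
}

#' Initialise a recommender model
#'
#' Creates all trainable tensors: the activity and word embedding tables,
#' the day-set attention parameters, both encoder stacks, the day
#' aggregator MLP, the fusion head, and the generator/discriminator pair.
#' Weights are N(0, 0.1), biases zero, layer-norm gains one.
#'
#' @param config an `ndm_config`.
#' @param seed integer seed for the initial weights.
#' @return An object of class `ndm_model`.
#' @export
ndm_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ndm_config"))
  set.seed(seed)
  d_e <- config$d_e; M <- config$n_activities; J <- config$n_words
  H <- config$d_hidden
  p <- list(
    act_emb = rmat(M, d_e),
    word_emb = rmat(J, d_e),
    da_q = rmat(d_e, 1L),
    da_b = matrix(0, 1L, d_e),
    da_W = rmat(d_e, d_e),
    ag_W1 = rmat(2L * d_e, d_e),
    ag_b1 = matrix(0, 1L, d_e),
    ag_W2 = rmat(d_e, 1L),
    ag_b2 = matrix(0, 1L, 1L),
    fu_Wd = rmat(d_e, M),
    fu_bd = matrix(0, 1L, M),
    fu_Wtxt = rmat(d_e, M),
    fu_btxt = matrix(0, 1L, M),
    fu_wp = matrix(1, 1L, M),
    fu_bp = matrix(0, 1L, M),
    g_W1 = rmat(d_e, d_e), g_b1 = matrix(0, 1L, d_e),
    g_W2 = rmat(d_e, d_e), g_b2 = matrix(0, 1L, d_e),
    g_W3 = rmat(d_e, M), g_b3 = matrix(0, 1L, M),
    D_W1 = rmat(M, H), D_b1 = matrix(0, 1L, H),
    D_W2 = rmat(H, H), D_b2 = matrix(0, 1L, H),
    D_W3 = rmat(H, 1L), D_b3 = matrix(0, 1L, 1L)
  )
  for (l in seq_len(config$day_layers))
    p <- init_encoder_layer(p, sprintf("day%d_", l), config)
  for (l in seq_len(config$hist_layers))
    p <- init_encoder_layer(p, sprintf("hist%d_", l), config)
  structure(list(config = config, params = p, opt = NULL, history = NULL),
            class = "ndm_model")
}

#' @export
print.ndm_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, 0L))
  cat("<ndm_model> d_e=", cfg$d_e, ", heads=", cfg$heads,
      ", layers day/hist=", cfg$day_layers, "/", cfg$hist_layers,
      ", M=", cfg$n_activities, ", J=", cfg$n_words,
      " (", n_par, " parameters)\n", sep = "")
  if (!is.null(x$history))
    cat("trained ", nrow(x$history), " epochs; final loss ",
        sprintf("%.4f", x$history$loss[nrow(x$history)]), "\n", sep = "")
  invisible(x)
}

day_attn_params <- function(p) list(q = p$da_q, b = p$da_b, W = p$da_W)
agg_params <- function(p) list(W1 = p$ag_W1, b1 = p$ag_b1,
                               W2 = p$ag_W2, b2 = p$ag_b2)
fusion_params <- function(p) list(W_d = p$fu_Wd, b_d = p$fu_bd,
                                  W_txt = p$fu_Wtxt, b_txt = p$fu_btxt,
                                  W_p = as.vector(p$fu_wp), b_p = as.vector(p$fu_bp))
gen_params <- function(p) list(W1 = p$g_W1, b1 = p$g_b1, W2 = p$g_W2,
                               b2 = p$g_b2, W3 = p$g_W3, b3 = p$g_b3)
disc_params <- function(p) list(W1 = p$D_W1, b1 = p$D_b1, W2 = p$D_W2,
                                b2 = p$D_b2, W3 = p$D_W3, b3 = p$D_b3)

encode_days_numeric <- function(model, instance) {
  cfg <- model$config; p <- model$params
  demb <- t(vapply(instance$observed_days, function(ids)
    day_embed(ids, p$act_emb, day_attn_params(p), mode = cfg$pooling,
              activation = cfg$day_attention_activation,
              normalize = cfg$normalize_day_attention),
    numeric(cfg$d_e)))
  x <- add_positions(demb)
  for (l in seq_len(cfg$day_layers))
    x <- encoder_block(x, layer_from(p, sprintf("day%d_", l), cfg$heads),
                       scale_mode = cfg$scale_mode, residual = cfg$residual)
  x
}

encode_history_numeric <- function(model, history) {
  cfg <- model$config; p <- model$params
  if (length(history) == 0L) return(NULL)
  x <- add_positions(p$word_emb[history, , drop = FALSE])
  for (l in seq_len(cfg$hist_layers))
    x <- encoder_block(x, layer_from(p, sprintf("hist%d_", l), cfg$heads),
                       scale_mode = cfg$scale_mode, residual = cfg$residual)
  aggregate_history(x)
}

#' Score the next-day activities for one instance
#'
#' Full forward pass: day-set embedding, positional encoding, both encoder
#' stacks, attention aggregation, and the gated fusion head.
#'
#' @param object a trained (or freshly initialised) `ndm_model`.
#' @param instance a `training_instance`.
#' @param k optional cutoff; when given, the top-K id list is included.
#' @param ... unused.
#' @return list with `scores` (length-M vector in (0,1)), `alpha` (fusion
#'   gate), `day_weights` (aggregation attention over observed days), `z_d`,
#'   `z_w`, and optionally `top_k`.
#' @export
predict.ndm_model <- function(object, instance, k = NULL, ...) {
  cfg <- object$config
  h_days <- encode_days_numeric(object, instance)
  agg <- aggregate_days(h_days, agg_params(object$params),
                        literal_ratio = cfg$literal_day_aggregation)
  z_w <- if (cfg$use_history) encode_history_numeric(object, instance$history)
         else NULL
  freq <- frequency_vector(instance$observed_days, cfg$n_activities)
  fu <- fuse(agg$z, z_w, freq, fusion_params(object$params),
             lambda = cfg$lambda, counts = cfg$counts,
             beta_mode = cfg$beta_mode)
  out <- list(scores = fu$scores, alpha = fu$alpha,
              day_weights = agg$weights, z_d = agg$z, z_w = z_w)
  if (!is.null(k)) out$top_k <- top_k(fu$scores, k)
  out
}

# ---------------------------------------------------------------------------
# differentiable forward pass (training)

tape_encoder_block <- function(x, pn, base, cfg, dropmask = NULL) {
  heads <- lapply(seq_len(cfg$heads), function(h) {
    hb <- paste0(base, "h", h, "_")
    q <- ad_affine(x, pn[[paste0(hb, "WQ")]], pn[[paste0(hb, "bQ")]])
    k <- ad_affine(x, pn[[paste0(hb, "WK")]], pn[[paste0(hb, "bK")]])
    v <- ad_affine(x, pn[[paste0(hb, "WV")]], pn[[paste0(hb, "bV")]])
    scale <- if (cfg$scale_mode == "sqrt") 1 / sqrt(cfg$d_k) else 1 / cfg$d_k
    s <- ad_smul(ad_mm(q, ad_t(k)), scale)
    ad_mm(ad_softmax_rows(s), v)
  })
  cc <- heads[[1L]]
  if (length(heads) > 1L)
    for (h in 2:length(heads)) cc <- ad_cbind2(cc, heads[[h]])
  a <- ad_mm(cc, pn[[paste0(base, "WO")]])
  if (cfg$residual == "standard")
    a <- ad_layernorm(ad_add(x, a), pn[[paste0(base, "ln2_g")]],
                      pn[[paste0(base, "ln2_b")]])
  hid <- ad_relu(ad_affine(a, pn[[paste0(base, "WF1")]],
                           pn[[paste0(base, "bF1")]]))
  if (!is.null(dropmask)) hid <- ad_mul(hid, dropmask)
  ffn <- ad_affine(hid, pn[[paste0(base, "WF2")]],
                   pn[[paste0(base, "bF2")]])
  ad_layernorm(ad_add(a, ffn), pn[[paste0(base, "ln_g")]],
               pn[[paste0(base, "ln_b")]])
}

tape_day_embed <- function(tp, pn, ids, cfg) {
  ids <- sort(unique(as.integer(ids)))
  e <- ad_rowselect(pn$act_emb, ids)
  if (cfg$pooling == "average") return(ad_colmeans(e))
  if (cfg$pooling == "max") return(ad_colmax(e))
  s <- ad_affine(e, pn$da_W, pn$da_b)
  s <- if (cfg$day_attention_activation == "tanh") ad_tanh(s) else ad_sigmoid(s)
  a <- ad_mm(s, pn$da_q)
  if (cfg$normalize_day_attention)
    return(ad_mm(ad_softmax_rows(ad_t(a)), e))
  ad_mm(ad_t(a), e)
}

tape_dropmask <- function(tp, nr, nc, rate) {
  if (rate <= 0) return(NULL)
  keep <- matrix(stats::runif(nr * nc) >= rate, nr, nc) / (1 - rate)
  ad_input(tp, keep)
}

# forward for one instance on an existing tape with parameter nodes pn;
# returns nodes for the prediction, mse, generator ce, adversarial log-term
tape_forward_instance <- function(tp, pn, instance, cfg, training = TRUE) {
  K <- length(instance$observed_days)
  dembs <- lapply(instance$observed_days, function(ids)
    tape_day_embed(tp, pn, ids, cfg))
  x <- if (K > 1L) ad_rbind_list(dembs) else dembs[[1L]]
  x <- ad_add(x, ad_input(tp, pe_matrix(K, cfg$d_e)))
  for (l in seq_len(cfg$day_layers))
    x <- tape_encoder_block(x, pn, sprintf("day%d_", l), cfg,
                            dropmask = if (training)
                              tape_dropmask(tp, K, cfg$d_f, cfg$dropout))
  # day aggregation against the last day
  hk <- ad_rowselect(x, rep(K, K))
  z <- ad_cbind2(x, hk)
  hid <- ad_relu(ad_affine(z, pn$ag_W1, pn$ag_b1))
  e <- ad_affine(hid, pn$ag_W2, pn$ag_b2)
  if (cfg$literal_day_aggregation) {
    s <- ad_sum(e)
    r <- ad_div(ad_input(tp, matrix(1, 1L, 1L)), s)
    w <- ad_t(ad_scale(e, r))
  } else {
    w <- ad_softmax_rows(ad_t(e))
  }
  z_d <- ad_mm(w, x)

  z_w <- NULL
  if (cfg$use_history && length(instance$history) > 0L) {
    xw <- ad_rowselect(pn$word_emb, instance$history)
    xw <- ad_add(xw, ad_input(tp, pe_matrix(length(instance$history), cfg$d_e)))
    for (l in seq_len(cfg$hist_layers))
      xw <- tape_encoder_block(xw, pn, sprintf("hist%d_", l), cfg,
                               dropmask = if (training)
                                 tape_dropmask(tp, length(instance$history),
                                               cfg$d_f, cfg$dropout))
    z_w <- ad_colmeans(xw)
  }

  M <- cfg$n_activities
  freq <- frequency_vector(instance$observed_days, M)
  l_raw <- if (cfg$counts == "normalized") freq$counts / freq$n_days
           else freq$counts
  l_const <- ad_input(tp, matrix(l_raw, 1L))
  ones <- ad_input(tp, matrix(1, 1L, M))
  alpha <- ad_sigmoid(ad_add(ad_mul(pn$fu_wp, l_const), pn$fu_bp))
  beta <- if (cfg$beta_mode == "all_ones") rep(1, M) else freq$beta
  beta_c <- ad_input(tp, matrix(beta, 1L))
  day_term <- ad_affine(z_d, pn$fu_Wd, pn$fu_bd)
  pre <- ad_add(ad_mul(ad_mul(ad_sub(ones, alpha), beta_c), day_term),
                ad_mul(alpha, l_const))
  if (!is.null(z_w)) {
    txt <- ad_affine(z_w, pn$fu_Wtxt, pn$fu_btxt)
    pre <- ad_add(pre, ad_smul(txt, cfg$lambda))
  }
  y_hat <- ad_sigmoid(pre)
  y_c <- ad_input(tp, matrix(instance$target_multihot, 1L))
  diff <- ad_sub(y_c, y_hat)
  mse <- ad_sum(ad_mul(diff, diff))

  # generator branch
  g_in <- if (cfg$adv_stop_gradient) ad_input(tp, ad_value(z_d)) else z_d
  h1 <- ad_relu(ad_affine(g_in, pn$g_W1, pn$g_b1))
  h2 <- ad_affine(h1, pn$g_W2, pn$g_b2)
  p_hat <- ad_sigmoid(ad_affine(h2, pn$g_W3, pn$g_b3))
  pc <- ad_clamp(p_hat, LOG_EPS, 1 - LOG_EPS)
  one_minus_y <- ad_sub(ones, y_c)
  ce <- ad_smul(ad_sum(ad_add(ad_mul(y_c, ad_log(pc)),
                              ad_mul(one_minus_y,
                                     ad_log(ad_sub(ones, pc))))),
                -1 / M)
  list(y_hat = y_hat, mse = mse, ce = ce, p_hat = p_hat, z_d = z_d)
}

# discriminator forward on tape (input node v: N x M)
tape_disc_forward <- function(v, dn) {
  h1 <- ad_relu(ad_affine(v, dn$D_W1, dn$D_b1))
  h2 <- ad_relu(ad_affine(h1, dn$D_W2, dn$D_b2))
  ad_sigmoid(ad_affine(h2, dn$D_W3, dn$D_b3))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, subset = NULL) {
  state$t <- state$t + 1L
  nms <- if (is.null(subset)) names(grads) else intersect(subset, names(grads))
  for (nm in nms) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

disc_param_names <- c("D_W1", "D_b1", "D_W2", "D_b2", "D_W3", "D_b3")

#' One adversarial training step on a mini-batch
#'
#' Performs the two-phase update: (1) the discriminator is updated on its
#' loss with generated vectors treated as fixed inputs; (2) the
#' recommendation network and generator are updated jointly on the total
#' loss (squared error + gamma * generator cross-entropy) plus the
#' adversarial generator loss. With `use_adversarial = FALSE` in the config,
#' phase (1) is skipped and phase (2) minimises the total loss only.
#'
#' @param model an `ndm_model`.
#' @param batch nonempty list of `training_instance`s.
#' @param lr learning rate (defaults to the config's).
#' @return list with the updated `model` and `losses` (finite scalars
#'   `loss`, `ce`, `d_loss`, `adv_loss`).
#' @export
adversarial_step <- function(model, batch, lr = NULL) {
  cfg <- model$config
  if (is.null(lr)) lr <- cfg$lr
  p <- model$params
  if (is.null(model$opt))
    model$opt <- list(main = adam_init(p), disc = adam_init(p))
  n <- length(batch)
  d_loss <- NA_real_

  if (cfg$use_adversarial) {
    # generated vectors for the discriminator phase, detached
    fakes <- t(vapply(batch, function(inst) {
      h_days <- encode_days_numeric(model, inst)
      agg <- aggregate_days(h_days, agg_params(p),
                            literal_ratio = cfg$literal_day_aggregation)
      generator_forward(agg$z, gen_params(p))
    }, numeric(cfg$n_activities)))
    reals <- t(vapply(batch, function(inst)
      as.numeric(inst$target_multihot), numeric(cfg$n_activities)))
    for (s in seq_len(cfg$d_steps)) {
      tp <- ad_tape()
      dn <- ad_params(tp, p[disc_param_names])
      dr <- ad_clamp(tape_disc_forward(ad_input(tp, reals), dn),
                     LOG_EPS, 1 - LOG_EPS)
      df <- ad_clamp(tape_disc_forward(ad_input(tp, fakes), dn),
                     LOG_EPS, 1 - LOG_EPS)
      ld <- ad_add(ad_smul(ad_sum(ad_log(dr)), -1 / n),
                   ad_smul(ad_sum(ad_log(ad_sub(ad_input(tp, matrix(1, n, 1L)),
                                                df))), -1 / n))
      d_loss <- as.vector(ad_value(ld))
      grads <- ad_collect_grads(ad_backward(ld), dn, p[disc_param_names])
      upd <- adam_step(p, grads, model$opt$disc, lr, subset = disc_param_names)
      p <- upd$params
      model$opt$disc <- upd$state
      model$params <- p
    }
  }

  # main phase: recommendation network + generator
  tp <- ad_tape()
  pn <- ad_params(tp, p)
  mse_n <- NULL; ce_n <- NULL; adv_n <- NULL
  for (inst in batch) {
    fw <- tape_forward_instance(tp, pn, inst, cfg, training = TRUE)
    mse_n <- if (is.null(mse_n)) fw$mse else ad_add(mse_n, fw$mse)
    ce_n <- if (is.null(ce_n)) fw$ce else ad_add(ce_n, fw$ce)
    if (cfg$use_adversarial) {
      dout <- tape_disc_forward(fw$p_hat, pn)
      la <- ad_log(ad_clamp(ad_sub(ad_input(tp, matrix(1, 1L, 1L)), dout),
                            LOG_EPS, 1))
      adv_n <- if (is.null(adv_n)) la else ad_add(adv_n, la)
    }
  }
  loss <- ad_add(ad_smul(mse_n, 1 / n), ad_smul(ce_n, cfg$gamma / n))
  l_val <- as.vector(ad_value(loss))
  ce_val <- as.vector(ad_value(ce_n)) / n
  adv_val <- NA_real_
  objective <- loss
  if (cfg$use_adversarial) {
    adv <- ad_smul(adv_n, 1 / n)
    adv_val <- as.vector(ad_value(adv))
    objective <- ad_add(loss, adv)
  }
  grads <- ad_collect_grads(ad_backward(objective), pn, p)
  main_names <- setdiff(names(p), disc_param_names)
  upd <- adam_step(p, grads, model$opt$main, lr, subset = main_names)
  model$params <- upd$params
  model$opt$main <- upd$state
  list(model = model,
       losses = c(loss = l_val, ce = ce_val, d_loss = d_loss,
                  adv_loss = adv_val))
}

#' Train the recommender
#'
#' Mini-batch Adam training with the adversarial schedule of
#' [adversarial_step()]. All randomness (shuffling, dropout) is driven by
#' `seed`, so identical seeds give identical runs.
#'
#' @param model an `ndm_model`.
#' @param instances training `training_instance`s.
#' @param epochs number of passes over the data.
#' @param batch_size mini-batch size.
#' @param lr learning rate (defaults to the config's).
#' @param seed integer seed.
#' @param validation optional instances evaluated (Recall\@10) each
#'   `eval_every` epochs.
#' @param eval_every epochs between validation evaluations.
#' @param verbose print per-epoch losses.
#' @return the trained `ndm_model`, with `$history` holding per-epoch mean
#'   losses (columns epoch, loss, ce, d_loss, adv_loss, val_recall10).
#' @export
train_model <- function(model, instances, epochs = 50L, batch_size = 32L,
                        lr = NULL, seed = 1L, validation = NULL,
                        eval_every = 10L, verbose = FALSE) {
  stopifnot(length(instances) > 0L)
  set.seed(seed)
  n <- length(instances)
  hist_rows <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    acc <- matrix(NA_real_, length(starts), 4L)
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + batch_size - 1L, n)]
      step <- adversarial_step(model, instances[idx], lr = lr)
      model <- step$model
      acc[bi, ] <- step$losses
    }
    val_rec <- NA_real_
    if (!is.null(validation) &&
        (ep %% eval_every == 0L || ep == epochs)) {
      rep_ <- evaluate_cohort(model, validation, model$config$n_activities,
                              k_set = 10L)
      val_rec <- rep_$summary$recall[1L]
    }
    hist_rows[[ep]] <- data.frame(epoch = ep,
                                  loss = mean(acc[, 1L]),
                                  ce = mean(acc[, 2L]),
                                  d_loss = mean(acc[, 3L]),
                                  adv_loss = mean(acc[, 4L]),
                                  val_recall10 = val_rec)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  ce %.4f  d %.4f  adv %.4f",
                      ep, mean(acc[, 1L]), mean(acc[, 2L]),
                      mean(acc[, 3L]), mean(acc[, 4L])))
  }
  model$history <- do.call(rbind, hist_rows)
  model
}

#' Save / load a model checkpoint
#'
#' Serialises the configuration and all parameter matrices.
#'
#' @param model an `ndm_model`.
#' @param path checkpoint file path.
#' @return `load_model` returns the restored `ndm_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(list(config = model$config, params = model$params,
               history = model$history), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  structure(list(config = obj$config, params = obj$params, opt = NULL,
                 history = obj$history),
            class = "ndm_model")
}
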