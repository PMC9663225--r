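# Brute-force scalar-loop oracles, independent of the package's vectorised
# implementations, plus small random-parameter builders used across tests.

sigm <- function(x) 1 / (1 + exp(-x))

rand_day_params <- function(d_e) {
  list(q = matrix(rnorm(d_e), d_e, 1),
       b = matrix(rnorm(d_e), 1),
       W = matrix(rnorm(d_e * d_e), d_e))
}

rand_layer <- function(d_e, heads, d_f = 2L * d_e) {
  d_k <- d_e %/% heads
  list(heads = lapply(seq_len(heads), function(h)
         list(W_Q = matrix(rnorm(d_e * d_k), d_e), b_Q = matrix(rnorm(d_k), 1),
              W_K = matrix(rnorm(d_e * d_k), d_e), b_K = matrix(rnorm(d_k), 1),
              W_V = matrix(rnorm(d_e * d_k), d_e), b_V = matrix(rnorm(d_k), 1))),
       W_o = matrix(rnorm(heads * d_k * d_e), heads * d_k),
       W_F1 = matrix(rnorm(d_e * d_f), d_e), b_F1 = matrix(rnorm(d_f), 1),
       W_F2 = matrix(rnorm(d_f * d_e), d_f), b_F2 = matrix(rnorm(d_e), 1),
       ln_gain = matrix(runif(d_e, 0.5, 1.5), 1), ln_bias = matrix(rnorm(d_e), 1),
       ln2_gain = matrix(runif(d_e, 0.5, 1.5), 1), ln2_bias = matrix(rnorm(d_e), 1))
}

rand_agg_params <- function(d_e) {
  list(W1 = matrix(rnorm(2 * d_e * d_e), 2 * d_e), b1 = matrix(rnorm(d_e), 1),
       W2 = matrix(rnorm(d_e), d_e, 1), b2 = matrix(rnorm(1), 1, 1))
}

rand_fusion_params <- function(d_e, M) {
  list(W_d = matrix(rnorm(d_e * M), d_e), b_d = matrix(rnorm(M), 1),
       W_txt = matrix(rnorm(d_e * M), d_e), b_txt = matrix(rnorm(M), 1),
       W_p = rnorm(M), b_p = rnorm(M))
}

# Eq.-style scalar loop: alpha_i = q' act(W' e_i + b); out = sum alpha_i e_i
oracle_day_embed <- function(ids, table, params, activation = "sigmoid") {
  ids <- sort(unique(ids))
  act <- if (activation == "sigmoid") sigm else tanh
  d_e <- ncol(table)
  out <- numeric(d_e)
  for (id in ids) {
    e <- table[id, ]
    s <- numeric(d_e)
    for (j in seq_len(d_e)) s[j] <- act(sum(e * params$W[, j]) + params$b[1, j])
    alpha <- sum(params$q[, 1] * s)
    out <- out + alpha * e
  }
  out
}

oracle_self_attention <- function(x, layer, scale_mode = "sqrt") {
  n <- nrow(x); d_e <- ncol(x)
  d_k <- ncol(layer$heads[[1]]$W_Q)
  scale <- if (scale_mode == "sqrt") 1 / sqrt(d_k) else 1 / d_k
  outs <- list()
  for (h in seq_along(layer$heads)) {
    hp <- layer$heads[[h]]
    Q <- K <- V <- matrix(0, n, d_k)
    for (i in seq_len(n)) for (j in seq_len(d_k)) {
      Q[i, j] <- sum(x[i, ] * hp$W_Q[, j]) + hp$b_Q[1, j]
      K[i, j] <- sum(x[i, ] * hp$W_K[, j]) + hp$b_K[1, j]
      V[i, j] <- sum(x[i, ] * hp$W_V[, j]) + hp$b_V[1, j]
    }
    H <- matrix(0, n, d_k)
    for (i in seq_len(n)) {
      s <- numeric(n)
      for (j in seq_len(n)) s[j] <- sum(Q[i, ] * K[j, ]) * scale
      w <- exp(s - max(s)); w <- w / sum(w)
      for (j in seq_len(n)) H[i, ] <- H[i, ] + w[j] * V[j, ]
    }
    outs[[h]] <- H
  }
  C <- do.call(cbind, outs)
  out <- matrix(0, n, d_e)
  for (i in seq_len(n)) for (j in seq_len(d_e))
    out[i, j] <- sum(C[i, ] * layer$W_o[, j])
  out
}

oracle_aggregate_days <- function(h, params) {
  K <- nrow(h); d_e <- ncol(h)
  e <- numeric(K)
  for (k in seq_len(K)) {
    z <- c(h[k, ], h[K, ])
    hid <- numeric(d_e)
    for (j in seq_len(d_e))
      hid[j] <- max(0, sum(z * params$W1[, j]) + params$b1[1, j])
    e[k] <- sum(hid * params$W2[, 1]) + params$b2[1, 1]
  }
  w <- exp(e - max(e)); w <- w / sum(w)
  z <- numeric(d_e)
  for (k in seq_len(K)) z <- z + w[k] * h[k, ]
  list(z = z, weights = w)
}

oracle_fuse <- function(z_d, z_w, freq, params, lambda = 0.5) {
  M <- length(freq$counts)
  l <- freq$counts / freq$n_days
  out <- numeric(M)
  for (j in seq_len(M)) {
    alpha_j <- sigm(params$W_p[j] * l[j] + params$b_p[j])
    day_j <- sum(z_d * params$W_d[, j]) + params$b_d[1, j]
    pre <- (1 - alpha_j) * freq$beta[j] * day_j + alpha_j * l[j]
    if (!is.null(z_w))
      pre <- pre + lambda * (sum(z_w * params$W_txt[, j]) + params$b_txt[1, j])
    out[j] <- sigm(pre)
  }
  out
}

oracle_ce_loss <- function(p_hat, y, eps = 1e-7) {
  M <- length(p_hat)
  tot <- 0
  for (i in seq_len(M)) {
    p <- min(max(p_hat[i], eps), 1 - eps)
    tot <- tot + y[i] * log(p) + (1 - y[i]) * log(1 - p)
  }
  -tot / M
}

oracle_disc_loss <- function(d_real, d_fake, eps = 1e-7) {
  n <- length(d_real)
  tot <- 0
  for (i in seq_len(n)) {
    dr <- min(max(d_real[i], eps), 1 - eps)
    df <- min(max(d_fake[i], eps), 1 - eps)
    tot <- tot + log(dr) + log(1 - df)
  }
  -tot / n
}

oracle_adv_loss <- function(d_fake, eps = 1e-7) {
  tot <- 0
  for (i in seq_along(d_fake))
    tot <- tot + log(min(max(1 - d_fake[i], eps), 1))
  tot / length(d_fake)
}

oracle_recall <- function(ranked, target, k) {
  top <- ranked[seq_len(min(k, length(ranked)))]
  hits <- 0
  for (t in unique(target)) if (t %in% top) hits <- hits + 1
  hits / length(unique(target))
}

oracle_ndcg <- function(ranked, target, k) {
  target <- unique(target)
  top <- ranked[seq_len(min(k, length(ranked)))]
  dcg <- 0
  for (i in seq_along(top))
    if (top[i] %in% target) dcg <- dcg + 1 / log2(i + 1)
  idcg <- 0
  for (i in seq_len(min(k, length(target)))) idcg <- idcg + 1 / log2(i + 1)
  dcg / idcg
}

# brute-force baseline oracles
oracle_personal_top <- function(days, M, k) {
  counts <- integer(M)
  for (d in days) for (id in unique(d)) counts[id] <- counts[id] + 1L
  ord <- order(-counts, seq_len(M))
  ord[seq_len(min(k, M))]
}

oracle_item_transfer <- function(days, M, k) {
  counts <- integer(M)
  for (d in days) for (id in unique(d)) counts[id] <- counts[id] + 1L
  score <- numeric(M)
  last <- unique(days[[length(days)]])
  for (i in last) for (j in seq_len(M)) {
    for (t in seq_len(length(days) - 1L)) {
      if (i %in% days[[t]] && j %in% days[[t + 1L]]) score[j] <- score[j] + 1
    }
  }
  ord <- order(-score, -counts, seq_len(M))
  ord[seq_len(min(k, M))]
}

random_instance <- function(M = 20L, d_range = 2:5, set_range = 1:6) {
  n_days <- sample(d_range, 1L)
  days <- lapply(seq_len(n_days), function(t)
    sample.int(M, sample(set_range, 1L)))
  training_instance(days, history = sample.int(10L, 4L),
                    target_set = sample.int(M, 3L), n_activities = M)
}

tiny_cohort <- function(...) {
  cfg <- synthetic_config(...)
  generate_cohort(cfg)
}
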