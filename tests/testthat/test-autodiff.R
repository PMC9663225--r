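# The training engine is a reverse-mode tape; these tests pin its gradients
# to central finite differences. ReLU kinks are avoided by keeping the
# finite-difference step small relative to preactivation magnitudes.

ns <- asNamespace("nextdayrec")

fd_check <- function(build, params, eps = 1e-5, tol = 1e-4, n_probe = 3L) {
  run <- function(p) {
    tp <- ns$ad_tape()
    pn <- ns$ad_params(tp, p)
    node <- build(tp, pn)
    list(val = as.vector(ns$ad_value(node)), pn = pn, node = node)
  }
  o <- run(params)
  gr <- ns$ad_collect_grads(ns$ad_backward(o$node), o$pn, params)
  for (nm in names(params)) {
    for (k in sample(length(params[[nm]]), min(n_probe, length(params[[nm]])))) {
      p2 <- params; p2[[nm]][k] <- p2[[nm]][k] + eps
      f1 <- run(p2)$val
      p2[[nm]][k] <- p2[[nm]][k] - 2 * eps
      f0 <- run(p2)$val
      num <- (f1 - f0) / (2 * eps)
      err <- abs(gr[[nm]][k] - num) / max(1e-3, abs(num), abs(gr[[nm]][k]))
      expect_lt(err, tol, label = sprintf("gradient error for %s[%d]", nm, k))
    }
  }
  invisible(o$val)
}

test_that("elementary op gradients match finite differences", {
  set.seed(61)
  params <- list(A = matrix(rnorm(12), 3), B = matrix(rnorm(12), 3),
                 W = matrix(rnorm(16), 4), b = matrix(rnorm(4), 1),
                 g = matrix(runif(4, 0.5, 1.5), 1), bb = matrix(rnorm(4), 1),
                 s = matrix(0.7, 1, 1))
  fd_check(function(tp, pn) {
    x <- ns$ad_mul(ns$ad_sigmoid(pn$A), ns$ad_tanh(pn$B))
    y <- ns$ad_affine(x, pn$W, pn$b)
    y <- ns$ad_layernorm(y, pn$g, pn$bb)
    y <- ns$ad_softmax_rows(y)
    y <- ns$ad_scale(y, pn$s)
    z <- ns$ad_log(ns$ad_clamp(ns$ad_exp(ns$ad_colmeans(y)), 1e-7, 10))
    ns$ad_sum(ns$ad_relu(z))
  }, params)
})

test_that("selection, stacking, and pooling gradients match finite differences", {
  set.seed(62)
  params <- list(E = matrix(rnorm(30), 10), q = matrix(rnorm(3), 3, 1))
  fd_check(function(tp, pn) {
    a <- ns$ad_rowselect(pn$E, c(2L, 7L, 2L))  # duplicate row: scatter-add
    b <- ns$ad_rowselect(pn$E, c(1L, 4L, 9L))
    s <- ns$ad_rbind_list(list(a, b))
    w <- ns$ad_cbind2(ns$ad_colmax(s), ns$ad_colmeans(s))
    v <- ns$ad_mm(s, pn$q)
    d <- ns$ad_div(v, ns$ad_cadd(ns$ad_mul(v, v), 2))
    ns$ad_add(ns$ad_sum(d), ns$ad_sum(w))
  }, params)
})

test_that("full model objective gradients match finite differences", {
  set.seed(63)
  coh <- tiny_cohort(n_patients = 4, mean_history_words = 12, mean_days = 5,
                     seed = 4)
  inst <- make_instances(coh$records, coh$config$n_activities, seed = 2)
  cfg <- model_config(coh$config$n_activities, coh$config$n_words,
                      d_e = 8L, heads = 2L, d_f = 16L)
  m <- ndm_model(cfg, seed = 3)
  build <- function(tp, pn) {
    tot <- NULL
    for (i in 1:2) {
      fw <- ns$tape_forward_instance(tp, pn, inst[[i]], cfg, training = FALSE)
      dout <- ns$tape_disc_forward(fw$p_hat, pn)
      la <- ns$ad_log(ns$ad_clamp(
        ns$ad_sub(ns$ad_input(tp, matrix(1, 1, 1)), dout), 1e-7, 1))
      term <- ns$ad_add(ns$ad_add(fw$mse, ns$ad_smul(fw$ce, 0.5)), la)
      tot <- if (is.null(tot)) term else ns$ad_add(tot, term)
    }
    tot
  }
  fd_check(build, m$params, n_probe = 2L)
})

test_that("tape forward values equal the numeric forward pass", {
  set.seed(64)
  coh <- tiny_cohort(n_patients = 6, mean_history_words = 15, seed = 6)
  inst <- make_instances(coh$records, coh$config$n_activities, seed = 2)
  configs <- list(
    model_config(coh$config$n_activities, coh$config$n_words,
                 d_e = 8L, heads = 2L, d_f = 16L),
    model_config(coh$config$n_activities, coh$config$n_words,
                 d_e = 8L, heads = 2L, d_f = 16L, pooling = "average"),
    model_config(coh$config$n_activities, coh$config$n_words,
                 d_e = 8L, heads = 2L, d_f = 16L, pooling = "max"),
    model_config(coh$config$n_activities, coh$config$n_words,
                 d_e = 8L, heads = 2L, d_f = 16L, use_history = FALSE),
    model_config(coh$config$n_activities, coh$config$n_words,
                 d_e = 8L, heads = 4L, d_f = 16L, residual = "standard",
                 scale_mode = "linear", day_attention_activation = "tanh",
                 normalize_day_attention = TRUE,
                 literal_day_aggregation = TRUE, beta_mode = "all_ones")
  )
  for (cfg in configs) {
    m <- ndm_model(cfg, seed = 5)
    for (i in seq_len(3)) {
      tp <- ns$ad_tape()
      pn <- ns$ad_params(tp, m$params)
      fw <- ns$tape_forward_instance(tp, pn, inst[[i]], cfg, training = FALSE)
      pred <- predict(m, inst[[i]])
      expect_equal(as.vector(ns$ad_value(fw$y_hat)), pred$scores,
                   tolerance = 1e-10)
      expect_equal(as.vector(ns$ad_value(fw$mse)),
                   sum((inst[[i]]$target_multihot - pred$scores)^2),
                   tolerance = 1e-10)
      expect_equal(as.vector(ns$ad_value(fw$ce)),
                   generator_ce_loss(generator_forward(pred$z_d,
                                       ns$gen_params(m$params)),
                                     inst[[i]]$target_multihot),
                   tolerance = 1e-10)
    }
  }
})
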