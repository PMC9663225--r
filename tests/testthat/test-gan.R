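zero_gen <- function(d_e, M) {
  list(W1 = matrix(0, d_e, d_e), b1 = matrix(0, 1, d_e),
       W2 = matrix(0, d_e, d_e), b2 = matrix(0, 1, d_e),
       W3 = matrix(0, d_e, M), b3 = matrix(0, 1, M))
}

zero_disc <- function(M, H = 4L) {
  list(W1 = matrix(0, M, H), b1 = matrix(0, 1, H),
       W2 = matrix(0, H, H), b2 = matrix(0, 1, H),
       W3 = matrix(0, H, 1), b3 = matrix(0, 1, 1))
}

rand_gen <- function(d_e, M) {
  list(W1 = matrix(rnorm(d_e^2, sd = 0.3), d_e), b1 = matrix(rnorm(d_e), 1),
       W2 = matrix(rnorm(d_e^2, sd = 0.3), d_e), b2 = matrix(rnorm(d_e), 1),
       W3 = matrix(rnorm(d_e * M, sd = 0.3), d_e), b3 = matrix(rnorm(M), 1))
}

rand_disc <- function(M, H = 6L) {
  list(W1 = matrix(rnorm(M * H, sd = 0.3), M), b1 = matrix(rnorm(H), 1),
       W2 = matrix(rnorm(H * H, sd = 0.3), H), b2 = matrix(rnorm(H), 1),
       W3 = matrix(rnorm(H), H, 1), b3 = matrix(rnorm(1), 1, 1))
}

# a discriminator computing sigmoid(v + c) for scalar inputs v >= 0
passthrough_disc <- function(c_) {
  list(W1 = matrix(1, 1, 1), b1 = matrix(0, 1, 1),
       W2 = matrix(1, 1, 1), b2 = matrix(0, 1, 1),
       W3 = matrix(1, 1, 1), b3 = matrix(c_, 1, 1))
}

test_that("generator outputs probabilities and zero weights give 0.5", {
  gp <- zero_gen(4L, 10L)
  expect_equal(generator_forward(rnorm(4), gp), rep(0.5, 10))
  set.seed(21)
  gp2 <- rand_gen(4L, 10L)
  out <- generator_forward(rnorm(4), gp2)
  expect_true(all(out > 0 & out < 1))
  expect_equal(generator_forward(c(1, 2, 3, 4), gp2),
               generator_forward(c(1, 2, 3, 4), gp2))
})

test_that("generator cross-entropy matches anchors, hand example, and oracle", {
  y <- c(1, 0, 1, 0, 0)
  expect_equal(generator_ce_loss(rep(0.5, 5), y), log(2))
  expect_lt(generator_ce_loss(c(1, 0, 1, 0, 0) * 0.9998 + 1e-4, y), 1e-3)
  # M = 2 hand evaluation: -(log 0.9 + log 0.8) / 2
  expect_equal(generator_ce_loss(c(0.9, 0.2), c(1, 0)),
               -(log(0.9) + log(0.8)) / 2, tolerance = 1e-12)
  expect_true(is.finite(generator_ce_loss(c(0, 1), c(1, 0))))
  set.seed(22)
  for (rep in 1:30) {
    M <- sample(3:12, 1)
    p <- runif(M); yy <- rbinom(M, 1, 0.4)
    expect_equal(generator_ce_loss(p, yy), oracle_ce_loss(p, yy),
                 tolerance = 1e-9)
  }
  expect_error(generator_ce_loss(runif(3), c(1, 0)), "mismatch")
})

test_that("discriminator scores are in (0,1), deterministic, batchable", {
  dp <- zero_disc(6L)
  expect_equal(discriminator_forward(rnorm(6), dp), 0.5)
  set.seed(23)
  dp2 <- rand_disc(6L)
  v <- runif(6)
  expect_equal(discriminator_forward(v, dp2), discriminator_forward(v, dp2))
  batch <- matrix(runif(24), 4)
  got <- discriminator_forward(batch, dp2)
  loop <- vapply(1:4, function(i) discriminator_forward(batch[i, ], dp2), 0)
  expect_equal(got, loop, tolerance = 1e-12)
  expect_true(all(got > 0 & got < 1))
})

test_that("discriminator loss matches anchors, hand example, and oracle", {
  dp <- zero_disc(6L)
  real <- matrix(rbinom(12, 1, 0.5), 2)
  fake <- matrix(runif(12), 2)
  expect_equal(discriminator_loss(real, fake, dp), 2 * log(2))
  # N = 1 hand example with D(real) = 0.8, D(fake) = 0.3
  d <- passthrough_disc(qlogis(0.3))
  vr <- matrix(qlogis(0.8) - qlogis(0.3), 1, 1)
  vf <- matrix(0, 1, 1)
  expect_equal(discriminator_forward(vr, d), 0.8, tolerance = 1e-12)
  expect_equal(discriminator_loss(vr, vf, d), -(log(0.8) + log(0.7)),
               tolerance = 1e-10)
  set.seed(24)
  dp2 <- rand_disc(6L)
  for (rep in 1:20) {
    real <- matrix(rbinom(18, 1, 0.4), 3)
    fake <- matrix(runif(18), 3)
    expect_equal(discriminator_loss(real, fake, dp2),
                 oracle_disc_loss(discriminator_forward(real, dp2),
                                  discriminator_forward(fake, dp2)),
                 tolerance = 1e-9)
  }
  expect_error(discriminator_loss(real[0, , drop = FALSE], fake, dp2),
               "nonempty")
})

test_that("adversarial generator loss matches anchors, hand example, and oracle", {
  dp <- zero_disc(6L)
  fake <- matrix(runif(12), 2)
  expect_equal(generator_adv_loss(fake, dp), log(0.5))
  # D(fakes) = 0.2 and 0.4: (log 0.8 + log 0.6) / 2
  d <- passthrough_disc(-2)
  v <- matrix(c(qlogis(0.2) + 2, qlogis(0.4) + 2), 2, 1)
  expect_equal(generator_adv_loss(v, d), (log(0.8) + log(0.6)) / 2,
               tolerance = 1e-10)
  # a certain discriminator drives the loss to the clamped floor, finitely
  d_sure <- passthrough_disc(40)
  expect_true(is.finite(generator_adv_loss(matrix(5, 1, 1), d_sure)))
  set.seed(25)
  dp2 <- rand_disc(6L)
  for (rep in 1:20) {
    fake <- matrix(runif(18), 3)
    expect_equal(generator_adv_loss(fake, dp2),
                 oracle_adv_loss(discriminator_forward(fake, dp2)),
                 tolerance = 1e-9)
  }
})

test_that("losses stay finite across the whole [0,1] input range", {
  dp <- rand_disc(4L)
  grid <- matrix(c(0, 0, 1, 1, 0.5, 1, 0, 1), 2)
  expect_true(is.finite(discriminator_loss(grid, grid, dp)))
  expect_true(is.finite(generator_adv_loss(grid, dp)))
  expect_true(is.finite(generator_ce_loss(c(0, 1), c(0, 1))))
})

test_that("one adversarial step updates both networks and reports finite losses", {
  set.seed(26)
  coh <- tiny_cohort(n_patients = 8, mean_history_words = 10, seed = 8)
  inst <- make_instances(coh$records, coh$config$n_activities, seed = 9)
  cfg <- model_config(coh$config$n_activities, coh$config$n_words,
                      d_e = 8L, heads = 2L, d_f = 16L)
  m <- ndm_model(cfg, seed = 10)
  st <- adversarial_step(m, inst[1:4])
  expect_true(all(is.finite(st$losses)))
  expect_false(identical(st$model$params$D_W1, m$params$D_W1))
  expect_false(identical(st$model$params$g_W1, m$params$g_W1))
  expect_false(identical(st$model$params$act_emb, m$params$act_emb))

  # no-adversarial ablation: discriminator untouched, loss report reduces to L
  cfg_na <- model_config(coh$config$n_activities, coh$config$n_words,
                         d_e = 8L, heads = 2L, d_f = 16L,
                         use_adversarial = FALSE)
  m2 <- ndm_model(cfg_na, seed = 10)
  st2 <- adversarial_step(m2, inst[1:4])
  expect_identical(st2$model$params$D_W1, m2$params$D_W1)
  expect_true(is.na(st2$losses["d_loss"]))
  expect_true(is.finite(st2$losses["loss"]))
})
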