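test_that("positional encoding matches the sinusoid formula and bounds", {
  pe0 <- positional_encoding(0, 8L)
  expect_equal(pe0[c(1, 3, 5, 7)], rep(0, 4))
  expect_equal(pe0[c(2, 4, 6, 8)], rep(1, 4))
  pe1 <- positional_encoding(1, 8L)
  expect_equal(pe1[1], sin(1), tolerance = 1e-12)
  expect_equal(pe1[2], cos(1), tolerance = 1e-12)
  expect_equal(pe1[3], sin(1 / 100^(2 / 8)), tolerance = 1e-12)
  for (pos in c(1, 5, 50, 500))
    expect_true(all(abs(positional_encoding(pos, 16L)) <= 1))
  expect_error(positional_encoding(1, 7L), "even")
})

test_that("add_positions adds PE(i) to element i", {
  z <- matrix(0, 3, 4)
  pe <- add_positions(z)
  for (i in 1:3) expect_equal(pe[i, ], positional_encoding(i, 4L))
  x <- matrix(rnorm(4), 1, 4)
  expect_equal(add_positions(x), x + matrix(positional_encoding(1, 4L), 1))
  a <- matrix(rnorm(12), 3); b <- matrix(rnorm(12), 3)
  expect_equal(add_positions(a) + add_positions(b) - 2 * add_positions(0 * a),
               a + b)
})

test_that("self-attention matches the per-head scalar-loop oracle", {
  set.seed(11)
  for (rep in 1:20) {
    d_e <- 8L; h <- sample(c(2L, 4L), 1)
    layer <- rand_layer(d_e, h)
    x <- matrix(rnorm(4 * d_e), 4)
    for (sm in c("sqrt", "linear")) {
      expect_equal(self_attention(x, layer, scale_mode = sm),
                   oracle_self_attention(x, layer, scale_mode = sm),
                   tolerance = 1e-6)
    }
  }
})

test_that("single-token and identical-row inputs behave as forced", {
  set.seed(12)
  layer <- rand_layer(6L, 2L)
  x1 <- matrix(rnorm(6), 1)
  # n = 1: the softmax over one score is 1, so output is the V -> W_o path
  v_path <- do.call(cbind, lapply(layer$heads, function(h)
    x1 %*% h$W_V + matrix(h$b_V, 1))) %*% layer$W_o
  expect_equal(self_attention(x1, layer), v_path, tolerance = 1e-12)

  xr <- matrix(rep(rnorm(6), each = 3), 3)
  out <- self_attention(xr, layer)
  expect_equal(out[1, ], out[2, ])
  expect_equal(out[2, ], out[3, ])
  expect_error(self_attention(matrix(NaN, 2, 6), layer), "finite")
})

test_that("attention rows are convex combinations (weights sum to one)", {
  set.seed(13)
  layer <- rand_layer(6L, 2L)
  # constant value vectors: output must equal that constant's W_o image for
  # any scores, which holds iff each softmax row sums to exactly 1
  v0 <- rnorm(3)
  for (h in seq_along(layer$heads)) {
    layer$heads[[h]]$W_V <- matrix(0, 6, 3)
    layer$heads[[h]]$b_V <- matrix(v0, 1)
  }
  x <- matrix(rnorm(5 * 6), 5)
  want <- matrix(rep(v0, length(layer$heads)), 5, 6, byrow = TRUE) %*% layer$W_o
  expect_equal(self_attention(x, layer), want, tolerance = 1e-9)
})

test_that("without positional encodings self-attention is permutation equivariant", {
  set.seed(14)
  layer <- rand_layer(8L, 2L)
  x <- matrix(rnorm(5 * 8), 5)
  perm <- sample(5)
  expect_equal(self_attention(x[perm, ], layer),
               self_attention(x, layer)[perm, ], tolerance = 1e-10)
  # with PE added first, equivariance is broken: order is the PE's signal
  xp <- add_positions(x)
  xpp <- add_positions(x[perm, ])
  expect_false(isTRUE(all.equal(self_attention(xpp, layer),
                                self_attention(xp, layer)[perm, ])))
})

test_that("encoder block normalises rows and keeps shape across a stack", {
  set.seed(15)
  layer <- rand_layer(8L, 2L)
  # zero FFN: H = LayerNorm(A); rows standardised before gain/bias
  lz <- layer
  lz$W_F1[] <- 0; lz$b_F1[] <- 0; lz$W_F2[] <- 0; lz$b_F2[] <- 0
  lz$ln_gain[] <- 1; lz$ln_bias[] <- 0
  x <- matrix(rnorm(4 * 8), 4)
  h <- encoder_block(x, lz)
  expect_equal(rowMeans(h), rep(0, 4), tolerance = 1e-8)
  expect_equal(rowMeans(h^2), rep(1, 4), tolerance = 1e-3)
  a <- self_attention(x, lz)
  expect_equal(h, nextdayrec:::layernorm_rows(a, lz$ln_gain, lz$ln_bias))

  out <- x
  for (l in 1:3) out <- encoder_block(out, layer)
  expect_equal(dim(out), c(4L, 8L))
  # the conventional two-residual variant runs and differs
  expect_false(isTRUE(all.equal(encoder_block(x, layer, residual = "standard"),
                                encoder_block(x, layer))))
})

test_that("day aggregation matches its oracle and degenerates correctly", {
  set.seed(16)
  for (rep in 1:20) {
    d_e <- 6L
    h <- matrix(rnorm(5 * d_e), 5)
    pars <- rand_agg_params(d_e)
    got <- aggregate_days(h, pars)
    want <- oracle_aggregate_days(h, pars)
    expect_equal(got$z, want$z, tolerance = 1e-6)
    expect_equal(got$weights, want$weights, tolerance = 1e-6)
    expect_true(all(got$weights >= 0))
    expect_equal(sum(got$weights), 1, tolerance = 1e-6)
  }
  pars <- rand_agg_params(6L)
  h1 <- matrix(rnorm(6), 1)
  expect_equal(aggregate_days(h1, pars)$z, as.vector(h1))
  # constant scores give uniform weights, i.e. the row mean
  pc <- pars; pc$W2[] <- 0; pc$b2[] <- 3
  hm <- matrix(rnorm(4 * 6), 4)
  expect_equal(aggregate_days(hm, pc)$z, colMeans(hm), tolerance = 1e-10)
  # literal ratio mode: w = e / sum(e)
  lit <- aggregate_days(hm, pars, literal_ratio = TRUE)
  e <- nextdayrec:::day_agg_scores(hm, pars)
  expect_equal(lit$weights, e / sum(e))
})

test_that("history aggregation averages non-padding hidden states", {
  h1 <- matrix(rnorm(6), 1)
  expect_equal(aggregate_history(h1), as.vector(h1))
  h2 <- matrix(rep(h1, each = 2), 2)
  expect_equal(aggregate_history(h2), as.vector(h1))
  toy <- rbind(c(1, 0), c(0, 1))
  expect_equal(aggregate_history(toy), c(0.5, 0.5))
  h3 <- rbind(c(1, 1), c(5, 5), c(9, 9))
  expect_equal(aggregate_history(h3, mask = c(TRUE, TRUE, FALSE)), c(3, 3))
  expect_error(aggregate_history(h3, mask = rep(FALSE, 3)), "padding")
})

test_that("padded-and-masked forward equals the unpadded forward", {
  set.seed(17)
  layer <- rand_layer(8L, 2L)
  pars <- rand_agg_params(8L)
  x <- matrix(rnorm(5 * 8), 5)
  xp <- rbind(x, matrix(0, 3, 8))
  mask <- c(rep(TRUE, 5), rep(FALSE, 3))
  expect_equal(self_attention(xp, layer, mask = mask)[1:5, ],
               self_attention(x, layer), tolerance = 1e-10)
  expect_equal(encoder_block(xp, layer, mask = mask)[1:5, ],
               encoder_block(x, layer), tolerance = 1e-10)
  hp <- encoder_block(xp, layer, mask = mask)
  hu <- encoder_block(x, layer)
  agg_p <- aggregate_days(hp, pars, mask = mask)
  agg_u <- aggregate_days(hu, pars)
  expect_equal(agg_p$z, agg_u$z, tolerance = 1e-10)
  expect_equal(agg_p$weights[1:5], agg_u$weights, tolerance = 1e-10)
  expect_equal(agg_p$weights[6:8], rep(0, 3))
  expect_equal(aggregate_history(hp, mask = mask), aggregate_history(hu),
               tolerance = 1e-10)
})
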