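#' @title Reverse-mode automatic differentiation tape
#'
#' @description
#' A minimal tape-based reverse-mode autodiff engine over dense matrices,
#' used to train the recommender end to end. Every value on the tape is a
#' plain \code{matrix}; vectors are represented as 1-row or 1-column
#' matrices by the caller. The forward pass records one op per node; a
#' single backward sweep accumulates gradients for every node, and callers
#' collect gradients for the nodes they registered as parameters.
#'
#' Supported primitives cover exactly what the model needs: elementwise
#' arithmetic, matrix product, transpose, row broadcasting of biases, row
#' selection with scatter-add gradients, sigmoid/tanh/ReLU/exp/log,
#' numerically stable row softmax, row layer normalisation, column means
#' and maxima, summation, clamping and scalar scaling.
#'
#' @name autodiff
#' @keywords internal
NULL

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", 256L)
  tp$ops  <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tp, id) structure(list(tp = tp, id = id), class = "adnode")

is_adnode <- function(x) inherits(x, "adnode")

ad_push <- function(tp, val, op, args = integer(), extra = NULL) {
  # force promises before reading the counter: evaluating `val`/`args` may
  # itself push nodes (nested calls), so laziness here would corrupt ids
  force(val); force(args); force(extra)
  n <- tp$n + 1L
  if (n > length(tp$vals)) {
    length(tp$vals) <- 2L * n
    length(tp$ops)  <- 2L * n
  }
  tp$vals[[n]] <- val
  tp$ops[[n]]  <- list(op = op, args = args, extra = extra)
  tp$n <- n
  out <- list(tp = tp, id = n)
  class(out) <- "adnode"
  out
}

# Leaf node: constant or parameter (the distinction is kept by the caller,
# which records which ids belong to trainable parameters).
ad_input <- function(tp, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  ad_push(tp, x, "input")
}

ad_value <- function(x) x$tp$vals[[x$id]]

v_ <- function(tp, id) tp$vals[[id]]

ad_add <- function(a, b) ad_push(a$tp, ad_value(a) + ad_value(b), "add", c(a$id, b$id))
ad_sub <- function(a, b) ad_push(a$tp, ad_value(a) - ad_value(b), "sub", c(a$id, b$id))
ad_mul <- function(a, b) ad_push(a$tp, ad_value(a) * ad_value(b), "mul", c(a$id, b$id))
ad_div <- function(a, b) ad_push(a$tp, ad_value(a) / ad_value(b), "div", c(a$id, b$id))

# multiply by a fixed scalar constant
ad_smul <- function(a, k) ad_push(a$tp, ad_value(a) * k, "smul", a$id, extra = k)
# add a fixed constant (same shape or scalar)
ad_cadd <- function(a, k) ad_push(a$tp, ad_value(a) + k, "cadd", a$id)

ad_mm <- function(a, b) ad_push(a$tp, ad_value(a) %*% ad_value(b), "mm", c(a$id, b$id))
ad_t  <- function(a) ad_push(a$tp, t(ad_value(a)), "t", a$id)

# X (n x d) + row vector b (1 x d), broadcast over rows
ad_addrow <- function(x, b) {
  xv <- ad_value(x); bv <- ad_value(b)
  ad_push(x$tp, xv + matrix(bv, nrow(xv), ncol(xv), byrow = TRUE),
          "addrow", c(x$id, b$id))
}

# fused affine map: X %*% W + b (b broadcast over rows)
ad_affine <- function(x, w, b) {
  xv <- ad_value(x)
  y <- xv %*% ad_value(w)
  y <- y + matrix(ad_value(b), nrow(y), ncol(y), byrow = TRUE)
  ad_push(x$tp, y, "affine", c(x$id, w$id, b$id))
}

# row subset with duplicate-aware scatter-add gradient
ad_rowselect <- function(x, idx) {
  xv <- ad_value(x)
  ad_push(x$tp, xv[idx, , drop = FALSE], "rowselect", x$id,
          extra = list(idx = as.integer(idx), nrow = nrow(xv)))
}

ad_cbind2 <- function(a, b) {
  av <- ad_value(a)
  ad_push(a$tp, cbind(av, ad_value(b)), "cbind2", c(a$id, b$id),
          extra = ncol(av))
}

ad_rbind_list <- function(nodes) {
  tp <- nodes[[1L]]$tp
  vals <- lapply(nodes, ad_value)
  ad_push(tp, do.call(rbind, vals), "rbind", vapply(nodes, function(n) n$id, 0L),
          extra = vapply(vals, nrow, 0L))
}

ad_sigmoid <- function(a) ad_push(a$tp, plogis(ad_value(a)), "sigmoid", a$id)
ad_tanh    <- function(a) ad_push(a$tp, tanh(ad_value(a)), "tanh", a$id)
ad_relu    <- function(a) {
  av <- ad_value(a)
  ad_push(a$tp, av * (av > 0), "relu", a$id)
}
ad_exp <- function(a) ad_push(a$tp, exp(ad_value(a)), "exp", a$id)
ad_log <- function(a) ad_push(a$tp, log(ad_value(a)), "log", a$id)

ad_clamp <- function(a, lo, hi) {
  av <- ad_value(a)
  ad_push(a$tp, pmin(pmax(av, lo), hi), "clamp", a$id, extra = c(lo, hi))
}

# numerically stable softmax along each row; optional additive mask of the
# same shape (0 / -Inf style, passed as a fixed matrix of large negatives)
ad_softmax_rows <- function(a, mask = NULL) {
  av <- ad_value(a)
  if (!is.null(mask)) av <- av + mask
  mx <- av[cbind(seq_len(nrow(av)), max.col(av, ties.method = "first"))]
  e <- exp(av - mx)
  s <- e / rowSums(e)
  ad_push(a$tp, s, "softmax_rows", a$id, extra = mask)
}

ad_sum <- function(a) ad_push(a$tp, matrix(sum(ad_value(a)), 1L, 1L), "sum", a$id)

ad_colmeans <- function(a) {
  av <- ad_value(a)
  ad_push(a$tp, matrix(colMeans(av), 1L), "colmeans", a$id, extra = nrow(av))
}

ad_colmax <- function(a) {
  av <- ad_value(a)
  amax <- max.col(t(av), ties.method = "first")
  ad_push(a$tp, matrix(av[cbind(amax, seq_len(ncol(av)))], 1L), "colmax", a$id,
          extra = amax)
}

# per-row layer normalisation (population variance), with gain/bias rows
ad_layernorm <- function(x, gain, bias, eps = 1e-5) {
  xv <- ad_value(x)
  mu <- rowMeans(xv)
  xc <- xv - mu
  sd_ <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd_
  y <- sweep(sweep(xhat, 2L, as.vector(ad_value(gain)), "*"),
             2L, as.vector(ad_value(bias)), "+")
  ad_push(x$tp, y, "layernorm", c(x$id, gain$id, bias$id),
          extra = list(xhat = xhat, sd = sd_))
}

# multiply a matrix by a 1x1 node
ad_scale <- function(x, s) {
  ad_push(x$tp, ad_value(x) * as.vector(ad_value(s)), "scale", c(x$id, s$id))
}

#' Backward sweep
#'
#' Accumulates d(loss)/d(node) for every node on the tape of `loss`, which
#' must be a 1x1 node. Returns the list of gradient matrices indexed by node
#' id (NULL where the node does not influence the loss).
#' @noRd
ad_backward <- function(loss) {
  tp <- loss$tp
  n <- tp$n
  gr <- vector("list", n)
  gr[[loss$id]] <- matrix(1, 1L, 1L)
  acc <- function(id, g) {
    gr[[id]] <<- if (is.null(gr[[id]])) g else gr[[id]] + g
  }
  for (i in seq.int(n, 1L)) {
    g <- gr[[i]]
    if (is.null(g)) next
    rec <- tp$ops[[i]]
    a <- rec$args
    switch(rec$op,
      input = NULL,
      add = { acc(a[1L], g); acc(a[2L], g) },
      sub = { acc(a[1L], g); acc(a[2L], -g) },
      mul = { acc(a[1L], g * v_(tp, a[2L])); acc(a[2L], g * v_(tp, a[1L])) },
      div = {
        bv <- v_(tp, a[2L])
        acc(a[1L], g / bv)
        acc(a[2L], -g * v_(tp, a[1L]) / bv^2)
      },
      smul = acc(a[1L], g * rec$extra),
      cadd = acc(a[1L], g),
      mm = {
        acc(a[1L], g %*% t(v_(tp, a[2L])))
        acc(a[2L], t(v_(tp, a[1L])) %*% g)
      },
      t = acc(a[1L], t(g)),
      addrow = {
        acc(a[1L], g)
        acc(a[2L], matrix(colSums(g), 1L))
      },
      affine = {
        acc(a[1L], g %*% t(v_(tp, a[2L])))
        acc(a[2L], t(v_(tp, a[1L])) %*% g)
        acc(a[3L], matrix(colSums(g), 1L))
      },
      rowselect = {
        gx <- matrix(0, rec$extra$nrow, ncol(g))
        sums <- rowsum(g, group = rec$extra$idx)
        gx[as.integer(rownames(sums)), ] <- sums
        acc(a[1L], gx)
      },
      cbind2 = {
        k <- rec$extra
        acc(a[1L], g[, seq_len(k), drop = FALSE])
        acc(a[2L], g[, -seq_len(k), drop = FALSE])
      },
      rbind = {
        rows <- rec$extra
        off <- 0L
        for (j in seq_along(a)) {
          acc(a[j], g[off + seq_len(rows[j]), , drop = FALSE])
          off <- off + rows[j]
        }
      },
      sigmoid = {
        sv <- v_(tp, i)
        acc(a[1L], g * sv * (1 - sv))
      },
      tanh = acc(a[1L], g * (1 - v_(tp, i)^2)),
      relu = acc(a[1L], g * (v_(tp, a[1L]) > 0)),
      exp = acc(a[1L], g * v_(tp, i)),
      log = acc(a[1L], g / v_(tp, a[1L])),
      clamp = {
        av <- v_(tp, a[1L])
        inside <- (av >= rec$extra[1L]) & (av <= rec$extra[2L])
        acc(a[1L], g * inside)
      },
      softmax_rows = {
        sv <- v_(tp, i)
        rs <- rowSums(g * sv)
        acc(a[1L], sv * (g - rs))
      },
      sum = acc(a[1L], matrix(as.vector(g), nrow(v_(tp, a[1L])), ncol(v_(tp, a[1L])))),
      colmeans = {
        nr <- rec$extra
        acc(a[1L], matrix(rep(as.vector(g) / nr, each = nr), nr))
      },
      colmax = {
        av <- v_(tp, a[1L])
        gx <- matrix(0, nrow(av), ncol(av))
        gx[cbind(rec$extra, seq_len(ncol(av)))] <- as.vector(g)
        acc(a[1L], gx)
      },
      layernorm = {
        xhat <- rec$extra$xhat
        sd_ <- rec$extra$sd
        gainv <- as.vector(v_(tp, a[2L]))
        gy <- sweep(g, 2L, gainv, "*")
        m1 <- rowMeans(gy)
        m2 <- rowMeans(gy * xhat)
        acc(a[1L], (gy - m1 - xhat * m2) / sd_)
        acc(a[2L], matrix(colSums(g * xhat), 1L))
        acc(a[3L], matrix(colSums(g), 1L))
      },
      scale = {
        sv <- as.vector(v_(tp, a[2L]))
        acc(a[1L], g * sv)
        acc(a[2L], matrix(sum(g * v_(tp, a[1L])), 1L, 1L))
      },
      stop("internal: unknown tape op ", rec$op)
    )
  }
  gr
}

# Register a named list of parameter matrices on a tape; returns a list of
# nodes with the same names plus the id map needed to read gradients back.
ad_params <- function(tp, params) {
  nodes <- lapply(params, function(p) ad_input(tp, p))
  nodes
}

ad_collect_grads <- function(grads, nodes, params) {
  out <- params
  for (nm in names(nodes)) {
    g <- grads[[nodes[[nm]]$id]]
    out[[nm]] <- if (is.null(g)) params[[nm]] * 0 else g
  }
  out
}
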