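sigmoid <- function(x) plogis(x)

#' Look up activity embeddings for a day's set
#'
#' Returns one embedding row per activity in the set, ordered by ascending
#' id (set semantics: the input order is irrelevant, duplicates collapse).
#'
#' @param ids nonempty integer vector of activity ids.
#' @param table M x d_e embedding matrix (one row per activity).
#' @return n x d_e matrix, rows ordered by ascending id.
#' @export
embed_activities <- function(ids, table) {
  ids <- sort(unique(as.integer(ids)))
  if (length(ids) == 0L) stop("a day's activity set must be nonempty")
  if (any(ids < 1L) || any(ids > nrow(table)))
    stop("activity id out of range 1..", nrow(table))
  table[ids, , drop = FALSE]
}

#' Soft-attention day embedding
#'
#' Summarises one day's activity set as a fixed-length vector. In
#' `soft_attention` mode each activity embedding e_i receives a learned
#' scalar weight
#' \deqn{\alpha_i = q^\top \sigma(W e_i + b)}
#' and the day vector is the weighted sum \eqn{\sum_i \alpha_i e_i}; the
#' weights are left unnormalised (as the model defines them), so the result
#' scales with the set size unless `normalize = TRUE`. `average` and `max`
#' modes are the pooling ablations (elementwise mean / max of the
#' embeddings).
#'
#' Convention: embeddings are rows; the map W is stored so that the linear
#' transform of e_i is `e_i %*% W` (i.e. the stored matrix is the transpose
#' of a column-vector formulation).
#'
#' @param ids nonempty integer vector of activity ids.
#' @param table M x d_e embedding matrix.
#' @param params list with `q` (d_e x 1), `b` (1 x d_e), `W` (d_e x d_e);
#'   ignored by the pooling modes.
#' @param mode one of `"soft_attention"`, `"average"`, `"max"`.
#' @param activation inner nonlinearity, `"sigmoid"` (default) or `"tanh"`.
#' @param normalize if TRUE, softmax-normalise the attention weights.
#' @return numeric vector of length d_e.
#' @export
day_embed <- function(ids, table, params = NULL,
                      mode = c("soft_attention", "average", "max"),
                      activation = c("sigmoid", "tanh"), normalize = FALSE) {
  mode <- match.arg(mode)
  activation <- match.arg(activation)
  E <- embed_activities(ids, table)
  if (mode == "average") return(colMeans(E))
  if (mode == "max") return(apply(E, 2L, max))
  a <- day_attention_weights(ids, table, params, activation = activation,
                             normalize = normalize)
  as.vector(t(a) %*% E)
}

#' Per-activity attention weights of the day embedding
#'
#' The weights \eqn{\alpha_i} used by [day_embed()] in soft-attention mode,
#' aligned to ascending activity id, exposed for inspection and export.
#'
#' @inheritParams day_embed
#' @return numeric vector of weights, one per (unique) activity, ascending id
#'   order.
#' @export
day_attention_weights <- function(ids, table, params,
                                  activation = c("sigmoid", "tanh"),
                                  normalize = FALSE) {
  activation <- match.arg(activation)
  E <- embed_activities(ids, table)
  act <- if (activation == "sigmoid") sigmoid else tanh
  S <- act(sweep(E %*% params$W, 2L, as.vector(params$b), "+"))
  a <- as.vector(S %*% params$q)
  if (normalize) {
    e <- exp(a - max(a))
    a <- e / sum(e)
  }
  a
}

#' Export day attention weights as a table
#'
#' Convenience wrapper producing the per-day, per-activity attention table
#' used for inspecting what the day embedding attends to.
#'
#' @param observed_days list of activity-id sets.
#' @param table,params,activation as in [day_embed()].
#' @param vocab optional `activity_vocab` to attach names.
#' @return data.frame with columns `day`, `activity_id`, (optional)
#'   `activity`, `weight`.
#' @export
attention_weight_table <- function(observed_days, table, params,
                                   activation = "sigmoid", vocab = NULL) {
  rows <- lapply(seq_along(observed_days), function(t) {
    ids <- sort(unique(as.integer(observed_days[[t]])))
    w <- day_attention_weights(ids, table, params, activation = activation)
    df <- data.frame(day = t, activity_id = ids, weight = w)
    if (!is.null(vocab)) df$activity <- vocab$names[ids]
    df
  })
  do.call(rbind, rows)
}

#' Sinusoidal positional encoding
#'
#' Deterministic position vector with
#' \eqn{PE_{pos,2i} = \sin(pos / 100^{2i/d_e})} and
#' \eqn{PE_{pos,2i+1} = \cos(pos / 100^{2i/d_e})}; all entries lie in
#' [-1, 1]. Positions are 1-based (pos = 1 is the first day or word);
#' pos = 0 is allowed as a boundary value of the formula.
#'
#' @param pos nonnegative integer position.
#' @param d_e even embedding dimension.
#' @return numeric vector of length d_e.
#' @export
positional_encoding <- function(pos, d_e) {
  if (d_e %% 2L != 0L) stop("d_e must be even for sin/cos pairing")
  if (pos < 0) stop("pos must be >= 0")
  i <- seq.int(0L, d_e / 2L - 1L)
  denom <- 100^(2 * i / d_e)
  pe <- numeric(d_e)
  pe[2L * i + 1L] <- sin(pos / denom)
  pe[2L * i + 2L] <- cos(pos / denom)
  pe
}

pe_matrix <- function(n, d_e) {
  t(vapply(seq_len(n), positional_encoding, numeric(d_e), d_e = d_e))
}

#' Add positional encodings to a sequence
#'
#' Element i (1-based) of the output is `x[i, ] + positional_encoding(i)`.
#'
#' @param x n x d_e matrix of sequence-element embeddings (rows in order).
#' @return n x d_e matrix.
#' @export
add_positions <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (nrow(x) == 0L) stop("sequence must be nonempty")
  x + pe_matrix(nrow(x), ncol(x))
}
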