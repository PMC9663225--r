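#' Frequency-ranking baseline
#'
#' Ranks activities by how many observed days each has occurred in since
#' admission (descending), ties broken by ascending id; activities never
#' observed follow in ascending id order, so the list always has
#' min(K, M) entries.
#'
#' @param instance a `training_instance` (only `observed_days` is used).
#' @param n_activities vocabulary size M.
#' @param k length of the recommendation list.
#' @return integer vector of activity ids, best first.
#' @export
personal_top <- function(instance, n_activities, k) {
  freq <- frequency_vector(instance$observed_days, n_activities)
  ord <- order(-freq$counts, seq_len(n_activities))
  ord[seq_len(min(k, n_activities))]
}

#' Per-patient day-to-day transfer counts
#'
#' M x M matrix T with T[i, j] = number of adjacent observed-day pairs
#' (t, t+1) having activity i on day t and activity j on day t+1, built from
#' this patient's observed days only.
#'
#' @param observed_days list of >= 2 activity-id sets.
#' @param n_activities vocabulary size M.
#' @return M x M integer matrix.
#' @export
transfer_matrix <- function(observed_days, n_activities) {
  tm <- matrix(0L, n_activities, n_activities)
  for (t in seq_len(length(observed_days) - 1L)) {
    from <- unique(as.integer(observed_days[[t]]))
    to <- unique(as.integer(observed_days[[t + 1L]]))
    tm[from, to] <- tm[from, to] + 1L
  }
  tm
}

#' Last-day transfer baseline
#'
#' Builds the patient's transfer matrix and scores each candidate j by the
#' total transfer count from the activities of the last observed day,
#' score_j = sum over i in last day of T[i, j]. Ranking is by descending
#' score, ties by descending observed frequency, then ascending id. With a
#' single observed day there are no adjacent pairs and the method falls back
#' to [personal_top()].
#'
#' @inheritParams personal_top
#' @return integer vector of activity ids, best first.
#' @export
item_transfer <- function(instance, n_activities, k) {
  days <- instance$observed_days
  if (length(days) < 2L) return(personal_top(instance, n_activities, k))
  tm <- transfer_matrix(days, n_activities)
  last <- unique(as.integer(days[[length(days)]]))
  score <- colSums(tm[last, , drop = FALSE])
  freq <- frequency_vector(days, n_activities)
  ord <- order(-score, -freq$counts, seq_len(n_activities))
  ord[seq_len(min(k, n_activities))]
}
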