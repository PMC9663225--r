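#' Recall at K
#'
#' Fraction of the true next-day activities recovered in the top K of the
#' ranked recommendation list: |top-K intersect S| / |S|.
#'
#' @param ranked integer vector of recommended ids, best first.
#' @param target nonempty integer vector of true next-day ids.
#' @param k cutoff.
#' @return scalar in [0, 1].
#' @export
recall_at_k <- function(ranked, target, k) {
  if (length(target) == 0L) stop("target set must be nonempty")
  top <- ranked[seq_len(min(k, length(ranked)))]
  length(intersect(top, target)) / length(unique(target))
}

#' Normalised discounted cumulative gain at K
#'
#' Rank-discounted hit quality,
#' \deqn{DCG = \sum_{k=1}^{K} \delta(\hat S_k \in S) / \log_2(k+1)}
#' normalised by the ideal ranking's
#' \deqn{IDCG = \sum_{k=1}^{\min(K, |S|)} 1 / \log_2(k+1).}
#'
#' @inheritParams recall_at_k
#' @return scalar in [0, 1].
#' @export
ndcg_at_k <- function(ranked, target, k) {
  target <- unique(target)
  if (length(target) == 0L) stop("target set must be nonempty")
  top <- ranked[seq_len(min(k, length(ranked)))]
  pos <- seq_along(top)
  dcg <- sum((top %in% target) / log2(pos + 1))
  ideal <- seq_len(min(k, length(target)))
  idcg <- sum(1 / log2(ideal + 1))
  dcg / idcg
}

#' Split a cohort across inpatients
#'
#' Seeded random split into train / validation / test index sets.
#'
#' @param n number of instances (or a list, whose length is used).
#' @param ratios length-3 nonnegative weights summing to 1.
#' @param seed integer seed for the shuffle.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
split_cohort <- function(n, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (is.list(n)) n <- length(n)
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-8)
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- floor(ratios[1L] * n)
  n_val <- floor(ratios[2L] * n)
  list(train = sort(idx[seq_len(n_train)]),
       val = sort(idx[n_train + seq_len(n_val)]),
       test = sort(idx[-seq_len(n_train + n_val)]))
}

ranker_for <- function(method, n_activities, k_max) {
  if (is.function(method)) return(method)
  if (inherits(method, "ndm_model")) {
    return(function(inst) top_k(predict(method, inst)$scores, k_max))
  }
  if (is.character(method)) {
    fun <- switch(method,
                  personal_top = personal_top,
                  item_transfer = item_transfer,
                  stop("unknown baseline method: ", method))
    return(function(inst) fun(inst, n_activities, k_max))
  }
  stop("method must be a model, a baseline name, or a ranking function")
}

#' Evaluate a recommender over a cohort
#'
#' Computes per-patient Recall\@K and NDCG\@K on each instance's true
#' next-day set and averages them (unweighted) over patients, for every K in
#' `k_set`.
#'
#' @param method an `ndm_model`, a baseline name (`"personal_top"` or
#'   `"item_transfer"`), or a function `instance -> ranked id vector`.
#' @param instances nonempty list of `training_instance`s.
#' @param n_activities vocabulary size M.
#' @param k_set integer cutoffs (default 10, 15, 20, 25).
#' @param label method name used in the summary table.
#' @return An object of class `metric_report`: list with `summary`
#'   (data.frame with columns method, k, recall, ndcg) and `per_patient`
#'   (list of per-K matrices with one row per instance).
#' @export
evaluate_cohort <- function(method, instances, n_activities,
                            k_set = c(10L, 15L, 20L, 25L),
                            label = NULL) {
  if (length(instances) == 0L) stop("no instances to evaluate")
  if (is.null(label)) {
    label <- if (is.character(method)) method
             else if (inherits(method, "ndm_model")) "model"
             else "custom"
  }
  rank_fun <- ranker_for(method, n_activities, max(k_set))
  ranked <- lapply(instances, rank_fun)
  per <- lapply(k_set, function(k) {
    m <- t(vapply(seq_along(instances), function(i) {
      c(recall = recall_at_k(ranked[[i]], instances[[i]]$target_set, k),
        ndcg = ndcg_at_k(ranked[[i]], instances[[i]]$target_set, k))
    }, c(recall = 0, ndcg = 0)))
    m
  })
  names(per) <- paste0("k", k_set)
  summary <- data.frame(method = label, k = k_set,
                        recall = vapply(per, function(m) mean(m[, "recall"]), 0),
                        ndcg = vapply(per, function(m) mean(m[, "ndcg"]), 0),
                        row.names = NULL)
  structure(list(summary = summary, per_patient = per),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  df <- x$summary
  df$recall <- sprintf("%.4f", df$recall)
  df$ndcg <- sprintf("%.4f", df$ndcg)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a metric table as delimited text
#'
#' @param report a `metric_report` (or a list of them, concatenated).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(report, path) {
  if (inherits(report, "metric_report")) report <- list(report)
  df <- do.call(rbind, lapply(report, function(r) r$summary))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
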