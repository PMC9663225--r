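#' Synthetic EHR cohort configuration
#'
#' Describes the generative process for synthetic admissions carrying the
#' structure the recommender is designed to exploit: a high-frequency
#' long-term-order subset issued (almost) daily, per-condition activity
#' clusters signalled by dedicated history words, day-to-day transfer rules
#' (trigger activity today implies consequent activities tomorrow), and
#' uniform background noise.
#'
#' Activity ids are laid out deterministically: long-term orders first
#' (ids 1..`longterm_set_size`), then one block of `cluster_size` ids per
#' condition, then one consequent id per transfer rule, with the remaining
#' ids forming the noise pool. Word ids start with 3 signal words per
#' condition, the rest being filler vocabulary.
#'
#' @param n_patients number of admissions to simulate.
#' @param n_activities activity vocabulary size M.
#' @param n_words history-word vocabulary size J.
#' @param n_conditions number of latent condition clusters.
#' @param mean_days mean length of stay; stays are `2 + Poisson(mean_days-2)`
#'   so every record can be truncated.
#' @param mean_activities_per_day target mean basket size; used to derive the
#'   noise rate when `noise_rate` is `NULL`.
#' @param mean_history_words mean history length in tokens.
#' @param longterm_set_size number of long-term orders.
#' @param p_longterm daily occurrence probability of each long-term order.
#' @param cluster_size activities per condition cluster.
#' @param p_cluster daily occurrence probability of each cluster activity for
#'   patients with that condition.
#' @param transfer_rules list of `list(trigger=, consequents=, prob=)`; by
#'   default one rule per condition: the condition's first cluster activity
#'   triggers a dedicated consequent id with probability 0.8.
#' @param condition_word_signal_strength expected fraction of history tokens
#'   that are the patient's condition signal words.
#' @param noise_rate expected number of uniform noise activities per day;
#'   derived from `mean_activities_per_day` when `NULL`.
#' @param seed integer seed driving all randomness of the generator.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 200L, n_activities = 50L,
                             n_words = 120L, n_conditions = 4L,
                             mean_days = 9, mean_activities_per_day = 8,
                             mean_history_words = 168,
                             longterm_set_size = 5L, p_longterm = 0.9,
                             cluster_size = 4L, p_cluster = 0.7,
                             transfer_rules = NULL,
                             condition_word_signal_strength = 0.15,
                             noise_rate = NULL, seed = 1L) {
  stopifnot(mean_days >= 2, p_longterm >= 0, p_longterm <= 1,
            p_cluster >= 0, p_cluster <= 1,
            condition_word_signal_strength >= 0,
            condition_word_signal_strength <= 1)
  L <- as.integer(longterm_set_size)
  cs <- as.integer(cluster_size)
  nc <- as.integer(n_conditions)
  clusters <- lapply(seq_len(nc), function(c)
    L + (c - 1L) * cs + seq_len(cs))
  next_id <- L + nc * cs
  if (is.null(transfer_rules)) {
    transfer_rules <- lapply(seq_len(nc), function(c)
      list(trigger = clusters[[c]][1L],
           consequents = next_id + c,
           prob = 0.8))
  }
  transfer_rules <- lapply(transfer_rules, function(r) {
    stopifnot(r$prob >= 0, r$prob <= 1)
    list(trigger = as.integer(r$trigger),
         consequents = as.integer(r$consequents),
         prob = r$prob)
  })
  used <- unique(c(seq_len(L), unlist(clusters),
                   unlist(lapply(transfer_rules, function(r)
                     c(r$trigger, r$consequents)))))
  if (max(used, 0L) > n_activities)
    stop("n_activities too small for the requested structure")
  if (3L * nc > n_words) stop("n_words too small for condition signal words")
  if (is.null(noise_rate)) {
    per_rule <- mean(vapply(transfer_rules, function(r)
      r$prob * length(r$consequents), 0))
    expected <- L * p_longterm + cs * p_cluster + p_cluster * per_rule
    noise_rate <- max(0, mean_activities_per_day - expected)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_activities = as.integer(n_activities),
                 n_words = as.integer(n_words),
                 n_conditions = nc,
                 mean_days = mean_days,
                 mean_activities_per_day = mean_activities_per_day,
                 mean_history_words = mean_history_words,
                 longterm_set_size = L, p_longterm = p_longterm,
                 cluster_size = cs, p_cluster = p_cluster,
                 clusters = clusters,
                 transfer_rules = transfer_rules,
                 condition_word_signal_strength = condition_word_signal_strength,
                 noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic cohort
#'
#' Simulates `n_patients` admissions under a `synthetic_config`. Per patient:
#' a condition is sampled; the history is a mixture of that condition's
#' signal words and filler words; the stay length is `2 + Poisson`; each day
#' is the union of long-term orders (each with probability `p_longterm`),
#' cluster activities (each with `p_cluster`), consequents of rules triggered
#' by the previous day, and Poisson-many uniform noise activities. All
#' randomness comes from `config$seed`.
#'
#' @param config a `synthetic_config`.
#' @return list with `records` (list of `patient_record`s), `truth` (the
#'   planted structure: long-term ids, clusters, rules, signal words, and the
#'   per-patient condition assignment), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  M <- config$n_activities
  nc <- config$n_conditions
  longterm <- seq_len(config$longterm_set_size)
  clusters <- config$clusters
  signal_words <- lapply(seq_len(nc), function(c) (c - 1L) * 3L + 1:3)
  filler_words <- setdiff(seq_len(config$n_words), unlist(signal_words))
  structured <- unique(c(longterm, unlist(clusters)))
  noise_pool <- setdiff(seq_len(M), structured)

  records <- vector("list", config$n_patients)
  conditions <- integer(config$n_patients)
  for (p in seq_len(config$n_patients)) {
    cond <- sample.int(nc, 1L)
    conditions[p] <- cond
    n_days <- 2L + stats::rpois(1L, config$mean_days - 2)
    n_hist <- stats::rpois(1L, config$mean_history_words)
    is_signal <- stats::runif(n_hist) < config$condition_word_signal_strength
    hist <- integer(n_hist)
    n_sig <- sum(is_signal)
    if (n_sig) hist[is_signal] <- sample(signal_words[[cond]], n_sig,
                                         replace = TRUE)
    if (n_hist - n_sig)
      hist[!is_signal] <- sample(filler_words, n_hist - n_sig, replace = TRUE)
    days <- vector("list", n_days)
    prev <- integer()
    for (t in seq_len(n_days)) {
      day <- longterm[stats::runif(length(longterm)) < config$p_longterm]
      clu <- clusters[[cond]]
      day <- c(day, clu[stats::runif(length(clu)) < config$p_cluster])
      for (r in config$transfer_rules) {
        if (r$trigger %in% prev && stats::runif(1L) < r$prob)
          day <- c(day, r$consequents)
      }
      n_noise <- if (config$noise_rate > 0) stats::rpois(1L, config$noise_rate)
                 else 0L
      if (n_noise > 0L && length(noise_pool))
        day <- c(day, sample(noise_pool, min(n_noise, length(noise_pool))))
      if (length(day) == 0L) day <- clu[1L]
      day <- sort(unique(day))
      days[[t]] <- day
      prev <- day
    }
    records[[p]] <- patient_record(patient_id = sprintf("p%04d", p),
                                   history = hist, days = days)
  }
  truth <- list(longterm = longterm,
                clusters = clusters,
                transfer_rules = config$transfer_rules,
                signal_words = signal_words,
                conditions = conditions,
                noise_pool = noise_pool)
  list(records = records, truth = truth, config = config)
}

#' Empirical summary statistics of a cohort
#'
#' @param records nonempty list of `patient_record`s.
#' @param n_activities optional vocabulary size for the frequency table
#'   (defaults to the largest id observed).
#' @return list with `n_patients`, `mean_days`, `mean_activities_per_day`,
#'   `mean_history_words`, and `activity_freq` (per-activity count of
#'   day-occurrences across the cohort).
#' @export
empirical_summary <- function(records, n_activities = NULL) {
  if (length(records) == 0L) stop("cohort is empty")
  stays <- vapply(records, function(r) length(r$days), 0L)
  sizes <- unlist(lapply(records, function(r) vapply(r$days, length, 0L)))
  all_ids <- unlist(lapply(records, function(r) unlist(r$days)))
  if (is.null(n_activities)) n_activities <- max(all_ids)
  freq <- tabulate(all_ids, nbins = n_activities)
  list(n_patients = length(records),
       mean_days = mean(stays),
       mean_activities_per_day = mean(sizes),
       mean_history_words = mean(vapply(records, function(r)
         length(r$history), 0L)),
       activity_freq = freq)
}
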