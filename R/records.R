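#' Patient admission record
#'
#' One hospital admission: a tokenised medical-history sequence plus the
#' ordered list of inpatient days, each day being a set of activity ids.
#'
#' @param patient_id scalar identifier.
#' @param history integer vector of word ids (possibly empty).
#' @param days list of integer vectors; each must be a nonempty set of
#'   activity ids (duplicates are collapsed, ids sorted ascending).
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, history = integer(), days = list()) {
  days <- lapply(days, function(d) sort(unique(as.integer(d))))
  if (any(vapply(days, length, 0L) == 0L))
    stop("every inpatient day must contain at least one activity")
  structure(list(patient_id = patient_id,
                 history = as.integer(history),
                 days = days),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record> ", x$patient_id, ": ", length(x$days), " days, ",
      length(x$history), " history tokens\n", sep = "")
  invisible(x)
}

#' Training instance
#'
#' A truncated admission: the observed prefix of days, the history tokens,
#' and the first post-cut day as the prediction target, both as an id set and
#' as a multi-hot vector over the activity vocabulary.
#'
#' @param observed_days list of >= 1 activity-id sets.
#' @param history integer vector of word ids.
#' @param target_set nonempty integer vector of next-day activity ids.
#' @param n_activities vocabulary size M (for the multi-hot target).
#' @param patient_id optional identifier carried along.
#' @return An object of class `training_instance`.
#' @export
training_instance <- function(observed_days, history, target_set, n_activities,
                              patient_id = NA) {
  observed_days <- lapply(observed_days, function(d) sort(unique(as.integer(d))))
  if (length(observed_days) < 1L) stop("need at least one observed day")
  target_set <- sort(unique(as.integer(target_set)))
  if (length(target_set) == 0L) stop("target set must be nonempty")
  y <- integer(n_activities)
  y[target_set] <- 1L
  structure(list(patient_id = patient_id,
                 observed_days = observed_days,
                 history = as.integer(history),
                 target_set = target_set,
                 target_multihot = y),
            class = "training_instance")
}

default_cleaner <- "[^\\p{L}\\p{N}\\s]"

# split a cleaned string into tokens: whitespace-delimited runs, with CJK
# characters additionally split one token per character
tokenize_text <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  chunks <- strsplit(trimws(text), "\\s+", perl = TRUE)[[1]]
  chunks <- chunks[nzchar(chunks)]
  out <- lapply(chunks, function(ch) {
    # isolate CJK characters, then resplit
    sp <- gsub("(\\p{Han})", " \\1 ", ch, perl = TRUE)
    parts <- strsplit(trimws(sp), "\\s+", perl = TRUE)[[1]]
    parts[nzchar(parts)]
  })
  unlist(out, use.names = FALSE)
}

#' Merge and tokenise the three history texts
#'
#' Concatenates past history, current medical history, and allergy history in
#' that order, removes characters matched by the cleaner pattern, tokenises
#' (whitespace split plus one-token-per-CJK-character), and maps tokens to
#' word ids. In `"build"` mode unseen tokens are appended to the vocabulary;
#' in `"apply"` mode they are dropped.
#'
#' @param past,current,allergy character scalars (may be empty or NA).
#' @param vocab a `word_vocab`; defaults to an empty one.
#' @param mode `"build"` (grow the vocabulary) or `"apply"` (drop unknowns).
#' @param cleaner perl regex of characters to remove; the default removes
#'   everything that is not a letter (any script), digit, or whitespace.
#' @return list with `ids` (integer token sequence) and the (possibly grown)
#'   `vocab`.
#' @examples
#' merge_history("hypertension.", "fever;", "")$ids
#' @export
merge_history <- function(past = "", current = "", allergy = "",
                          vocab = word_vocab(), mode = c("build", "apply"),
                          cleaner = default_cleaner) {
  mode <- match.arg(mode)
  txts <- vapply(list(past, current, allergy),
                 function(x) if (is.null(x) || is.na(x)) "" else as.character(x),
                 "")
  merged <- paste(txts, collapse = " ")
  cleaned <- gsub(cleaner, " ", merged, perl = TRUE)
  tokens <- tokenize_text(cleaned)
  if (mode == "build") {
    new <- setdiff(unique(tokens), vocab$words)
    if (length(new)) vocab <- word_vocab(c(vocab$words, new))
    ids <- match(tokens, vocab$words)
  } else {
    ids <- match(tokens, vocab$words)
    ids <- ids[!is.na(ids)]
  }
  list(ids = as.integer(ids), vocab = vocab)
}

#' Canonicalise one day's raw activity names
#'
#' Maps raw names through the synonym map and vocabulary, collapsing
#' duplicates to set semantics.
#'
#' @param raw_names character vector of activity names observed in one day.
#' @param vocab an `activity_vocab`.
#' @param strict error on unknown or empty input (default), otherwise drop
#'   unknowns with a warning.
#' @return sorted integer vector of unique activity ids.
#' @export
canonicalize_day <- function(raw_names, vocab, strict = TRUE) {
  if (length(raw_names) == 0L) {
    if (strict) stop("a day must contain at least one activity")
    return(integer())
  }
  sort(unique(activity_ids(vocab, raw_names, strict = strict)))
}

#' Filter records by length of stay
#'
#' Drops admissions with too few or too many inpatient days; input order is
#' preserved.
#'
#' @param records list of `patient_record`s.
#' @param min_days,max_days inclusive bounds on the number of days.
#' @return the retained records.
#' @export
filter_by_stay_length <- function(records, min_days = 3L, max_days = 30L) {
  if (min_days < 1L || max_days < min_days)
    stop("need 1 <= min_days <= max_days")
  keep <- vapply(records, function(r) {
    n <- length(r$days)
    n >= min_days && n <= max_days
  }, NA)
  records[keep]
}

#' Truncate an admission into a training instance
#'
#' Keeps the first K days as the observed sequence, where K is a fraction f
#' of the stay drawn uniformly from `fraction_range` (or fixed to its
#' midpoint in deterministic mode), clamped so that at least one observed day
#' and one target day remain: K = clamp(round(f * n), 1, n - 1). The day
#' immediately after the cut becomes the ground-truth next-day set.
#'
#' @param record a `patient_record` with at least 2 days.
#' @param n_activities vocabulary size M.
#' @param fraction_range numeric length-2 truncation-fraction interval.
#' @param deterministic if TRUE use f = mean(fraction_range) instead of a
#'   random draw.
#' @return a `training_instance`.
#' @export
truncate_record <- function(record, n_activities,
                            fraction_range = c(0.70, 0.80),
                            deterministic = FALSE) {
  n <- length(record$days)
  if (n < 2L) stop("record needs at least 2 days to truncate")
  f <- if (deterministic) mean(fraction_range)
       else stats::runif(1L, fraction_range[1L], fraction_range[2L])
  k <- max(1L, min(n - 1L, as.integer(round(f * n))))
  training_instance(observed_days = record$days[seq_len(k)],
                    history = record$history,
                    target_set = record$days[[k + 1L]],
                    n_activities = n_activities,
                    patient_id = record$patient_id)
}

#' Build training instances from a cohort
#'
#' Applies stay-length filtering and per-record random truncation. Randomness
#' is drawn from R's RNG; call `set.seed()` (or pass `seed`) for
#' reproducibility.
#'
#' @param records list of `patient_record`s.
#' @param n_activities vocabulary size M.
#' @param min_days,max_days stay-length bounds.
#' @param fraction_range truncation-fraction interval.
#' @param deterministic fixed-fraction truncation instead of per-record draws.
#' @param seed optional integer seed.
#' @return list of `training_instance`s.
#' @export
make_instances <- function(records, n_activities, min_days = 3L, max_days = 30L,
                           fraction_range = c(0.70, 0.80),
                           deterministic = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kept <- filter_by_stay_length(records, min_days, max_days)
  lapply(kept, truncate_record, n_activities = n_activities,
         fraction_range = fraction_range, deterministic = deterministic)
}

#' Read and write record files
#'
#' Records are stored as line-delimited JSON, one admission per line with
#' fields `patient_id`, `history` (word ids) and `days` (array of
#' activity-id arrays). Writing then reading reproduces the records exactly.
#'
#' @param records list of `patient_record`s.
#' @param path file path.
#' @return `read_records` returns a list of `patient_record`s;
#'   `write_records` returns `path` invisibly.
#' @export
write_records <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(list(patient_id = r$patient_id,
                          history = I(r$history),
                          days = lapply(r$days, I)),
                     auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE,
                                       simplifyMatrix = FALSE),
                    error = function(e)
                      stop("malformed record on line ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    if (is.null(obj$patient_id) || is.null(obj$days))
      stop("record on line ", i, " is missing a required field", call. = FALSE)
    days <- obj$days
    if (!is.list(days)) days <- list(days)
    out[[i]] <- patient_record(patient_id = obj$patient_id,
                               history = if (is.null(obj$history)) integer()
                                         else as.integer(unlist(obj$history)),
                               days = days)
  }
  out
}

#' Read and write training-instance files
#'
#' Training instances are stored as line-delimited JSON with fields
#' `patient_id`, `observed_days`, `history`, and `target` (the target
#' activity-id set); the multi-hot target is rebuilt from the vocabulary
#' size on read.
#'
#' @param instances list of `training_instance`s.
#' @param path file path.
#' @param n_activities vocabulary size M used to rebuild multi-hot targets.
#' @return `read_instances` returns a list of `training_instance`s;
#'   `write_instances` returns `path` invisibly.
#' @export
write_instances <- function(instances, path) {
  lines <- vapply(instances, function(x) {
    jsonlite::toJSON(list(patient_id = x$patient_id,
                          observed_days = lapply(x$observed_days, I),
                          history = I(x$history),
                          target = I(x$target_set)),
                     auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_instances
#' @export
read_instances <- function(path, n_activities) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE,
                                       simplifyMatrix = FALSE),
                    error = function(e)
                      stop("malformed instance on line ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    if (is.null(obj$observed_days) || is.null(obj$target))
      stop("instance on line ", i, " is missing a required field",
           call. = FALSE)
    days <- obj$observed_days
    if (!is.list(days)) days <- list(days)
    training_instance(observed_days = days,
                      history = if (is.null(obj$history)) integer()
                                else as.integer(unlist(obj$history)),
                      target_set = as.integer(unlist(obj$target)),
                      n_activities = n_activities,
                      patient_id = obj$patient_id)
  })
}
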