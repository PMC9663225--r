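#' Activity vocabulary
#'
#' An ordered vocabulary of medical-activity names (drug administrations,
#' tests, nursing orders, ...). Activity ids are the positions 1..M of the
#' names, so ids and names are bijective. A synonym map carries raw spellings
#' (for example a Chinese and an English name for the same drug) to their
#' canonical entry.
#'
#' @param names character vector of unique canonical activity names.
#' @param synonyms named character vector; names are raw spellings, values are
#'   canonical names that must exist in `names`.
#' @return An object of class `activity_vocab` with elements `names` and
#'   `synonyms`.
#' @examples
#' v <- activity_vocab(c("aspirin", "ct scan"),
#'                     synonyms = c("阿司匹林" = "aspirin"))
#' activity_ids(v, c("aspirin", "阿司匹林"))
#' @export
activity_vocab <- function(names, synonyms = character()) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("activity names must be unique")
  if (length(synonyms)) {
    if (is.null(base::names(synonyms)) || any(base::names(synonyms) == ""))
      stop("synonyms must be a named character vector")
    missing <- setdiff(unname(synonyms), names)
    if (length(missing))
      stop("synonym targets not in vocabulary: ", paste(missing, collapse = ", "))
  }
  structure(list(names = names, synonyms = synonyms), class = "activity_vocab")
}

#' @export
print.activity_vocab <- function(x, ...) {
  cat("<activity_vocab> ", length(x$names), " activities, ",
      length(x$synonyms), " synonyms\n", sep = "")
  invisible(x)
}

#' Number of entries in a vocabulary
#' @param vocab an `activity_vocab` or `word_vocab`.
#' @return integer count.
#' @export
vocab_size <- function(vocab) {
  UseMethod("vocab_size")
}

#' @export
vocab_size.activity_vocab <- function(vocab) length(vocab$names)

#' @export
vocab_size.word_vocab <- function(vocab) length(vocab$words)

#' Map activity names to ids
#'
#' Raw names are first passed through the synonym map, then looked up in the
#' vocabulary. Unknown names raise an error in strict mode and are dropped
#' (with a warning) otherwise.
#'
#' @param vocab an `activity_vocab`.
#' @param raw_names character vector of raw activity names.
#' @param strict error on unknown names (default) instead of dropping them.
#' @return integer vector of ids (1..M), same order as the retained inputs.
#' @export
activity_ids <- function(vocab, raw_names, strict = TRUE) {
  raw_names <- as.character(raw_names)
  hit <- match(raw_names, names(vocab$synonyms))
  canon <- ifelse(is.na(hit), raw_names, unname(vocab$synonyms)[hit])
  ids <- match(canon, vocab$names)
  if (anyNA(ids)) {
    bad <- unique(raw_names[is.na(ids)])
    if (strict) stop("unknown activity name(s): ", paste(bad, collapse = ", "))
    warning("dropping unknown activity name(s): ", paste(bad, collapse = ", "))
    ids <- ids[!is.na(ids)]
  }
  as.integer(ids)
}

#' Word vocabulary for medical-history text
#'
#' Ordered lexicon of history tokens. Token ids are positions 1..J; the id 0
#' is reserved for padding and never denotes a real word.
#'
#' @param words character vector of unique tokens.
#' @return An object of class `word_vocab` with elements `words` and `pad_id`.
#' @export
word_vocab <- function(words = character()) {
  words <- as.character(words)
  if (anyDuplicated(words)) stop("words must be unique")
  structure(list(words = words, pad_id = 0L), class = "word_vocab")
}

#' @export
print.word_vocab <- function(x, ...) {
  cat("<word_vocab> ", length(x$words), " words (pad id ", x$pad_id, ")\n",
      sep = "")
  invisible(x)
}
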