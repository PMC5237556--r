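# The 14 lexical features of a transcript.
#
# All counts are pure functions of the tokens, marker events and terminators
# delivered by the CHAT reader; marker-derived counts (repetitions,
# revisions, ...) are exactly the marker_counts() tallies.

#' Default closed-class function word list
#'
#' Determiners, pronouns, prepositions, conjunctions and auxiliaries.  The
#' list is configurable in [lexical_profile()]; matching is case-insensitive.
#'
#' @return Character vector of function words.
#' @export
ld_function_words <- function() {
  c(# determiners / quantifiers
    "the", "a", "an", "this", "that", "these", "those", "some", "any",
    "each", "every", "no", "all", "both", "few", "many", "much", "more",
    "most", "other", "another", "such",
    # pronouns
    "i", "you", "he", "she", "it", "we", "they", "me", "him", "her", "us",
    "them", "my", "your", "his", "its", "our", "their", "mine", "yours",
    "hers", "ours", "theirs", "myself", "yourself", "himself", "herself",
    "itself", "ourselves", "themselves", "who", "whom", "whose", "which",
    "what", "there", "here",
    # prepositions
    "in", "on", "at", "by", "for", "with", "about", "against", "between",
    "into", "through", "during", "before", "after", "above", "below", "to",
    "from", "up", "down", "of", "off", "over", "under", "out", "near",
    # conjunctions
    "and", "or", "but", "nor", "so", "yet", "because", "although", "while",
    "if", "unless", "until", "when", "where", "as", "than", "whether",
    # auxiliaries / copula
    "am", "is", "are", "was", "were", "be", "been", "being", "do", "does",
    "did", "have", "has", "had", "will", "would", "shall", "should", "can",
    "could", "may", "might", "must", "not")
}

#' Count morphemes with a small English inflection segmenter
#'
#' Each word contributes one free morpheme plus one bound morpheme per
#' recognised inflection: plural/3sg `-s`, past `-ed`, progressive `-ing`,
#' possessive `'s` and negation `n't`.  A crude but deterministic stand-in
#' for full morphological analysis.
#'
#' @param x a character vector of tokens or an `ld_transcript`.
#' @return Total morpheme count.
#' @export
morpheme_count <- function(x) {
  if (inherits(x, "ld_transcript"))
    x <- unlist(lapply(x$utterances, `[[`, "tokens"), use.names = FALSE)
  if (!length(x)) return(0L)
  w <- tolower(x)
  n <- length(w)
  bound <- integer(n)
  has <- function(pat, minlen) grepl(pat, w) & nchar(w) >= minlen
  bound <- bound + has("n't$", 4L)
  w2 <- sub("n't$", "", w)
  bound <- bound + grepl("'s$", w2)
  w2 <- sub("'s$", "", w2)
  bound <- bound + (grepl("ing$", w2) & nchar(w2) > 4L)
  bound <- bound + (grepl("ed$", w2) & nchar(w2) > 3L)
  bound <- bound + (grepl("[^su]s$", w2) & nchar(w2) > 3L)
  as.integer(n + sum(bound))
}

#' The 14-feature lexical profile of a transcript
#'
#' * `utterances`: number of main-tier utterances.
#' * `mlu`: mean length of utterance, total words / utterances (word-based,
#'   not the classic morpheme-based MLU).
#' * `function_words`: tokens found in `function_words` (case-insensitive).
#' * `unique_words`: word count minus immediately repeated word tokens
#'   (the `[/]` marker scope).
#' * `word_count`: all word tokens, repeated words included.
#' * `character_length`: non-whitespace characters over all surface tokens.
#' * `total_sentences`: terminator-delimited sentence groups.
#' * `repetitions`, `revisions`, `trailing_off`, `word_replacement`,
#'   `incomplete_words`, `filler_words`: marker tallies.
#' * `morphemes`: [morpheme_count()].
#'
#' @param t an `ld_transcript`.
#' @param function_words closed word list used for `function_words`.
#' @return Named numeric vector of the 14 features (all zero, `mlu = 0`,
#'   for an empty transcript).
#' @export
lexical_profile <- function(t, function_words = ld_function_words()) {
  stopifnot(inherits(t, "ld_transcript"))
  tokens <- unlist(lapply(t$utterances, `[[`, "tokens"), use.names = FALSE)
  if (is.null(tokens)) tokens <- character()
  n_utt <- length(t$utterances)
  wc <- length(tokens)
  mk <- marker_counts(t)
  repeated_tokens <- 0L
  for (u in t$utterances) {
    ev <- u$events
    if (nrow(ev))
      repeated_tokens <- repeated_tokens +
        sum(ev$width[ev$kind == "repetition"])
  }
  c(utterances = n_utt,
    mlu = if (n_utt) wc / n_utt else 0,
    function_words = sum(tolower(tokens) %in% tolower(function_words)),
    unique_words = wc - repeated_tokens,
    word_count = wc,
    character_length = sum(nchar(gsub("[[:space:]]", "", tokens))),
    total_sentences = length(sentence_groups(t)),
    repetitions = unname(mk["repetition"]),
    revisions = unname(mk["revision"]),
    morphemes = morpheme_count(tokens),
    trailing_off = unname(mk["trailing_off"]),
    word_replacement = unname(mk["replacement"]),
    incomplete_words = unname(mk["incomplete_word"]),
    filler_words = unname(mk["filler"]))
}

#' Canonical names of the 23 syntactic + lexical features
#' @return Character vector, syntactic block first.
#' @export
feature_names_23 <- function() {
  c("coordinated_sentences", "subordinated_sentences", "reduced_sentences",
    "n_predicates", "avg_predicates_per_sentence", "n_dependencies",
    "avg_dependencies_per_sentence", "dependency_distance",
    "n_production_rules",
    "utterances", "mlu", "function_words", "unique_words", "word_count",
    "character_length", "total_sentences", "repetitions", "revisions",
    "morphemes", "trailing_off", "word_replacement", "incomplete_words",
    "filler_words")
}

#' Build the subjects-by-features table
#'
#' @param transcripts list of `ld_transcript`.
#' @param parses optional list (same length) of `list(trees=, deps=)` per
#'   subject; when absent the 9 syntactic columns are zero.
#' @param function_words see [lexical_profile()].
#' @return Data frame with `subject_id`, `group`, `age` and the 23 feature
#'   columns of [feature_names_23()].
#' @export
build_feature_table <- function(transcripts, parses = NULL,
                                function_words = ld_function_words()) {
  stopifnot(is.null(parses) || length(parses) == length(transcripts))
  rows <- lapply(seq_along(transcripts), function(i) {
    t <- transcripts[[i]]
    syn <- if (is.null(parses)) {
      stats::setNames(numeric(9), feature_names_23()[1:9])
    } else {
      syntactic_profile(parses[[i]]$trees, parses[[i]]$deps)
    }
    lex <- lexical_profile(t, function_words)
    cbind(data.frame(subject_id = t$subject_id, group = t$group,
                     age = t$age, stringsAsFactors = FALSE),
          as.data.frame(as.list(c(syn, lex))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a feature table as CSV
#' @param ft table from [build_feature_table()].
#' @param path output file.
#' @export
write_feature_table <- function(ft, path) {
  utils::write.csv(ft, path, row.names = FALSE)
  invisible(path)
}
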