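# Bigram/trigram count features over a corpus vocabulary.
#
# N-grams are sliding windows within an utterance (never across utterance
# boundaries, no padding); tokens are lowercased; filler words are marker
# events, not tokens, so they never enter n-grams.

#' Extract n-grams from a token sequence
#'
#' @param tokens character vector (one utterance, markers stripped).
#' @param n window size, `n >= 1`.
#' @return Character vector of space-joined n-grams (a multiset: duplicates
#'   are retained).  Empty when `length(tokens) < n`.
#' @export
extract_ngrams <- function(tokens, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  tokens <- tolower(tokens)
  L <- length(tokens)
  if (L < n) return(character())
  vapply(seq_len(L - n + 1L), function(i)
    paste(tokens[i:(i + n - 1L)], collapse = " "), "")
}

transcript_ngrams <- function(t, orders = c(2L, 3L)) {
  unlist(lapply(t$utterances, function(u)
    unlist(lapply(orders, function(n) extract_ngrams(u$tokens, n)),
           use.names = FALSE)), use.names = FALSE)
}

#' Build the corpus n-gram count table
#'
#' One column per distinct bigram/trigram observed anywhere in the corpus
#' (column order: first seen wins, lexicographic within a transcript via
#' scan order); one row of raw counts per subject.
#'
#' @param transcripts list of `ld_transcript`.
#' @param orders n-gram orders, default bigrams and trigrams.
#' @return List with `counts` (a sparse `dgCMatrix`, subjects x vocabulary),
#'   `vocabulary`, and `subjects`.
#' @export
build_ngram_table <- function(transcripts, orders = c(2L, 3L)) {
  per_subj <- lapply(transcripts, transcript_ngrams, orders = orders)
  vocab <- unique(unlist(per_subj, use.names = FALSE))
  if (is.null(vocab)) vocab <- character()
  subjects <- vapply(transcripts, function(t) t$subject_id, "")
  i <- integer(); j <- integer(); x <- integer()
  for (s in seq_along(per_subj)) {
    if (!length(per_subj[[s]])) next
    tab <- table(per_subj[[s]])
    j <- c(j, match(names(tab), vocab))
    i <- c(i, rep.int(s, length(tab)))
    x <- c(x, as.integer(tab))
  }
  counts <- Matrix::sparseMatrix(
    i = i, j = j, x = x,
    dims = c(length(transcripts), max(length(vocab), 1L)),
    dimnames = list(subjects,
                    if (length(vocab)) vocab else "__empty__"))
  if (!length(vocab)) counts <- counts[, 0, drop = FALSE]
  structure(list(counts = counts, vocabulary = vocab, subjects = subjects),
            class = "ld_ngram_table")
}

#' @export
print.ld_ngram_table <- function(x, ...) {
  cat(sprintf("<ld_ngram_table> %d subjects x %d n-grams (%d nonzero)\n",
              nrow(x$counts), length(x$vocabulary),
              Matrix::nnzero(x$counts)))
  invisible(x)
}

#' Export an n-gram table
#'
#' Sparse MatrixMarket (`.mtx` + row/column label files) or dense CSV.
#'
#' @param nt an `ld_ngram_table`.
#' @param path output path; `format="mtx"` appends `.mtx`, `.rows`, `.cols`.
#' @param format `"mtx"` or `"csv"`.
#' @export
write_ngram_table <- function(nt, path, format = c("mtx", "csv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(nt$counts, paste0(path, ".mtx"))
    writeLines(nt$subjects, paste0(path, ".rows"))
    writeLines(nt$vocabulary, paste0(path, ".cols"))
  } else {
    utils::write.csv(as.data.frame(as.matrix(nt$counts)), paste0(path, ".csv"))
  }
  invisible(path)
}
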