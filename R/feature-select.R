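# Information-gain feature ranking.
#
# Numeric features are discretized by supervised MDL binning (Fayyad-Irani
# recursive entropy partitioning with the MDLPC acceptance criterion), then
# IG = H(class) - H(class | bin) in bits.  Features for which no cut is
# accepted have a single bin and hence zero gain.

entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

class_entropy <- function(labels) entropy_bits(table(labels))

# Candidate cut points are boundary midpoints between adjacent distinct
# values (restricting to class-boundary points is an optimisation only; all
# midpoints are scanned for robustness with ties).
best_cut <- function(x, y) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(NULL)
  cuts <- (ux[-1] + ux[-length(ux)]) / 2
  n <- length(x)
  best <- NULL
  for (cp in cuts) {
    left <- y[x <= cp]; right <- y[x > cp]
    e <- (length(left) / n) * class_entropy(left) +
         (length(right) / n) * class_entropy(right)
    if (is.null(best) || e < best$e - 1e-12)
      best <- list(cut = cp, e = e,
                   left = left, right = right)
  }
  best
}

# Fayyad-Irani MDLPC acceptance for a candidate binary split.
mdl_accepts <- function(y, left, right) {
  n <- length(y)
  k <- length(unique(y)); k1 <- length(unique(left)); k2 <- length(unique(right))
  ent <- class_entropy(y)
  gain <- ent - (length(left) / n) * class_entropy(left) -
                (length(right) / n) * class_entropy(right)
  delta <- log2(3^k - 2) -
    (k * ent - k1 * class_entropy(left) - k2 * class_entropy(right))
  gain > (log2(n - 1) + delta) / n
}

#' Supervised MDL cut points for a numeric feature
#'
#' @param x numeric values.
#' @param y class labels (any atomic type).
#' @return Sorted numeric vector of accepted cut points (possibly empty).
#' @export
mdl_cuts <- function(x, y) {
  rec <- function(xs, ys) {
    b <- best_cut(xs, ys)
    if (is.null(b) || !mdl_accepts(ys, b$left, b$right)) return(numeric())
    li <- xs <= b$cut
    c(rec(xs[li], ys[li]), b$cut, rec(xs[!li], ys[!li]))
  }
  sort(rec(x, y))
}

#' Information gain of a feature for a class variable
#'
#' `IG = H(class) - H(class | feature)` in bits, with numeric features
#' discretized by [mdl_cuts()].  By convention single-class labels and
#' constant features have zero gain.
#'
#' @param values numeric feature vector.
#' @param labels class labels, same length.
#' @return Gain in bits, in `[0, H(class)]`.
#' @export
information_gain <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  if (!length(values)) return(0)
  if (length(unique(labels)) < 2L) return(0)
  if (length(unique(values)) < 2L) return(0)
  cuts <- mdl_cuts(values, labels)
  if (!length(cuts)) return(0)
  bins <- findInterval(values, cuts)
  n <- length(values)
  cond <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    cond <- cond + (sum(sel) / n) * class_entropy(labels[sel])
  }
  max(class_entropy(labels) - cond, 0)
}

#' Rank features by information gain and keep the top k
#'
#' Stable sort by gain descending, ties broken by feature name so the
#' ranking is deterministic.  Features whose gain is exactly zero carry no
#' class information under the selection metric and are discarded by
#' default (the usual gain-threshold-0 ranker cutoff); when nothing has
#' positive gain the first `k` features in tie order are kept so callers
#' always get a usable model.
#'
#' @param x data frame or matrix (dense or sparse) of feature columns.
#' @param labels class labels, one per row.
#' @param k number of features to keep (`k >= ncol` returns everything).
#' @param drop_zero_gain discard zero-gain features (default TRUE).
#' @return List with `ranking` (data frame `feature`, `gain_bits`, all
#'   features, gains non-increasing) and `selection` (top-k feature names).
#' @export
rank_top_k <- function(x, labels, k = 1000L, drop_zero_gain = TRUE) {
  stopifnot(k >= 1)
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(x)))
  gains <- vapply(seq_len(ncol(x)), function(j) {
    col <- if (is.data.frame(x)) as.numeric(x[[j]]) else as.numeric(x[, j])
    information_gain(col, labels)
  }, 0)
  ord <- order(-gains, nm)
  ranking <- data.frame(feature = nm[ord], gain_bits = gains[ord],
                        stringsAsFactors = FALSE)
  sel <- if (drop_zero_gain && any(ranking$gain_bits > 0))
    ranking$feature[ranking$gain_bits > 0] else ranking$feature
  list(ranking = ranking,
       selection = utils::head(sel, k))
}

#' Feature-group masks for the published model names
#'
#' Maps a model name to the feature columns it uses:
#' * `23-syntactic-lexical-only`: the 23 syntactic + lexical features.
#' * `top-1000-n-gram-only`: IG top-k n-gram columns only.
#' * `top-combined-1000`: IG top-k over the combined feature space.
#' * `11-t-test-sig`: the 11 screening-significant syntactic/lexical
#'   features.
#' * `3-MLR-sig`: the three features surviving age-adjusted logistic
#'   regression.
#'
#' @param model one of the names above.
#' @param feature_names all available feature names (23 features first,
#'   n-grams after), used for the IG-based masks.
#' @param labels class labels (required for IG-based masks).
#' @param x feature matrix aligned with `feature_names` (required for
#'   IG-based masks).
#' @param k top-k size for the IG masks.
#' @return Character vector of selected feature names.
#' @export
feature_mask <- function(model, feature_names, labels = NULL, x = NULL,
                         k = 1000L) {
  f23 <- feature_names_23()
  sig11 <- c("reduced_sentences", "n_predicates",
             "avg_predicates_per_sentence", "utterances", "mlu",
             "repetitions", "revisions", "trailing_off", "word_replacement",
             "incomplete_words", "filler_words")
  sig3 <- c("reduced_sentences", "mlu", "trailing_off")
  switch(model,
    "23-syntactic-lexical-only" = intersect(f23, feature_names),
    "11-t-test-sig" = intersect(sig11, feature_names),
    "3-MLR-sig" = intersect(sig3, feature_names),
    "top-1000-n-gram-only" = {
      ng <- setdiff(feature_names, f23)
      stopifnot(!is.null(labels), !is.null(x))
      idx <- match(ng, feature_names)
      rank_top_k(x[, idx, drop = FALSE], labels, k)$selection
    },
    "top-combined-1000" = {
      stopifnot(!is.null(labels), !is.null(x))
      rank_top_k(x, labels, k)$selection
    },
    stop("unknown model name: ", model))
}
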