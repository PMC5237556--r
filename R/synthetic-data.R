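# Synthetic two-group cohorts of CHAT-formatted picture-description
# transcripts.
#
# The generator states a world: per-subject feature targets are drawn from
# the configured group distributions (rounded truncated normals for counts,
# a lognormal for MLU, Poisson for planted phrase rates), then a transcript
# is assembled from a small template bank so that the CHAT reader and the
# feature extractors recover the planted values.  Arithmetic identities
# (word_count = sum of utterance lengths = mlu x utterances) hold by
# construction; where the three configured marginals cannot hold
# simultaneously, utterances and MLU are drawn and word count is realized
# through a Gaussian copula whose correlation is derived from the
# configured word-count mean (see the methods vignette).

# ---------------------------------------------------------------- config --

two_group <- function(pradg_mean, pradg_sd, heg_mean, heg_sd) {
  list(PrADG = c(mean = pradg_mean, sd = pradg_sd),
       HEG = c(mean = heg_mean, sd = heg_sd))
}

#' Cohort generator configuration
#'
#' Defaults are the published group summary parameters of the clinical
#' study this package emulates: 99 subjects per group, per-feature
#' mean (sd) for each planted lexical/syntactic target, per-n-gram
#' occurrence rates, and group age distributions.
#'
#' @param n_per_group subjects per group.
#' @param overrides named list replacing individual entries (same shapes as
#'   the defaults).
#' @return List of class `ld_cohort_config`.
#' @export
cohort_config <- function(n_per_group = 99L, overrides = list()) {
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    age = two_group(70.45, 8.916, 65.26, 8.388),
    lexical = list(
      utterances       = two_group(50.52, 35.61, 31.05, 15.49),
      mlu              = two_group(2.65, 1.70, 4.03, 2.25),
      word_count       = two_group(127.79, 72.62, 127.69, 68.45),
      function_words   = two_group(58.00, 35.84, 59.71, 35.33),
      total_sentences  = two_group(14.01, 8.33, 12.48, 5.56),
      repetitions      = two_group(2.09, 3.08, 0.70, 1.03),
      revisions        = two_group(4.54, 5.27, 2.02, 2.20),
      trailing_off     = two_group(0.85, 1.18, 0.14, 0.38),
      word_replacement = two_group(1.28, 1.37, 0.44, 0.77),
      incomplete_words = two_group(5.56, 4.05, 3.11, 3.42),
      filler_words     = two_group(6.47, 6.89, 4.30, 3.53)),
    syntactic = list(
      coordinated_sentences  = two_group(5.09, 3.22, 4.85, 2.99),
      subordinated_sentences = two_group(5.42, 3.63, 5.13, 3.19),
      reduced_sentences      = two_group(2.95, 2.48, 4.08, 2.57),
      n_predicates           = two_group(5.54, 3.44, 6.94, 3.53)),
    # mean occurrence counts per transcript of the planted n-grams
    ngram_rates = list(
      "the window"     = c(PrADG = 0.12, HEG = 0.62),
      "mother is"      = c(PrADG = 0.15, HEG = 0.60),
      "be quiet"       = c(PrADG = 0.01, HEG = 0.22),
      "is open"        = c(PrADG = 0.04, HEG = 0.31),
      "the mother"     = c(PrADG = 0.22, HEG = 0.61),
      "tipping over"   = c(PrADG = 0.00, HEG = 0.17),
      "window is"      = c(PrADG = 0.01, HEG = 0.19),
      "girl is"        = c(PrADG = 0.14, HEG = 0.44),
      "is tipping"     = c(PrADG = 0.00, HEG = 0.14),
      "the window is"  = c(PrADG = 0.01, HEG = 0.18),
      "the mother is"  = c(PrADG = 0.11, HEG = 0.42),
      "of the cookie"  = c(PrADG = 0.08, HEG = 0.32),
      "the stool"      = c(PrADG = 0.33, HEG = 0.58),
      "is overflowing" = c(PrADG = 0.05, HEG = 0.22),
      "the sink"       = c(PrADG = 0.68, HEG = 1.17),
      "this is"        = c(PrADG = 0.25, HEG = 0.02),
      "cookie out"     = c(PrADG = 0.00, HEG = 0.11),
      "cookie out of"  = c(PrADG = 0.00, HEG = 0.11),
      "a cookie out"   = c(PrADG = 0.00, HEG = 0.10),
      "off the cookie" = c(PrADG = 0.01, HEG = 0.14)))
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  validate_cohort_config(cfg)
  structure(cfg, class = "ld_cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_per_group >= 1)
  all_sd <- c(vapply(cfg$lexical, function(g) c(g$PrADG["sd"], g$HEG["sd"]), numeric(2)),
              vapply(cfg$syntactic, function(g) c(g$PrADG["sd"], g$HEG["sd"]), numeric(2)))
  if (any(all_sd < 0)) stop("configured sds must be >= 0")
  if (any(unlist(cfg$ngram_rates) < 0)) stop("n-gram rates must be >= 0")
  for (g in c("PrADG", "HEG")) {
    lex <- cfg$lexical
    m <- function(f) lex[[f]][[g]]["mean"]
    # marker chunks consume words; the configuration must leave room for
    # them inside the expected word budget
    demand <- 2 * m("repetitions") + 2 * m("revisions") +
      m("word_replacement")
    if (demand > m("word_count"))
      stop("infeasible config for group ", g,
           ": expected marker words (", round(demand, 1),
           ") exceed expected word count (", m("word_count"), ")")
  }
  invisible(cfg)
}

# ---------------------------------------------------------- template bank --

tpl <- function(tokens, tree, rel = character(), head = integer(),
                dep = integer(), cc = 0L, sub = 0L, red = 0L, pred = 0L) {
  list(tokens = tokens, tree = tree,
       deps = data.frame(relation = rel, head = as.integer(head),
                         dep = as.integer(dep), stringsAsFactors = FALSE),
       cc = cc, sub = sub, red = red, pred = pred)
}

# Phrase units planted for the n-gram features.  `primary` names the target
# n-gram whose configured rate drives the unit's Poisson rate after
# residualizing overlaps with longer units.
ngram_units <- function() {
  list(
    u_cookie_jar = c(tpl(c("a", "cookie", "out", "of", "the", "cookie", "jar"),
      "(NP (NP (DT a) (NN cookie)) (PP (IN out) (PP (IN of) (NP (DT the) (NN cookie) (NN jar)))))",
      c("det", "case", "case", "det", "compound", "nmod"),
      c(2, 7, 7, 7, 7, 2), c(1, 3, 4, 5, 6, 7)),
      primary = "a cookie out"),
    u_window_open = c(tpl(c("the", "window", "is", "open"),
      "(S (NP (DT the) (NN window)) (VP (VBZ is) (ADJP (JJ open))))",
      c("det", "nsubj", "acomp"), c(2, 3, 3), c(1, 2, 4)),
      primary = "the window is"),
    u_mother_is3 = c(tpl(c("the", "mother", "is"),
      "(S (NP (DT the) (NN mother)) (VP (VBZ is)))",
      c("det", "nsubj"), c(2, 3), c(1, 2)),
      primary = "the mother is"),
    u_is_tipping_over = c(tpl(c("is", "tipping", "over"),
      "(VP (VBZ is) (VP (VBG tipping) (PRT (RP over))))",
      c("aux", "prt"), c(2, 2), c(1, 3), red = 1L),
      primary = "is tipping"),
    u_cookie_out_of = c(tpl(c("cookie", "out", "of"),
      "(FRAG (NN cookie) (IN out) (IN of))",
      c("dep", "dep"), c(1, 1), c(2, 3)),
      primary = "cookie out of"),
    u_of_the_cookie = c(tpl(c("of", "the", "cookie"),
      "(PP (IN of) (NP (DT the) (NN cookie)))",
      c("case", "det"), c(3, 3), c(1, 2)),
      primary = "of the cookie"),
    u_off_the_cookie = c(tpl(c("off", "the", "cookie"),
      "(PP (IN off) (NP (DT the) (NN cookie)))",
      c("case", "det"), c(3, 3), c(1, 2)),
      primary = "off the cookie"),
    u_is_overflowing = c(tpl(c("is", "overflowing"),
      "(VP (VBZ is) (VP (VBG overflowing)))",
      c("aux"), 2, 1, red = 1L),
      primary = "is overflowing"),
    u_tipping_over = c(tpl(c("tipping", "over"),
      "(VP (VBG tipping) (PRT (RP over)))",
      c("prt"), 1, 2, red = 1L),
      primary = "tipping over"),
    u_the_window = c(tpl(c("the", "window"),
      "(NP (DT the) (NN window))", "det", 2, 1),
      primary = "the window"),
    u_window_is = c(tpl(c("window", "is"),
      "(S (NP (NN window)) (VP (VBZ is)))", "nsubj", 2, 1),
      primary = "window is"),
    u_is_open = c(tpl(c("is", "open"),
      "(VP (VBZ is) (ADJP (JJ open)))", "acomp", 1, 2),
      primary = "is open"),
    u_the_mother = c(tpl(c("the", "mother"),
      "(NP (DT the) (NN mother))", "det", 2, 1),
      primary = "the mother"),
    u_mother_is = c(tpl(c("mother", "is"),
      "(S (NP (NN mother)) (VP (VBZ is)))", "nsubj", 2, 1),
      primary = "mother is"),
    u_be_quiet = c(tpl(c("be", "quiet"),
      "(VP (VB be) (ADJP (JJ quiet)))", "acomp", 1, 2),
      primary = "be quiet"),
    u_girl_is = c(tpl(c("girl", "is"),
      "(S (NP (NN girl)) (VP (VBZ is)))", "nsubj", 2, 1),
      primary = "girl is"),
    u_the_stool = c(tpl(c("the", "stool"),
      "(NP (DT the) (NN stool))", "det", 2, 1),
      primary = "the stool"),
    u_the_sink = c(tpl(c("the", "sink"),
      "(NP (DT the) (NN sink))", "det", 2, 1),
      primary = "the sink"),
    u_this_is = c(tpl(c("this", "is"),
      "(S (NP (DT this)) (VP (VBZ is)))", "nsubj", 2, 1),
      primary = "this is"))
}

# count sliding-window occurrences of `gram` (space-joined) in tokens
count_occ <- function(gram, tokens) {
  g <- strsplit(gram, " ")[[1]]
  n <- length(g); L <- length(tokens)
  if (L < n) return(0L)
  sum(vapply(seq_len(L - n + 1L), function(i)
    all(tokens[i:(i + n - 1L)] == g), TRUE))
}

#' Planting design for the target n-grams
#'
#' Units (template phrase utterances) are assigned Poisson rates so that
#' the expected extracted count of every configured target n-gram equals
#' its configured rate: units are processed longest-first and each unit's
#' rate is the residual of its primary target after subtracting overlap
#' contributions from longer units (floored at 0).
#'
#' @param cfg an `ld_cohort_config`.
#' @return List with `units` (the template bank), `rates` (units x groups
#'   matrix), and `contain` (targets x units occurrence matrix).
#' @export
ngram_plant_design <- function(cfg = cohort_config()) {
  units <- ngram_units()
  targets <- names(cfg$ngram_rates)
  ord <- order(-vapply(units, function(u) length(u$tokens), 0L))
  units <- units[ord]
  contain <- matrix(0L, length(targets), length(units),
                    dimnames = list(targets, names(units)))
  for (un in names(units))
    for (g in targets)
      contain[g, un] <- count_occ(g, units[[un]]$tokens)
  rates <- matrix(0, length(units), 2,
                  dimnames = list(names(units), c("PrADG", "HEG")))
  for (g in c("PrADG", "HEG")) {
    for (i in seq_along(units)) {
      un <- names(units)[i]
      tgt <- units[[un]]$primary
      if (is.null(cfg$ngram_rates[[tgt]])) next   # target not configured
      want <- cfg$ngram_rates[[tgt]][[g]]
      have <- if (i > 1)
        sum(rates[seq_len(i - 1L), g] * contain[tgt, seq_len(i - 1L)]) else 0
      rates[i, g] <- max(0, want - have)
    }
  }
  list(units = units, rates = rates, contain = contain)
}

# Chunk library for background utterances.  Everything outside the planted
# phrase units is assembled from small fragments placed side by side inside
# FRAG-rooted utterances; markers and syntactic targets cost at most two
# tokens each, emulating disfluent speech instead of burning the word
# budget on dedicated carrier sentences.  The vocabulary is deliberately
# disjoint from the content words of every planted n-gram, so background
# text never creates target n-grams by accident.
.ld_filler_nouns <- c("plate", "water", "chair", "house", "garden", "carpet",
                      "curtain", "kitchen", "ceiling", "picture", "blanket",
                      "cupboard", "armchair", "staircase")

# A chunk: tokens, tree fragment, arcs (relative positions), optional
# marker event (relative position), and the position of its head word.
new_chunk <- function(tokens, tree, rel = character(), head = integer(),
                      dep = integer(), event = NULL, headpos = NA_integer_) {
  list(tokens = tokens, tree = tree,
       rel = rel, head = as.integer(head), dep = as.integer(dep),
       event = event, headpos = headpos)
}

make_chunk <- function(kind, noun = NULL, noun2 = NULL) {
  switch(kind,
    inthe = new_chunk(c("in", "the", noun),
                  sprintf("(PP (IN in) (NP (DT the) (NN %s)))", noun),
                  c("case", "det"), c(3, 3), c(1, 2), headpos = 3L),
    the = new_chunk(c("the", noun), sprintf("(NP (DT the) (NN %s))", noun),
                "det", 2, 1, headpos = 2L),
    bare = new_chunk(noun, sprintf("(NP (NN %s))", noun), headpos = 1L),
    fn_in = new_chunk("in", "(PP (IN in))"),
    fn_the = new_chunk("the", "(NP (DT the))"),
    cc = new_chunk("and", "(CC and)"),
    red = new_chunk("falling", "(VP (VBG falling))"),
    sub = new_chunk(noun,
                sprintf("(SBAR (S (NP (NN %s))))", noun),
                headpos = 1L),
    pred = new_chunk(c("saw", noun),
                 sprintf("(VP (VBD saw) (NP (NN %s)))", noun),
                 "dobj", 1, 2, headpos = 1L),
    rep = new_chunk(c(noun, noun),
                sprintf("(NP (NN %s) (NN %s))", noun, noun),
                "dep", 1, 2,
                event = list(kind = "repetition", position = 1L, width = 1L),
                headpos = 1L),
    rev = new_chunk(c(noun, noun2),
                sprintf("(NP (NN %s) (NN %s))", noun, noun2),
                "dep", 2, 1,
                event = list(kind = "revision", position = 1L, width = 1L),
                headpos = 2L),
    repl = new_chunk(noun, sprintf("(NP (NN %s))", noun),
                 event = list(kind = "replacement", position = 1L, width = 1L),
                 headpos = 1L),
    stop("unknown chunk kind ", kind))
}

# Background padding mix delivering `k` tokens of which `f` are function
# words, via "in the N" (2 func), "the N" (1 func), bare "N" and detached
# function-word chunks ("the"/"in", density 1, as dangling fragments of
# disfluent speech); single-token splits also raise the chunk count to
# `min_chunks` without changing token or function-word totals.
padding_plan <- function(k, f, min_chunks = 0L) {
  f <- max(0L, min(f, k))
  s <- max(0L, as.integer(ceiling((3 * f - 2 * k) / 1)))   # density > 2/3
  s <- min(s, f)
  s <- max(s, 0L)
  # s detached function words, remainder at density <= 2/3
  k2 <- k - s; f2 <- f - s
  a <- max(0L, as.integer(2 * f2 - k2))         # "in the N"
  b <- as.integer(f2 - 2L * a)                  # "the N"
  cc <- as.integer(k2 - 3L * a - 2L * b)        # bare "N"
  fn_the <- s; fn_in <- 0L
  while (a + b + cc + fn_in + fn_the < min_chunks) {
    if (a > 0L) { a <- a - 1L; fn_in <- fn_in + 1L; b <- b + 1L }
    else if (b > 0L) { b <- b - 1L; fn_the <- fn_the + 1L; cc <- cc + 1L }
    else break
  }
  c(inthe = a, the = b, bare = cc, fn_in = fn_in, fn_the = fn_the)
}

# ------------------------------------------------------------- drawing ----

# expected value of round(N(mu, s)) conditioned on >= lo
e_rtnorm_round <- function(mu, s, lo = 0L) {
  if (s == 0) return(max(lo, round(mu)))
  ks <- seq.int(lo, max(lo, ceiling(mu + 10 * s)))
  p <- stats::pnorm((ks + 0.5 - mu) / s) - stats::pnorm((ks - 0.5 - mu) / s)
  if (sum(p) <= 0) return(lo)
  sum(ks * p) / sum(p)
}

# pre-truncation mean such that the rounded truncated normal realizes the
# configured mean (truncation at `lo` otherwise inflates small means)
calibrate_tn_mean <- function(target, s, lo = 0L) {
  if (s == 0 || target <= lo) return(target)
  f <- function(mu) e_rtnorm_round(mu, s, lo) - target
  lower <- target - 8 * s
  upper <- target + 2 * s
  if (f(lower) > 0 || f(upper) < 0) return(target)
  stats::uniroot(f, c(lower, upper), tol = 1e-6)$root
}

# rounded truncated normal: round(N(m, s)) conditioned on >= lo
rtnorm_round <- function(n, m, s, lo = 0L) {
  if (s == 0) return(rep(max(lo, round(m)), n))
  out <- round(stats::rnorm(n, m, s))
  bad <- out < lo
  guard <- 0L
  while (any(bad)) {
    out[bad] <- round(stats::rnorm(sum(bad), m, s))
    bad <- out < lo
    guard <- guard + 1L
    if (guard > 10000L) { out[bad] <- lo; break }
  }
  as.integer(out)
}

lnorm_pars <- function(m, s) {
  cv2 <- (s / m)^2
  sl <- sqrt(log(1 + cv2))
  list(meanlog = log(m) - sl^2 / 2, sdlog = sl)
}

# expectation helper used to derive the utterances/MLU copula correlation
e_clamped_lnorm <- function(m, s, lo = 1) {
  if (s == 0) return(max(lo, m))
  p <- lnorm_pars(m, s)
  m * stats::pnorm((p$meanlog + p$sdlog^2 - log(lo)) / p$sdlog) +
    lo * stats::plnorm(lo, p$meanlog, p$sdlog)
}

# Draw the per-subject feature targets for one group.  `unit_reserve` is
# the expected extra-token load of the planted phrase utterances, used when
# checking per-subject marker feasibility.
draw_group_features <- function(cfg, group, n, unit_reserve = 5) {
  lex <- lapply(cfg$lexical, function(f) f[[group]])
  syn <- lapply(cfg$syntactic, function(f) f[[group]])
  gm <- function(x) unname(x["mean"]); gs <- function(x) unname(x["sd"])
  # truncation-calibrated count draw: realizes the configured mean exactly
  draw_count <- function(spec, lo = 0L) {
    rtnorm_round(n, calibrate_tn_mean(gm(spec), gs(spec), lo), gs(spec), lo)
  }

  # utterances and MLU are drawn; word count is realized as U * MLU with a
  # copula correlation chosen so E[W] matches the configured word mean
  mU <- gm(lex$utterances); sU <- gs(lex$utterances)
  mM <- gm(lex$mlu); sM <- gs(lex$mlu)
  mW <- gm(lex$word_count)
  muU <- calibrate_tn_mean(mU, sU, 1L)
  em <- e_clamped_lnorm(mM, sM, 1)
  rho <- if (sU == 0 || sM == 0) 0 else
    max(-0.9, min(0.9, (mW - mU * em) / (sU * sM)))

  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  U <- as.integer(round(muU + sU * z1))
  bad <- U < 1
  while (any(bad)) {
    z1b <- stats::rnorm(sum(bad))
    U[bad] <- as.integer(round(muU + sU * z1b))
    z2[bad] <- rho * z1b + sqrt(1 - rho^2) * stats::rnorm(sum(bad))
    bad <- U < 1
  }
  lam <- if (sM == 0) rep(max(1, mM), n) else {
    p <- lnorm_pars(mM, sM)
    pmax(1, exp(p$meanlog + p$sdlog * z2))
  }
  W <- pmax(U, as.integer(round(U * lam)))

  # sentences cannot outnumber utterances; clip and pass the excess to
  # subjects with room so the group mean is preserved
  S <- draw_count(lex$total_sentences, 1L)
  excess <- sum(pmax(0L, S - U))
  S <- pmin(U, S)
  room <- U - S
  while (excess > 0L && any(room > 0L)) {
    cand <- which(room > 0L)
    i <- if (length(cand) == 1L) cand else sample(cand, 1L)
    S[i] <- S[i] + 1L
    room[i] <- room[i] - 1L
    excess <- excess - 1L
  }
  trl <- pmin(S, draw_count(lex$trailing_off))
  # function words scale with transcript length: drawn as a per-subject
  # function-word ratio around the configured mean ratio, applied to W
  # (an independent count draw could exceed the achievable 2/3 density)
  fr_mean <- gm(lex$function_words) / mW
  FW <- if (gs(lex$function_words) == 0) {
    rep(as.integer(round(gm(lex$function_words))), n)
  } else {
    r <- stats::rnorm(n, fr_mean, 0.06)
    r <- pmin(pmax(r, 0.05), 0.55)
    as.integer(round(r * W))
  }
  # predicates/repetitions/revisions each cost one token beyond the
  # one-per-utterance base; a short transcript cannot host its full draw.
  # Clip per subject and redistribute the clipped counts to subjects with
  # spare word budget, preserving the group totals (longer transcripts
  # carry more markers, as in real speech).
  reps <- draw_count(lex$repetitions)
  revs <- draw_count(lex$revisions)
  preds <- draw_count(syn$n_predicates)
  cap <- pmax(0L, W - U - as.integer(ceiling(unit_reserve)))
  pool <- c(0L, 0L, 0L)
  for (i in seq_len(n)) {
    over <- preds[i] + reps[i] + revs[i] - cap[i]
    while (over > 0L) {
      v <- c(preds[i], reps[i], revs[i])
      k <- which.max(v)
      if (v[k] == 0L) break
      if (k == 1L) preds[i] <- preds[i] - 1L
      else if (k == 2L) reps[i] <- reps[i] - 1L
      else revs[i] <- revs[i] - 1L
      pool[k] <- pool[k] + 1L
      over <- over - 1L
    }
  }
  spare <- cap - (preds + reps + revs)
  for (k in sample(3L)) {
    while (pool[k] > 0L) {
      cand <- which(spare > 0L)
      if (!length(cand)) break
      i <- if (length(cand) == 1L) cand else sample(cand, 1L)
      if (k == 1L) preds[i] <- preds[i] + 1L
      else if (k == 2L) reps[i] <- reps[i] + 1L
      else revs[i] <- revs[i] + 1L
      spare[i] <- spare[i] - 1L
      pool[k] <- pool[k] - 1L
    }
  }

  data.frame(
    group = group,
    age = round(stats::rnorm(n, gm(cfg$age[[group]]), gs(cfg$age[[group]]))),
    utterances = U, word_count = W, mlu = W / U, total_sentences = S,
    function_words = FW,
    repetitions = reps,
    revisions = revs,
    word_replacement = draw_count(lex$word_replacement),
    incomplete_words = draw_count(lex$incomplete_words),
    filler_words = draw_count(lex$filler_words),
    trailing_off = trl,
    coordinated_sentences = draw_count(syn$coordinated_sentences),
    subordinated_sentences = draw_count(syn$subordinated_sentences),
    reduced_sentences = draw_count(syn$reduced_sentences),
    n_predicates = preds,
    stringsAsFactors = FALSE)
}

#' Draw per-subject feature targets for a whole cohort (no text assembly)
#'
#' The first stage of [generate_cohort()]: the per-subject feature values
#' the generator will plant, before any transcript text exists.  Useful for
#' cheap power/type-I simulations of the screening statistics.
#'
#' @param cfg an `ld_cohort_config`.
#' @param seed RNG seed.
#' @return Data frame, one row per subject (PrADG block first).
#' @export
draw_cohort_features <- function(cfg = cohort_config(), seed = 1L) {
  set.seed(seed)
  design <- ngram_plant_design(cfg)
  unit_extra <- vapply(design$units, function(u) length(u$tokens) - 1L, 0L)
  reserve <- colSums(design$rates * unit_extra)
  out <- rbind(draw_group_features(cfg, "PrADG", cfg$n_per_group,
                                   unit_reserve = reserve[["PrADG"]]),
               draw_group_features(cfg, "HEG", cfg$n_per_group,
                                   unit_reserve = reserve[["HEG"]]))
  out$subject_id <- sprintf("%s-%03d", out$group,
                            c(seq_len(cfg$n_per_group), seq_len(cfg$n_per_group)))
  out
}

# ------------------------------------------------------------ assembly ----

finalize_utterance <- function(tokens, incomplete, events, terminator) {
  if (any(incomplete))
    events <- rbind(events, data.frame(kind = "incomplete_word",
                                       position = which(incomplete),
                                       width = 1L, stringsAsFactors = FALSE))
  new_utterance(tokens, incomplete, events, terminator)
}

# Assemble one subject's utterances, trees and arcs from its drawn targets.
assemble_subject <- function(d, design) {
  units <- design$units
  unit_counts <- vapply(names(units), function(un)
    stats::rpois(1, design$rates[un, d$group]), 0L)

  # phrase units are standalone utterances (n-grams never cross utterance
  # boundaries, so planted counts are exact)
  unit_pool <- list()
  for (un in names(units))
    for (i in seq_len(unit_counts[[un]]))
      unit_pool[[length(unit_pool) + 1L]] <- units[[un]]
  n_unit <- length(unit_pool)
  unit_tokens <- sum(vapply(unit_pool, function(u) length(u$tokens), 0L))
  unit_red <- sum(unit_counts * vapply(units, `[[`, 0L, "red"))

  # budgets first: the drawn utterance and word targets are preserved
  # exactly (they carry the MLU identity); planted marker/syntax chunks are
  # scaled down when a short transcript cannot host the drawn counts
  U <- max(d$utterances, n_unit + 1L)
  rem_u <- U - n_unit                       # background utterances
  bgw <- max(d$word_count - unit_tokens, rem_u)
  W <- unit_tokens + bgw

  sizes <- c(cc = 1L, sub = 1L, red = 1L, pred = 2L,
             rep = 2L, rev = 2L, repl = 1L)
  counts <- c(cc = d$coordinated_sentences,
              sub = d$subordinated_sentences,
              red = max(0L, d$reduced_sentences - unit_red),
              pred = d$n_predicates,
              rep = d$repetitions, rev = d$revisions,
              repl = d$word_replacement)
  # chunks beyond one token per background utterance compete for the slack
  # W - U.  When a short transcript cannot host the drawn marker counts,
  # give up utterances first (their group dispersion is wide) and only
  # then scale the multi-token chunks down
  # scale a count vector to a budget with largest-remainder apportioning
  # (plain floor() systematically wipes out count-1 markers)
  apportion <- function(cnt, wts, budget) {
    tot <- sum(cnt * wts)
    if (tot <= budget) return(cnt)
    s <- budget / tot
    base <- floor(cnt * s)
    left <- budget - sum(base * wts)
    rem <- cnt * s - base
    for (k in order(-rem)) {
      add <- min(cnt[k] - base[k], left %/% max(wts[k], 1))
      base[k] <- base[k] + add
      left <- left - add * wts[k]
    }
    as.integer(base)
  }
  multi <- sizes > 1L
  extra <- sum(counts[multi] * (sizes[multi] - 1L))
  deficit <- extra - max(0L, bgw - rem_u)
  if (deficit > 0) {
    rem_u <- max(1L, rem_u - deficit)
    U <- n_unit + rem_u
    counts[multi] <- apportion(counts[multi], sizes[multi] - 1L,
                               max(0L, bgw - rem_u))
  }
  counts <- apportion(counts, sizes, bgw)   # degenerate very-short subjects
  names(counts) <- names(sizes)

  noun <- function() sample(.ld_filler_nouns, 1L)
  noun2 <- function() sample(.ld_filler_nouns, 2L)
  chunks <- list()
  put <- function(ch) chunks[[length(chunks) + 1L]] <<- ch
  n_cc <- counts[["cc"]]; n_sub <- counts[["sub"]]
  n_red <- counts[["red"]]; n_pred <- counts[["pred"]]
  for (i in seq_len(n_cc)) put(make_chunk("cc"))
  for (i in seq_len(n_sub)) put(make_chunk("sub", noun()))
  for (i in seq_len(n_red)) put(make_chunk("red"))
  for (i in seq_len(n_pred)) put(make_chunk("pred", noun()))
  for (i in seq_len(counts[["rep"]])) put(make_chunk("rep", noun()))
  for (i in seq_len(counts[["rev"]])) { nn <- noun2(); put(make_chunk("rev", nn[1], nn[2])) }
  for (i in seq_len(counts[["repl"]])) put(make_chunk("repl", noun()))

  fw <- tolower(ld_function_words())
  planted_tokens <- sum(vapply(chunks, function(c) length(c$tokens), 0L))
  planted_fn <- sum(vapply(chunks, function(c) sum(c$tokens %in% fw), 0L))
  unit_fn <- sum(vapply(unit_pool, function(u) sum(u$tokens %in% fw), 0L))

  pad_w <- bgw - planted_tokens
  pad_f <- d$function_words - planted_fn - unit_fn
  plan <- padding_plan(pad_w, pad_f, min_chunks = max(0L, rem_u - length(chunks)))
  for (kind in names(plan))
    for (i in seq_len(plan[[kind]]))
      put(make_chunk(kind, noun()))

  # distribute chunks over the background utterances: shuffle, give every
  # utterance one chunk, then balance token totals
  chunks <- chunks[sample(length(chunks))]
  n_bg <- min(rem_u, length(chunks))
  assign_to <- integer(length(chunks))
  assign_to[seq_len(n_bg)] <- seq_len(n_bg)
  if (length(chunks) > n_bg) {
    tot <- vapply(seq_len(n_bg), function(i)
      length(chunks[[i]]$tokens), 0L)
    for (ci in seq.int(n_bg + 1L, length(chunks))) {
      tgt <- which.min(tot)
      assign_to[ci] <- tgt
      tot[tgt] <- tot[tgt] + length(chunks[[ci]]$tokens)
    }
  }

  bg_pool <- vector("list", n_bg)
  for (i in seq_len(n_bg)) {
    idx <- which(assign_to == i)
    tokens <- character(); incomplete <- logical()
    ev <- empty_events()
    trees <- character()
    rel <- character(); hd <- integer(); dp <- integer()
    first_head <- NA_integer_
    for (ci in idx) {
      ch <- chunks[[ci]]
      base <- length(tokens)
      tokens <- c(tokens, ch$tokens)
      incomplete <- c(incomplete, logical(length(ch$tokens)))
      trees <- c(trees, ch$tree)
      if (length(ch$rel)) {
        rel <- c(rel, ch$rel); hd <- c(hd, ch$head + base); dp <- c(dp, ch$dep + base)
      }
      if (!is.null(ch$event))
        ev <- rbind(ev, data.frame(kind = ch$event$kind,
                                   position = ch$event$position + base,
                                   width = ch$event$width,
                                   stringsAsFactors = FALSE))
      if (!is.na(ch$headpos)) {
        if (is.na(first_head)) first_head <- ch$headpos + base
        else { rel <- c(rel, "dep"); hd <- c(hd, first_head); dp <- c(dp, ch$headpos + base) }
      }
    }
    bg_pool[[i]] <- list(
      tokens = tokens, incomplete = incomplete, events = ev,
      tree = if (length(trees) == 1L) trees else
        paste0("(FRAG ", paste(trees, collapse = " "), ")"),
      deps = data.frame(relation = rel, head = hd, dep = dp,
                        stringsAsFactors = FALSE))
  }

  pool <- c(lapply(unit_pool, function(u) list(
    tokens = u$tokens, incomplete = logical(length(u$tokens)),
    events = empty_events(), tree = u$tree, deps = u$deps)), bg_pool)

  # incomplete-word flags: tokens of length >= 3 outside marker scopes
  n_inc <- d$incomplete_words
  if (n_inc > 0) {
    elig <- list()
    for (ui in seq_along(pool)) {
      p <- pool[[ui]]
      marked <- if (nrow(p$events))
        unlist(lapply(seq_len(nrow(p$events)), function(r)
          seq.int(p$events$position[r],
                  p$events$position[r] + 2L * p$events$width[r] - 1L)))
      else integer()
      ok <- setdiff(which(nchar(p$tokens) >= 3L), marked)
      for (k in ok) elig[[length(elig) + 1L]] <- c(ui, k)
    }
    n_take <- min(n_inc, length(elig))
    if (n_take > 0) {
      pick <- sample(length(elig), n_take)
      for (e in elig[pick]) pool[[e[1]]]$incomplete[e[2]] <- TRUE
    }
    n_inc <- n_take
  }

  # fillers: "&-uh" events, any utterance
  n_fil <- d$filler_words
  if (n_fil > 0 && length(pool)) {
    where <- sample(length(pool), n_fil, replace = TRUE)
    for (ui in where) {
      pool[[ui]]$events <- rbind(
        data.frame(kind = "filler", position = 1L, width = 1L,
                   stringsAsFactors = FALSE), pool[[ui]]$events)
    }
  }

  pool <- pool[sample(length(pool))]

  # sentence grouping: S sentences over U utterances
  U <- length(pool)
  S <- min(d$total_sentences, U)
  cutpoints <- if (S > 1) sort(sample(U - 1L, S - 1L)) else integer()
  ends <- c(cutpoints, U)
  term <- rep("continuation", U)
  term[ends] <- "period"
  n_trl <- min(d$trailing_off, S)
  if (n_trl > 0) term[ends[sample(S, n_trl)]] <- "trailing_off"

  utts <- vector("list", U)
  trees <- character(U)
  deps <- vector("list", U)
  for (i in seq_len(U)) {
    p <- pool[[i]]
    utts[[i]] <- finalize_utterance(p$tokens, p$incomplete, p$events, term[i])
    trees[i] <- p$tree
    deps[[i]] <- p$deps
  }

  tokens_all <- unlist(lapply(utts, `[[`, "tokens"), use.names = FALSE)
  truth <- c(
    utterances = U, mlu = length(tokens_all) / U,
    function_words = sum(tolower(tokens_all) %in% fw),
    unique_words = length(tokens_all) - counts[["rep"]],
    word_count = length(tokens_all),
    character_length = sum(nchar(tokens_all)),
    total_sentences = S, repetitions = counts[["rep"]],
    revisions = counts[["rev"]], morphemes = morpheme_count(tokens_all),
    trailing_off = n_trl, word_replacement = counts[["repl"]],
    incomplete_words = n_inc, filler_words = d$filler_words,
    coordinated_sentences = n_cc,
    subordinated_sentences = n_sub,
    reduced_sentences = n_red + unit_red,
    n_predicates = n_pred)

  list(utterances = utts, trees = trees, deps = deps,
       unit_counts = unit_counts, truth = truth)
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject feature targets ([draw_cohort_features()]) and
#' assembles, for every subject, a CHAT transcript plus per-utterance
#' constituency trees and dependency arcs that realize them.  Fully
#' reproducible from `seed`.
#'
#' @param cfg an `ld_cohort_config`.
#' @param seed RNG seed.
#' @param dir optional directory: when given the cohort is also written out
#'   via [write_cohort()].
#' @return Object of class `ld_cohort`: `transcripts` (list of
#'   `ld_transcript`), `parses` (per subject `list(trees=, deps=)` with
#'   parsed trees), `tree_text` (bracketed strings), `manifest` (data frame
#'   of realized ground-truth features), `unit_counts` (planted phrase
#'   counts), `design`, `config`, `seed`.
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = 1L, dir = NULL) {
  draws <- draw_cohort_features(cfg, seed)
  design <- ngram_plant_design(cfg)
  n <- nrow(draws)
  transcripts <- vector("list", n)
  parses <- vector("list", n)
  tree_text <- vector("list", n)
  truth <- vector("list", n)
  ucounts <- matrix(0L, n, length(design$units),
                    dimnames = list(draws$subject_id, names(design$units)))
  for (i in seq_len(n)) {
    a <- assemble_subject(draws[i, ], design)
    transcripts[[i]] <- new_transcript(a$utterances,
                                       subject_id = draws$subject_id[i],
                                       group = draws$group[i],
                                       age = draws$age[i])
    parses[[i]] <- list(trees = lapply(a$trees, parse_tree), deps = a$deps)
    tree_text[[i]] <- a$trees
    truth[[i]] <- a$truth
    ucounts[i, ] <- a$unit_counts
  }
  manifest <- cbind(
    data.frame(subject_id = draws$subject_id, group = draws$group,
               age = draws$age, stringsAsFactors = FALSE),
    as.data.frame(do.call(rbind, truth)))
  cohort <- structure(list(transcripts = transcripts, parses = parses,
                           tree_text = tree_text, manifest = manifest,
                           unit_counts = ucounts, design = design,
                           config = cfg, seed = seed),
                      class = "ld_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.ld_cohort <- function(x, ...) {
  cat(sprintf("<ld_cohort> %d subjects (%d PrADG / %d HEG), seed %d\n",
              length(x$transcripts),
              sum(x$manifest$group == "PrADG"),
              sum(x$manifest$group == "HEG"), x$seed))
  invisible(x)
}

# ------------------------------------------------------------ rendering ---

render_token <- function(tok, inc) {
  if (!inc) return(tok)
  stopifnot(nchar(tok) >= 3L)
  paste0(substr(tok, 1L, nchar(tok) - 2L), "(",
         substr(tok, nchar(tok) - 1L, nchar(tok)), ")")
}

render_utterance <- function(u) {
  ev <- u$events
  parts <- character()
  n_fil <- if (nrow(ev)) sum(ev$kind == "filler") else 0L
  parts <- c(parts, rep("&-uh", n_fil))
  marker_at <- list()
  if (nrow(ev)) {
    for (r in seq_len(nrow(ev))) {
      if (ev$kind[r] %in% c("repetition", "revision", "replacement"))
        marker_at[[as.character(ev$position[r])]] <-
          list(kind = ev$kind[r], width = ev$width[r])
    }
  }
  i <- 1L
  n <- length(u$tokens)
  while (i <= n) {
    mk <- marker_at[[as.character(i)]]
    if (!is.null(mk)) {
      w <- mk$width
      grp <- vapply(seq.int(i, i + w - 1L), function(k)
        render_token(u$tokens[k], u$incomplete[k]), "")
      if (mk$kind == "replacement") {
        parts <- c(parts, "sommat", paste0("[: ", paste(u$tokens[i:(i + w - 1L)],
                                                        collapse = " "), "]"))
      } else {
        # explicit angle scoping always, so the reader's bare-marker
        # scope-widening heuristic can never reinterpret the width
        code <- if (mk$kind == "repetition") "[/]" else "[//]"
        parts <- c(parts, paste0("<", paste(grp, collapse = " "), ">"), code)
      }
      i <- i + w
    } else {
      parts <- c(parts, render_token(u$tokens[i], u$incomplete[i]))
      i <- i + 1L
    }
  }
  term <- switch(u$terminator, period = ".", question = "?",
                 exclamation = "!", trailing_off = "+...",
                 continuation = "+,")
  paste0("*PAR:\t", paste(c(parts, term), collapse = " "))
}

#' Render a transcript back to CHAT text
#'
#' The inverse of [read_chat()] for the supported dialect: planted markers
#' come out as `[/]`, `[//]`, `[: word]`, `(...)`, `&-uh` and `+...` codes
#' such that re-reading recovers the same tokens, marker events and
#' terminators.
#'
#' @param t an `ld_transcript`.
#' @return Character vector of CHAT lines.
#' @export
render_chat <- function(t) {
  stopifnot(inherits(t, "ld_transcript"))
  age_str <- if (is.na(t$age)) "" else sprintf("%d;", as.integer(t$age))
  c("@UTF8", "@Begin", "@Languages:\teng",
    "@Participants:\tPAR Participant",
    sprintf("@ID:\teng|lingdx|PAR|%s||%s|||Participant||", age_str,
            ifelse(t$group == "unknown", "", t$group)),
    vapply(t$utterances, render_utterance, ""),
    "@End")
}

#' Write a cohort to disk
#'
#' Per subject: `<id>.cha` (CHAT), `<id>.trees` (one bracketed tree per
#' utterance) and `<id>.deps` (blank-line-separated arc blocks); plus
#' `manifest.csv` (subject_id, group, age, path and the realized
#' ground-truth features) and `config.json`.
#'
#' @param cohort an `ld_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$transcripts)) {
    t <- cohort$transcripts[[i]]
    id <- t$subject_id
    writeLines(render_chat(t), file.path(dir, paste0(id, ".cha")))
    writeLines(unlist(cohort$tree_text[[i]]), file.path(dir, paste0(id, ".trees")))
    dblk <- vapply(seq_along(cohort$parses[[i]]$deps), function(k) {
      d <- cohort$parses[[i]]$deps[[k]]
      hdr <- sprintf("# sentence %d", k)
      if (nrow(d))
        paste(c(hdr, sprintf("%s\t%d\t%d", d$relation, d$head, d$dep)),
              collapse = "\n")
      else hdr
    }, "")
    writeLines(dblk, file.path(dir, paste0(id, ".deps")))
  }
  man <- cohort$manifest
  man$path <- paste0(man$subject_id, ".cha")
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = cohort$seed,
                            n_per_group = cohort$config$n_per_group),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Extract the feature table of a cohort
#'
#' Runs the real extraction path: lexical features from the transcripts,
#' syntactic features from the attached parses.
#'
#' @param cohort an `ld_cohort`.
#' @return See [build_feature_table()].
#' @export
cohort_feature_table <- function(cohort) {
  build_feature_table(cohort$transcripts, cohort$parses)
}
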