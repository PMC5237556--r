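# shared fixtures: tiny hand-written CHAT lines and parse trees

chat_fixture_lines <- function() {
  c("@UTF8",
    "@Begin",
    "@Languages:\teng",
    "@ID:\teng|lingdx|PAR|71;||PrADG|||Participant||",
    "*PAR:\tthe boy [/] the boy is falling .",
    "%mor:\tdet|the n|boy v|fall-PROG .",
    "*PAR:\t<the boy> [//] the girl is smiling .",
    "*INV:\tand what else ?",
    "*PAR:\t&-uh the &-uh mother +...",
    "*PAR:\tshe is goi(ng) +...",
    "*PAR:\tsommat [: water] is running .",
    "@End")
}

toy_trees <- function() {
  list(
    parse_tree(paste0("(S (NP (NP (DT the) (NN boy)) (CC and) ",
                      "(NP (DT the) (NN girl))) (VP (VBP smile)))")),
    parse_tree(paste0("(S (NP (PRP she)) (VP (VBZ thinks) ",
                      "(SBAR (S (NP (PRP he)) (VP (VBZ is) ",
                      "(VP (VBG falling)))))))")))
}

toy_deps <- function() {
  list(
    data.frame(relation = c("det", "nsubj", "cc", "conj", "det"),
               head = c(2L, 6L, 2L, 2L, 5L), dep = c(1L, 2L, 3L, 5L, 4L)),
    data.frame(relation = c("nsubj", "ccomp", "nsubj", "aux"),
               head = c(2L, 2L, 5L, 5L), dep = c(1L, 5L, 3L, 4L)))
}

# exhaustive Mann-Whitney p by enumerating all label assignments
mw_brute_force <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  vals <- c(x, y)
  r <- rank(vals)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combs <- utils::combn(N, n1)
  Us <- apply(combs, 2, function(id) sum(r[id]) - n1 * (n1 + 1) / 2)
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# brute-force recursive MDL-accepted information gain: enumerates every
# cut point at each level instead of scanning for the entropy minimum
ig_brute_force <- function(x, y) {
  ent <- function(l) {
    p <- table(l) / length(l)
    -sum(p[p > 0] * log2(p[p > 0]))
  }
  accepts <- function(y, left, right) {
    n <- length(y)
    k <- length(unique(y)); k1 <- length(unique(left)); k2 <- length(unique(right))
    gain <- ent(y) - (length(left) / n) * ent(left) -
      (length(right) / n) * ent(right)
    delta <- log2(3^k - 2) - (k * ent(y) - k1 * ent(left) - k2 * ent(right))
    gain > (log2(n - 1) + delta) / n
  }
  rec <- function(xs, ys) {
    ux <- sort(unique(xs))
    if (length(ux) < 2) return(numeric())
    cands <- (ux[-1] + ux[-length(ux)]) / 2
    es <- vapply(cands, function(cp) {
      l <- ys[xs <= cp]; r <- ys[xs > cp]
      (length(l) / length(ys)) * ent(l) + (length(r) / length(ys)) * ent(r)
    }, 0)
    cp <- cands[which.min(es)]
    l <- xs <= cp
    if (!accepts(ys, ys[l], ys[!l])) return(numeric())
    c(rec(xs[l], ys[l]), cp, rec(xs[!l], ys[!l]))
  }
  cuts <- sort(rec(x, y))
  if (!length(cuts)) return(0)
  bins <- findInterval(x, cuts)
  cond <- 0
  for (b in unique(bins)) cond <- cond + mean(bins == b) * ent(y[bins == b])
  max(ent(y) - cond, 0)
}

# deterministic linear scorer usable as an injected LPOCV trainer
linear_trainer <- function(Xtr, ytr) {
  mu1 <- colMeans(Xtr[ytr == 1, , drop = FALSE])
  mu0 <- colMeans(Xtr[ytr == 0, , drop = FALSE])
  w <- mu1 - mu0
  function(Xn) drop(as.matrix(Xn) %*% w)
}
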