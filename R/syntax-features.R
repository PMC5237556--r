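# Syntactic features from constituency trees and dependency arcs.
#
# Trees are bracketed Penn-Treebank s-expressions, one sentence per line.
# Feature definitions depend only on the tree/arc structure, so any parser
# (or a hand-written fixture) can supply them.

#' Parse a bracketed Penn-Treebank tree
#'
#' @param text a single s-expression, e.g.
#'   `"(S (NP (DT the) (NN boy)) (VP (VBZ runs)))"`.
#' @return A nested list with elements `label` and `children`; terminals are
#'   character scalars.
#' @export
parse_tree <- function(text) {
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", text)[[1]]
  if (m[1] == -1) stop("empty tree")
  toks <- regmatches(text, list(m))[[1]]
  i <- 0L
  nxt <- function() { i <<- i + 1L; toks[[i]] }
  peek <- function() if (i < length(toks)) toks[[i + 1L]] else NA_character_
  rec <- function() {
    t <- nxt()
    if (t != "(") return(t)            # bare terminal
    label <- nxt()
    if (label %in% c("(", ")")) stop("malformed tree: missing label")
    children <- list()
    while (!is.na(peek()) && peek() != ")")
      children[[length(children) + 1L]] <- rec()
    if (is.na(peek())) stop("malformed tree: unbalanced parentheses")
    nxt()                              # consume ")"
    structure(list(label = label, children = children), class = "ld_tree")
  }
  out <- rec()
  if (i != length(toks)) stop("malformed tree: trailing material")
  out
}

is_terminal <- function(x) is.character(x) && length(x) == 1L

#' Read bracketed trees, one per line
#'
#' Blank lines are skipped.
#' @param file path or connection.
#' @return List of `ld_tree` objects.
#' @export
read_trees <- function(file) {
  lines <- readLines(file, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, parse_tree)
}

#' Read dependency arcs in CoNLL-style blocks
#'
#' Each sentence is a block of whitespace-delimited `relation head dep`
#' triples with 1-based word positions.  Blocks are delimited either by
#' `# ...` header lines (which preserve empty sentences) or by blank
#' lines.
#'
#' @param file path or connection.
#' @return List of data frames with columns `relation`, `head`, `dep`.
#' @export
read_deps <- function(file) {
  lines <- readLines(file, warn = FALSE, encoding = "UTF-8")
  empty_block <- function() data.frame(relation = character(),
                                       head = integer(), dep = integer(),
                                       stringsAsFactors = FALSE)
  parse_block <- function(b) {
    b <- b[nzchar(trimws(b)) & !grepl("^#", b)]
    if (!length(b)) return(empty_block())
    f <- do.call(rbind, strsplit(trimws(b), "[[:space:]]+"))
    data.frame(relation = f[, 1], head = as.integer(f[, 2]),
               dep = as.integer(f[, 3]), stringsAsFactors = FALSE)
  }
  if (any(grepl("^#", lines))) {
    idx <- cumsum(grepl("^#", lines))
    blocks <- split(lines[idx > 0], idx[idx > 0])
    return(unname(lapply(blocks, parse_block)))
  }
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  blocks <- lapply(blocks, function(b) b[nzchar(trimws(b))])
  blocks <- Filter(length, blocks)
  unname(lapply(blocks, parse_block))
}

#' @export
new_dependency_arcs <- function(relation, head, dep) {
  stopifnot(length(relation) == length(head), length(head) == length(dep),
            all(head != dep))
  data.frame(relation = as.character(relation), head = as.integer(head),
             dep = as.integer(dep), stringsAsFactors = FALSE)
}

tree_walk <- function(tree, fn) {
  # pre-order traversal over internal nodes
  if (is_terminal(tree)) return(invisible())
  fn(tree)
  for (ch in tree$children) tree_walk(ch, fn)
  invisible()
}

#' Leaves (surface words) of a tree
#' @param tree an `ld_tree`.
#' @return Character vector of terminals in order.
#' @export
tree_leaves <- function(tree) {
  if (is_terminal(tree)) return(tree)
  unlist(lapply(tree$children, tree_leaves), use.names = FALSE)
}

# preterminal = internal node whose only child is a terminal
is_preterminal <- function(node) {
  !is_terminal(node) && length(node$children) == 1L &&
    is_terminal(node$children[[1L]])
}

pos_tags <- function(tree) {
  tags <- character()
  tree_walk(tree, function(n) {
    if (is_preterminal(n)) tags <<- c(tags, n$label)
  })
  tags
}

# The clause node a parser roots the sentence in: unwrap ROOT/TOP wrappers.
effective_root <- function(tree) {
  while (!is_terminal(tree) && tree$label %in% c("ROOT", "TOP") &&
         length(tree$children) == 1L)
    tree <- tree$children[[1L]]
  tree
}

#' Coordinated-sentence feature: CC tag frequency
#'
#' @param trees list of `ld_tree` (a narrative).
#' @return Total count of CC-tagged leaves.
#' @export
count_coordinated <- function(trees) {
  sum(vapply(trees, function(tr) sum(pos_tags(tr) == "CC"), 0))
}

#' Subordinated-sentence feature: embedded S nodes
#'
#' Counts S-labelled internal nodes, excluding each tree's own root clause
#' (a sentence does not subordinate itself).
#'
#' @param trees list of `ld_tree`.
#' @return Count of embedded S nodes.
#' @export
count_subordinated <- function(trees) {
  one <- function(tr) {
    n <- 0L
    tree_walk(tr, function(nd) if (nd$label == "S") n <<- n + 1L)
    if (effective_root(tr)$label == "S") n <- n - 1L
    max(n, 0L)
  }
  sum(vapply(trees, one, 0L))
}

#' Reduced-sentence feature: nonfinite verb forms
#'
#' Subordination without a conjunction surfaces as gerunds/participles, so
#' the feature is the total frequency of VBG and VBN tags.
#'
#' @param trees list of `ld_tree`.
#' @return Count of VBG + VBN leaves.
#' @export
count_reduced <- function(trees) {
  sum(vapply(trees, function(tr) sum(pos_tags(tr) %in% c("VBG", "VBN")), 0))
}

#' Extract predicates (transitive verbs with arguments)
#'
#' A predicate is a VB* leaf whose parent VP contains at least one following
#' sibling argument constituent (NP, PP, SBAR or S).
#'
#' @param tree an `ld_tree`.
#' @return List of `list(verb=, n_args=)`, one element per predicate.
#' @export
extract_predicates <- function(tree) {
  args_lab <- c("NP", "PP", "SBAR", "S")
  preds <- list()
  tree_walk(tree, function(nd) {
    if (nd$label != "VP") return()
    kids <- nd$children
    for (i in seq_along(kids)) {
      k <- kids[[i]]
      if (is_preterminal(k) && grepl("^VB", k$label)) {
        if (i < length(kids)) {
          following <- kids[(i + 1L):length(kids)]
          labs <- vapply(following, function(x)
            if (is_terminal(x)) "" else x$label, "")
          n_args <- sum(labs %in% args_lab)
          if (n_args >= 1L)
            preds[[length(preds) + 1L]] <<-
              list(verb = k$children[[1L]], n_args = n_args)
        }
      }
    }
  })
  preds
}

count_predicates <- function(trees) {
  sum(vapply(trees, function(tr) length(extract_predicates(tr)), 0L))
}

#' Dependency distance of a narrative
#'
#' Per sentence, the sum of absolute serial-position differences over all
#' arcs; the narrative-level score is the mean of the per-sentence sums.
#'
#' @param deps list of arc data frames (one per sentence).
#' @return Mean per-sentence distance sum (0 for an empty narrative).
#' @export
dependency_distance <- function(deps) {
  if (!length(deps)) return(0)
  sums <- vapply(deps, function(d)
    if (nrow(d)) sum(abs(d$head - d$dep)) else 0, 0)
  mean(sums)
}

#' Unique production rules of a narrative
#'
#' Counts unique LHS -> RHS context-free expansions across all trees,
#' lexical rules included.
#'
#' @param trees list of `ld_tree`.
#' @return Number of unique rules.
#' @export
production_rules <- function(trees) {
  rules <- character()
  for (tr in trees) {
    tree_walk(tr, function(nd) {
      rhs <- vapply(nd$children, function(ch)
        if (is_terminal(ch)) ch else ch$label, "")
      rules <<- c(rules, paste(nd$label, "->", paste(rhs, collapse = " ")))
    })
  }
  length(unique(rules))
}

#' The 9-feature syntactic profile of a narrative
#'
#' @param trees list of `ld_tree`, one per sentence.
#' @param deps optional list of arc data frames aligned with `trees`.
#' @return Named numeric vector with components `coordinated_sentences`,
#'   `subordinated_sentences`, `reduced_sentences`, `n_predicates`,
#'   `avg_predicates_per_sentence`, `n_dependencies`,
#'   `avg_dependencies_per_sentence`, `dependency_distance`,
#'   `n_production_rules`.  Averages are totals over the number of
#'   sentences (0 when there are none).
#' @export
syntactic_profile <- function(trees, deps = NULL) {
  ns <- length(trees)
  if (is.null(deps)) deps <- list()
  n_pred <- count_predicates(trees)
  uniq_rel <- if (length(deps))
    length(unique(unlist(lapply(deps, `[[`, "relation")))) else 0L
  per_sent_rel <- if (length(deps))
    mean(vapply(deps, function(d) length(unique(d$relation)), 0)) else 0
  c(coordinated_sentences = count_coordinated(trees),
    subordinated_sentences = count_subordinated(trees),
    reduced_sentences = count_reduced(trees),
    n_predicates = n_pred,
    avg_predicates_per_sentence = if (ns) n_pred / ns else 0,
    n_dependencies = uniq_rel,
    avg_dependencies_per_sentence = per_sent_rel,
    dependency_distance = dependency_distance(deps),
    n_production_rules = production_rules(trees))
}
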