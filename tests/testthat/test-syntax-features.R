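test_that("coordination counts CC leaves and is additive", {
  t1 <- parse_tree("(S (NP (DT the) (NN boy)))")
  t2 <- toy_trees()[[1]]
  expect_equal(count_coordinated(list(t1)), 0)
  expect_equal(count_coordinated(list(t2)), 1)
  expect_equal(count_coordinated(list(t2, t2)), 2)
})

test_that("subordination counts embedded S nodes, never the root clause", {
  single <- parse_tree("(S (NP (PRP she)) (VP (VBZ runs)))")
  embedded <- parse_tree(paste0("(S (NP (PRP she)) (VP (VBZ thinks) ",
                                "(SBAR (S (NP (PRP he)) (VP (VBZ runs))))))"))
  frag <- parse_tree("(FRAG (NP (DT the) (NN boy)))")
  expect_equal(count_subordinated(list(single)), 0)
  expect_equal(count_subordinated(list(embedded)), 1)
  expect_equal(count_subordinated(list(frag)), 0)
  # ROOT wrappers unwrap before the root-clause exclusion
  wrapped <- parse_tree("(ROOT (S (NP (PRP she)) (VP (VBZ runs))))")
  expect_equal(count_subordinated(list(wrapped)), 0)
})

test_that("reduced sentences are VBG + VBN leaves", {
  vbg <- parse_tree("(VP (VBZ is) (VP (VBG falling)))")
  vbn <- parse_tree("(VP (VBZ is) (VP (VBN broken)))")
  none <- parse_tree("(VP (VB be) (VP (VBZ runs)))")
  expect_equal(count_reduced(list(vbg)), 1)
  expect_equal(count_reduced(list(vbn)), 1)
  expect_equal(count_reduced(list(none)), 0)
  expect_equal(count_reduced(list(vbg, vbn)), 2)
})

test_that("predicates are VB* leaves with following argument siblings", {
  trans <- parse_tree("(VP (VBZ sees) (NP (DT the) (NN dog)))")
  intrans <- parse_tree("(VP (VBZ sleeps))")
  ditrans <- parse_tree("(VP (VBZ gives) (NP (PRP her)) (NP (DT a) (NN cookie)))")
  p1 <- extract_predicates(trans)
  expect_length(p1, 1)
  expect_equal(p1[[1]]$verb, "sees")
  expect_length(extract_predicates(intrans), 0)
  p3 <- extract_predicates(ditrans)
  expect_length(p3, 1)
  expect_equal(p3[[1]]$n_args, 2)
  # non-argument following siblings (ADJP, ADVP) do not qualify
  cop <- parse_tree("(VP (VBZ is) (ADJP (JJ happy)))")
  expect_length(extract_predicates(cop), 0)
})

test_that("dependency distance is the mean of per-sentence |head-dep| sums", {
  one <- list(data.frame(relation = c("a", "b"), head = c(2L, 2L),
                         dep = c(1L, 4L)))
  expect_equal(dependency_distance(one), 3)        # 1 + 2
  expect_equal(dependency_distance(list()), 0)
  none <- list(data.frame(relation = character(), head = integer(),
                          dep = integer()))
  expect_equal(dependency_distance(none), 0)
  two <- c(one, list(data.frame(relation = "c", head = c(1L), dep = c(6L))))
  expect_equal(dependency_distance(two), 4)        # mean(3, 5)
})

test_that("production rules are unique expansions including lexical rules", {
  tr <- parse_tree("(S (NP (DT the) (NN boy)) (VP (VBZ runs)))")
  expect_equal(production_rules(list(tr)), 6)
  expect_equal(production_rules(list(tr, tr)), 6)  # uniqueness
  expect_equal(production_rules(list()), 0)
})

test_that("the 9-feature profile matches a hand computation", {
  trees <- toy_trees()
  deps <- toy_deps()
  prof <- syntactic_profile(trees, deps)
  # tree 1: 1 CC, no VBG, no predicates; tree 2: embedded S, 1 VBG,
  # "thinks" with following SBAR is a predicate
  expect_equal(unname(prof["coordinated_sentences"]), 1)
  expect_equal(unname(prof["subordinated_sentences"]), 1)
  expect_equal(unname(prof["reduced_sentences"]), 1)
  expect_equal(unname(prof["n_predicates"]), 1)
  expect_equal(unname(prof["avg_predicates_per_sentence"]), 0.5)
  # relations: det, nsubj, cc, conj (s1) + nsubj, ccomp, aux (s2)
  expect_equal(unname(prof["n_dependencies"]), 6)
  expect_equal(unname(prof["avg_dependencies_per_sentence"]), 3.5)
  expect_equal(unname(prof["dependency_distance"]),
               mean(c(1 + 4 + 1 + 3 + 1, 1 + 3 + 2 + 1)))
  expect_equal(unname(prof["n_production_rules"]),
               production_rules(trees))
})

test_that("profiles are order-invariant and zero for empty narratives", {
  trees <- toy_trees(); deps <- toy_deps()
  a <- syntactic_profile(trees, deps)
  b <- syntactic_profile(rev(trees), rev(deps))
  expect_equal(a, b)
  z <- syntactic_profile(list())
  expect_true(all(z == 0))
})

test_that("tree and dependency readers round-trip text files", {
  dir <- withr::local_tempdir()
  tf <- file.path(dir, "x.trees")
  writeLines(c("(S (NP (NN water)) (VP (VBZ runs)))",
               "(NP (DT the) (NN sink))"), tf)
  trees <- read_trees(tf)
  expect_length(trees, 2)
  expect_equal(tree_leaves(trees[[1]]), c("water", "runs"))
  df <- file.path(dir, "x.deps")
  writeLines(c("# sentence 1", "nsubj\t2\t1", "# sentence 2"), df)
  deps <- read_deps(df)
  expect_length(deps, 2)
  expect_equal(deps[[1]]$relation, "nsubj")
  expect_equal(nrow(deps[[2]]), 0)
})

test_that("malformed trees raise errors", {
  expect_error(parse_tree("(S (NP (DT the)"), "unbalanced")
  expect_error(parse_tree("(S (NN x)) extra"), "trailing")
})
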