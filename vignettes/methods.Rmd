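---
title: "Linguistic biomarker screening and diagnostic modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linguistic biomarker screening and diagnostic modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lingdx)
```

# The problem

Connected-speech tasks such as the Cookie-Theft picture description elicit
language whose syntactic and lexical properties degrade measurably in
probable Alzheimer's disease. `lingdx` implements the full analysis chain
for a two-group diagnostic study of that kind: a probable-AD group
(PrADG) versus a healthy elderly group (HEG), each subject contributing
one CHAT-formatted transcript. The chain is:

1. **CHAT ingestion** (`read_chat`): participant main-tier utterances,
   with the disfluency markers `[/]` (immediate repetition), `[//]`
   (retrace-and-correct), `[: word]` (word replacement), word-internal
   `(...)` (noncompletion), `&-` fused fillers and the `+...`
   trailing-off terminator.
2. **Feature extraction**: 9 syntactic features from constituency trees
   and dependency arcs, 14 lexical features from tokens/markers, and
   bigram/trigram counts over the corpus vocabulary.
3. **Statistical screening** (`screen_features`, `mlr_adjusted`): pooled
   two-sample *t* with 95% CIs, Mann-Whitney *U*, and age-adjusted
   multiple logistic regression with Wald $\chi^2$ and odds ratios.
4. **Diagnostic modelling** (`lpocv`): an RBF-kernel SVM evaluated by
   leave-pair-out cross-validation (LPOCV), with the pairwise AUC

   $$ c(p,n)=\mathbb{1}[c(p)>c(n)], \qquad
      \mathrm{AUC}(c,P,N)=\frac{1}{|P||N|}\sum_{p\in P}\sum_{n\in N}c(p,n), $$

   and its closed-form variance

   $$ \sigma^2_{AUC} = \frac{A(1-A) + (|P|-1)\!\left(\tfrac{A}{2-A}-A^2\right)
        + (|N|-1)\!\left(\tfrac{2A^2}{1+A}-A^2\right)}{|P||N|}. $$

The clinical corpus such studies use (DementiaBank) is access-restricted,
so the package carries a synthetic cohort generator whose defaults state
the published group parameters; every pipeline stage is testable against
that stated world.

# Feature definitions and their edges

**Syntactic.** Coordination is the CC tag frequency; subordination counts
S-labelled nodes excluding each tree's own root clause (a sentence does
not subordinate itself — `ROOT`/`TOP` wrappers are unwrapped first);
reduced sentences are VBG+VBN frequencies; a predicate is a `VB*` leaf
whose parent VP has at least one following sibling in {NP, PP, SBAR, S}.
Dependency distance is the per-sentence sum of $|head-dep|$ positions,
averaged over sentences: the published magnitude (~16–17) is consistent
with a per-sentence mean, not a narrative-wide sum over ~100 arcs.
"Number of dependencies" deduplicates by relation label per narrative, as
the source's wording ("unique syntactic dependency relations") states,
although its printed magnitude (~101) suggests arc counting; both readings
leave the feature non-significant between groups, and the label reading is
kept. Production rules are unique LHS→RHS expansions, lexical rules
included.

**Lexical.** MLU here is *words*/utterances (the study's definition),
not the classic morpheme-based MLU. Unique words subtract only the
*immediate* repetition scope of `[/]` markers. A bare `[/]` formally
scopes one word in CHAT, but transcribers often omit the angle brackets on
multi-word retraces, so the reader widens a bare marker's scope to the
longest preceding token sequence actually repeated after it (explicit
`<...>` scopes are never reinterpreted). Character length counts
non-whitespace characters of surface tokens; whether the study included
spaces is unstated, and the choice only shifts a non-significant feature.
Morphemes are words plus bound-morpheme increments from a deterministic
inflection segmenter (plural/3sg *-s*, *-ed*, *-ing*, *'s*, *n't*).
Function words are counted against a closed configurable list of English
determiners, pronouns, prepositions, conjunctions and auxiliaries
(`ld_function_words()`); the study never published its list.

**N-grams.** Sliding windows of width 2 and 3 inside utterances
(no padding, no crossing of utterance boundaries), lowercased; filler
words are marker events, not tokens, and never enter n-grams. Counts are
raw per-transcript counts — published per-n-gram group means
(e.g. "the sink" 0.68 vs 1.17) are means of raw counts.

# Feature selection

Numeric features are discretized by Fayyad–Irani recursive entropy
partitioning with the MDLPC acceptance criterion, then ranked by
information gain in bits — the behaviour of the toolkit the study used.
Strict MDL implies that weakly informative features at small *n* receive a
gain of exactly zero; `rank_top_k()` drops those before taking the top
*k* (the usual threshold-0 ranker cutoff), falling back to deterministic
tie order when nothing is informative so a null model can still be
evaluated. Selection is computed once on the full dataset before LPOCV,
as the study describes; this leaks label information into the feature
list, and a leakage-safe variant (re-running selection inside every fold)
is possible via the injected-trainer interface but is not the default,
because the default mirrors the published procedure.

# Statistical screening

The pooled (equal-variance) *t* is the default because recomputing the
published per-feature rows from printed MEAN(SD) at $n=99/99$ reproduces
the printed statistics to ±0.02; a Welch variant is available by flag.
Mann-Whitney *U* uses midranks, exact enumeration for
$\min(n)\le 8$ without ties, and a tie-corrected continuity-corrected
normal approximation otherwise. The logistic regression is
maximum-likelihood IRLS with standard errors from the inverse observed
information; Wald $\chi^2 = (\beta/SE)^2$; OR CIs use the fixed 1.96
quantile, matching published-table arithmetic, not profile likelihood.
Quasi-complete separation is flagged when coefficients diverge or the
deviance collapses to zero. Age enters in untransformed years. No
multiple-testing correction is applied (none was in the source analysis).

# The SVM and LPOCV

No SVM implementation ships with this environment's R stack, so the
package carries a compact SMO solver (compiled code): Platt-style working
set selection with an error cache and deterministic heuristics — no RNG,
so refits are bit-reproducible; it agrees with libsvm's `SVC` to ~1e-3
on reference fixtures. Defaults are the study's fixed hyperparameters
(RBF kernel, $C = 1.4786727172414378$, $\gamma = 0.0014243946679106075$),
found once by Bayesian search on a development split and treated as
constants here. The confidence $c(e)$ is the signed kernel-space margin
(the source never defines it beyond "the classifier's confidence").
Features are z-scored on each training fold only. Ties in $c(p)$ vs
$c(n)$ score 0, faithful to the published definition; a conventional
0.5-credit option exists (`ties = "half"`). The LPOCV driver runs the
whole loop (fold standardization, kernel, SMO, scoring) in compiled code;
any alternative trainer can be injected as a closure for property tests.

The percentage convention: published AUC tables print the sd multiplied
by 100 (e.g. "0.93(1.89)"); `auc_variance(0.93, 99, 99)` gives
$\sigma = 0.01905$, i.e. 1.9%.

# The synthetic cohort generator: a stated world

Defaults state the published world: 99 subjects per group; per-feature
group means and sds for the 11 directly planted lexical targets and 4
syntactic targets; per-n-gram occurrence rates for the 20 published
n-grams; ages $\mathcal{N}(70.45, 8.916^2)$ vs
$\mathcal{N}(65.26, 8.388^2)$.

*Distributional forms.* Count targets are rounded truncated normals
(true generative forms are unknowable from printed summaries); MLU is
lognormal at the printed mean/sd (a positive ratio); n-gram plantings are
Poisson. Three calibrations are derived from the configuration — never
from test outcomes:

1. *Truncation calibration.* The pre-truncation mean of every count draw
   is solved numerically so the realized mean equals the configured mean
   (naive truncation at zero would inflate e.g. repetitions 2.09 → 3.2).
2. *The MLU identity.* $W = \mathrm{MLU}\times U$ cannot hold jointly
   with all three printed marginals. Utterances and MLU are drawn through
   a Gaussian copula whose correlation is chosen so that
   $E[U\cdot\mathrm{MLU}]$ equals the printed word-count mean; the word
   count is the realized product. Consequence: word-count *means* are
   preserved (the feature stays null between groups) but its sd is
   inflated (~135 vs printed ~70) — irreducible under the product
   identity.
3. *Feasibility redistribution.* A 10-utterance, 12-word transcript
   cannot host five coordinations and four revisions. Markers and
   predicates that exceed a subject's word slack are reassigned to
   subjects with room, preserving group totals; sentence counts clip at
   the utterance count with the excess passed on likewise.

*Assembly.* Transcripts are built from a template bank: the 20 target
n-grams are planted as standalone phrase utterances whose Poisson rates
are residualized longest-first so the *expected extracted count* of every
target equals its configured rate despite n-gram containment overlaps
("the window is" also produces "the window" and "window is"); background
utterances are verbless noun/PP fragment salads over a vocabulary chosen
to be disjoint from all target content words (no accidental target
n-grams) and with mean word length matching the published
characters-per-word ratio; syntactic targets and markers are planted as
one- or two-token chunks inside background utterances (an `and` for CC, a
`falling` for VBG, a noun pair for `[/]`/`[//]`, an event-annotated noun
for `[: word]`). Repetition groups are always rendered with explicit
`<...>` scoping so the reader's scope-widening heuristic cannot
reinterpret widths. Each utterance carries a deterministic fragment tree
and arc set, so parse-dependent features need no external parser.

*What a green test does and does not establish.* Round-trip tests prove
the CHAT renderer/reader and the extractors agree exactly with the
generator's bookkeeping; recovery tests prove group means of planted
features land within 3 SE of the printed parameters; screening and LPOCV
tests prove the statistics and the evaluator behave correctly *in this
world*. The world is not linguistically realistic discourse: count
features are unimodal (real disfluency counts are zero-inflated),
background text is fragment salad, trees come from templates rather than
a parser, and the published headline AUCs on the clinical corpus are
expressly not reproduction targets. Two published quantities are
structurally out of reach and are tested as such: the morphemes mean
(printed *below* the word count, impossible under a words-plus-inflections
segmenter — the generator minimizes bound morphemes and the test asserts
`morphemes >= word_count` with a small gap) and the trailing-off *t*
(ill-conditioned at the printed two-decimal precision).

# Numerical choices

- Sorting of ranked features: gain descending, feature name ascending —
  fully deterministic.
- `pooled_t_test` with zero pooled variance: equal means give $t=0$;
  unequal means raise an error (degenerate configuration).
- IRLS: linear-predictor clamp at ±30, ridge-free, convergence on
  deviance change $<10^{-10}$, cap 100 iterations.
- SMO: tolerance $10^{-3}$, pass cap 200; kernel matrix precomputed per
  fold; all-constant training columns get unit scale to avoid division
  by zero.
- The exact Mann-Whitney p uses the standard counting recursion (memoized
  DP), two-tailed by symmetry of the null distribution of $U$.

# Known limitations

- The generator's feature dependence structure is the minimum the
  identities require; real transcripts correlate nearly everything.
- Age is drawn but not coupled to severity, so the synthetic MLR
  age-adjustment exercises the arithmetic, not a real confounding
  structure.
- Sentence-level constituency for multi-utterance sentences is
  represented as independent per-utterance fragments.
- The CHAT dialect is the pragmatic subset listed above; exotic codes are
  stripped with a warning, not modelled.
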