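---
title: "Validating dictionary-based emotion taggers against human coders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating dictionary-based emotion taggers against human coders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(textdx)
```

## The problem

Word-count programs of the LIWC family tag text word by word against a
dictionary of words, word stems and (in newer versions) emoticons, each
mapped into a hierarchy of psychological categories. For emotion the
hierarchy is: total affect at the root, positive and negative emotion
beneath it, and anxiety, anger and sadness as subcategories of negative
emotion. The program reports, per writer, the percentage of their words
falling in each category.

Whether those percentages mean what researchers want them to mean is a
diagnostic-accuracy question. Treating every word token as one
observation, with a human coder's token-level emotion label as the
reference standard, a dictionary tagger is a diagnostic test:
*sensitivity* is the fraction of human-coded emotion words it flags,
*specificity* the fraction of non-emotion words it leaves alone, *PPV*
(precision) the fraction of its flags that the human agrees with, *NPV*
the fraction of its non-flags that are truly non-emotion, and the *F
score* `2·PPV·sens/(PPV+sens)` balances over- against
under-identification. Differences between dictionary versions are tested
with pooled two-proportion z tests under a Bonferroni-corrected
threshold, and per-participant percentages are compared by Pearson
correlation.

`textdx` implements that entire pipeline — lexicon engine, token-level
alignment, metric battery — together with a seeded synthetic-data
generator, so that every stage can be exercised and calibrated against
known ground truth. Validation studies of this kind typically cannot
share their ingredients: clinical corpora are confidential and the
commercial dictionaries are proprietary. The synthetic generator stands
in for both, with the dial set to the regime such studies report: about
63 writers, ~165,000 words, and a human-coded emotion prevalence of
about 1.8% of tokens (0.9% positive, 0.9% negative; 0.3% anxiety, 0.1%
anger, 0.2% sadness).

## The lexicon engine

An entry is an exact word, a stem (`stammer*` matches `stammered` and
`stammering`), or an emoticon, carrying one or more category ids. A hit
expands upward through the hierarchy: `cried → {sadness}` also counts
toward negative emotion and total affect. Matching semantics that the
dictionary format itself does not force are fixed as follows:

* **Tokenization.** Words are maximal runs of letters and internal
  apostrophes after Unicode case folding; hyphenated forms split at the
  hyphen; chunks exactly matching a configured emoticon inventory become
  emoticon tokens; everything else (digits, punctuation) yields nothing.
  "Word" is not defined by the dictionary programs' documentation, so
  the definition lives in one place (`tokenize()`) and is used for both
  the machine and the reference side, keeping positions comparable.
* **Precedence.** An exact entry beats every stem; among stems the
  longest pattern wins and contributes its full category set. The least
  surprising convention when an exact and a stem entry coexist for
  related strings.
* **Context rules.** A rule for a target word grants categories only
  when a trigger word appears among the 1–2 preceding normalized tokens
  (the "I like / they like / will like" behavior of newer dictionary
  versions), and can suppress ordinary lookup for that target. Missing
  neighbors at a document start never satisfy a rule. Only the quoted
  preceding-word patterns are implemented; no tense or aspect analysis.
* **Denominators.** Emoticon tokens count toward the word-token
  denominator only when the lexicon sets `count_emoticons_as_words`,
  emulating the version generation that introduced netspeak. Whether the
  original programs include such tokens in their denominators is not
  documented; the flag makes the choice explicit and testable.
* **Multi-category entries** increment each of their categories once per
  token occurrence; within one category a token can count at most once.

The dictionary file dialect (see `?read_lexicon`) is this package's own,
since the commercial dictionaries cannot be redistributed; it is defined
by its grammar and a round-trip identity test, and ships only as small
open mini-lexicons built in code.

## Reference annotations and alignment

Human coders assign at most one of eight subcategories per token:
positive feelings, optimism, other positive, anxiety, anger, sadness,
other negative, not-emotion. For comparison with the machine hierarchy,
labels roll up: the three positive subcategories map to positive
emotion (the finer positive distinctions were dropped from newer
dictionaries for poor base rates, so no machine counterpart exists);
anxiety/anger/sadness keep their machine subcategory; other-negative
maps to negative emotion; everything gains total affect; not-emotion
maps to the empty set. A consequence worth stating: a human *anxiety*
word that the machine calls *sadness* is a true positive at the
negative-emotion and total-affect levels and simultaneously a false
negative for anxiety and a false positive for sadness — one-vs-rest
evaluation at every level of the hierarchy.

Inter-coder agreement is quantified with Cohen's kappa from the joint
label table, `(p_o − p_e)/(1 − p_e)`; it is symmetric, invariant to
relabeling, and undefined in the degenerate single-category case.

## The metric battery

Confidence intervals for proportions use the Wilson score interval by
default, with a Wald option. The choice matters at the extremes this
problem lives at — specificity and NPV around 0.99+ — where Wald
intervals collapse or cross 1. The coverage test simulates binomial
draws at p ∈ {0.01, 0.3, 0.9} and asserts 93–97% coverage; its n = 500
was fixed in advance by exact enumeration of Wilson coverage over the
whole binomial support, not by simulation.

Version comparisons use the pooled two-sided two-proportion z test. For
sensitivity the denominator is the human-coded positive count for the
category; for specificity, PPV and NPV the corresponding confusion-table
margins. F scores have no natural denominator; comparisons treat F as a
proportion with the category's human-coded reference-group size as an
effective n — an approximation, flagged as such in the report, chosen to
mirror how such comparisons are reported in the validation literature.
Bonferroni families default to m = 24 for the four count-based-metric
tables (threshold .0021 at alpha .05) and m = 6 for the per-category
F-score comparisons (threshold .0083); both are configurable.

Two published-grid cells are worth documenting: applying the F formula
to the printed sensitivity/PPV grid of the classic three-version
validation reproduces the printed F scores to three decimals in 12 of 18
cells and to within one unit in the third decimal in 4 more (the
authors evidently computed from unrounded inputs), but the printed
negative-emotion/2001 (0.561 vs computed 0.620) and sadness/2007 (0.497
vs computed 0.472) cells are inconsistent with their own printed inputs.
The acceptance tests assert the 16 consistent cells and exclude those
two.

Because PPV depends on prevalence while sensitivity and specificity do
not, the package exposes the Bayes relation
`ppv_from_prevalence(sens, spec, π) = sens·π / (sens·π + (1−spec)(1−π))`
and the test suite checks the exact identity between PPV computed from
any confusion table and the closed form evaluated at that table's own
prevalence. At the default operating regime (sens .858, spec .967,
π .018) the closed form gives ≈ 0.32: even a highly sensitive and
specific tagger is imprecise when only 2% of tokens are emotional.

## The synthetic generator

`generate_corpus()` draws, per token, one of the eight human
subcategories at the configured prevalences (single-label, matching the
human scheme; machine multi-labeling arises only via hierarchy or
lexicon collisions). Defaults are 63 participants × 2,631 words =
165,753 tokens and the prevalence vector above; the human positive mass
is split equally across the three positive subcategories, a choice made
once for want of any published subcategory split. Emotion tokens take
surfaces from per-subcategory pseudo-word vocabularies disjoint from the
neutral vocabulary — deliberately not natural language, so oracle tests
are free of confounds. Per-participant prevalence heterogeneity is
available (beta-distributed participant effects) but off by default;
uniform token counts per participant are used absent any published
distribution.

`generate_predictions()` simulates a tagger with dialed-in per-category
operating points. Naively drawing each category independently and then
closing the sets upward would inflate every parent's realized positive
rate, destroying the very marginals the recovery tests check. Instead,
each token draws a single uniform and each category compares it to a
threshold that depends on the token's reference subcategory; thresholds
are solved bottom-up by weighted water-filling so that (a) a child's
threshold never exceeds its parent's on any token class, making
predicted sets hierarchy-closed with probability one, and (b) the
class-count-weighted mean threshold equals `sens` over
reference-positive classes and `1 − spec` over negative ones, making
every configured marginal exact in expectation given the realized class
composition. This also accommodates the empirically common situation
where a subcategory is *more* sensitive than its parent (the parent's
sensitivity being a weighted average across child token subsets).
Operating points that closure makes unrealizable — a parent sensitivity
below the weighted mean of its children's detection rates — raise a
configuration error rather than being silently adjusted. The price of
exactness is within-token dependence between category draws; tokens
remain independent, which is all the one-vs-rest metrics see.

`generate_lexicon()` closes the loop end-to-end: it emits a mini
dictionary (exact entries, a stem with a deliberate trap word, a context
rule, an emoticon) plus a corpus and reference built so the engine's
confusion counts must equal a planted assignment log exactly, with no
tolerance.

## Numerical and design choices

* All randomness flows from explicit integer seeds
  (`withr::local_seed`), and identical configuration plus seed gives
  byte-identical JSON reports (no timestamps in the report).
* Water-filling thresholds are solved with `uniroot` at tolerance 1e-12;
  the residual is orders of magnitude below Monte-Carlo noise.
* Degenerate inputs fail loudly with typed conditions: zero-denominator
  metrics, pooled proportions of 0 or 1, constant columns in correlation
  tables, kappa with a single category, participants with no countable
  tokens, reference labels beyond a document's end.
* Problem sizes in the test suite are the package's calibration choices:
  the engine-vs-brute-force oracle runs 200 random lexicon/document
  pairs; operating-point recovery uses 200 replicates of 63 × 2,600
  tokens and asserts that dialed-in sensitivity and specificity fall
  inside their own 95% CIs in at least 93% of (replicate, category,
  metric) checks — scoring jointly per replicate would demand
  ~0.95^12 ≈ 54% and test nothing; test calibration uses 5,000 null
  simulations at n = 2,000 per arm; the law-of-large-numbers check uses
  10^6 tokens at ±0.002.

## What passing does and does not show

The synthetic corpus has independent tokens, a closed vocabulary, no
spelling variation, no multiword emotional phrases, and single-label
references by construction. Passing recovery and calibration tests
therefore demonstrates that the *measurement machinery* is correct —
counts, intervals, tests and their interrelations — not that any
particular dictionary is valid for any particular population. Real-data
caveats remain: PPV will drop in less emotionally expressive
populations, human coders use sentence context no word-level dictionary
sees, and a coder's single label per token is itself a simplification.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 1, n_participants = 20,
                        tokens_per_participant = 2000)
syn <- generate_corpus(cfg)
taggers <- list(
  "2001" = generate_predictions(syn, operating_points_published("2001"),
                                seed = 2)$tagged,
  "2015" = generate_predictions(syn, operating_points_published("2015"),
                                seed = 3)$tagged)
report <- run_validation(syn$docs, syn$reference, taggers, seed = 1)
report
compare_versions(report, "2001", "2015", "affect", "f_score")
```
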