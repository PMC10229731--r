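---
title: "Measuring emotional language in APRQ interviews: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring emotional language in APRQ interviews: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aprqtext)
```

## The problem

Alexithymia — difficulty identifying and describing one's own emotions — is
usually measured by self-report (the TAS-20), which is conceptually awkward:
people with limited insight into their own emotional states are being asked
to report on exactly that limitation. The Alexithymia Provoked Response
Questionnaire (APRQ) takes a different route: seventeen hypothetical,
emotionally provocative scenarios are put to the participant in a structured
interview ("someone threatens you with a gun", "someone you love dies"), and
what the participant actually *says* is analysed. `aprqtext` implements a
complete bag-of-words analysis pipeline for such transcripts: lexicon-based
emotion scoring, lexical-diversity measures, provocation congruence,
questionnaire scoring, and the group-comparison and classification
statistics needed to contrast an autistic (ASD) and a neurotypical (NT)
sample.

Because clinical interview recordings are not publicly distributable, the
package pairs the pipeline with a synthetic cohort generator that emulates
the statistical structure of such data. Every stage of the pipeline is
tested end-to-end against generated cohorts.

## Measures

**Emotion scoring.** A token counts as an emotion word iff it exactly
matches a term in a configurable affect lexicon (lowercase, single tokens;
no stemming or lemmatization). The packaged lexicon
(`default_emotion_lexicon()`) is a curated, synthetic stand-in: roughly 115
base adjectival affect terms plus hand-listed syntactic variants
(`angry`/`anger`/`angrily`), organised into anger, anxiety, sadness,
positive, negative and other-affect categories. Variant expansion is
data-driven rather than algorithmic because stemming over-matches
(e.g. "moved" → "move" would pull in ordinary motion verbs). The lexicon is
an input, not a constant: any TSV with `term`, `variants`, `category`
columns can be supplied, and the category assignment is an editable table.

**Category dictionaries.** Percentage-of-words-per-category scoring (the
style popularised by word-count text analysis software) is supported through
an open `.dic` dialect with literal and prefix-wildcard patterns
(`hate*`). `category_dictionary_from_lexicon()` derives a dictionary from
the emotion lexicon so that category analyses and lexicon analyses cannot
drift apart; an independent `.dic` file can be used instead.

**Features.** Per participant, over the concatenated 17 responses:

* raw word count (before stopword removal) and content word count (after);
* emotion token count and its complement, the non-emotion word count
  (these two always sum to the content count);
* Emotion Vocabulary (EV): distinct emotion *types* as a percentage of the
  content word count — an emotional-granularity measure;
* type/token ratio (TTR): distinct content types as a percentage of the
  content word count — a general verbal-diversity control.

Both EV and TTR keep emotion words in the denominator: for some respondents
to an all-emotional interview, emotion words are a substantial fraction of
everything said, and removing them would distort the ratios. Both are on a
0–100 scale. When a transcript has no content tokens the ratios are
undefined and reported as `NA`, never silently zero.

**"Feel" bigrams.** Bag-of-words counting misses frames like "feel awful".
`extract_feel_bigrams()` returns all bigrams whose first token is
`feel`/`feels`/`feeling`, a stopword-filtered view, and the residual view
with lexicon-matching second words removed — what is left is the evidence
for emotional expression *not* already captured by the lexicon. The three
views are nested by construction.

**Stopwords.** The packaged base list is a conventional English
function-word inventory; `build_stopwords()` adds transcription fillers
("hmm", "ahm", "ehm") by default. Which base list to use is a configuration
knob — exact counts depend on it, so it is always an explicit argument.

**Instruments.** `score_tas20()` sums the 20 five-point items after
reversing the standard reverse-keyed set {4, 5, 10, 18, 19} (configurable;
total ≥ 61 flags alexithymia). `score_aq10()` applies bimodal scoring
(agree/disagree sides merged; default agree-keyed set {1, 7, 8, 10};
total ≥ 6 screens positive). Out-of-range or missing items mark the whole
instrument missing rather than being imputed. `auto_score_aprq()` is an
automated approximation of the human 0/1 APRQ rating: an item scores 1 iff
any token matches the lexicon. Human raters additionally exclude
physical-sensation and situation descriptions; the automated rule treats
any lexicon match as affect regardless of context. This is a stated
validity caveat, not a claim of equivalence with human rating.

**Provocation congruence.** Items 2, 3, 5, 6, 9, 10 are anger provocations,
items 4, 8, 14, 15 anxiety provocations, and item 13 the loss/sadness
provocation. The two compliment (positive) items are not identified by
number in the instrument literature we rely on, so the remaining six items
are `unclassified` and excluded from congruence testing. The unit of
analysis is the individual item response pooled across participants —
response-level tests are the only design consistent with the large
fractional degrees of freedom such analyses report — with Welch's
unequal-variance t-test and Cohen's d oriented ASD minus NT. A
participant-level analysis can be run by aggregating the feature table.

## Statistics

Linguistic count data are heavily right-skewed (Zipf's law), so the
group-comparison battery is primarily nonparametric: Wilcoxon rank-sum
tests paired with the Vargha–Delaney A probability-of-superiority effect
size. A is computed from the rank-sum identity (ties credited 0.5, the
standard convention) and interpreted on the published bands — negligible
0.45–0.55, small 0.56–0.63 or 0.35–0.44, medium 0.64–0.70 or 0.30–0.34,
large above 0.70 or below 0.30 — with boundaries between printed bands
assigned to the milder label so the bands partition [0, 1]. The rank-sum
p-value is exact (full enumeration) when both groups have at most 10
observations and there are no ties; otherwise the normal approximation with
tie and continuity corrections is used. Exact mode for larger tie-free
samples is available via `exact = TRUE` and is simply slower, not
different in kind.

Correlations are Spearman throughout, with the first-order partial rank
correlation (EV vs AQ-10 controlling for TTR) computed by the standard
partial-correlation formula on the pairwise rank correlations — equivalent
to correlating rank residuals. Two-sided p-values everywhere; no
multiple-testing correction is applied by default (the analyses are
exploratory contrasts, reported with effect sizes), and any family-wise
correction can be applied downstream with `p.adjust`.

Group classification uses binomial logistic regression (IRLS, convergence
tolerance 1e-8) with diagnostic status as outcome. Two models mirror the
natural increment: TAS-20 alone, then TAS-20 plus emotion and non-emotion
word counts. Composite scores (EV, TTR) are excluded as predictors: they
are ratios of the count predictors and would manufacture
multicollinearity. Reported per model: coefficients with Wald z, odds
ratios with 95% Wald intervals, Cox & Snell and Nagelkerke pseudo-R², AIC,
the likelihood-ratio model chi-square, and correct classification at the
0.5 threshold against the majority-class baseline. The diagnostic battery
is the conventional one: Hosmer–Lemeshow over deciles of fitted risk
(equal-frequency groups, ties kept together, df = g − 2, zero-expected
groups merged with a warning), Box–Tidwell x·ln(x) augmentation for
linearity of the logit (predictors must be strictly positive; a documented
+1 shift handles zero-containing counts), variance inflation factors from
regressing each predictor on the others (threshold 5 as the conventional
flag), and Cook's distances from the one-step working-response
approximation (threshold 0.5). Perfect separation aborts the fit with a
diagnostic error rather than returning unidentifiable coefficients.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions the pipeline is designed
for. Its defaults (`default_paper_profile()`) are calibrated once against
the published group summaries of an ASD/NT APRQ comparison at n = 32 per
group and then fixed:

* raw interview lengths are log-normal with group means ≈ 1066 (ASD) and
  606 (NT) words and the corresponding heavy right skew;
* stopword/filler share ≈ 0.80/0.78, giving content counts ≈ 209/134;
* emotion token counts ≈ 24 (ASD) vs 29 (NT) with SDs ≈ 11–12; expected
  emotion tokens grow sublinearly with content length
  (`emotion_length_scaling = 0.5`), reflecting that verbose interviews
  dilute their emotion-word rate — this is what reproduces the much lower
  dispersion of emotion counts than of total counts;
* emotion words are drawn from the provocation-congruent sublexicon with a
  Zipf concentration (`emotion_diversity`), switched to an incongruent core
  category with probability 0.25; unclassified items draw from all
  categories;
* neutral content words are Zipf-distributed over a 5000-word synthetic
  vocabulary with group-specific exponents chosen so the groups' TTRs are
  near-equal (the no-general-verbal-deficit condition) while the ASD group
  retains the larger distinct-word count its longer interviews imply;
* "feel <word>" bigrams are injected at rate 0.18 per response with
  stopword/emotion/other second words mixed 50/30/20, so the bigram stage
  is exercised;
* AQ-10 totals are generated from a latent expressiveness trait with group
  means 7.5/3.0 and noise SD 3, yielding a pooled AQ-10 vs
  emotion-proportion Spearman correlation of about −0.35; TAS-20 totals are
  Normal(62, 9) vs Normal(52, 9) — putting roughly 56% of the ASD group and
  16% of the NT group over the ≥ 61 cut-off — and are generated
  *independently* of emotion-language use within group, since no
  population-level association is established (the link is exposed as
  `tas_trait_slope`, default 0, rather than asserted);
* one NT participant's TAS-20 is missing, so classification models run on
  63 completers with a majority-class baseline of 50.79%;
* questionnaire items are back-generated from the target totals as random
  Likert patterns consistent with the total, so the instrument scorers run
  on realistic item-level input.

Responses are synthetic token streams, not natural language. That is
sufficient — every downstream operation is bag-of-words or bigram based —
but it bounds what passing tests show about real data: the generator does
not model syntax, negation, word-sense ambiguity of affect homographs
("cross", "moved"), self- vs other-attributed emotion, or covariates such
as education and sex. Results on synthetic cohorts validate the *pipeline*,
not any clinical claim.

Generation is fully reproducible: a config plus seed yields byte-identical
JSONL output, and the caller's RNG stream is untouched.

## Numerical and design choices

* **Tokenizer.** Lowercase alphabetic runs with internal apostrophes
  preserved ("i'd" is one token); digits and punctuation discarded.
  Contractions are not expanded, matching how interview responses are
  quoted. The definition is centralized in `tokenize()` so every count is
  reproducible.
* **Rounding.** Reported percentages round half-to-even at the printed
  precision (base R's `round`), reproducing conventions like 56.25 → 56.2.
* **Degenerate inputs.** Empty content → `NA` ratios; identical samples →
  p = 1 by convention; zero-variance correlations → `NA` with a warning;
  all-zero category cells → congruence tests skipped with a warning;
  collinear predictors → infinite VIF; separation → error.
* **Problem sizes in tests.** The validation suite runs the null
  calibration at 500 replicates of reduced cohorts (16 per group, ~150-word
  interviews) and the direction-pattern check at 120 replicates of the full
  n = 32 profile; the acceptance script uses 300 and 60. These sizes give
  Monte-Carlo error comfortably inside the tolerances being checked while
  keeping a full run in the low minutes on a single core.

## Known limitations

The automated APRQ rating over-credits affect relative to human raters
(any lexicon match counts). The packaged lexicon approximates, but is not,
any published affective taxonomy; substitute your own for lexicon-sensitive
work. Exact-match scoring misses negated and morphologically novel forms.
Congruence analysis ignores the positive items because their item numbers
are not fixed by the instrument literature we follow. The generator's
TAS-20/language independence is an assumption exposed as a parameter, not a
finding.
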