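# aprqtext

Emotional-language analysis of Alexithymia Provoked Response Questionnaire
(APRQ) interview transcripts.

## What this is for

Alexithymia — difficulty identifying and describing one's own emotions — is
usually assessed with the TAS-20 self-report scale, which presupposes the
very self-insight it tries to measure. The APRQ instead elicits speech:
seventeen emotionally provocative hypothetical scenarios are put to the
participant in a structured interview, and the language of the responses is
analysed. `aprqtext` is an R package for researchers running that kind of
analysis on two-group designs (e.g. autistic vs neurotypical samples). It
provides:

* **Lexicon scoring** — exact-match affect lexicons with data-driven
  variant expansion (`load_emotion_lexicon()`), LIWC-dialect `.dic`
  category dictionaries with wildcard patterns
  (`load_category_dictionary()`), and configurable stopword lists with
  interview fillers (`build_stopwords()`).
* **Per-participant features** (`compute_features()`, `feature_table()`) —
  raw/content/distinct word counts, emotion vs non-emotion token counts,
  Emotion Vocabulary `EV = 100 · unique emotion types / content tokens`,
  type/token ratio `TTR = 100 · distinct types / content tokens`, category
  percentages, and `feel`-bigram views (`extract_feel_bigrams()`).
* **Instrument scoring** — TAS-20 totals with reverse keying and the ≥ 61
  cut-off, AQ-10 bimodal scoring with the ≥ 6 screen, an automated
  lexicon-based APRQ 0/1 rating, and Cronbach's alpha.
* **Provocation congruence** — per-response percentages of anger/anxiety/
  sadness words against the emotion each APRQ item is designed to provoke
  (`congruence_table()`, `incongruence_tests()`).
* **The statistical battery** — Wilcoxon rank-sum (exact or corrected
  approximation) with the Vargha–Delaney A effect size
  `A = [#(x>y) + ½#(x=y)] / (n_x n_y)` and its interpretation bands,
  Spearman and partial Spearman correlations, Welch t / Cohen's d,
  chi-square, and logistic regression with odds ratios, Cox & Snell and
  Nagelkerke R², Hosmer–Lemeshow, Box–Tidwell, VIF and Cook's-distance
  diagnostics (`logistic_fit()` and friends).
* **A calibrated synthetic cohort generator** (`generate_cohort()`,
  `default_paper_profile()`) emulating the joint structure such studies
  report — log-normal interview lengths, group-specific emotion rates,
  congruent/incongruent emotion word placement, questionnaire totals tied
  to a latent expressiveness trait — so the entire pipeline can be
  developed and validated without access to clinical recordings.

`run_full_analysis()` orchestrates everything into a single report object;
`write_report()` emits the tables as CSV/JSON.

## Worked example

```r
library(aprqtext)

cohort <- generate_cohort(default_paper_profile(seed = 2024))
report <- run_full_analysis(cohort)
report
```

```
APRQ emotional-language analysis: 64 participants ( 32 ASD / 32 NT )
Lexicon terms: 349 | stopwords: 180

Group comparisons (Wilcoxon rank-sum, Vargha-Delaney A):
               variable asd_mean  asd_sd nt_mean   nt_sd     W p_value   vda interpretation
         raw_word_count 1091.438 878.250 738.688 576.114 670.5   0.034 0.655         medium
    emotion_token_count   22.938   9.595  28.812  12.390 360.0   0.042 0.352          small
 non_emotion_word_count  191.344 162.781 141.156 125.176 638.0   0.092 0.623          small
             ev_percent    8.729   4.049  12.594   6.744 335.0   0.018 0.327         medium
            ttr_percent   62.117   7.797  61.541   7.443 534.0   0.773 0.521     negligible
  ...

'feel' bigrams: 184 total, 89 after stopword filtering, 41 residual non-lexicon

Model 2 (TAS-20 + emotion + non-emotion word counts):
        term            estimate     se       z      p odds_ratio
 (Intercept)             -0.6305 2.3974 -0.2630 0.7926     0.5323
 tas20_total              0.0658 0.0371  1.7756 0.0758     1.0680
 emotion_token_count     -0.2517 0.0695 -3.6204 0.0003     0.7775
  ...
Correct classification: 80.95% (baseline 50.79%)
```

Reading the output: the synthetic ASD group talks *more* overall
(raw count A = 0.655) yet uses *fewer* emotion words (A = 0.352) and has a
lower Emotion Vocabulary (A = 0.327, a medium effect), while the type/token
ratio — general verbal diversity — shows no group difference (A ≈ 0.5).
An emotion-word odds ratio below 1 in the logistic model means each
additional emotion token lowers the odds of being classified into the ASD
group; adding the two word counts lifts correct classification well above
the TAS-20-only model and the 50.79% majority-class baseline (63
questionnaire completers: one participant is missing the TAS-20).

The methods vignette (`vignettes/aprqtext-methods.Rmd`) documents the
measures, the statistics, the generator's calibration, and the package's
design decisions and limitations.

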