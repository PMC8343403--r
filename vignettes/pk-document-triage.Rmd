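---
title: "Methods: triage of pharmacokinetic literature with pkTriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triage of pharmacokinetic literature with pkTriage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkTriage)
```

## The problem and the model

Most records returned by a broad pharmacokinetics literature search do not
actually estimate PK parameters from in-vivo data; the positive class
("Relevant": publications reporting newly estimated in-vivo PK parameters)
is around 20% of such corpora. `pkTriage` implements a supervised triage
pipeline for this problem: documents are encoded from their publicly
available PubMed fields (title, abstract, metadata) and classified with a
gradient-boosted decision-tree ensemble,

$$H_L(x) = \sum_{l=1}^{L} \eta \, w_l \, f_l(x),$$

fitted to minimise weighted average cross-entropy. Each learner $f_l$ is a
depth-limited regression tree fitted to the negative gradient of the loss;
the learner weight $w_l$ has no separate user-visible knob — it is absorbed
into the trees' fitted leaf values by the boosting engine, scaled by the
learning rate $\eta$. The engine behind this interface is xgboost; all of
its hyperparameters other than the ones exposed in `boosterConfig()` stay
at the engine's documented defaults and are recorded in run manifests.

Two assumptions shape the design. First, relevance is largely lexical: the
presence of parameter terminology ("clearance", "volume of distribution",
"half-life", numeric estimates) in the title or abstract carries most of
the signal, which is why a bag-of-words model with careful token
normalisation is competitive. Second, class imbalance (~1:4) would bias an
unweighted fit toward the majority class, so per-sample weights are set
inversely proportional to class frequency: with prevalence $p$, every
Relevant sample's loss is scaled by $1/p$ (a factor of five at 20%).

## Token normalisation

Title and abstract text go through a fixed chain, in this order:

1. **Tokenisation.** A rule-based tokeniser splits on whitespace and
   punctuation boundaries while keeping decimal numbers (`5.2`) and
   hyphenated terms (`half-life`) whole; any other punctuation character is
   its own token. The tokeniser is a pluggable contract — any
   `function(text) -> character` can replace the built-in rule set.
2. **Chemical masking.** Chemical mentions are replaced by the single token
   `@CHEM` so the classifier cannot key on specific compound names. The
   default masker is dictionary-based (deterministic, shipped lexicon);
   masking happens on raw surface forms, *before* any case-folding or
   stemming, because entity recognition operates on surface text.
3. **Lowercasing**, then **in-token punctuation stripping** (tokens reduced
   to nothing are dropped), then **digit masking**: tokens consisting
   entirely of digits become `##`. Because punctuation stripping runs
   first, a decimal token `3.5` becomes `35` and then `##` — the most
   aggressive consistent reading; `maskDecimals = FALSE` exempts decimals.
4. **Stopword removal** against a frozen English list shipped in
   `inst/extdata/stopwords_en.txt` (punctuation pre-stripped so the list
   matches post-stage-3 tokens), then **Porter stemming**. Stemming is last
   and stopword removal precedes it, so stopwords are matched in their
   dictionary form.

Mask tokens (`@CHEM`, `##`) are exempt from every transformation. The
chain without stemming is idempotent (verified property); stemming is not,
which is inherent to suffix stripping. The Porter stemmer is implemented in
the package from the algorithm's published definition (no stemming library
is part of the dependency set) and is tested against the algorithm's
canonical example words.

## Bag-of-words encoding

Every document contributes: unigrams (and optionally bigrams/trigrams,
joined with `_`) of its normalised title/abstract tokens, plus metadata
values as single namespaced tokens (`publication_type=Review`,
`mesh_terms=...`) with no further pre-processing. N-grams are generated
only from title/abstract, not from metadata. The default field set is the
*Optimal Fields* preset — title, abstract, MeSH terms, publication type —
the combination found to carry the discriminant information for this task.

The vocabulary keeps terms whose document frequency is at least `min_df`
(default 20) in deterministic byte-lexicographic order, and one `min_df`
applies uniformly to text and metadata terms. Cell values are term counts
divided by $T_d$, the total number of *in-vocabulary* term occurrences in
the document, so the encoded row is exactly L1-normalised (documents with
no in-vocabulary term are zero vectors). The alternative denominator — all
tokens including filtered ones — would break the exact unit norm; it is
available via `encodeBow(..., denominator = "all_terms")` but not default.

## Distributed representations

Token-level embedding providers return per-token vectors (conceptually the
element-wise sum of a transformer encoder's last four hidden layers,
dimension $d$); document-level providers return one $d$-vector per record.
Pooling compositions produce fixed-length blocks: **mean pooling**
concatenates the per-field token means (dimension $2d$; 1536 at $d=768$),
**mean + min/max pooling** concatenates mean, element-wise minimum and
maximum per field ($6d$; 4608), and document-level vectors pass through
($d$; 768). A field with no tokens contributes a zero sub-vector — the
choice matters because ~13% of records have no abstract; the alternative
(duplicating the title pooling) is not the default. Embedding providers see
the *raw tokenised* title/abstract (no stemming or masking): encoders
expect surface forms, and the normalisation chain is BoW-specific.

Tests and offline runs use a deterministic hash-based provider: each token
maps to a pseudo-random vector that depends only on (token string,
dimension, seed), so identical corpora give identical features. Real
transformer adapters plug in behind the same contract; sequence truncation
at the encoder's maximum length is the adapter's concern.

## Training and early stopping

`fitBoostedClassifier()` takes explicit train and dev sets. Defaults:
$\eta = 0.1$, at most 2000 boosting rounds, early stopping when the
dev-set F1 — computed at probability threshold 0.5, since the stopping
metric needs a hard decision rule — has not improved for 100 rounds; the
returned ensemble is truncated at the best-dev-F1 round. A dev set with no
positive documents is rejected (F1 is undefined as a stopping signal).
Sample weights are normalised to mean 1 before entering the engine so that
only weight *ratios* matter; without this, the overall weight scale would
interact with the engine's L2 leaf regularisation and rescaling all weights
by a constant would change the fit.

## Evaluation machinery

**Bootstrap comparison.** Each iteration draws a stratified 60/20/20
split (temp training / temp dev / temp test), fits with early stopping on
temp dev, and records precision, recall and F1 for the Relevant class on
temp test. Stratification allocates each class by largest-remainder
rounding, so every part's class count is within one document of the exact
proportion, and errors when a class cannot populate all parts. Iterations
are seeded as `masterSeed + i`, so single iterations are reproducible and
two pipeline variants run with the same master seed see identical splits.
Summaries report the per-metric median and 95% CI as empirical
2.5th/97.5th percentiles under R's default interpolated (type-7) quantile
rule — the percentile convention had to be fixed somewhere, and linear
interpolation between closest ranks is the documented choice. The **IQV**
reported alongside F1 is implemented as the interquartile range of the F1
samples on the percent scale; the acronym has no standard formula, so this
reading is flagged here deliberately.

`bootstrapCompare()` operates on a matrix featurised once from the full
corpus (vocabulary included), matching the featurize-then-bootstrap
workflow of the command line. Rebuilding the vocabulary inside every
split would be stricter (no document-frequency information crossing the
split), at roughly the featurisation cost per iteration; on the synthetic
corpora the difference is negligible because signal terms are frequent,
but on small real corpora the reported medians should be read as very
mildly optimistic.

**Agreement.** `cohenKappa()` implements standard binary Cohen's kappa,
$K = (p_o - p_e)/(1 - p_e)$ with $p_e$ from the annotators' marginal label
frequencies, erroring when $p_e = 1$. With more than two annotators the
intended use is pairwise kappa averaged over pairs; no Fleiss-style
multi-annotator statistic is provided. (Descriptions of computing kappa
"on the Relevant class" in this literature are non-standard phrasing; the
package implements the standard binary statistic.)

**Grid search.** `gridSearchCV()` enumerates the Cartesian grid —
`min_df` in (2, 512, doubling), `max_depth` in (2, 64, doubling),
`colsample_bytree` in (1/3, 2/3, 1); 162 points — with stratified k-fold
(default 5) cross-validation. The vocabulary is rebuilt per `min_df` on
the full supplied corpus, mirroring a grid search run "on the whole
training set"; early stopping inside each fold reuses the fold's held-out
part as the dev set (no third split within CV). Ties are broken toward
smaller `min_df`, then smaller `max_depth`, then larger `colsample` —
i.e. toward the simpler, cheaper model. A grid point whose `min_df`
empties the vocabulary scores `NA` and cannot win.

## The synthetic corpus generator

`generateCorpus()` emulates the statistical structure of labelled PK
corpora: exact label counts at prevalence 0.2 (counts are fixed, not
Bernoulli-sampled, so stratified-split edge cases are deterministic);
PK-parameter-like signal terms (including multi-word terms like "volume of
distribution", so the n-gram path is exercised) injected per-term with
probability 0.9 into Relevant and 0.05 into Not Relevant documents, in
both title and abstract by default (`signalField` narrows this — the
title-vs-abstract comparison below uses abstract-only injection);
publication type "Review" at rate 0.5 for Not Relevant vs 0.02 for
Relevant records; background text drawn from a 500-word Zipf-distributed
synthetic vocabulary (exponent 1.05); abstracts dropped with probability
0.13 *after* signal injection, so a missing abstract loses its signal as a
real record would; and occasional chemical names from the shipped lexicon
so the masking path is exercised. Generation is fully deterministic given
the mandatory seed and restores the caller's RNG state.

What the generator does **not** emulate: real abstract language (filler
tokens are i.i.d. Zipf draws, not prose), the joint availability
distribution of PubMed fields, annotation noise, or topical correlation
between metadata and text. Passing tests on these corpora therefore
demonstrate that the pipeline machinery is correct and that it recovers
planted signal under realistic prevalence, imbalance and missingness —
not that any particular F1 level would be attained on real PubMed data,
where reported medians for this task are in the high 70s to low 80s
(percent) and require the real labelled corpus and transformer embeddings.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
full suite finishes in a few minutes on one CPU: behavioural checks use
n = 600 documents at prevalence 0.2 with 50 bootstrap iterations (20 for
the label-shuffled control), unit tests use corpora of 15–500 documents,
and grid-search tests use reduced grids (the full 162-point grid is
enumerated, not fitted, in tests). The label-shuffled control is compared
against the analytic ceiling for label-independent predictors,
$F_1 \le 2p/(1+p)$ (1/3 at $p = 0.2$, attained by predicting everything
positive), with a 0.1 allowance for bootstrap noise.

Other numerical conventions: L1 norms hold to 1e-12 (exactly representable
divisions aside, this is float roundoff headroom); the `@CHEM` and `##`
mask strings are frozen constants, as are the `_` n-gram join and `=`
namespace separators; label strings are normalised case-insensitively with
whitespace collapsed ("Not Relevant" and "NotRelevant" are the same
label); duplicate PMIDs across XML inputs resolve to the last record seen
(update-file semantics), and citations without a PMID are skipped with a
counted warning. Degenerate metric denominators (no predicted positives,
or no true positives) yield 0 with a message rather than NaN.

## Known limitations

- The dictionary chemical masker only covers its lexicon; real deployments
  should plug an NER adapter into the masker contract.
- Probabilities from the boosted ensemble are not calibrated; the decision
  threshold (default 0.5) is a config knob, not a fitted quantity.
- `bootstrapCompare()` shares one vocabulary across splits (see above).
- Sub-word pooling semantics are delegated to transformer adapters; the
  hash provider pools over whole tokens.
- Multi-language records and records lacking titles are out of scope: the
  parser skips PMID-less citations and requires non-empty titles.
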