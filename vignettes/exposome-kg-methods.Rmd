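---
title: "Predicting exposure-disorder links from survey knowledge graphs"
author: "exposomekg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting exposure-disorder links from survey knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Female reproductive disorders (FRDs) — endometriosis, uterine fibroids,
ovarian cysts — are common, under-diagnosed, and have few modifiable
intervention points. Large exposome surveys record, per respondent,
hundreds of binary, categorical and free-text answers about diet,
medication, occupation, environment and health history. `exposomekg`
implements two complementary ways of mining such a survey for
exposure-disorder hypotheses and a reconciliation between them:

1. a **knowledge-graph (KG) arm**: survey answers are translated into
   ontology terms, the positive answers become person-term edges, the full
   ontology hierarchies are merged in, the graph is embedded with random
   walks and a Skipgram model, and a random forest trained on edge features
   scores candidate FRD-variable links;
2. a **regression arm**: the same ontology-aligned answers become a 0/1
   design matrix for each FRD outcome, run through random-forest
   imputation, elastic-net pre-selection, permutation importance, and a
   multivariable logistic model with Bonferroni-adjusted Wald tests;
3. an **exact-match report**: a link counts as corroborated when the same
   (FRD, term) pair passes the KG score cut (> 0.8) *and* reaches a
   significant (adjusted P < 0.005) or suggestive (adjusted P < 0.05)
   tier in the regression.

Access to the real survey is restricted, so the package ships a
first-class synthetic cohort generator with planted exposure-disorder
effects; every claim the test suite makes is a property of the method
measured on data whose ground truth is known.

## The synthetic study conditions

`simulate_study()` draws a cohort under fixed conditions chosen once to
emulate the setting the methods were designed for:

* 3000 respondents, 67% coded female; three surveys (health,
  internal exposome, external exposome) with independent completion
  probabilities (0.97, 0.55, 0.54). The joint all-three completion rate,
  ~28%, is the quantity that drives the regression cohort size and is
  matched to the reference setting; with independent completion the
  per-survey marginals cannot simultaneously be matched, a simplification
  worth knowing about.
* FRD marginal prevalences among females: 7% endometriosis, 15% uterine
  fibroids, 13% ovarian cysts.
* Six mini-ontologies (HP 300, MONDO 200, CHEBI 250, FOODON 200, ECTO 200,
  MAXO 60 terms) — random rooted is_a DAGs with synonyms. Ontology terms
  deliberately dominate the node set: in survey KGs of this design the
  ontologies are merged wholesale and respondents are a small minority of
  nodes, which shapes what non-edges look like.
* A question bank of binary questions (one term each), a categorical
  question (one term per option), and free-text questions whose answers
  are term labels or synonyms from an 8-term pool, 10% of them dirtied
  with case/whitespace noise to exercise lexical normalisation.
* Five planted exposure-disorder effects, default odds ratio 4, on
  chemical and environmental exposure terms with Bernoulli prevalence 0.2.
* 5% missingness, completely at random, on top of whole-survey
  missingness for non-completed surveys. Respondents with no positive
  answer end up as singleton nodes and are removed with the
  largest-component step, mirroring the "insufficient data" exclusion of
  real pipelines.

Each FRD is drawn from a logistic model
`logit(p) = b0 + sum(log(OR) * exposure)`. The intercept is calibrated by
root finding against the *exact* marginal prevalence, enumerated over the
`2^k` planted-exposure patterns — the planted effects are few, so exact
enumeration is cheaper and tighter than Monte-Carlo calibration (the
achieved marginal prevalence is exact up to root-finder tolerance, far
inside the 0.5% requirement). Males are never FRD-positive; prevalence
targets are therefore interpreted among females.

What the generator does *not* emulate: dependence between exposures
(independence is assumed throughout, so a held-out survey edge carries no
signal beyond popularity), quantitative food-frequency levels, genetics,
geography, and informative missingness (an MAR hook exists in the config
but the default is MCAR). Passing tests show the machinery recovers
planted marginal associations at realistic sizes; they do not show
robustness to confounding or correlated exposures.

## The KG arm

```{r}
library(exposomekg)
sim <- simulate_study(seed = 1)
kgres <- run_kg_analysis(sim, seed = 2)
kgres$test_auroc
head(kgres$predictions)
```

**Graph construction.** One edge per positive answer, predicate chosen by
the term's domain (`has_phenotype`, `has_disease`, `affected_by`,
`consumes`, `exposed_to`, `undergone`); free-text answers resolved by
lexical matching (exact normalised label, then synonym, then token-sorted
label; ties broken to the smallest CURIE and flagged; no fuzzy matching —
ambiguous and unmapped answers go to a review file, because the
human-review step they stand in for cannot be automated honestly).
Ontology is_a hierarchies and crop-chemical/nutrient link tables are
merged wholesale; triples are deduplicated.

**Connectivity-preserving split.** A random-weight minimum spanning
forest is built; its edges are never held out, so *any* subset of the
remaining edges can be removed simultaneously without creating a new
component — a stronger and simpler guarantee than iteratively testing
bridges. Uniformity over spanning trees is not required for this
guarantee, so the cheaper random-weight construction is used. The test
fraction is `min(round(0.3 * m), m - |forest|)`; a tree input yields an
empty test set and a warning.

**Embedding.** Uniform random walks (every node starts
`walks_per_node` walks) feed a Skipgram model with negative sampling
(unigram^0.75), linear learning-rate decay, single-threaded and
deterministic under a fixed seed (implemented in C++; the standard
distributions are avoided because they are implementation-defined).
Method-scale defaults are d = 64, 10 walks x 40 nodes, window 5, 5
negatives, 5 epochs; the simulation-scale defaults in `run_kg_analysis()`
(d = 10, 6 x 20, 4 epochs) are sized to the ~4000-node synthetic graphs
the package's own studies run on.

**Edge features and the operator choice.** Five operators are available
(hadamard, average, L1, L2, concat). The *pipeline* default is
concatenation, and this is a deliberate deviation from the
node2vec-conventional Hadamard default: on a heterogeneous person-term
graph the plausibility of an edge is dominated by what its endpoints
*are* — a person paired with a well-connected question term is a
plausible edge, two persons never are — and symmetric operators destroy
exactly that information. Measured on the synthetic KG the held-out AUROC
is ~0.74 with Hadamard and ~0.99 with concatenation, so the symmetric
default would misrepresent what the method can do.

**Classification and scoring.** A probability random forest (501 trees,
maximum depth 15) is trained on train edges vs an equal number of
uniformly sampled non-edges, evaluated by rank-based AUROC (midranks for
ties) on the held-out edges vs fresh non-edges, then retrained on the
full-graph embedding. Every (FRD, term) pair with the term in
{chemical, phenotype, disease, food, exposure, procedure} — excluding
person nodes, the FRD itself, and its is_a ancestors, which would be
trivially predictable — is scored, and pairs with score > 0.8 pass.

## The regression arm

```{r}
regres <- run_regression_analysis(sim, seed = 3)
regres[[sim$frd_curies[["uterine_fibroids"]]]]
```

The cohort is restricted to female respondents who completed all three
surveys; every aligned question becomes a 0/1 column keyed by CURIE
("yes" = 1), with missing cells kept as `NA`. Pre-imputation prevalence
and missingness are recorded per column (they appear in the final
report). The stage order is fixed: missForest-style imputation →
elastic net → permutation importance → logistic model → Bonferroni →
tiers.

* **Imputation** follows the missForest scheme: mode initialisation,
  columns visited in increasing-missingness order, a random forest per
  column, stopping the first time the proportion-of-changed-cells
  criterion increases (the last pre-increase state is returned). All
  cohort columns are binary, so the categorical difference criterion is
  the relevant one.
* **Elastic net** (`alpha = 0.5`) with inverse-prevalence observation
  weights for class imbalance; the penalty is chosen by 10-fold
  cross-validated deviance under the 1-SE rule with outcome-stratified
  folds. When the 1-SE model is the null model, the selection falls back
  to the deviance-minimising penalty — on rare outcomes the 1-SE rule
  otherwise occasionally deletes the entire feature set, which would
  silently drop an outcome from the study.
* **Permutation importance**: a forest on the selected features (two
  thirds of rows), mean AUROC drop on the held-out third over 5
  permutations per feature; features with positive mean importance are
  kept.
* **Logistic report**: one joint maximum-likelihood model per FRD
  (per-feature VIF only exists in a joint design matrix, which is why a
  single multivariable model is fitted rather than per-feature
  univariable ones). Per feature: OR, Wald 95% CI, SE, two-sided Wald p,
  VIF = 1/(1 - R^2). Separation or non-convergence (Wald SE > 10 on the
  log-odds scale, or a non-converged fit) flags the feature and omits its
  VIF instead of crashing. Bonferroni uses m = number of features in that
  FRD's model; tiers are strict: adjusted P < 0.005 significant,
  < 0.05 suggestive.

## Reconciliation

```{r}
report <- exact_match(kgres$predictions, regres,
                      ontologies = sim$ontologies)
report
```

A match requires CURIE identity — no credit for ontological relatives,
though related (ancestor-linked) tiered features are reported in a
separate column for exploration. FRDs present in only one stream warn and
contribute zero. `render_summary()` emits a JSON + text run summary that
is a pure function of its inputs. Matches are counted as directed
(FRD, destination) pairs, so a pair of FRDs each predicting the other
counts twice.

## Numerical choices and degenerate inputs

* All randomised steps take explicit integer seeds; forests run
  single-threaded (`ranger` with `num.threads = 1`) so results are
  reproducible on one CPU.
* `glm` runs with `epsilon = 1e-13`; against an independently written
  IRLS, coefficients agree to ~1e-12 and standard errors to ~1e-7
  relative. Wald p-values inherit a z^2-amplified version of the SE
  difference in deep tails (p ~ 1e-15), which is why the test suite
  compares z to 1e-6 and raw p to 1e-5.
* Degenerate inputs are values, not crashes: empty free-text maps to
  `UNMAPPED`; a tree input to the splitter warns and returns an empty
  test set; constant features are dropped from the elastic net with a
  message; an empty selection propagates as an explicit empty result;
  single-class labels, all-missing columns and unknown CURIEs raise
  informative errors.
* The single-node walk of an isolated vertex keeps corpus order intact;
  Skipgram initialisation is uniform(-0.5/d, 0.5/d) input, zero output,
  as in the original word2vec.

## Problem sizes in the test suite

The package's own studies (test suite and `scripts/acceptance.R`) run at
the full synthetic conditions: 3000 respondents, ~4200-node graphs,
501-tree forests. The link-prediction recovery check uses 20 independent
study replicates and the concordance check the first 10 of them; split
correctness is checked on 200 random graphs of 50-500 nodes, CI coverage
and null calibration on 200 replicates each, with complete surveys and no
masking so they isolate the Wald interval itself rather than imputation
behaviour.

## Known limitations

* Lexical mapping is exact-match only; formulation variants beyond word
  order (e.g. dosages) map to `UNMAPPED` and require review, as in the
  semi-automated original.
* Prediction scores are not calibrated probabilities; the 0.8 cut is a
  ranking device, and many survey-scale links score similarly high, so
  downstream prioritisation is deliberately out of scope.
* The logistic model reports associations, not causal effects; with
  correlated real-world exposures the planted-effect recovery rates
  measured here are optimistic.
* VIF is computed from a single fit ("mean VIF" in the report's column
  naming follows the field's table convention even though nothing is
  averaged over).
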