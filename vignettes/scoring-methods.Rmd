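---
title: "Scoring LLM output consistency: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring LLM output consistency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llmrr)
```

## The estimands

A *run* is one sampled generation for a fixed (case, prompt, model,
sampling parameters) condition. Repeated runs under one condition form a
*run set*; the run sets of one case under several prompts form a *prompt
family*. The package estimates four quantities, all mapped to [0, 1] with
1 meaning perfect consistency:

* **Semantic repeatability** — mean pairwise cosine similarity between
  the sequence embeddings of the `R` runs of a run set, rescaled by
  `(x + 1)/2`. It asks: *do repeated answers mean the same thing?*
* **Internal repeatability** — one minus the mean per-position Shannon
  entropy (bits) of the sampling distribution, normalized by `log2(k)`.
  It asks: *is the token-generating process itself stable?* The two
  scores are deliberately complementary: a model can be internally noisy
  yet semantically stable (many phrasings, one meaning) and vice versa.
* **Semantic reproducibility** — mean pairwise cosine between
  *prompt-mean* embeddings across the `P` prompts of a family.
* **Internal reproducibility** — one minus the mean absolute pairwise
  difference of prompt-level mean entropies, normalized by `log2(k)`.
  Note the asymmetry with repeatability: this score measures *agreement
  of entropy across prompts*, not low entropy — five equally noisy
  prompts are perfectly reproducible.

## From API logs to distributions

Completion APIs log, per generated position, the top-k candidate tokens
with log-probabilities. Two regimes are supported via
`logprobs_post_temperature`:

* `TRUE` (default, the API case): logged values are already normalized
  log-probabilities with temperature baked in. They are exponentiated,
  truncated to the k most probable candidates, and renormalized.
* `FALSE` (raw logits, e.g. self-hosted models): the temperature-scaled
  softmax `exp(z/T) / Σ exp(z'/T)` is applied first.

Double-applying temperature would silently corrupt every entropy, which
is why the regime is an explicit, provenance-stamped flag rather than a
guess. Both paths are invariant to adding a constant to a position's
logits (max-subtraction before exponentiation), and top-k selection
breaks ties by the logged candidate order, so results do not depend on
platform sort stability.

Positions whose sampled token fell outside the logged top-k (`null` in
the on-disk `sampled_index`) are kept in the text but excluded from
entropy averaging: a truncated distribution that does not contain its own
sample would bias `H` downward invisibly. These exclusions are counted
and surfaced as a validation warning.

## Logarithm base and normalization

Entropy is computed in base 2 throughout, the only base for which the
normalizer `log2(k)` makes the internal scores span exactly [0, 1]:
uniform over the top-k gives exactly 0, a one-hot distribution exactly 1.
For `k = 1` the normalizer vanishes and the score is defined as 1 by
continuity — a single-candidate distribution is perfectly deterministic.
Scores are clamped to [0, 1] after floating arithmetic; a clamp larger
than 1e-6 triggers a warning because it indicates a logic error upstream
rather than rounding.

## Stopwords

Filler words carry little meaning but real probability mass, so the
default pipeline removes them twice, each switchable independently:

* `filter_semantic` — stopwords are removed from the text before
  embedding (`filter_stopwords_text()`), so semantic similarity reflects
  content words.
* `mask_internal` — token positions whose normalized piece (surrounding
  whitespace and punctuation stripped, lowercased) is a stopword are
  excluded from entropy averaging (`stopword_position_mask()`).

The 179-word English list is vendored into the package so scores cannot
drift with an external resource's version; `read_stopwords()` accepts a
one-word-per-line override. Matching is per token piece: a subword piece
that happens to spell a stopword is masked even when the tokenizer split
a longer word oddly. This is deterministic and documented; exact
reconstruction of tokenizer word boundaries is out of scope. Both flags
are stamped into every output file.

## Embeddings

The semantic scores are agnostic to the embedding model. A backend is any
object exposing a `dimension` and a deterministic `embed(text)`;
`register_embedding_backend()` is the plug-in point for production
encoders. Embeddings are cached by exact post-filter text, so verbatim
repeats cost one call and scores never depend on call order or count.

Prompt-mean embeddings average *raw* vectors by default, following the
definition of the reproducibility estimand literally;
`l2_normalize_before_mean = TRUE` switches to direction-only averaging
for users who want magnitude discounted. The raw average can have zero
norm under exact antipodal cancellation; this is flagged as an error
naming the prompt when the mean is later used in a cosine, rather than
silently propagating a NaN. Cosine values are clamped to [−1, 1] after
floating arithmetic.

`R = 1` repeatability is refused rather than scored 1: the estimand is
pairwise and undefined for a single run. Single-prompt families are
likewise flagged ineligible and listed in the skip report; nothing is
silently dropped.

## The group test

Score pairs (semantic, internal) are compared across groups with a
multivariate extension of the Kruskal–Wallis test. No single canonical
variant exists, so the package uses the transparent one: each dimension
is midrank-transformed over the pooled sample; with `t_j` the group mean
rank deviation from the grand mean and `V` the pooled rank covariance
(divisor `n − 1`), the statistic is `Σ_j n_j t_j' V⁻¹ t_j`. In one
dimension without ties this is exactly the classical H. Inference uses a
permutation null (default 9,999 seeded label shuffles;
`p = (1 + #{perm ≥ obs}) / (1 + B)`), which is two-sided by construction,
distribution-free, valid under ties, and honest at the small group sizes
typical of per-case scores; the asymptotic chi-square p
(`2 × (groups − 1)` df) is reported alongside for reference. An
exhaustive mode enumerates all distinct label assignments for small
samples. A constant dimension makes `V` singular; the statistic then
falls back to the Moore–Penrose pseudo-inverse with a warning.

P-values are per-comparison and uncorrected by default — consistency
comparisons are usually few and pre-specified — with an optional Holm
adjustment (`holm = TRUE`) across a batch.

## The simulator

`simulate_runs()` emulates the data-generating process the scores target,
not language itself:

* **Token distributions**: each position draws a probability vector from
  a symmetric Dirichlet(α) over a synthetic vocabulary; α is the entropy
  knob (α → 0 approaches one-hot, α → ∞ uniform). Prompt heterogeneity
  multiplies α by `2^shift` per prompt — a monotone knob rather than an
  exact entropy inversion, which would add a brittle root-finding layer;
  realized mean entropies are recorded in the ground-truth sidecar
  instead of promised analytically.
* **Embeddings**: each run draws a unit vector from a von Mises–Fisher
  distribution (Wood's rejection sampler) around a prompt-specific mean
  direction; κ is the semantic knob, and prompt mean directions are
  separated by a configurable angle along a great circle.
* **Seeding**: every case × prompt cell derives its own RNG substream
  from the master seed, so enlarging the design never perturbs existing
  cells and identical configs are byte-identical on disk.

Default concentrations (`dirichlet_alpha = 0.05`, `vmf_kappa = 300` at
`vmf_dim = 64`) are calibrated so the null generator sits in the highly
repeatable regime that repeated low-temperature generations of a fixed
prompt exhibit — semantic repeatability near 0.9, reproducibility near 1
absent prompt heterogeneity. Design-size defaults (`R = 100`, `P = 5`,
608 cases, `T = 0.5`, `top_k = 30`) mirror a full factorial evaluation
study.

What the simulator deliberately does **not** emulate: natural-language
structure (texts are token concatenations), sequential dependence between
positions (draws are i.i.d. within a run), heavy-tailed or
case-heterogeneous dispersion, and embedding-model idiosyncrasies such as
anisotropy or norm variation. Passing recovery tests therefore shows the
*estimators* track their estimands under known dispersion — it does not
certify behavior on any particular real model or corpus.

## Validation sizes and numerical tolerances

The test suite validates against independent oracles (direct-summation
entropy, pair-enumeration cosine, exhaustive split enumeration for the
permutation test) at 1e-12, and runs parameter recovery at sizes chosen
from a power calculation: 20 cases × 50 runs per configuration, run
lengths 8–10, vocabulary 30–50. The κ monotonicity grid uses embedding
dimension 8 because the κ = 1 vs κ = 0 separation scales as 1/d and must
exceed Monte-Carlo noise of the mean pairwise cosine; at d = 64 that
separation (~1e-4) is unresolvable at any reasonable run count, at d = 8
it is a comfortable multiple of the standard error. Test-level
calibration uses 1,000 null replicates of 999 permutations at 30 points
per group. All simulation tests fix their seeds; none asserts beyond what
its own Monte-Carlo precision supports.

## Known limitations

* Semantic scores inherit every bias of the chosen embedding model;
  comparisons are only meaningful within one backend.
* Internal scores depend on the provider's logging: if the top-k list is
  shorter than k, the entropy ceiling shrinks accordingly, and providers
  that renormalize their logged probabilities differently are
  indistinguishable from the log alone — hence the explicit
  `logprobs_post_temperature` contract.
* The mean absolute entropy difference used for internal reproducibility
  compares prompt *averages*; two prompts with equal mean but different
  entropy profiles across positions count as perfectly reproducible.
* The permutation test assumes exchangeability of score points across
  groups under the null; scores of the same case under different prompts
  are not independent, so when comparing prompts, case-level pairing
  information is ignored (a conservative simplification).
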