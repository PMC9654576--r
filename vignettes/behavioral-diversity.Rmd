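---
title: "Measuring behavioral diversity: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring behavioral diversity: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behavdiv)
```

## The measurement problem

An ethogram-coded behavioral study yields, per animal or session, a count
vector: how many scans recorded each behavior category. Summarising such a
vector into one "diversity" number requires choosing what the number should
respond to. Three properties are in tension:

* **richness** — how many distinct categories were observed (`S`);
* **evenness** — how uniformly observations are spread over those categories;
* **sampling effort** — how many observations were made at all (`N`).

No single index is sensitive to all three in a useful way, and several
well-known indices are deliberately blind to one of them. `behavdiv`
implements the full family so that the choice is explicit, and pairs it with
deterministic scenario sweeps that demonstrate each index's sensitivities by
construction rather than by anecdote.

## The data model

Raw inputs are long-format observation records (one row per scan:
grouping identifiers, a behavior label, an out-of-sight flag).
`tally_behaviors()` aggregates them into count vectors; every index consumes
counts. Three conventions are applied consistently:

* **Counts are non-negative integers.** Instantaneous/scan sampling yields
  tallies, and the Simpson and Chao1 formulas are combinatorial — they count
  pairs of observations — so fractional "counts" have no meaning there.
  Whether a study's unit of observation is a scan, a bout, or something
  else is a protocol decision the package does not arbitrate; it only
  requires that the same unit is used throughout. Duration-based proportion
  data are accepted on a separate path, and only where mathematically valid:
  `index_shannon(x, input = "proportions")` (the entropy depends on `p_i`
  alone). Proportions must sum to 1 within `1e-9`.
* **Out-of-sight records are not behaviors.** They are excluded from `N` by
  default, because visibility is a property of the sampling process, not of
  the animal's repertoire; treating them as a category would inflate
  richness and distort every effort-sensitive index. Their per-group tally is
  kept as an attribute so effort can be audited, and
  `out_of_sight = "pseudo_category"` re-includes them as a `.out_of_sight`
  category for sensitivity analysis.
* **Zero-count categories never contribute.** `S` counts categories actually
  observed; an ethogram category that was never recorded affects no index
  except the Behavioral Variety Index, whose whole purpose is to compare the
  observed set against the expected repertoire.

Behavior labels are opaque, case-sensitive strings. Ethogram granularity
(whether "locomotion" is one category or five) changes every index and is
the user's responsibility; `validate_against_ethogram()` reports labels that
fall outside the declared ethogram but deliberately never fails, since
coding slips should surface as reports in a batch run, not abort it.

## The indices and their edge contracts

With `n_i` the count of the *i*th category, `N = Σ n_i`, `S` the observed
richness, and `F1`/`F2` the singleton/doubleton counts:

| index | formula | defined when | blind to |
|---|---|---|---|
| richness | `S` | always | evenness, effort |
| Shannon–Wiener | `H' = −Σ p_i ln p_i` | `N ≥ 1` | effort |
| Simpson's D | `Σ n_i(n_i−1)/(N(N−1))` | `N ≥ 2` | — |
| Simpson's diversity | `1 − D` | `N ≥ 2` | — |
| Simpson's reciprocal | `1/D` | `N ≥ 2`, `D > 0` | — |
| Menhinick | `S/√N` | `N ≥ 1` | evenness |
| Margalef | `(S−1)/ln N` | `N ≥ 2` | evenness |
| Chao1 | `S + F1(F1−1)/(2(F2+1))` | `N ≥ 1` | evenness |
| BVI | `Ob/Ex × 100` | `Ex ≥ 1` | evenness, effort |

Numerical conventions: natural logarithms everywhere (no base-2 option);
`0·ln 0 = 0`, so empty categories drop out of the entropy sum; Shannon's
single-category value is normalised to exactly `0` (not IEEE `−0`). Where an
index is undefined the functions return `NA` with a machine-readable `note`
("undefined: insufficient observations (N < 2)") instead of throwing. This
is a deliberate batch-processing contract: scenario sweeps legitimately pass
through `S = 1` and `N = 1` cells, and a roster that silently drops rows or
aborts mid-sweep is worse than one that reports why a value is missing.

One definitional point deserves flagging. Simpson's D is implemented in its
without-replacement form, the probability that two distinct observations
share a behavior. This form is defined (and equals 1) for a single dominant
category whenever `N ≥ 2`; descriptions of the index sometimes suggest no
value exists when only one behavior occurs. We follow the formula: the
single-category case is the index's stated lower-diversity bound, and
refusing to compute it would break the `1 − D` and `1/D` identities at that
bound. Only `N < 2` is genuinely undefined (no pairs exist to compare).

Chao1 is implemented in its bias-corrected form
`S + F1(F1−1)/(2(F2+1))`, which is defined even when no doubletons were
seen and collapses to `S` exactly when `F1 ≤ 1` — matching the estimator's
interpretation that only singletons carry evidence of unobserved categories.
The classic `S + F1²/(2F2)` variant is available via
`index_chao1(x, variant = "classic")` for cross-checks against software that
uses it; it is undefined at `F2 = 0` and is reported as such.

For the BVI, observed categories that are missing from the expected
repertoire (e.g. stereotypies such as pacing, or captivity-specific
behaviors) do **not** count toward `Ob`: the index measures expression of
the wild-type repertoire, not repertoire size. They trigger a warning and a
note. With raw integer inputs `Ob > Ex` is accepted but flagged, since
captive animals can genuinely express behaviors absent from a wild ethogram.

## Tunable parameters

* `chao1_variant` — `"bias_corrected"` (default, always defined) or
  `"classic"`.
* `out_of_sight` — `"exclude"` (default) or `"pseudo_category"`; see above.
* `precision` — decimal places in CSV output (default 6); values are
  full-precision internally and in tibbles, rounding happens only at
  serialisation.
* `group_by` — which record columns define an analysis unit. Indices are
  never pooled across units; each unit gets its own count vector and roster.

## What the scenario generator emulates — and what it does not

`scenario()` builds *deterministic* count profiles: equal-abundance vectors
(`S` categories at `m` observations each), dominance profiles (the first
category inflated by a factor `k`), effort grids (`m` swept over
`{1, 2, 3, 4, 5, 10, 100}`), and singleton sweeps (`n` of `S` categories
reduced to one observation). These are designed to isolate one index
property per sweep:

1. equal abundance realises the Shannon maximum `H' = ln S` at every `S`;
2. the three Simpson variants on a shared grid verify `1 − D` and `1/D`
   cell-wise;
3. dominance (`k = 1, 2, 10, 100`) lowers Shannon and raises D monotonically
   at fixed `S`;
4. the effort grid moves Simpson's D at fixed proportions while Shannon is
   provably unchanged;
5. and 6. Menhinick and Margalef fall strictly with effort at fixed `S`;
7. the singleton sweep drives Chao1 from `S` upward, never downward.

Defaults: `S` sweeps `1..10`; effort levels `{1, 2, 3, 4, 5, 10, 100}`;
dominance factors `{1, 2, 10, 100}`; base count `m = 5`. The base count
matters only for indices that read raw counts — Shannon's curves are
identical for any `m` — and `5` was chosen once as a realistic per-behavior
tally for a short scan-sampling session; it is configurable everywhere. The
singleton sweep requires `m ≥ 2` so that reducing a category to a single
observation actually changes `F1`.

Because the profiles are deterministic, the sweeps contain **no sampling
noise**: they characterise the index functions, not the sampling process.
Real scan data adds multinomial sampling variation, observer error,
non-independent consecutive scans, and out-of-sight censoring, none of which
the sweeps emulate. Passing the sweep-based tests therefore certifies the
algebraic behavior of the indices — bounds, identities, monotonicities,
sensitivity patterns — and says nothing about the sampling distribution of
any index on real data (no confidence intervals, bootstrap, or rarefaction
are provided; they are natural extensions, as are Pielou's evenness and Hill
numbers, but are out of scope here). A seeded multinomial-sampling scenario
is a documented extension point, deliberately left out of the deterministic
v1 generator.

## Design choices that were genuinely open

* **Undefined values as data, not errors.** See above; the alternative
  (exceptions) was rejected because every sweep grid contains undefined
  cells by design.
* **Case-sensitive opaque labels.** Any normalisation (case folding,
  synonym mapping) risks silently merging ethogram categories; we prefer
  `validate_against_ethogram()` reports plus explicit user-side recoding.
* **Integer counts enforced, proportions quarantined.** Allowing fractional
  counts everywhere would make Simpson and Chao1 silently wrong; restricting
  proportions to the Shannon path keeps each formula on the data type it is
  defined for.
* **Grid completeness checked at export.** `export_sweep_table()` refuses to
  write a table with missing grid cells, listing them, so a downstream
  plot can never silently show a partial sweep.
* **BVI intersection rule.** `Ob` counts only expected categories; the
  alternative (counting all observed categories) measures richness, not
  repertoire expression, and would let stereotypies raise a welfare index.

## Problem sizes

All computations are closed-form on small vectors; the bundled test suite
exhaustively verifies Simpson's D against a brute-force pair-matching oracle
over every count vector with up to four categories and at most eight
observations (490 vectors), and runs all seven reference sweeps, in well
under a minute on one core.

## Known limitations

* No uncertainty quantification: indices are point estimates.
* Chao1's variance and confidence bounds are not implemented.
* No between-condition hypothesis testing; export the tidy results and use
  standard tools.
* The generator cannot reproduce the exact Simpson curves of a dominance
  demonstration without knowing its base count `m`, since D is
  count-sensitive; all qualitative trends are `m`-invariant and that is what
  the tests assert.
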