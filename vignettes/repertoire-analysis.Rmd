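---
title: "Methods: clonotype-table analysis with clonkit"
author: "clonkit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonotype-table analysis with clonkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonkit)
```

## The data model

A Rep-Seq experiment, after upstream V-(D)-J mapping, yields a *clonotype
table*: one row per unique rearrangement carrying a read (or UMI) count, a
frequency, the CDR3 nucleotide and amino-acid sequences, V/D/J segment
calls, optionally the V-(D)-J markup within the CDR3 and a per-base
Phred+33 quality string. `clonotype_table()` is the container every
analysis consumes. Three conventions are fixed once and tested everywhere:

* **Canonical order** is count-descending with a lexicographic CDR3nt
  tie-break, so every ranking, quantile split and top-N highlight is
  reproducible.
* **Markup coordinates** are 0-based and half-open within the CDR3, with
  `-1` encoding absence.
* **Frame and functionality are always derived, never trusted from input**:
  a clonotype is out-of-frame iff its CDR3 nucleotide length is not a
  multiple of 3, and functional iff it is in-frame and its translation has
  no stop codon. Out-of-frame status is therefore a property of length
  alone; translation of out-of-frame sequences (5'→3', dropping the
  incomplete tail) is used only for display, never for matching. These two
  notions are kept separate deliberately: out-of-frame rearrangements
  escape thymic selection and are analytically useful, while stop-codon
  clonotypes are in-frame but non-productive.

Frequencies are always recomputed as `count / total`; fractions present in
input files are advisory only, which guarantees internal consistency after
any subsetting, filtering or down-sampling. Counts are treated identically
whether they represent raw reads or UMI-labeled molecules; the unit lives
in metadata.

Summary statistics include all clonotypes by default (out-of-frame bars
are part of the standard spectratype display); a `functional_only` flag
restricts to productive rearrangements where that is wanted.

## Input dialects

`parse_clonotype_table()` reads the concise internal TSV plus six
read-only adapters (MiTCR, MIGEC, MiXCR, IgBlast/AIRR, IMGT HighV-QUEST,
ImmunoSEQ), auto-detected from frozen header signatures. The tools
themselves document their column layouts; the signatures and column maps
are versioned in one registry (`dialect_registry()`) so the inevitable
historical variants can be added as aliases without touching parse logic.
Non-integer template estimates are rounded half-up with a floor of one;
duplicate (CDR3nt, V, J) rows are merged with counts summed and a warning.
ImmunoSEQ rearrangement sequences are kept verbatim — no re-extraction of
a C…F/W-delimited CDR3 is attempted.

## Down-sampling

Samples are compared at equal depth by drawing `m` reads *without
replacement* (multivariate hypergeometric over clonotype counts, drawn by
sequential conditional `rhyper`). Without-replacement sampling is the
physically correct model for uniquely labeled cDNA molecules; it also
makes the analytic rarefaction expectation (below) an exact oracle for the
sampler, a cross-check the test suite exercises in both directions.

## Diversity estimation

All estimators consume the frequency-count table `f_k` (number of
clonotypes seen exactly `k` times in `n` reads).

**Analytic rarefaction.** The expected richness of a subsample of size
`m` is the hypergeometric expectation

$$E[S(m)] = S_{obs} - \sum_i \binom{n - n_i}{m} \Big/ \binom{n}{m},$$

evaluated per distinct multiplicity with exact binomial-ratio products for
small counts and log-gamma otherwise (with an early exit when
`n - n_i < m`). For an error-free uniform repertoire (all counts 1) the
curve is exactly linear, `E[S(m)] = m`, to machine rounding (observed
error ~1e-12 at n = 10,000) — the anchor that separates true richness
from error-inflated richness.

**Extrapolation.** The dashed extension beyond the observed depth uses the
Chao1-conditioned multinomial form

$$E[S(n + m^*)] = S_{obs} + \hat f_0 \left(1 - \Big(1 -
\tfrac{f_1}{n \hat f_0 + f_1}\Big)^{m^*}\right),
\qquad \hat f_0 = \frac{f_1^2}{2 f_2}$$

(with `f1(f1-1)/2` when `f2 = 0`). Chao1 is the field-standard companion
to analytic rarefaction; the curve is continuous at `m = n` and approaches
`S_obs + f0`.

**Efron–Thisted estimator.** The unseen-species mass at Euler depth `d` is

$$\Delta_d = \sum_{x=1}^{d} (-1)^{x+1} f_x\, b_{x,d}, \qquad
b_{x,d} = P[\mathrm{Binomial}(d, 1/2) \ge x],$$

with standard error `sqrt(sum(b^2 f_x))`. The depth used is the largest
`d <= max_depth` whose coefficient of variation `SE/(S_obs + Delta)` stays
below `cv_threshold` (default 0.05); when no depth qualifies, the depth
minimizing the SE is used, and the unseen mass is clamped at zero so the
estimate never falls below the observed diversity. The original estimator
admits several parameterizations; this one is fixed, documented and
hand-verified (on `f = {1: 2, 2: 1}` at depth 2 the weights give
4.25 ± 1.0897 exactly). A `depth` argument pins the depth explicitly.
Two behaviors of the depth rule are worth knowing: with no singletons or
doubletons, small depths add nothing, but depths ≥ 3 pick up higher-order
terms; and near sampling saturation the clamped estimator's upward noise
can exceed the tiny true unseen count, so the estimator earns its keep in
genuinely undersampled repertoires (the regime it was designed for).

**The saturation model.** For comparison, `fit_saturation_model()` fits
`S(n) = a(1 - e^{-bn}) + kn` by constrained nonlinear least squares
(Levenberg–Marquardt with non-negativity bounds, quasi-Newton fallback)
from multiple seeded random restarts, then polishes the best solution.
All restart solutions are reported because the model is the point: on an
exactly linear curve — precisely the error-free uniform case — materially
different parameter vectors (`k = 1` with any `a, b`; large `a` with tiny
`b`) reach the same residual floor, so the "true clonotype count" `a` is
unidentifiable. The package demonstrates rather than hides this
degeneracy.

## Clonality

The nested breakdown assigns read mass to singletons, doubletons and five
quantiles of high-order (count ≥ 3) clonotypes: Q1 is the top 20% of
unique high-order clonotypes by abundance, and so on. When the high-order
count is not divisible by five the remainder goes to the highest quantiles
first — one fixed, tested convention for an otherwise ambiguous split.
Masses sum to one by construction.

## Error correction

Three strategies, matching the comparison the package is designed to
support:

* **Quality filtering** removes any clonotype with at least one CDR3 base
  below a Phred threshold (20 and 35 being the conventional settings).
* **Frequency-ratio merging** folds a child clonotype into a parent when
  the sequences are equal-length at Hamming distance 1 (substitutions
  dominate the error profile; indels are out of scope), the V and J calls
  agree (relaxable — the constraint is exposed as a flag since either
  convention is defensible), and the child/parent count ratio is at most
  1/20, i.e. merging requires more than a 20-fold abundance difference.
  Parents are scanned largest-first, each child merges at most once into
  its largest eligible parent, candidate pairs are found by a
  position-mask hash join rather than all-pairs comparison, and passes
  repeat to a fixed point so the operation is idempotent; reads are
  conserved exactly.
* **Replicate intersection** keeps only strict (CDR3nt, V, J) keys present
  in both replicates. Its known blind spot — errors reproducible across
  replicates, e.g. early-cycle PCR artifacts — is exactly what the
  synthetic generator's `reproducible` error mode emulates.

## Matching, joining and screening

`match_spec()` declares a matching rule: level (`nt_strict`, `nt`,
`aa_vj`, `aa`, or `aa_not_nt`), optional V/J segment sets, a frame filter,
an anchored CDR3 pattern with `X` wildcards and a mismatch budget
(substring search is spelled with explicit `X` padding, keeping the
semantics unambiguous), and a frequency floor; all criteria combine by
conjunction. `join_samples()` aggregates per-sample counts and frequencies
under a match key and records incidence; `public_clonotypes()` thresholds
on incidence. The `aa_not_nt` level is implemented as a post-filter on the
amino-acid join — keys shared by at least two samples with pairwise
disjoint nucleotide variant sets — since the mode is named but its
mechanics are not standardized.

Contamination screening formalizes a simple dichotomy for an amino-acid
key shared across donors: exactly one underlying nucleotide variant is the
signature of physical cross-sample contamination (one rearrangement cannot
plausibly recur identically in unrelated donors at the nucleotide level),
whereas two or more variants indicate convergent recombination. Donor
identity comes from the metadata file; sharing is counted per sample, with
donor collapsing available through the donor map.

## Statistical tests

Out-of-frame abundance between two samples is compared with a two-sided
Fisher's exact test on the reads 2×2 table (point-probability convention,
via `stats::fisher.test`). Clonotype-set overlap uses the upper
hypergeometric tail `P(X >= k)` via `stats::phyper`, stable for universes
as large as the ~1e8 unique CDR3 amino-acid variants. Both are checked
against full enumeration oracles in the test suite. No multiple-testing
machinery is included: the package defines no family of tests.

## The synthetic generator

`sim_config()` fixes the study conditions for every property test:
power-law (Zipf, default exponent 2 — a heavy tail typical of expanded
PBMC repertoires) or uniform clone abundances; a V/J usage pool; CDR3
lengths of 12–16 codons centered on 14 (the observed human TRB mode);
junction N-insertions (Poisson, mean 4); per-base substitution errors
(default 0.1%, up to the 10% cap); and a quality model in which an error
base is flagged low-quality with probability 0.3 — quality filtering
catches some but not most errors, which reproduces the known weakness of
quality-based correction.

Error molecules are modeled as *additional* error-bearing PCR duplicates
next to their parent (parents keep their counts), distributed across
single-mismatch variants so that no child exceeds
`max(1, floor(parent/20))` molecules — child/parent ratios stay within
the frequency-merging regime by construction, which is what makes exact
ground-truth recovery a testable invariant. With `reproducible = TRUE`
the variant sequences and their quality flags are a pure function of the
parent sequence and config seed, so replicates share their artifact set —
the scenario in which replicate intersection fails and frequency merging
succeeds. What the generator does *not* emulate: indels, chimeras, UMI
collisions, hypermutation, or realistic germline-templated junctions;
passing tests demonstrate algorithmic correctness under the stated model,
not biological fidelity of the sequences.

## Numerical choices and problem sizes

* Binomial-coefficient ratios: exact products for multiplicities ≤ 64,
  log-gamma beyond; frequencies printed at 9 significant digits.
* Ties everywhere broken by canonical order; seeded RNG is scoped (the
  caller's RNG stream is never disturbed).
* Degenerate inputs error early with informative messages: empty tables,
  over-deep down-sampling, missing quality strings, inconsistent pattern
  alphabets.
* The bundled checks run at deliberate desk scale: rarefaction anchors at
  n = 10,000; the error-correction rehearsal uses two replicates of 2,000
  reads over 100 uniform clones with 0.5% per-base reproducible errors
  (built at the expected 20-reads-per-clone allocation so merge ratios are
  below 1/20 by construction); Monte-Carlo oracle comparisons use a few
  hundred seeded draws per case. These sizes make every property sharp
  without requiring external data.

## Known limitations

Indel-tolerant matching, repertoire similarity indices (Jaccard,
Morisita), Shannon/Simpson-type indices, B-cell hypermutation and
paired-chain analysis are out of scope. Historical export variants of the
supported tools may need signature aliases. The Efron–Thisted CV depth
rule can overshoot near saturation, as discussed above. The internal
format is the only write target.
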