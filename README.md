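# clonkit — clonotype table analysis for immune repertoire sequencing

High-throughput sequencing of T- and B-cell receptor repertoires
(Rep-Seq/AIRR-seq) ends, after upstream V-(D)-J mapping, in a *clonotype
table*: one row per unique rearrangement with its read or UMI count, CDR3
nucleotide/amino-acid sequence and V/D/J segment calls. `clonkit` is an R
toolkit for everything a repertoire analyst does with those tables:

* **Parsing** — a concise internal TSV plus auto-detected adapters for
  MiTCR, MIGEC, MiXCR, IgBlast/AIRR, IMGT HighV-QUEST and ImmunoSEQ
  exports (gzip transparent, frequencies always recomputed from counts).
* **Single-sample summaries** — CDR3 spectratypes (with out-of-frame bins
  and top-clonotype highlights), V-spectratypes, V–J segment usage
  matrices, and the nested singleton/doubleton/quantile clonality
  breakdown.
* **Diversity** — analytic (hypergeometric) rarefaction with Chao1
  extrapolation, the Efron–Thisted unseen-species estimator, and a
  constrained multi-restart fit of the saturating model
  `S(n) = a(1 − e^(−bn)) + kn` that demonstrates its identifiability
  failure on error-free data.
* **Error correction** — Phred quality filtering, frequency-ratio
  single-mismatch merging (1:20 rule), and replicate intersection, each
  with a machine-readable correction report.
* **Multi-sample analysis** — flexible clonotype matching (nucleotide,
  amino-acid, segment-constrained, amino-acid-not-nucleotide), pattern
  search with wildcards and mismatch budgets, sample joining with
  incidence, public-clonotype detection, and cross-sample contamination
  screening that separates identical-nucleotide sharing from convergent
  recombination.
* **Statistics** — Fisher's exact test for out-of-frame abundance and the
  log-space hypergeometric overlap test (universes up to ~1e9).
* **Simulation** — a seeded generator of ground-truth repertoires with
  power-law clone sizes, segment usage, quality strings, reproducible PCR
  errors and contaminant spikes, so every claim above is testable without
  external data.

The core quantities, in standard notation: with `f_k` the number of
clonotypes seen exactly `k` times among `n` reads and `S_obs = Σ f_k`,
rarefaction computes `E[S(m)] = S_obs − Σ_i C(n−n_i, m)/C(n, m)`;
Chao1 adds `f0 = f1²/(2 f2)` unseen clonotypes; Efron–Thisted adds
`Δ_d = Σ_x (−1)^(x+1) f_x P[Bin(d, ½) ≥ x]` with SE
`√(Σ b² f_x)` and CV-based depth selection.

## Worked example

Simulate a heavy-tailed repertoire with sequencing errors, then summarize,
estimate diversity and correct:

```r
library(clonkit)

cfg   <- sim_config(n_clones = 200, abundance_model = "power_law", alpha = 2,
                    error_rate = 0.005, seed = 42)
truth <- generate_repertoire(cfg)
rep1  <- inject_errors(sample_reads(truth, 5000, seed = 101,
                                    sample_id = "rep1", cfg = cfg), cfg, seed = 201)
rep2  <- inject_errors(sample_reads(truth, 5000, seed = 102,
                                    sample_id = "rep2", cfg = cfg), cfg, seed = 202)

summarize_sample(rep1)
#> sample 'rep1': 6183 reads, 167 clonotypes
#>   out-of-frame: 0.0000 of reads, 0.0000 of clonotypes
#>   non-functional read fraction: 0.0032
#>   mean CDR3 length (freq-weighted): 46.54 nt

fct <- frequency_count_table(rep1)
efron_thisted_estimate(fct)
#> efron_thisted diversity estimate: 219.2 +/- 10.9 (s_obs = 167, depth 11)
diversity_estimate(fct, "chao1")
#> chao1 diversity estimate: 251.5 +/- 27.2 (s_obs = 167)

clonality_breakdown(rep1)
#> clonality of 'rep1':
#>   singletons 0.0113, doubletons 0.0094
#>   high-order quantiles: 0.8802 0.0608 0.0220 0.0100 0.0063

frequency_merge_correct(rep1)$report
#> frequency_merge correction: 167 -> 115 clonotypes (1146 reads reassigned, 0 dropped)
replicate_intersect_filter(rep1, rep2)$report
#> replicate_intersect correction: 356 -> 194 clonotypes (0 reads reassigned, 1254 dropped)
```

Reading: 5,000 sampled molecules picked up ~1,200 error molecules (0.5%
per base over ~47 nt), inflating observed diversity well past the 78 true
clones actually drawn; the total-diversity estimators reach toward the
200-clone truth, frequency merging collapses the single-mismatch error
children, and one quantile (a single dominant expansion) carries 88% of
the read mass. The same flows are scriptable from a shell through
`inst/exec/clonkit` (`convert`, `summary`, `spectratype`, `usage`,
`clonality`, `rarefaction`, `diversity`, `correct`, `downsample`,
`search`, `join`, `public`, `test`, `simulate`), each output carrying a
`#` provenance header.

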