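---
title: "Analysing a culturable endophyte survey with endodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing a culturable endophyte survey with endodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endodiv)
```

## The problem

Culture-dependent surveys of endophytic fungi produce a table of isolates:
each strain is cultured from a tissue (root, stem, leaf, tuber) of a host
plant, barcoded on the ITS region, and assigned the binomial of its closest
database match. `endodiv` covers the downstream computation for such a
survey: genus-level community profiling per tissue, alpha-diversity indices,
a neighbor-joining phylogeny with bootstrap support, and the arithmetic of
the accompanying bioassays (seed-germination phytotoxicity and
disc-diffusion antibacterial screens).

The package ships the transcribed tables of a survey of 77 culturable
endophytes from *Pinellia ternata* and *P. pedatisecta* as fixtures
(`pinellia_catalog()`, `pinellia_phytotoxicity()`,
`pinellia_antibacterial()`), and all examples below run on them.

## The community model and the six indices

Analysis is at **genus rank**: the unit of the abundance vector for a
stratum (one plant x tissue combination) is the genus of the closest match,
taken as the first token of the binomial. Genus rank is a deliberate choice:
the per-stratum index values of the packaged survey are reproduced at four
decimals only when richness counts genera; species rank does not reproduce
them. For genus counts $N_i$, total $N_t$, richness $S$ and
$P_i = N_i/N_t$, all with natural logarithms:

$$D' = \frac{S-1}{\ln N_t}, \qquad
  H' = -\sum_i P_i \ln P_i, \qquad
  D_s = 1 - \sum_i P_i^2, \qquad
  \lambda = \sum_i P_i^2,$$

$$PIE = \sum_i \frac{N_i}{N_t}\,\frac{N_t-N_i}{N_t-1}, \qquad
  J = \frac{H'}{\ln S}.$$

Two identities tie these together and are asserted as test invariants:
$\lambda + D_s = 1$ always, and $PIE = \frac{N_t}{N_t-1} D_s$ whenever
$N_t > 1$.

```{r diversity}
catalog <- pinellia_catalog()
tbl <- diversity_table(catalog)
format_diversity_table(tbl, digits = 4)
```

### Degenerate strata

A stratum with one genus has $\ln S = 0$, so $J$ is undefined; a stratum
with one isolate has $\ln N_t = 0$ and an empty pair space, so $D'$ and
$PIE$ are undefined. These cases yield `NaN` with machine-readable flags
(`undefined_J`, `undefined_D`, `undefined_PIE`) rather than errors, so a
full grid always renders. Empty strata are omitted with a warning, because
every index is undefined at $N_t = 0$.

### Presentation rounding and the one non-reproducing cell

Reports round half-to-even to 4 decimals (base R's `round()`), matching the
survey's presentation; full precision is kept internally. Comparing the
computed grid against the survey's reported values
(`flag_index_discrepancies()`) flags exactly one cell: the *P. ternata*
root Margalef index is reported as 2.7906, while the displayed formula with
$S = 5$, $N_t = 6$ gives $4/\ln 6 = 2.2324$. Whether the reported cell used
a species-rank richness ($S = 6$ gives $5/\ln 6 = 2.7906$) cannot be
settled from the published text, so the package computes from the formula
and reports the discrepancy — it is never special-cased to match.

```{r discrepancy}
flag_index_discrepancies(tbl)
```

A related, smaller inconsistency: pooling stems over both plants yields 10
distinct genera in the transcription, whereas the survey narrative says 9.
`summary_counts()` reports the computed value.

## The phylogeny stage

The ITS phylogeny pipeline is re-implemented from the distance level up and
deliberately does not wrap external tree software (ape is used only as the
`phylo` container and Newick parser; `ape::nj` and `ape::dist.dna` appear in
the test suite as independent cross-checks).

* **Distances** (`compute_distances()`): p-distance, JC69
  ($-\tfrac34\ln(1-\tfrac43 p)$) or K2P, under pairwise deletion — a site
  contributes to a pair only if both sequences carry an unambiguous base.
  Pairwise deletion is the default-and-only gap policy because it keeps all
  taxa comparable on ragged ITS data. The model defaults to p-distance; the
  original analysis named only "neighbor joining", so the model is
  configuration, not an inferred "true" setting.
* **Joining** (`nj_tree()`): Saitou–Nei agglomeration on
  $Q(i,j) = (r-2)\,d(i,j) - R_i - R_j$. Ties in $Q$ are broken by the
  smallest (row, column) index pair, which makes runs reproducible;
  negative branch lengths are clamped to zero with the deficit moved to the
  sister branch so the joined pair's path length is preserved. NJ is
  consistent on additive matrices, and the suite verifies exact bipartition
  recovery on random additive cases of 4–12 taxa.
* **Bootstrap** (`bootstrap_support()`): columns are resampled with
  replacement; supports are mapped onto the reference tree by canonical
  bipartition matching, never by node order. Replicates whose resampled
  columns leave a pair incomparable are skipped and counted (warning above
  10% skipped). Each replicate draws from a named substream of the master
  seed, so identical seeds give identical supports and changing the
  replicate count never reshuffles earlier replicates.
* **Newick** (`write_newick()` / `read_newick()`): labels containing
  metacharacters are single-quoted; round-trips preserve topology, branch
  lengths (to 1e-9) and supports.

The packaged survey's own tree is **not** reproduced here: that would
require downloading the deposited ITS sequences (accessions
ON677855–ON677931) and an external alignment step, both out of scope. The
phylogeny stage is instead validated on simulated alignments evolved along
known trees.

## Bioassay summarisation

The radicle-elongation inhibition rate uses the standard germination-bioassay
definition — the source protocol cites its method papers without printing a
formula, so the definition is recorded here as the package's choice:

$$\text{rate} = \frac{\bar{x}_{\text{control}} - \bar{x}_{\text{treated}}}
                     {\bar{x}_{\text{control}}} \times 100\%,$$

clipped below at zero, with nonpositive rates reported as NI (not
inhibited). Because the replicate pairing between treated and control dishes
is not recorded, the standard deviation is propagated replicate-wise: each
treated replicate is scored against the control mean and the sd of those
per-replicate rates is reported.

Activity bands are half-open: complete = exactly 100%, strong = [80, 100),
potent = [60, 80), weak = [10, 60), NI below 10. The conventional
"weak 10–60%" band overlaps threshold queries such as "more than 50%"; both
are supported (`classify_bands()`, `count_over()`). On the packaged screen
the strict `>` reading of "more than 50%" yields 52 strains — with 52.0%
entries present, the non-strict reading would differ, so strictness is an
inference from the data, exposed as a flag. Group comparisons use the
classical one-way ANOVA decomposition with Fisher's (unprotected) LSD
pairwise tests on the within-group mean square, plus pooled/Welch t tests,
mirroring the "significantly different from control / from the reference
strain" marking style of screen tables.

The disc-diffusion screen stores mean inhibition-zone diameters (IZD, mm;
active zones must exceed the 6 mm disc) and MIC values on the twofold
dilution ladder 100…1.56 µg/mL with a censored ceiling ">100" that sorts
after measured values. MIC is stored and validated, never modelled.

## Synthetic data: what it emulates, what it does not

The generators produce inputs with the statistical structure the analysis
assumes, so every stage is testable without network access:

* `simulate_catalog()`: multinomial genus counts per stratum from a
  probability vector (optionally forcing the expected counts exactly);
* `simulate_radicle_assay()`: control lengths
  $\mathcal N(\mu, \sigma)$ truncated at 0, treated lengths
  $\mathcal N(\mu(1-e), \sigma)$ truncated at 0, with `effect = 1` emitting
  exactly-zero lengths (complete kill is deterministic, not noisy);
* `evolve_sequences()`: i.i.d. uniform root, Jukes–Cantor site-independent
  evolution along each branch.

Truncation at zero (rather than resampling) slightly biases means upward at
large $\sigma/\mu$; tests therefore use small ratios. The sequence
generator has no indel or rate-heterogeneity process and no chimeras, and
the catalog generator draws strata independently — passing tests show the
pipeline arithmetic is right, not that real ITS data are this well behaved.

All randomness flows through `substream_seed(seed, name)`: one master seed,
one named substream per draw site.

### A caution on plug-in Shannon recovery

The plug-in $H'$ estimator is biased low by roughly $(S-1)/2N_t$ in small
samples. At the packaged survey's tuber stratum ($S = 12$ probabilities,
$N_t = 28$) the bias is about 0.22 nats, so the mean of $H'$ over many
simulated catalogs sits near 2.01, not at the generating community's
2.2299. The generators recover the exact index only when counts are forced;
under multinomial sampling at $N_t = 28$ the shortfall is structural, and
the suite documents it rather than hiding it (no bias correction is
applied, since the survey's own indices are plug-in values).

## Problem sizes used in the checks

The suite validates NJ on 100 random additive matrices of 4–12 taxa,
bootstrap resolution on a 6-taxon alignment of 2000 sites with 100
replicates, the statistics against brute-force oracles on 1000 random
inputs, and the Monte-Carlo Shannon experiment on 1000 seeded catalogs —
sizes at which every property under test is already fully expressed.

## One-shot runs

`run_all()` (and the thin `inst/cli/endodiv.R` wrapper) executes the whole
pipeline from a `run_config()`: diversity grid, discrepancy annotations,
headline counts, band counts and (given an alignment) a bootstrap tree.
Payload files are deterministic under a fixed config and seed; the
timestamp lives only in a sidecar metadata file (with a config fingerprint
and tool version) so payloads are byte-comparable across reruns. Exit codes
in the wrapper: 0 success, 2 validation error, 3 computation error.
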