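---
title: "Hit calling and network statistics for proteome-microarray SUMOylation screens"
author: "sumoarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hit calling and network statistics for proteome-microarray SUMOylation screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumoarray)
```

# The experiment this package models

A proteome microarray SUMOylation screen probes thousands of individually
purified human proteins, printed in duplicate within pin blocks on glass
slides, with an in-vitro SUMOylation mix: E1 activating enzyme, E2
conjugating enzyme (Ubc9), fluorescently labelled SUMO1 or SUMO2, and
optionally one of six E3 ligases (PIAS1–4, RanBP2, TOPORS). Two enzyme
regimes matter:

* **Saturating E1/E2 ("50x")** — many substrates are modified without any
  E3; these reactions act as the E3-independent reference.
* **Limiting E1/E2 ("1x")** — background modification is barely detectable,
  so adding an E3 ligase makes its substrate repertoire directly readable.
  The 1x reaction *without* E3 is the negative control.

Every condition is run in triplicate. After scanning, each spot is
quantified as a foreground and a local background fluorescence intensity;
everything downstream of that quantification is what this package
implements: hit calling, E3-dependent substrate derivation, bipartite
network statistics, motif scanning, and set enrichment, with a synthetic
generator that emulates the whole study so every stage can be exercised and
validated without external data.

# The hit-calling model

The signal intensity of a spot is its foreground/background ratio
$r = F/B$. The pipeline applies, in fixed order:

1. **Ratio floor.** Backgrounds below `floor` × median(background) are
   raised to that value, and ratios below `floor` are raised to `floor`
   (default 0.1). This keeps ratios finite and positive for spots with
   degenerate background estimates; both events are counted.
2. **Block-median normalization.** True reactions are rare and roughly
   evenly dispersed across print blocks, so each block is forced to a
   median signal intensity of one by dividing every ratio in a block by the
   block's median over included spots. Control spots and spots flagged bad
   or saturated are excluded from all statistics. The operation is
   idempotent, and the final hit set is invariant to rescaling all
   intensities of a block (a pure pin/print effect).
3. **Duplicate-spot threshold.** With $\mu$ and $\sigma$ the center and
   spread of all included normalized ratios on the array, a substrate is a
   positive on that array only when **both** spots of its duplicate pair
   exceed $\mu + k\sigma$ strictly, with $k = 5$ by default. A pair with an
   excluded spot is not callable; a protein printed more than twice is
   called when at least one full pair passes.
4. **Replicate consensus.** A substrate must be called in at least 2 of the
   3 replicates.
5. **Negative-control removal.** Substrates also called on the
   matching-isoform 1x negative-control arrays are removed; this also
   applies to the 50x hit lists.
6. **50x subtraction.** For E3 conditions, substrates called in the
   matched-isoform 50x reaction are removed; what remains is the
   **E3-ligase-dependent** substrate set. A union-of-isoforms policy is
   available via `hitcallParams(subtract50x = "union")`.

## Open choices and how they were resolved

Several details of this recipe are under-determined and were fixed as
package defaults, each switchable:

* **Statistic population.** $\mu, \sigma$ are computed array-wide over all
  included normalized ratios (default) rather than per block; after block
  normalization the blocks are on a common scale, and the array-wide pool
  is larger. `statPopulation = "block"` restores the per-block variant.
* **Raw vs normalized ratios for the threshold.** Normalized (the threshold
  is applied after step 2); applying it to raw ratios would re-import the
  block effects the normalization removes.
* **Strict inequality.** Ties at the threshold are excluded ("above the
  mean" read strictly); with continuous intensities this is immaterial.
* **Estimator.** `mean_sd` (the plain mean and standard deviation) is the
  default. The robust `median_mad` variant exists for simulator studies,
  and it matters: when active spots are more than a few percent of the
  array, the spikes themselves inflate the plain SD until
  $\mu + 5\sigma$ rises *above* the typical hit ratio and calling
  self-censors. At a realistic screen scale (the 50x reference sets here
  are >10% of the proteome) the robust estimator is the one that makes the
  5-SD rule behave as intended, so all simulator-driven analyses in this
  package use `estimator = "median_mad"`; the plain estimator remains the
  default because it is the published recipe. This sensitivity is a real
  property of mean/SD thresholds under contamination, not an artifact of
  the simulation.
* **Saturation.** Spots flagged saturated are kept in the data model but
  excluded from statistics; a scan with more than 25% saturated spots
  (`maxSaturation`) is unusable, mirroring screens where an entire
  condition had to be discarded for saturation. Fewer than two usable
  replicates is an error, not a silent degradation.

# Network statistics

`buildNetwork()` turns per-condition hit tables into a bipartite graph of
condition nodes (named `PIAS1-SUMO1`, `50X-SUMO2`, ...) and substrate
nodes. On top of it:

* `uniqueSubstrates()` — substrates of network degree 1, i.e. called in
  exactly one reaction.
* `isoformPreference()` — for an E3, the percentage of its total hits
  modified with SUMO1 vs SUMO2. Substrates modified with both isoforms are
  counted in both totals, so the two percentages always sum to 100. Note
  that in the published screen counts bundled with the package
  (`screenCounts()`), one E3's printed preference (RanBP2, 62.8%) does not
  equal the value implied by its own totals (64.6%); the basis of that
  printed figure is unknown and the package makes no attempt to reproduce
  it.
* `sharedFraction()` — the "share x% of their substrates" statistic. The
  denominator behind such statements is ambiguous, so the method is
  explicit: Jaccard (default), fraction of the smaller set, or fraction of
  the first set; reports should always state which.

Exports target Cytoscape (SIF, GraphML) plus a plain TSV edge list that
round-trips through `readNetwork()`.

# Motif scanning

`scanConsensus()` implements the SUMOylation consensus ΨKxE/D as a direct
residue-class scan: a forward hit at a lysine K requires a large
hydrophobic residue Ψ immediately before it and E or D two residues after;
the inverted variant (E/D)-x-K-Ψ is optional. Ψ defaults to
`{A, I, L, M, P, F, V}` — a deliberately broad hydrophobic set, since
published predictors differ — and is configurable. `X` never satisfies a
residue class but is allowed at the wildcard position. Hit positions are
reported at the acceptor K, 1-based. `scanSIM()` scans a configurable
SUMO-interacting-motif core, default `[VIL][VIL].[VIL][VIL]`; this default
is explicitly a stand-in for the heterogeneous SIM definitions in the
literature and is labelled as such in reports. Published per-condition
motif-site counts were produced by external predictors with undisclosed
thresholds, so this package's scanner is not expected to reproduce those
printed ranges; `summarizeMotifCoverage()` reports the in-repo scanner's
coverage honestly instead.

# Enrichment

All over-representation statistics are exact hypergeometric upper tails
(`stats::phyper`), with the **array's substrate universe** as background —
never the genome — because only printed proteins could have been called.
`enrichTerms()` tests GMT term sets intersected with the background,
reports raw p-values (the conventional report filter is raw p < 0.05) and
always computes Benjamini–Hochberg q-values alongside, since no
multiple-testing correction is implied by a raw-p filter.

# The synthetic-array generator

`simulateStudy()` emulates the screen structure end to end: a design of
`nProteins` proteins printed in duplicate across pin blocks with
interleaved control spots; planted per-condition true substrate sets; and
triplicate scans per condition. The generative model is log-normal
throughout, because fluorescence intensities are positive and
right-skewed:

* background $B \sim \mathrm{lognormal}(7,\ 0.5)$ (arbitrary fluorescence
  units);
* per-block factor $\mathrm{lognormal}(0,\ 0.3)$ multiplying all
  foregrounds of a block (the pin effect that block normalization must
  remove);
* per-spot ratio $\mathrm{lognormal}(0,\ 0.15)$ for inactive spots and
  $\mathrm{lognormal}(\log 20,\ 0.2)$ for active ones, with
  $F = B \times \mathrm{ratio} \times \mathrm{blockfactor}$.

The default study plan is the enumerable condition set of the screen: for
each isoform a 50x control and a 1x negative control, plus six E3 ligases
× two isoforms — 16 conditions × 3 replicates = 48 arrays. (The published
description mentions eighteen reactions without enumerating the final two,
so condition handling is entirely data-driven and nothing is hard-coded to
16.) Default planted sizes are 250/200 substrates for the two 50x
conditions, 50 E3-dependent substrates per E3 condition, and 2%
cross-reactive proteins that light up on *every* array including the
negative controls; half of the matched 50x set also reacts on each E3
array, which is exactly what the 50x subtraction must remove. At the
default desk scale of 2,000 proteins this mirrors the real screen's
proportions (where 50x hits were >10% of ~17,000 proteins) while keeping
a full study simulation and calling run in seconds; full scale is a
parameter change, not a code change.

**Dropout models enzyme-limited stochasticity.** A planted substrate of a
1x + E3 reaction fails (both duplicate spots together) with probability
0.1 per replicate — it is the limiting-enzyme reactions that fail
stochastically, which is also what makes the 2-of-3 consensus rule
consequential. Saturating-enzyme (50x) signals and cross-reactive binding
(which is not enzymatic at all) are generated without dropout. A
consequence worth stating: the negative-control and 50x subtractions are
exact on simulated data, because the reference conditions always re-detect
their own signals. On real arrays a reference condition can miss a
substrate that then leaks through the subtraction; the simulator does not
model that failure mode.

Randomness uses R's default Mersenne–Twister generator; every generator
function derives a sub-seed from `(seed, condition, replicate)`, so any
single scan is reproducible in isolation. Generator functions set the R
RNG state.

What the simulator deliberately does **not** emulate: spatial artifacts
(scratches, gradients, print-tip trends beyond the block factor), optical
saturation beyond a flag, correlated noise between duplicate spots, and
sequence-dependent signal. Passing recovery tests therefore demonstrates
the correctness of the pipeline's logic and its statistical behavior under
the stated noise model — not robustness to every failure mode of real
scans.

# Recovery scoring and problem sizes

`evaluateRecovery()` scores called sets against planted truth per
condition (precision is 1 by convention when nothing is called; recall 1
when the truth set is empty) and macro-averages across conditions. The
package's own validation runs use: a full 2,000-protein, 16-condition
study in triplicate for end-to-end recovery; twenty seeded null studies
(no planted substrates, no cross-reactives) for the false-positive
control; 200 randomized arrays of at most 500 spots checked against an
independently coded single-pass oracle; exhaustive hypergeometric
enumeration for all parameter tuples with N ≤ 12; and 1,000 random
500-residue sequences checked against a regex oracle for all three motif
classes.

# Known limitations

* The pairwise-overlap planner (`plantTruth()`) honors each requested
  pairwise intersection exactly by drawing it from the earlier set's
  exclusive region, which forces triple overlaps to zero; arbitrary
  higher-order overlap structures are out of scope.
* The published screen's absolute hit counts are not reproducible from the
  package alone — the raw scans behind them were never deposited — so the
  bundled `screenCounts()` table is carried as *input* data for the
  network statistics, and recovery claims are made only against planted
  synthetic truth.
* GPR parsing targets the tab-separated GenePix dialect (any header
  length, minimal column set, configurable wavelength); binary or exotic
  scanner exports are not supported.
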