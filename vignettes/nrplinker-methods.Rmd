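---
title: "NRPlinker: model, numerical conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NRPlinker: model, numerical conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NRPlinker)
```

NRPlinker identifies non-ribosomal peptides (NRPs) by matching candidate
peptide structures, predicted from NRPS biosynthetic gene clusters (BGCs),
against tandem mass spectra. This vignette is the package's own account of
the underlying model: what each stage assumes, which knobs matter, and where
design choices were genuinely open.

## Input model and its assumptions

The engine starts downstream of genome mining: a BGC arrives as ordered ORFs
of ordered NRPS modules, each module carrying a set of tiered substrate
predictions for its adenylation (A-) domain — a Stachelhaus-code percent
identity (0–100) and an SVM tier (`single`, `small_cluster`,
`large_cluster`, `none`). Domain-presence flags (methylation PF08242-type,
epimerization, cytochrome P450, C-starter) are boolean annotations in the
input. The package deliberately defines its own JSON/TSV schema rather than
parsing genome-mining output directly: that decouples the engine from any
particular external predictor, and the flags make the out-of-scope HMM layer
explicit. BGCs with fewer than 3 A-domains are rejected — with one or two
residues constrained, essentially any spectrum can be matched, so such
clusters carry no discriminating information. Spectra with fewer than 20
peaks are rejected for the mirror-image reason: a shared-peak-count score
over a sparse spectrum cannot separate signal from chance.

## Specificity scores

For a substrate prediction, the SVM tier maps to 100/90/80/0 and the
specificity score is the mean of the Stachelhaus identity and the SVM score,
computed on the raw values; predictions with identity ≤ 50 (strict) or SVM
score 0 are excluded. Averaging precedes any integer rounding — rounding
happens once, at normalization — because truncating twice loses a digit of
evidence for no benefit. Per position, scores are normalized to
`round(100 · s / max s)` so the best substrate is exactly 100; this removes
the systematic advantage of well-characterized A-domains, whose absolute
scores run higher than those of rare domains. "Nearest integer" is
implemented as half-away-from-zero: R's default half-to-even rule would make
results depend on parity, and a fixed tie rule keeps runs reproducible. A
module whose alphabet empties after filtering makes the whole BGC
unpredictable and the cluster is skipped with a warning; inventing wildcard
residues would silently turn a genomics-driven search into a de novo one.
More than 12 surviving substrates per domain is logged but not capped, since
inputs may come from predictors with other tier structures.

## Assembly lines

Non-canonical biosynthesis is modeled at ORF granularity only: `orfDel`
removes any subset of up to two ORFs (not only contiguous ones), `orfDup`
repeats exactly one ORF's modules in tandem once or twice. Deletion and
duplication are not combined — each generator models a distinct documented
biological phenomenon (subunit skipping, iterative subunit use), and their
composition would square the line count for speculative gain. Lines are kept
between 3 and 20 modules, the bound applied to the final line (after
duplication). For a k-ORF cluster with no size exclusions this gives
`1 + C(k,1) + C(k,2)` deletion lines and `1 + 2k` duplication lines — 11 and
9 for k = 4, which the acceptance suite pins.

## Filtering the core space

The number of cores at each adenylation score is computed by the bottom-up
dynamic program `numCores(i, s) = Σ_a numCores(i−1, s − S(i, a))` with
`numCores(0, 0) = 1`, stored as doubles (exact below 2^53; genome-scale
clusters overflow 32-bit integers long before that). The retention threshold
is the greatest score s′ with at least N = 1000 cores scoring ≥ s′; when the
whole space is smaller than N everything is kept. Candidate emission walks
the acyclic graph of (position, score) nodes depth-first, score-descending
with lexicographic residue tie-breaks, and truncates at a hard cap of 10^5
cores. One subtlety: a threshold defined through cumulative counts can
select far more than N cores when the distribution has large ties at the
threshold score; the enumeration cap — rather than a threshold adjustment —
is what guarantees bounded downstream work, because adjusting the threshold
upward would silently drop all tied cores rather than a deterministic
prefix.

## Structures and theoretical spectra

Every core yields a linear backbone (water offset +18.01056 Da for the free
termini) and a head-to-tail cyclic backbone (offset 0); clusters with a P450
domain additionally yield branch-cyclic backbones for every chord (i, j)
with j ≥ i + 2 (adjacent chords would duplicate a backbone bond).
Methylation-flagged positions expand to the power set of optional
+14.01565 Da variants — monoisotopic, since matching happens at 0.02 Da.
Epimerization changes stereochemistry, not mass, and is metadata only.

The theoretical spectrum enumerates all bridges and minimal 2-edge cuts of
the peptide graph and records each connected fragment's neutral mass:
2(n−1) fragments for a linear peptide, n(n−1) for a cyclic one. Fragment
terminal offsets are a convention the fragmentation literature leaves open
at this level of abstraction; the package adopts the unique rule under which
the two fragments of any cut sum exactly to the structure mass in all three
topologies: suffix fragments of a linear chain carry the water, everything
else is a bare residue sum. The rule lives in one function
(`fragmentWaterOffset`) so it can be swapped wholesale. The proton offset
(+1.00728 Da) is applied once, at comparison time.

## Scoring and the blind modification search

`spcScore` counts distinct theoretical peaks (deduplicated at 1e-5 Da, the
scale where summation order noise lives) with at least one experimental peak
within ε = 0.02 Da. A theoretical peak counts at most once, but several
theoretical peaks may share one experimental peak — the score is a pure
per-theoretical-peak count, not a matching. Intensities are read but unused
by the score; they matter only for networking.

When the precursor and structure masses agree within Δ = 0.02 Da the match
is scored unmodified. Otherwise the blind search places the full offset
`ω = Mass(S) − Mass(P)` on each residue in turn (positions where the
shifted residue mass would go negative are inadmissible) and keeps the
best-scoring position, ties to the smallest index. This is an exact O(n)
scan per candidate; sublinear indexing schemes exist for the same objective
but change no result, and at the package's operating scale the scan is not
the bottleneck. One modification per structure is the model's limit:
compound modifications are indistinguishable from a single merged offset at
the precursor level, and the per-position scan only localizes one site.
Modifications above MaxMass = 150 Da (configurable; 200 is a sensible
setting for lipopeptide-rich data) are invisible by design — a documented
miss class, not a bug.

## Statistical significance

The p-value of a PSM is the probability that a uniformly random peptide of
the same length and topology reaches the observed score. The null alphabet
defaults to the standard-20 residue multiset (so Ile/Leu mass degeneracy is
represented twice, as in nature); it is configurable to candidate-derived
frequencies. Topology-matched null peptides were chosen over linear ones
because cyclic theoretical spectra have n(n−1) peaks versus 2(n−1) — a
linear null would overstate the significance of every cyclic match.

Two estimators are provided. `pvalueExhaustive` enumerates spaces up to 10^6
peptides and is the oracle. `pvalueMcmc` is a multilevel-splitting estimator:
a population (default 10,000) of random peptides, score levels raised at the
empirical 0.1-survival quantile, population restarts from survivors, and a
single-position substitution kernel with rejection below the current level —
a Metropolis chain whose stationary law is uniform on the level set. The
p-value is the product of conditional survival fractions. The estimator is
reproducible given its seed, returns 1 for observed score 0, and floors at
1/(population+1) when a forced level strands the population (a tail beyond
the space's resolution). The test suite verifies factor-of-3 agreement with
enumeration for tails down to 1e-5 on 6-residue spaces; note the estimate of
a tail that is *exactly zero* (an observed score no null peptide attains) is
reported at the floor, which is the correct one-sided statement "below
resolution", not an unbiased estimate of zero. E-values multiply the p-value
by the numbers of spectra and structures searched; the significance gate
defaults to p ≤ 1e-15, with optional target-decoy FDR control at 1% using
residue-shuffled, topology-preserving decoys.

The 1e-15 default presumes realistic search spaces (peptides of 6+ residues,
thousands of structures). A tail probability can never undercut roughly
1/|null space|, so on deliberately tiny synthetic problems the gate must be
scaled to the problem — the package's own tests do exactly that and say so.

## Spectral networking

Identified spectra are clustered greedily (single linkage) when precursors
agree within tolerance and the modified cosine reaches 0.7; cluster count
estimates distinct NRPs. The modified cosine aligns peak pairs directly or
offset by the precursor mass difference, with square-root intensity
weighting (a common variance-stabilizing choice, exposed as a knob) and a
greedy best-product one-to-one matching. Cluster representatives (highest
total ion current) are joined into a network whose connected components are
reported as NRP families; a family is reported only when it contains a PSM
with p ≤ 1e-20. The threshold is applied as cosine ≥ 0.7: an edge exists
when similarity *reaches* the threshold. The full iterative consensus
clustering of dedicated tools is intentionally simplified — counts, not
consensus spectra, are this engine's contract.

## The synthetic-data generator

`fixtureSpec`/`makeBgc`/`simulateSpectrum` generate the study conditions the
tests run under. A fixture BGC plants one substrate per A-domain with
perfect evidence (Stachelhaus 100, single SVM tier) among distractors with
strictly weaker evidence (identity 55–90, cluster tiers), so the planted
core is the unique top-scoring candidate; planted residues are drawn without
replacement so a planted modification position is identifiable. Simulated
spectra protonate the theoretical peaks and degrade them with Gaussian
jitter truncated at 3 sd (capped at ε/2 — beyond that the fixture is
unsolvable by construction and `fixtureSpec` refuses it), Bernoulli
peak dropout, and uniform noise peaks over [50, precursor]. Intensities are
uniform draws: the generator makes no attempt at instrument-realistic
intensity or isotope modeling, so passing tests demonstrate correctness of
the combinatorics, scoring, and statistics — not robustness to real
instrument artifacts, chimeric spectra, or in-source fragmentation. Default
shapes (2 ORFs × 2–3 modules, 3 substrates per domain, dropout 0.3 / 20
noise peaks for the degraded condition) keep exhaustive oracles feasible
while exercising every code path; the acceptance suite uses 100-seed
batteries at these settings, 200 random assembly lines with alphabet
products ≤ 4^6 for the dynamic-programming oracle, and 60 estimator runs at
10,000 simulations against 6-residue exhaustive enumerations.

## Known limitations

- No glycosylation/acylation enzymology: unanticipated chemistry appears
  only as a blind mass offset, with no structural interpretation.
- No stereochemistry in mass space; epimerization is carried as metadata.
- One modification per mature peptide.
- Fragment model has no isotope envelopes, no multiply-charged theoretical
  peaks, and no neutral losses beyond the water convention.
- Clustering is greedy single-linkage; pathological chaining is possible at
  permissive cosine thresholds.
- The p-value floor of the splitting estimator (product of ~1/N terms) means
  extremely small reported values are order-of-magnitude statements, not
  precise probabilities.
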