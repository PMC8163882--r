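# NRPlinker

NRPlinker is a peptidogenomics engine for discovering non-ribosomal peptides
(NRPs): it links biosynthetic gene clusters (BGCs) found in microbial genomes
to tandem mass spectra of the molecules those clusters produce. It is aimed
at natural-product and microbiome researchers who have (i) per-adenylation-
domain substrate predictions for NRPS clusters (e.g. from an SVM/Stachelhaus-
code predictor) and (ii) MS/MS data of culture extracts, and want
statistically scored peptide–spectrum matches (PSMs) without knowing the
peptide structures in advance.

## The method

An NRPS **assembly line** is the ordered sequence of adenylation (A-) domains
`A_1..A_n`; each domain carries a small scored alphabet of candidate
residues. NRPlinker explores non-canonical lines too: deletion of up to two
whole ORFs (**orfDel**) and tandem duplication of one ORF (**orfDup**), with
lines kept between 3 and 20 modules.

Per-domain evidence is combined as the mean of the Stachelhaus percent
identity and the SVM-tier score (100/90/80 for single / small-cluster /
large-cluster predictions), keeping only substrates with identity > 50 and a
positive SVM score, then normalized per position so the best substrate scores
exactly 100. A core peptide `a_1..a_n` gets the additive **adenylation
score** `Score(a_1..a_n) = Σ_i S(i, a_i)`.

Because the cartesian product of alphabets is astronomically large for real
clusters, NRPlinker counts cores by score with the dynamic program

    numCores(i, s) = Σ_{a ∈ A_i} numCores(i-1, s - S(i, a))

in `O(k · n · 100n)` time, picks the score threshold retaining the top N
(default 1000, hard cap 10^5) candidates, and emits exactly the cores above
threshold as paths of an acyclic (position, score) graph.

Each candidate core becomes linear, head-to-tail cyclic, and (when a P450
domain licenses side-chain cyclization) branch-cyclic **peptide graphs**;
methylation domains add optional +14.01565 Da variants. The **theoretical
spectrum** of a graph is the multiset of fragment masses from all bridge
removals and minimal 2-edge cuts. A structure is scored against a spectrum by
the **shared peak count** (SPCScore): the number of distinct theoretical
peaks within ε = 0.02 Da of an experimental peak. Blind post-assembly
modifications are handled by scanning `Variant(P, i, ω)` — the offset
`ω = Mass(S) − Mass(P)` placed on each residue in turn — up to
|ω| ≤ 150 Da.

PSM significance is the probability that a random peptide of the same length
and topology scores at least as high, estimated exactly by enumeration on
small alphabets and by **multilevel-splitting Monte Carlo** (a rare-event
estimator over a peptide-substitution Markov chain) in general; E-values
multiply by the numbers of spectra and structures. Identified spectra are
grouped by modified-cosine **spectral networking** into putative NRP
families.

## Worked example

The package ships a scored eight-domain alphabet for the cyclic-surugamide
assembly line (`inst/extdata/surugamide_alphabet.tsv`). Scoring the
surugamide A core against it, then filtering the core space:

```r
library(NRPlinker)
tab  <- read.delim(system.file("extdata", "surugamide_alphabet.tsv",
                               package = "NRPlinker"))
line <- assemblyLineFromScores(tab, bgcId = "surugamideAL")
adenylationScore(line, c("ile","phe","leu","ile","ala","ile","ile","lys"))
#> [1] 766
counts <- countByScore(line)
sum(counts@counts[9, ])                       # all possible cores
#> [1] 64800
thr <- thresholdScore(counts, 1000)           # top-1000 score threshold
thr
#> [1] 775
nrow(enumerateCandidates(line, counts, thr))  # candidates actually kept
#> [1] 1024
```

The score 766 is the sum of the per-position normalized scores of the
surugamide A residues (80 + 100 + 100 + 100 + 100 + 100 + 100 + 86); the
filter keeps 1024 of 64,800 cores. A full synthetic
run — generate a BGC with a planted peptide plus spectra carrying a planted
+99.07 Da modification, then search:

```sh
Rscript inst/scripts/nrplinker fixtures --seed 7 --out-prefix fx \
    --pam-position 2 --pam-delta 99.06841
#> planted core: asn-tyr-cys-ala-met-trp
Rscript inst/scripts/nrplinker search --bgc fx.json --mgf fx.mgf \
    --out fxout --mode canonical --n-sim 300 --pvalue 1e-3
#> PSMs: 3 (significant: 3); outputs in fxout
```

The top PSM in `fxout/psms.tsv` recovers the planted core with
`variantPosition 2` and `variantDelta 99.06841` — the blind search localized
the modification without being told it exists.

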