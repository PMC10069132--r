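---
title: "Models and methods behind popscanr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popscanr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

popscanr analyses diploid SNP-array genotypes from a two-population design:
per-population diversity, between-population differentiation, inbreeding
from runs of homozygosity (ROH), and cross-population haplotype scans for
signatures of divergent selection. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Quality control

`apply_qc()` applies six filters in a fixed order: (1) SNP call rate
strictly above 0.90; (2) SNPs without a chromosome or physical position
removed; (3) samples with missing fraction at or above 0.05 removed; (4)
SNPs with minor allele frequency at or below 0.01 removed, with MAF
recomputed after the sample filter; (5) non-autosomal markers removed; (6)
one member of each sample pair with identity-by-state (IBS) at or above
0.99 removed, keeping the first-seen sample. All inequalities are strict
on the "keep" side, reading thresholds such as "call rate higher than
0.90" literally. PLINK interleaves these filters differently; the fixed
enumeration order used here makes each removal attributable to exactly one
rule and keeps the report's counts telescoping. The filter is idempotent.

`ld_prune()` implements 50-SNP/5-SNP/0.5 sliding-window pruning on
composite (genotype-dosage) r², which needs no phase information. When a
window contains a pair above the ceiling, the member of the worst pair
with the lower call rate is removed (tie: the higher marker index) —
PLINK's exact tie-breaking is undocumented, so a deterministic rule was
chosen and the post-condition (no surviving within-window pair with
r² > 0.5) is enforced by repeated passes and verified in tests.

## Diversity and structure

Heterozygosities use the plain PLINK conventions: per marker and group,
H_O is the heterozygote fraction among non-missing calls and H_E = 2p(1−p)
(an unbiased `2n/(2n−1)` variant is switchable). Summaries average over
all markers, monomorphic included.

Differentiation uses the Weir–Cockerham (1984) moment estimator θ for two
populations, combined over loci as the ratio of sums of the per-locus
numerator and denominator components. Significance comes from permuting
individuals between the pair (default 10,000 permutations, the
conventional choice; tests use fewer) with the `(hits + 1)/(n + 1)`
smoothed p-value. Reynolds distance is the drift-linearised
D = −ln(1 − θ), with θ clamped to [0, 1) so D is defined at degenerate
inputs. AMOVA-based estimators (Arlequin) differ slightly from θ; the
Weir–Cockerham form was chosen because it is the field standard and
analytically checkable against the simulator's target.

Structure is summarised by classical (Torgerson) MDS on the IBS distance
1 − (mean shared-allele fraction), via double-centering and
eigendecomposition (`cmdscale`); explained proportions are eigenvalues
over the sum of positive eigenvalues. IBS distances are not exactly
Euclidean, so small negative eigenvalues can occur and are excluded from
the denominator.

Effective population size uses the LD method: for syntenic pairs at
recombination distance c (constant 1 cM/Mb map — no linkage map is
assumed), the mean composite r² in a distance bin, corrected by −1/n for
sample size, gives N_e = (1/(4c̄))(1/r̄²_adj − α) at t = 1/(2c̄)
generations back, with α = 1 by default. Groups are fixed at n = 20
(larger groups are subsampled, smaller skipped) because r² in small
samples is dominated by sampling noise; the N_e13/N_e50 summaries read
the bins with t nearest 13 and 50. The full SNeP adjustment family
(mutation, phasing corrections) is deliberately reduced to the α and 1/n
terms; consequently N_e is validated by simulation recovery (a
Wright–Fisher population of known size), not by parity with any one tool.

## Runs of homozygosity

`detect_roh()` implements the stated segment criteria directly and
exhaustively: a run must have ≥ 30 SNPs, span ≥ 1 Mb, contain at most one
heterozygous and one missing call, have at least one SNP per 100 kb, and
no adjacent-marker gap above 500 kb; returned segments are maximal
(no qualifying superset), and overlapping qualifying segments of one
individual merge when their union qualifies, otherwise the longest (tie:
leftmost) is kept. This is deliberately not PLINK's scanning-window
heuristic, whose behaviour depends on an unstated 50-SNP window; the
exhaustive-maximal semantics are verified against a brute-force
subinterval oracle in the tests. Spans are measured first-SNP to last-SNP
(PLINK convention). ROH should be called on the unpruned post-QC marker
set — pruning removes exactly the local redundancy the caller needs.

F_ROH = L_ROH / L_AUT with L_AUT defaulting to 2452.06 Mb, the autosomal
length covered by the ovine 50K array; supply `l_aut_bp` matching your
array or simulated genome. Because a run is bounded by the first
disqualifying call *outside* the autozygous stretch, detected runs extend
slightly beyond planted spans (about one marker spacing plus the
one-allowed-het extension per side); with 2–4 Mb segments at 25–50 kb
spacing this inflates recovered F_ROH by well under 0.01.

ROH islands: per SNP, incidence = fraction of the group's individuals
whose ROH covers it; the threshold sits at the 0.999 point of the
incidence distribution and islands are maximal runs of SNPs strictly
above it. Two threshold variants are provided. The nearest-rank quantile
(`method = "rank"`) is conservative but self-defeating on small genomes:
a strong island whose tied-at-maximum block exceeds 0.1% of markers
raises the threshold to its own value and excludes itself (at 50-kb
spacing a 2-Mb island would need a > 2 Gb genome to be flaggable). The
default (`method = "range"`) therefore places the threshold 99.9% of the
way through the observed incidence range, which flags tied-at-maximum
blocks, returns nothing when incidence is constant, and coincides with
the rank method's intent on large, smooth incidence distributions. The
threshold is computed per group, genome-wide; island contiguity is
consecutive markers in the map, with no gap-bridging.

## Haplotype scans

Site-specific EHH (EHHS) partitions haplotypes into classes identical
over the interval from a core marker to each flanking marker. The Tang
variant normalises the identical-pair count by the core-allele pair
count, `Σ_k n_k(n_k−1) / Σ_a n_a(n_a−1)`; the Sabeti variant by the total
pair count, `Σ_k C(n_k,2) / C(n,2)`. Both are defined to equal 1 at the
core. A haplotype with a missing allele leaves all classes from that
marker outward (synthetic data is complete, so this path is edge-tested
only). iES is the trapezoidal integral of EHHS over physical position,
each side truncated at the first marker below 0.05 (included as the final
endpoint); a side that reaches the chromosome end first leaves iES
undefined by default (`discard_at_border`), the convention of standard
EHH implementations.

Rsb uses the Tang variant and median-centering; XP-EHH the Sabeti variant
and mean-centering; both scale by the genome-wide SD of
raw = ln(iES_A/iES_B) over sites defined in both populations (a plain
Z-test; no frequency-binned standardisation). The p-score is
−log10(1 − 2|Φ(z) − 0.5|). Windows of 250 kb, overlapping 10 kb, tile
each chromosome from its first marker; a window is significant with ≥ 3
SNPs strictly above p-score 4. Terminal windows may be shorter but use
the same count. Per method, overlapping or adjacent significant windows
merge into regions bounded by the first and last significant SNP
(SNP-edge, not window-edge, boundaries); regions of different methods —
including ROH islands — overlapping by ≥ 1 bp consolidate into one
candidate region carrying the union span and the set of supporting
methods.

A practical limit worth knowing: with plain genome-wide SD
standardisation, a sweep occupying a fraction f of the scanned markers
inflates its own yardstick, capping the attainable Z near 1/√f. With the
p-score-4 threshold (|z| ≈ 3.89) a planted sweep should therefore occupy
at most ~2.5% of the simulated genome to be reliably detectable — on a
40-Mb test chromosome, a 1-Mb swept haplotype is comfortably recovered, a
2-Mb one is marginal. Real genome-scale data (thousands of Mb) does not
approach this cap.

## The synthetic-data generator

`simulate_haplotypes()` builds each population in three layers: (i) per
SNP, an ancestral frequency drawn uniformly in (0.1, 0.9) and a
population frequency from the Balding–Nichols distribution
Beta(p(1−F)/F, (1−p)(1−F)/F) with F = `fst_target`; (ii) a founder pool
of 200 haplotypes sampled site-wise at the population frequency; (iii)
each sample haplotype a recombinant mosaic of founders with Poisson
crossovers at 2e-6 per bp (500-kb mean segments). Defaults: 2 × 50
diploids, one 50-Mb chromosome at one SNP per 50 kb, F = 0.05 — a
plausible within-breed-group differentiation on a medium-density array.
The founder pool size matters: the founder-sampling layer adds roughly
1/n_founders of extra differentiation on top of the Balding–Nichols
target, so 200 founders keep realised θ within a few percent of
`fst_target` (measured 0.105 at a 0.10 target) while still giving
haplotype sharing and EHH decay on the few-hundred-kb scale of livestock
arrays. Sweeps are planted by copying one template haplotype into a
`round(target_freq × 2n)` subset over a window; autozygosity by copying
haplotype 1 onto haplotype 2 of a carrier fraction over a span — both
exactly recorded in a truth set that round-trips through TSV.

What the generator does *not* emulate: coalescent genealogies (LD beyond
the founder-mosaic scale is absent), soft sweeps, allele-frequency
spectra of ascertained arrays, genotyping-batch artifacts, and background
inbreeding at realistic livestock levels (simulated individuals pair
independent haplotypes, so chance ROH are much rarer than in real
breeds). Passing recovery tests therefore demonstrates correctness of the
statistics and the detection machinery under known truth — not
calibration against any real breed's demography.

`sim_wright_fisher()` complements this with a discrete-generation
random-mating diploid population (constant size, Poisson recombination at
1 cM/Mb, 200 generations from linkage equilibrium), used to validate the
LD-based N_e estimator against a known census size.

## Problem sizes and determinism

The test-suite simulations use one 40–50 Mb chromosome at 10–50 kb
spacing (1,000–5,000 SNPs) and 20–50 diploids per population — large
enough for stable genome-wide standardisation and binned r² means, small
enough that the full suite runs in minutes on one CPU. Every stochastic
operation derives its RNG stream from the master seed and the operation
name, so stages are reproducible independently and bit-identical under a
fixed seed. Degenerate inputs are handled explicitly: monomorphic loci
contribute zero to both θ components; a constant raw scan track gets unit
scale (scores 0 everywhere); θ is clamped before the Reynolds log;
r̄²_adj at or above 1/α marks the N_e bin undefined rather than negative.
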