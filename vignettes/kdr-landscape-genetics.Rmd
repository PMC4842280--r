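---
title: "Methods: landscape genetics of kdr resistance mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape genetics of kdr resistance mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdrscape)
```

## The scientific problem

Knockdown resistance (*kdr*) to pyrethroid insecticides in *Anopheles
sinensis* is conferred by amino-acid replacements of leucine at codon L1014
of the *para*-type sodium channel gene. The package analyses a 1285 bp
fragment spanning this codon and its two flanking introns to ask how many
times the resistant alleles (L1014F/C/S, codons TTT/TTC, TGT, TCG from the
wild-type TTG) have arisen, and to relate their patchy geographic
distribution to the demographic and spatial structure of the mosquito
populations that carry them. The introns, being untranslated, serve as the
quasi-neutral genetic background on which the resistant codons ride: a codon
state recurring on several distinct intron backgrounds is evidence for
independent mutational origins, while uniformly low intron diversity around
a near-fixed resistant codon is the classic footprint of a selective sweep.

## Fragment model

The fragment is modelled as an exon/intron tiling in 1-based inclusive
coordinates: exon 1–74, intron-1 75–979 (905 bp), exon 980–1166 (187 bp,
containing the focal codon at 1160–1162), intron-2 1167–1230 (64 bp), exon
1231–1285 (55 bp). This is the unique arrangement consistent with the
documented segment lengths and the known polymorphic-site positions (181,
940, 943 in intron-1; 1197, 1210, 1226 in intron-2; codon bases at 1161 and
1162). All site positions are reported in these full-fragment coordinates,
even after analyses restrict to the 969 intron columns.

Columns containing `-` or `N` are excluded from site-based statistics
(complete deletion) but retained for haplotype identity; pairwise difference
counts skip only the positions missing within that pair (pairwise
deletion). This is the common sequence-polymorphism convention and keeps
the mean pairwise difference robust to sporadic missing data; a
`deletion = "complete"` switch provides strict parity with
complete-deletion software. Note one deliberate reporting choice: per-site
diversity is always π = K/L over all analysed sites. Summary tables in the
source literature for this system normalise by a reduced site set (π there
is close to K/65 on a 969-site region), so printed π values are not
directly comparable; K, S, h and Hd are.

## Statistics and their null distributions

Tajima's D, Fu & Li's D\* and F\* (with the Simonsen–Churchill–Aquadro
corrected variance coefficients), Fu's Fs and the Ramos-Onsins–Rozas R2 are
computed per population on the intron region. Multi-allelic columns
contribute 1 to S but (k−1) mutations to η, the infinite-sites count the
Fu & Li tests use; singleton mutations are derived states (relative to the
majority base) carried by exactly one sequence.

Fu's Fs is evaluated through the Ewens sampling distribution of the number
of alleles, with unsigned Stirling numbers of the first kind computed by
recurrence in log space. This stays finite and accurate up to the largest
sample analysed here (546 chromosomes); S′ and 1−S′ are both computed as
log-sum-exp tail sums so the logit never suffers cancellation.

Significance is assessed against a coalescent null conditioned on the
observed number of segregating sites: neutral constant-size genealogies
with exactly S mutations placed multinomially on branches in proportion to
branch length. Conditioning on S rather than θ removes the nuisance
parameter and matches the convention of the standard desktop tools for
these tests. Tails are two-sided for D, D\* and F\* and lower-tailed for Fs
and R2 (the expansion/sweep direction); the upper tail of Fs is also
reported so either star convention found in published tables can be
applied. Because D\* is a function of the discrete pair (η, η\_s), its null
has large probability lumps on single values; empirical p-values therefore
count ties at half weight (mid-p), which keeps all five tests at their
nominal level (the package's calibration test verifies type-I error within
[0.03, 0.07] at nominal 5 %). Across populations, p-values are adjusted by
Benjamini–Hochberg FDR (Bonferroni is available for the pairwise matrices,
where the source literature used both conventions in different places;
FDR is the default).

## The sudden-expansion model

The mismatch distribution under a stepwise expansion from θ₀ to θ₁ at
mutational time τ is the equilibrium geometric law at θ₁ plus an
exponentially damped convolution of Poisson(τ) with the difference of the
θ₀ and θ₁ equilibria. Its two analytic limits anchor the implementation:
τ = 0 collapses to the geometric law, and θ₀ = 0, θ₁ → ∞ to Poisson(τ).

Two estimators are provided. The moment estimator uses the mean m and
variance v of pairwise differences: θ̂₀ = √max(v−m, 0), τ̂ = m − θ̂₀, with
θ₁ at its moment-method limit (infinity). The least-squares estimator
minimises the sum of squared deviations (SSD) between observed and expected
*relative frequencies* (the SSD scale used throughout) over (τ, θ₀, θ₁),
by a coarse grid followed by L-BFGS-B refinement multi-started from the
best grid point and from the moment estimate. θ₁ is constrained to
θ₁ ≥ θ₀ and capped at 10× the largest mismatch class: the likelihood
surface is flat in θ₁ above that scale, and the capped model approaches
the infinite-growth limit to O(1/θ₁).

Goodness of fit uses a parametric bootstrap: coalescent samples are
simulated under the fitted demography (a coalescence-rate step of factor
θ₁/θ₀ at scaled time τ/θ₁), refitted with the same method, and SSD and
Harpending's raggedness r compared by the ≥ convention with add-one
correction, p = (b+1)/(reps+1), avoiding p = 0 artifacts. The mutation
rate μ needed to convert τ to years is a user input and never assumed.

## AMOVA, SAMOVA and spatial analyses

All variance partitions are haploid and operate on a per-individual
squared-distance matrix: haplotype identity (0/1) for frequency-based
F-statistics, and pairwise nucleotide differences — the squared Euclidean
distance between sequences — for the Φ-statistics. Sums of squares follow
the standard molecular-variance construction with unequal-sample-size
coefficients; each statistic has its own permutation scheme (individuals
among all populations for F_ST, individuals among populations within groups
for F_SC, whole populations among groups for F_CT). When every group holds
exactly one population the within-group level drops out and F_SC is
undefined rather than fabricated.

SAMOVA searches the grouping of populations that maximises F_CT with
simulated annealing: random valid start, single-population moves that never
empty a group, Metropolis acceptance, and geometric cooling (T₀ = 0.1 on
the F_CT scale, factor 0.999 per iteration — the cooling schedule is not
fixed by the method's description and these values give stable acceptance
rates; both are exposed as arguments). Because the F_CT objective only
needs population-level pair sums, proposals are evaluated in O(P²), and the
search is verified against exhaustive enumeration for up to 8 populations.
Proposals are not geographically constrained, matching the unconstrained
variant of the method.

Geographic distances are haversine great circles on a 6371 km sphere.
Isolation by distance is tested with a one-tailed Mantel permutation test
on F_ST/(1−F_ST). The genetic landscape surface builds a Delaunay
triangulation over the site coordinates (brute-force circumcircle test —
adequate for tens of sites; collinear layouts fall back to the complete
graph), places each pairwise genetic distance at its edge midpoint, and
interpolates inverse-distance-weighted heights over a uniform grid
(default 80×80, α = 1) after an equirectangular planar projection about
the mean latitude — an approximation appropriate at the regional scale of
a survey like this one. IDW heights are convex combinations, so the
surface is always bounded by the input distances.

## The parsimony network and origin counting

The network is built on the informative sites: intron columns with
minor-allele frequency above 10 % across all chromosomes, plus the codon's
variable positions as designated sites. Distinct selected-site states are
nodes; candidate edges are pairs within the two-step connection limit, and
edges are added level by level, skipping any pair already connected at
equal or smaller path cost — so all co-minimal alternative connections are
retained (the tie-break the original software used is undocumented, and
keeping every co-minimal edge reports the full set of equally parsimonious
connections). The 0.95 connection probability of the original procedure is
carried as metadata; the two-step limit itself is taken as given rather
than recomputed. Root probability within a component is proportional to
haplotype frequency, the usual frequency–age surrogate, and the direction
of change on an edge runs away from the higher-root-probability node.

An origin event is an edge whose endpoints differ at a codon position such
that the allele class changes from wild type to a resistant class, or
between two resistant classes along the inferred direction (so a cysteine
codon reached through a phenylalanine intermediate counts as a further,
separate origin). Synonymous codon changes within a class are not origins.
Components with resistant members but no wild type contribute one event per
class founder, making all reported counts lower bounds.

## The synthetic-data generator

The generator is the package's study-condition model, not a tuning knob.
Time is scaled in units of 2N generations per deme with mutation rate
θ/2 per lineage, so an equilibrium pair differs at Poisson(θt) sites; a
sudden expansion of mutational age τ is a coalescence-rate step at scaled
time τ/θ₁, which places the mismatch mode near τ. Demes exchange lineages
as an n-island model with an arbitrary backwards migration-rate matrix, and
all demes merge into one panmictic ancestral population at a configurable
divergence time (which also makes zero-migration scenarios well-defined).
Mutations follow the infinite-sites model and are confined to the intron
columns; the focal codon is written as wild-type TTG. The selective sweep
is phenomenological: the analyses consume the *signature* of a sweep
(near-fixed resistant codons on few intron backgrounds, reduced linked
diversity), so the overlay writes resistant codons onto the most frequent
backgrounds and resamples the deme to the target frequency, rather than
simulating selection forward in time.

The survey configuration fixes the defaults to the surveyed
conditions: the 15 published collection sites with their degree-minute
coordinates and per-site chromosome counts (546 in all, converted to
decimal degrees as deg + min/60 for great-circle distances); three regions
(southwest/south/central); sudden expansion (τ = 6, θ₀/θ₁ = 0.02) in every
deme except the two Yunnan sites, which stay constant-size; a sweep
driving L1014F to frequency 0.95 on two intron backgrounds in the five
central demes; θ = 0.004 per intron site (θ ≈ 3.9 for the locus, giving
southern-deme diversity on the observed scale); within-region migration 5,
a south–central corridor of 0.1, and a 0.01 trickle into the southwest.
The between-region rates were set so that the among-region variance
component is of the printed magnitude for this system (F_CT ≈ 0.2–0.4 per
realisation) and robustly detectable from a single non-recombining locus —
single-locus genealogies have large evolutionary variance, which is the
main feature of real data this generator deliberately shares. What the
generator does not emulate: recombination within the fragment, sequencing
error, statistical phasing uncertainty, and explicit selection dynamics;
passing tests therefore demonstrate correctness of the estimators on data
satisfying the model assumptions, not robustness to those complications.

A separate deterministic construction, `synthetic_deposited_panel()`,
stands in for the deposited reference panel of 85 haplotypes, which is not
redistributed with the package. It is built so that its design truth
mirrors the documented summary structure (1285 bp; 71 polymorphic sites of
which 65 intronic; six informative intron sites at the published positions;
18 six-site haplotypes; resistant codons arising on seven distinct
backgrounds), and the tests verify that the full pipeline *recovers that
constructed truth* — a machinery check, not a validation against the
deposited sequences themselves.

## Problem sizes and numerical choices

The shipped tests run the oracle-equivalence suites at 200 randomized
instances each; null calibration on 2000 neutral datasets (n = 30, θ = 5)
against 600-replicate fixed-S nulls shared across datasets with equal
(n, S) — statistically equivalent to per-dataset nulls and far cheaper;
Mantel calibration on 500 replicates; expansion recovery on 200 simulated
expansions (n = 20, τ = 6); and the end-to-end pattern check on 20 seeded
survey-mimic runs. Permutation defaults are 1000 (pairwise tests drop to
100–200 inside the heavier loops). All stochastic stages take explicit
seeds, and the pipeline derives per-stage seeds from one master seed, so
whole report bundles are reproducible byte for byte.

Known limitations: the network's root-probability direction rule can
misorient edges between similarly frequent haplotypes; Nei distances for
populations sharing no haplotype are capped (default 10) and flagged
rather than infinite; the Delaunay construction assumes general position;
and the landscape projection distorts at continental scales.
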