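---
title: "Integrative biosystematics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative biosystematics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biosystax)
```

Taxonomic revisions of closely related plant taxa — the *Datura* species
complexes are the motivating case — increasingly rest on several independent
evidence streams at once: dominant DNA fingerprints (ISSR, SCoT, CDDP),
karyotype morphometrics, metabolite chemotaxonomy, and the expression of
biosynthetic genes. biosystax implements each stream's standard statistics and
a transparent way to fuse them into an overall similarity and a rank
suggestion. This vignette documents the models, the numerical conventions, and
the choices made where the design was genuinely open.

## Dominant-marker statistics

Dominant fingerprinting systems score each locus as band present/absent; a
heterozygote is indistinguishable from the band-carrying homozygote, so all
statistics work on the band frequency $p$ (fraction of genotypes showing the
band), never on allele frequencies. The conventions:

* **Monomorphic** = present in every genotype; everything else is
  polymorphic; polymorphism % = 100 · polymorphic / total.
* **Unique band** = present in exactly one genotype (a positive diagnostic
  marker). Bands *absent* in exactly one genotype are reported separately as
  `negative_unique` and excluded from `unique_bands`: the two kinds of
  diagnostic band answer different questions and folding them together would
  inflate the count.
* **PIC** for a dominant biallelic locus is $1 - p^2 - (1-p)^2 = 2p(1-p)$,
  bounded by 0.5 at $p = 1/2$. This is the standard presence/absence
  convention and reproduces the 0–0.5 range reported for such markers.
* **Similarity**: simple matching $(a+d)/n$ counts shared absences, Dice
  $2a/(2a+b+c)$ and Jaccard $a/(a+b+c)$ do not. Dice ≥ Jaccard always. A pair
  with no bands at all (a+b+c = 0) is indistinguishable on the data; Dice and
  Jaccard return 1 there, with a warning, rather than an arbitrary 0 or NaN.

Band frequencies are computed over genotypes because each genotype contributes
one consensus banding profile, not a population sample.

## Distance-based trees and concordance

All trees are `ape::phylo` objects. Neighbor joining follows the classical
Saitou–Nei agglomeration and is exact on additive distances — the package's
property tests verify recovery of random planted trees up to 8 tips from
their path-length matrices. Negative estimated branch lengths, which arise on
non-additive input, are clamped to zero with a warning that reports the raw
minimum (the standard practice; the magnitude tells you how non-additive the
input was). UPGMA places each merge at half the average inter-cluster
distance, so the cophenetic matrix of a tree built from an ultrametric input
reproduces that input exactly. Ties between merge candidates are resolved by
the deterministic agglomeration order of `stats::hclust`; any fixed rule
would do, determinism across platforms is the point.

Binary band data carry no substitution process, so distances enter the tree
builders as $1 - s$ with $s$ a binary similarity. A Jukes–Cantor transform is
available (`jukes_cantor()`) for users holding genuine sequence p-distances,
but it is never applied implicitly: applying a nucleotide substitution
correction to band mismatch fractions would assert a model the data do not
support.

Concordance between evidence systems uses two standard statistics. The
cophenetic correlation is the Pearson correlation between a distance matrix's
upper triangle and the tree-implied distances. The Mantel test permutes rows
and columns of one matrix simultaneously; the p-value is one-sided (positive
association, the direction of interest for concordant marker systems) with
the add-one convention $p = (1 + \#\{r_\pi \ge r\})/(n_{perm}+1)$, which can
never report $p = 0$. Under the null the p-values are uniform; the
acceptance suite checks the 5% rejection rate over 1000 replicate pairs of
independent matrices at `n_perm = 999`.

## Karyotype morphometrics

For each chromosome with short arm $s$ and long arm $l$ (µm): total length
$c = s + l$, relative length $RL = 100\,c/\sum c$ (summing to 100 within each
cell), and centromeric index $ci = 100\,s/c \in [0, 50]$. The Levan position
classes use the classical boundaries 12.5, 25.0, 37.5, 50.0. Since adjacent
classes share these boundary values in the verbal definitions, the package
fixes a strict partition: $ci = 0$ is telocentric, then left-open/right-closed
intervals with the printed boundaries as class *maxima* — (0, 12.5]
acrocentric, (12.5, 25] subtelocentric, (25, 37.5] submetacentric, (37.5, 50]
metacentric. Equal arms can evaluate to $50 + \varepsilon$ in floating point;
a 1e-9 tolerance clamp keeps such chromosomes metacentric.

Asymmetry follows Romero Zarco: intrachromosomal $A_1 = 1 - \overline{s/l}$
(0 for a perfectly metacentric complement, 1 for all-telocentric) and
interchromosomal $A_2 = \mathrm{sd}(c)/\mathrm{mean}(c)$, Pearson's
coefficient of variation. `asymmetry_indices()` computes these on whatever
chromosome records it is given; `karyotype_summary()` follows the classical
reading and evaluates $A_1$ on homolog-pair mean arms while taking $A_2$ over
individual chromosomes. Homologs are paired by sorting the cell's chromosomes
by decreasing total length and chunking consecutive pairs — the implicit
behavior of metaphase karyotyping software; an odd (aneuploid) count leaves
the smallest chromosome unpaired with a warning. Ploidy labels express the
modal count as $kx + r$ ("2n=2x+3=27"); count-mode ties across cells break
toward the smaller count, the conservative reading.

## Calibration chemistry

Total phenolics, flavonoids and alkaloids assays all reduce to a linear
standard curve $A = mC + b$ fitted by ordinary least squares and inverted as
$C = (A - b)/m$, scaled by a dilution factor and normalized per sample mass.
Absorbances below the intercept are clamped to 0 with a warning (a negative
equivalent concentration is chemically meaningless, and silently returning it
propagates nonsense downstream); absorbances outside the calibrated range are
flagged as extrapolations. Two-point curves are accepted but flagged because
$r = 1$ by construction carries no information about linearity.

## Chemometrics

PCA defaults to autoscaling (column mean-centering plus unit-variance
scaling), the convention of chemometric software for concentration tables
whose columns live on different scales; both steps are switchable, and UV
spectra are better analysed with `scale. = FALSE` since all wavelengths share
one unit. Constant columns under scaling are an error naming the column.
Variance explained is $100\,\sigma_k^2/\sum\sigma^2$ and always sums to 100.

HCA routes Euclidean row distances (quantitative profiles) or 1 − Dice
(presence/absence patterns) through the same UPGMA implementation the tree
module uses. Thresholded metabolite profiles (`presence_absence()`) return a
genuine `band_matrix`, so the *entire* marker/tree machinery — Dice
dendrograms of alkaloid patterns included — applies unchanged to
chemotaxonomic data.

## Relative expression

Gene expression uses the Livak $2^{-\Delta\Delta Ct}$ estimator with a single
reference gene (actin by default) and a configurable calibrator genotype.
Amplification efficiency defaults to 2.0 (100%) and is exposed as a
parameter; when no standard-curve efficiencies are reported, 100% is the
universal default for SYBR single-reference designs. Fold changes are
strictly positive, the calibrator column is exactly 1, and the estimator is
invariant to adding a constant to every Ct. Association with metabolite
accumulation uses Spearman rank correlation; for up to 8 genotypes the
permutation p-value is exact (all $n!$ permutations, two-sided on $|\rho|$,
midranks for ties, identity included so $p > 0$), avoiding large-sample
approximations that are meaningless at $n = 6$.

## Multi-evidence consensus

Each evidence distance is standardized by dividing its off-diagonal by its
maximum (scale-invariant, keeps zero structure), then fused as a weighted
mean — simple and auditable, in contrast to consensus-tree methods whose
result is hard to trace back to the inputs. Weights default to equal. The
consensus feeds UPGMA for the combined dendrogram, and similarity percentages
are $100(1-d)$. The rank rule mapping similarity bands to infraspecific
ranks (defaults: ≥ 80% form, ≥ 55% subspecies, below that distinct species)
is *pure configuration* mirroring how such similarity bands are argued in
revisions; every suggestion echoes the rule that produced it and must never
be read as a nomenclatural act.

## The synthetic cohort

`simulate_cohort()` plants a 3+1+2 structure — three conspecific forms, one
intermediate taxon, two outgroup-like taxa — and generates every input the
pipeline consumes:

* **Bands** come from a cluster-profile model. Each cluster carries a latent
  reference pattern; genotypes copy their own cluster's reference with
  probability $\theta_w$ (else another cluster's), and references of distinct
  clusters agree per locus with probability $\theta_b$. With
  $w = \theta_w^2 + (1-\theta_w)^2$, the expected simple-matching similarity
  at a polymorphic locus is $w + 2\theta_w(1-\theta_w)\theta_b$ within a
  cluster and $w\,\theta_b + 2\theta_w(1-\theta_w)$ between clusters whose
  references agree with probability $\theta_b$ — closed forms the recovery
  tests verify by independent Monte-Carlo simulation. This model, rather than
  independent per-genotype Bernoulli draws, is what makes the expected
  similarity controllable. Defaults: 3 systems × 6 primers × 18 loci (108
  bands per system, matching the scale such marker screens report), 20%
  monomorphic, $\theta_w = 0.95$, $\theta_b = 0.55$.
* **Metabolites**: 31 compounds (the scale of a tropane-alkaloid GC-MS
  screen) with a 13-compound shared core and 6 cluster-specific compounds per
  cluster; presence is Bernoulli per genotype and abundances are log-normal
  (positive and right-skewed, like peak areas).
* **Karyotypes**: diploid 2n = 2x = 24 cells (8 per genotype, mean length
  4 µm) with cluster-specific arm-ratio means, so the karyotype distance
  carries signal through $A_1$.
* **Expression**: six tropane-pathway genes (PMT, TR1, TR2, H6H, HDH, AT4)
  whose true fold gradients follow the orderings reported for such pathways;
  Ct tables are generated by inverting the Livak model with replicate noise
  (sd 0.2 cycles).
* **UV spectra**: two Gaussian bands (Band II near 265 nm, Band I near
  340 nm) on the 250–400 nm grid, amplitudes separating the stramonium-like
  and outgroup-like groups.

What the generator deliberately does **not** emulate: electrophoresis
artifacts (smears, co-migrating bands), chromatographic retention shifts,
satellite chromosomes, or morphological characters. Passing tests on this
cohort therefore demonstrate that the *statistical machinery* recovers
planted structure under the stated noise model — not that any particular real
dataset will behave as cleanly.

## Problem sizes and numerical conventions

The package's own test battery runs at desk scale: NJ exactness on random
trees up to 8 tips; Mantel null calibration with 1000 replicate pairs at 999
permutations; 10^5 random chromosomes for the RL and Levan invariants; 1000
seeds for calibration-slope recovery; 100 seeds for planted-structure
recovery (the observed recovery rate is at ceiling with the default
concordances). Degenerate inputs error early and loudly: zero-variance
distance triangles (cophenetic and Mantel correlations undefined), constant
off-diagonals in standardization, constant columns under autoscaling,
all-zero band loci. Seeds are explicit arguments everywhere
(`withr::with_seed`), never global state, so every generator is a pure
function of its spec.

## Limitations

The consensus is one defensible fusion, not a reconstruction of any
particular published synthesis; published overall-similarity figures mix
evidence in ways rarely specified exactly. The rank thresholds are
heuristics. Dominant-marker similarity treats genotypes as units — no
population-level allele-frequency estimation (and hence no AMOVA) is
attempted. Bootstrap support, likelihood and Bayesian tree inference are out
of scope; the trees here summarize distance structure.
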