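---
title: "Quantifying leaf-scale genetic heterogeneity from clone libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leaf-scale genetic heterogeneity from clone libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighclone)
```

## The measurement problem

Somatic mutations accumulate during plant growth, so the cells of a single
leaf are not genetically uniform. One practical way to measure this
*intraorganismal genetic heterogeneity* (IGH) at a locus is a clone
library: a fragment is PCR-amplified from leaf DNA or cDNA, the product is
cloned so that every plasmid carries a single template molecule, and ~15
independent clones per plant are Sanger-sequenced and aligned. Variation
*among the clones of one plant* then reflects heterogeneity among the
template molecules of that leaf (plus PCR/cloning artifacts), and
comparing materials — e.g. a wild population against a cultivar, three
biological replicate plants each — asks whether one genotype maintains a
tighter leaf-scale sequence pool.

`ighclone` implements this analysis end to end: per-plant polymorphic-site
calling, the classical diversity estimators, a cross-plant classification
of heterogeneous sites within a material, substitution spectra, and
protein-level haplotype collapse for coding fragments. Because clone
libraries of this kind are rarely deposited, the package also ships a
seeded simulator that generates clone sets with *known* planted structure;
every stage is validated against that ground truth.

The unit of analysis is the **clone set**: all aligned clone sequences
from one plant at one locus. Sequences are normalized on input (uppercase,
`U` to `T`); `-` is the gap state and every IUPAC ambiguity code,
including `N`, collapses to a single missing state. The two non-base
states are deliberately pooled: downstream rules exclude "gaps or missing
bases" as one class, so distinguishing `R` from `N` buys nothing and
invites inconsistent handling.

## Site calling

A column is **polymorphic** within a plant when at least two *distinct
valid nucleotides* (A/C/G/T) are observed among its clones, each supported
by at least `min_minor_count` clones. The default is
`min_minor_count = 1`: in this study design artifact control is
procedural (high-fidelity polymerase, replicate plants, and the
requirement of concordant trends across loci), not a frequency filter, so
a singleton allele still counts. The threshold is exposed because a user
with noisier chemistry may reasonably set it to 2; every function that
calls sites takes it as an argument.

Gap and missing states are never valid nucleotides. A column with 14 `A`
and one gap is monomorphic; a column with `A`, `G` and an `N` is
polymorphic (two valid bases among the called clones) but flagged as not
fully called. Columns where gaps face bases contribute **indel events**
rather than substitution polymorphism: a maximal run of consecutive gap
columns carried by an identical clone set is counted as one event,
because a single multi-column deletion is one mutational event, not five.
Overlapping deletions with different carriers split the run — the
single-event rule is about one deletion scored once, not about merging
unrelated deletions that happen to touch.

## Diversity estimators

For one clone set with $n$ clones:

* **S** — the number of polymorphic columns (indel events excluded).
* **Haplotypes** — equivalence classes of exact sequence identity over
  the *full* alignment, gap and missing characters included. Identity is
  unqualified on purpose: two clones differing only by an `N` sample
  different molecules as far as we can tell, and merging them would
  silently overstate haplotype frequencies. $h$ is the class count.
* **Haplotype diversity**
  $H_d = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$, the small-sample
  corrected probability that two random clones are different haplotypes.
* **Nucleotide diversity**
  $\pi = \frac{2}{n(n-1)} \sum_{i<j} \frac{d_{ij}}{L}$, the mean
  proportion of differing bases per callable column over all clone pairs.
  The default gap handling is *complete deletion* (columns containing any
  gap or missing base are dropped for everyone, $L$ = remaining columns),
  matching the default behaviour of the standard polymorphism software
  this field uses; *pairwise deletion* (each pair normalized by its own
  callable columns, pair proportions averaged) is available by flag.

Material-level summaries report mean and **sample** standard deviation
(denominator $n-1$) across the replicate plants — with three replicates
the population SD would understate the error bars — and material
contrasts use the two-tailed pooled-variance Student's *t* with
$df = n_a + n_b - 2$. Zero pooled variance is handled explicitly (equal
means: $t=0, p=1$; unequal: $p \approx 0$ with a degeneracy flag) because
replicate counts of 3 make degenerate samples a real occurrence, and
`stats::t.test` does not expose the distinction; the standard
implementation serves as a cross-check in the test suite instead. A
multi-locus **concordance check** finally asks whether the sign of the
material difference (in S or $\pi$) is the same, and nonzero, at every
locus — the design's guard against single-locus artifacts. A zero
difference counts as non-concordant: "no difference" at one locus is not
evidence for a trend.

## Cross-plant classification

Within one material, the three replicate plants are compared on a
**common callable mask**: a column qualifies only if *every clone of every
plant* carries a valid base there. This strict rule is why the callable
count can differ slightly between materials at the same locus — one gap
in one clone of one plant removes the column for that material only.

Polymorphic columns inside the mask are partitioned by the number of
plants in which they are polymorphic: **shared by all 3**, **shared by
exactly 2**, or **plant-specific**. The reported total is the union of
per-plant polymorphic columns *within the mask*, which makes the identity

$$\text{total} = \text{shared}_3 + \text{shared}_2 + \text{specific}$$

hold structurally for every input; the table writer re-verifies it before
emitting anything and aborts on violation rather than printing an
inconsistent row. No attempt is made to label sites as somatic mutation
versus inherent heterozygosity versus homoeologous divergence — with
clone counts of 15 per plant and no parental genotypes that separation is
not identifiable, and the output is deliberately described as
heterogeneous sites, nothing stronger.

## Substitution spectra and Ts/Tv

At each polymorphic column the most frequent valid base is taken as the
major allele; every other observed base contributes one typed
substitution, directed major → minor. There is no outgroup polarization —
direction means "away from the within-plant consensus", nothing
ancestral. Counting is per allele at a site, not per carrying clone, so a
site's weight does not grow with its minor-allele frequency. Transitions
are the A↔G and C↔T classes; the Ts/Tv ratio is undefined (reported `NA`)
when no transversions were typed, rather than clamped to a number.

One design point deserves a note. A frequency tie for the major allele
must be broken somehow, and an alphabetical tie-break — the obvious
choice — silently breaks a symmetry the spectrum should have:
reverse-complementing the entire clone set must leave Ts/Tv unchanged,
but complementation pairs A with T and C with G, and no ordering of the
four bases survives that involution. At a tied multiallelic column an
alphabetical rule can therefore type an A↔C pair on one strand and a G↔C
pair on the other. `ighclone` instead breaks ties in favour of the base
carried by the earliest clone in input order, which commutes with
complementation and makes strand invariance exact for all inputs. The
price — clone order matters at exactly tied columns — is small: with an
odd clone count a two-allele tie for the majority is impossible, and the
case essentially never arises outside adversarial inputs.

## Coding fragments: protein haplotype collapse

For a coding fragment (the motivating case is a 240-bp BRCT-domain
fragment, CDS positions 171–411 under the half-open convention where the
length is end − start), nucleotide haplotypes are translated with the
standard code and merged when their amino-acid sequences coincide.
Labels `h1..hk` are assigned by descending clone count with
lexicographic tie-break, so labelling is stable across runs. Translation
drops a trailing partial codon, translates internal stops as `*` with a
flag, and refuses sequences whose gap runs are not multiples of three —
an out-of-frame deletion cannot be translated meaningfully, and guessing
would misreport every downstream residue. In-frame deletion haplotypes
are translated after gap stripping. Variant amino-acid positions are
reported 1-based *within the fragment*; mapping to full-protein numbering
requires the fragment's position in the full CDS and is left to the user.

## The simulator

`simulate_material()` generates the data structure the analysis assumes:
a uniform-random reference sequence (configurable GC weight), three
plants of `n_clones = 15` clones, planted biallelic sites with a
specified sharing structure (shared-by-3 planted in all plants,
shared-by-2 in a designated pair, specific in one plant), each with a
specified minor-clone count, optional multi-column deletion events, and
finally independent per-base uniform miscalls at rate $\varepsilon$
standing in for sporadic PCR/cloning artifacts (no polymerase-specific
bias is modelled; the study gives no basis for one). Injected errors are
recorded, so truth remains exact even in noisy runs.

Determinism is strict: a master seed derives one substream for the
reference and one per plant (`derive_seed(master, plant)`), so the same
`(config, seed)` is byte-identical and adding a plant never perturbs the
others. `truth_summary()` returns the expected outputs: per-plant S, the
analytic diversity
$\pi = \sum_{\text{sites}} \frac{2k(n-k)}{n(n-1)} / L$ for planted
minor-clone count $k$, and the expected category counts.

Minor-clone counts in the shipped random fixtures are drawn uniformly on
$[1, \lfloor n/2 \rfloor]$ — the study publishes no per-site
minor-allele frequencies, so this is an explicit assumption, not an
estimate. The fixture families mirror the published study's scales: a
sparse 1129-column locus (category structures 1/0/3 and 20/1/5), a dense
647-column locus (35/27/4 and 53/83/31), and a deterministic 240-bp
coding fixture whose 60 clones collapse to six protein haplotypes with
variant fragment positions {15, 30, 34, 55, 62, 75}.

What the simulator does *not* emulate — and what passing recovery tests
therefore do not establish about real data: chromatogram-level base
quality, PCR recombination between templates, template-resampling among
clones (clones are independent draws here), homoeologous co-amplification
in polyploids, and any spatial or lineage structure within the leaf.
Recovery at $\varepsilon = 0$ shows the estimators are exact on clean
input; it does not show that a real clone library's artifacts are
ignorable.

## Numerical and testing choices

* All user-facing coordinates are 1-based; interval lengths are
  half-open (end − start).
* Outputs are deterministically ordered (columns ascending, carrier sets
  sorted by clone id, haplotypes by descending count then sequence) and
  written locale-independently with `.` as decimal separator.
* π is validated against a naive all-pairs oracle to 1e−12 on 500 random
  clone sets (n ≤ 10, L ≤ 50) and against `ape`'s raw pairwise
  distances; planted-truth recovery runs 100 noise-free simulations,
  including the published-scale fixture structures; error-model
  calibration uses 200 seeded clone sets of 15 × 1000 bases at
  $\varepsilon = 10^{-3}$. These sizes keep the full suite under a
  minute on a laptop while leaving each check statistically meaningful.
* The error-calibration check is two-part: the pooled injected-error
  count must fall inside the central 99% interval of its pooled binomial
  law, and at least 97% of per-set counts must fall inside the per-set
  central 99% interval. Requiring *every* draw inside a 99% interval
  would reject a correctly calibrated simulator most of the time.

## Limitations

The package consumes pre-aligned clone sets; it does not build
alignments, read chromatograms, or re-inspect questionable peaks. The
cross-plant classifier requires exactly three plants per material, the
published design; the per-site assignment table generalizes, but the
three-category output is only emitted for triples. Ts/Tv direction is
consensus-relative, and fragment amino-acid numbering is
fragment-relative. None of the statistics distinguish somatic mutation
from fixed heterozygosity or homoeologous contamination — interpret S
and π as leaf-scale heterogeneity, not as a mutation rate.
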