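---
title: "Detecting and correcting sample mix-ups in expression genetic studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and correcting sample mix-ups in expression genetic studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In an expression genetic (eQTL) study on an experimental cross, three
kinds of material carry a sample's identity: the DNA that is genotyped,
the mRNA that is hybridized to expression arrays (often in several
tissues), and the written records (sex, phenotypes, plate positions).
Any of these can be mislabeled — a pipetting slip displaces a column of
DNA wells by one position, two tubes are swapped, an array is
hybridized twice. Such errors silently dilute every downstream
genotype–phenotype association.

The remedy exploited here is that genotype and expression are not
independent: a transcript with a strong **local eQTL** is, in effect, a
genotype assay. With enough such transcripts, the expression profile of
a sample predicts its genotypes well enough to check — and to restore —
its identity. Similarly, tissues share expression signal, so arrays of
the same individual in two tissues are recognizably correlated.

`crossalign` implements this program for an F2 intercross between two
inbred strains (genotypes `BB`, `BR`, `RR` with expected frequencies
1/4, 1/2, 1/4), together with a synthetic-study generator that plants
known errors so that every stage can be verified without any external
data.

## Aligning expression arrays across tissues

For each pair of tissues we compute, probe by probe, the correlation of
expression across samples assayed in both tissues, and keep probes with
correlation above 0.75 (most probes are uninformative: unexpressed
genes correlate near zero across tissues). Across this probe subset we
then correlate *sample i in tissue s* with *sample j in tissue t*,
giving a similarity matrix per tissue pair; the per-tissue summary
`r_ijs` is the median over the pairs involving tissue *s*.

A sample mislabeled in tissue *s* shows a *small self-similarity*
(diagonal entry) and, if its true array is present under another label,
a *large off-diagonal* entry identifying it. We relabel only when the
row maximum is high (default 0.8) and clears the second-highest value
by a margin (default 0.1); an anomalous row without a confident match
is `unfixable`, and a row with no self-similarity at all (sample
assayed in only one tissue) is `unverifiable` unless a confident match
exists.

**Fault localization with few tissues.** With the six tissues of a
large study, the median over five pairs is robust: one faulty tissue
cannot drag a correct sample's summary down. With only three tissues —
this package's default simulation — the median over two pairs is their
mean, so a swap in tissue 3 would half-depress the self-similarity of
the same samples in tissues 1 and 2. `align_expression()` therefore
declares a sample mislabeled in tissue *t* only when its
self-similarity is below threshold in **every** available pair
involving *t*; a row whose anomaly is confined to pairs with one other
tissue is exonerated, because the fault lies there. The replacement
label is still inferred from the median row. With two tissues a swap
is intrinsically ambiguous (each tissue implicates the other); three or
more tissues are needed for localization, which is why the default
simulation uses three.

Within-tissue duplicates (the same array under two labels) are found by
between-sample correlations inside a tissue over the selected probes
(threshold 0.9 — true duplicates are nearly perfectly correlated).
Corrections apply relabelings as permutations (swaps and k-cycles),
combine duplicates by per-probe averaging, and drop unfixable rows.

## Aligning DNA to mRNA via eQTL classifiers

Genotype side. Multipoint genotype probabilities are computed on a
grid of markers plus pseudomarkers (maximum spacing 0.5 cM) by a hidden
Markov model for the F2: chromosome-start prior (1/4, 1/2, 1/4),
transition matrices from the recombination fraction of each
adjacent-gap interval under the Carter–Falconer map function (strong
positive interference), and a symmetric genotyping-error emission
model with rate 0.2% (the error probability split evenly between the
two wrong codominant calls — the simplest symmetric choice). The
forward–backward recursions are rescaled at every position, so
arbitrarily long chromosomes do not underflow. The X chromosome is
excluded: hemizygous males cannot be distinguished from homozygotes,
and all eQTL used are autosomal. The *observed eQTL genotype* at a
position is the state of maximal posterior probability provided it
exceeds 0.99, otherwise missing.

Expression side. For every autosomal probe with known location we
compute a single-position Haley–Knott regression LOD at the nearest
grid position: the phenotype is regressed on the genotype
probabilities (columns `p_BR`, `p_RR` against a `BB` baseline — any
full-rank recoding gives the identical fit), optionally with sex as an
interactive covariate, and
`LOD = (n/2) log10(RSS0/RSS1)`. Probes with LOD > 100 — effectively
error-free genotype surrogates — are grouped by grid position into
eQTL units of one to three probes.

For each unit, a k-nearest-neighbour classifier (k = 40, Euclidean
distance in the 1–3-dimensional probe space) predicts the eQTL
genotype of any sample from expression alone; a prediction is made
only when strictly more than 80% of the neighbours agree, otherwise
the inferred genotype is missing (boundary points abstain). When a
sample's own record is in the training set, it is excluded from its
neighbour set — otherwise a mislabeled sample would partly predict
itself. After a first pass, samples whose own observed and inferred
genotypes match in under 70% of eQTL are removed from the training
data and the classifiers refitted once (two passes in total; the
filter removes mislabeled training records, which sharpens the
classifiers).

The similarity between DNA sample *i* and mRNA sample *j* is the
proportion of matches between *i*'s observed and *j*'s inferred eQTL
genotypes, pooled across all eQTL and all tissues (total matches over
total comparisons, not a mean of per-tissue proportions). For a
correct sample this is near 1; for a mismatched pair it concentrates
near the chance rate `sum(f_g^2) = 0.375` at F2 frequencies. The same
self/max/second decision rule as above (defaults 0.8 / 0.8 / 0.1 on
the match-proportion scale) yields the DNA diagnosis; two DNA rows
whose best match is the same mRNA sample — one of them that sample's
own row — are duplicates.

Expression-side corrections are applied **before** genotype alignment:
the classifiers should be trained against arrays whose labels are
already internally consistent.

## Genotype quality control and plate geometry

- **Duplicate DNA**: unordered pairs with more than 98% identical
  calls across jointly typed markers (pairs with under 50 shared
  markers are uninformative and skipped).
- **Sex versus X chromosome**: in this cross design (strain R
  grandmother, strain B grandfather), F2 females are `RR` or `BR` on
  the X and males are hemizygous (stored as homozygous). A female with
  `BB` calls or a male with `BR` calls on the X is discordant; one
  discordant call is reported as a probable genotyping error, two or
  more flag the sample. The pipeline runs this check *after* DNA
  correction, since mislabeled DNA itself produces discordances that
  correction resolves; what remains are genuine sex-record errors.
- **Per-sample metrics**: missing-call rate, proportion of homozygous
  autosomal calls, and an inferred crossover count — the sum over
  adjacent grid positions of the allele-dose difference along the
  maximal-posterior genotype path (`BB` to `RR` counts two). Cutoffs
  are robust (median + 5 MAD) rather than fixed.
- **Plate geometry**: every inferred DNA relabeling is mapped to the
  signed offset, in plate filling order (column-major by default,
  matching single-channel pipetting down the columns), between the
  well where the true sample belonged and the well where it was
  found. Offsets of 1 and 2 are the classic off-by-one/off-by-two
  pipetting signatures; runs of consecutive equal offsets are reported
  as single events with their length.

## The synthetic study generator

`simulate_study()` generates a complete study from one seed:

- **Cross**: 300 F2 mice; five autosomes of 100, 90, 80, 70 and 60 cM
  with 20 equally spaced markers each, plus an X chromosome (50 cM, 10
  markers). Gametes are first-order Markov chains over the markers
  with switch probability given by the inverse map function of each
  gap — crossover interference enters only through the map function on
  adjacent intervals, which is the resolution at which the HMM sees
  the data anyway. The X follows the cross design (females `RR`/`BR`;
  males hemizygous, stored as homozygous). Genotyping errors at rate
  0.2% and missing calls at 2%.
- **Expression**: three tissues of 1000 probes. Each tissue draws its
  own 60 local-eQTL probes (grouped into units of 1–3 probes at shared
  positions) with model `y = a*dose + d*het + noise`, `a = 1`,
  `d = 0.25`, residual SD 0.25 — a single-position LOD around 140 at
  n = 300, comfortably in the `LOD > 100` selection regime. Keeping the
  eQTL sets tissue-specific matters: pooling match proportions across
  tissues then accumulates distinct loci, which is what gives the
  combined similarity its tight null distribution. 120 probes load on
  per-mouse latent factors shared across tissues (loading 0.75,
  residual SD 0.25, between-tissue correlation 0.9) and drive the
  expression alignment. One X-linked probe is elevated in females and
  one Y-like probe in males. The rest are noise; a few percent carry
  no genomic annotation.
- **Planted errors** (defaults): a DNA plate-shift run of 8 wells at
  offset +1 — the DNA intended for well *i* lands in well *i + 1*, so
  the head well duplicates its upstream neighbour and the tail
  sample's DNA is lost, mirroring how such runs present on real
  plates; one cross-plate DNA swap; per tissue one expression swap; a
  three-way expression cycle in the first tissue; per tissue one
  expression duplicate; and one exchange of recorded sex between a
  male/female pair. Sex-swap victims are chosen among samples whose X
  genotypes make the error detectable (at least two informative X
  calls); an undetectable sex swap (e.g. a male hemizygous R
  throughout the X) would be invisible to any method using these data.
- **Truth ledger**: the exact permutation of every planted error, the
  pre-error genotype and expression matrices, true crossover counts
  (at marker resolution, by the same dose metric the QC uses — strand
  pairs that both recombine in one interval are invisible in genotype
  data by construction), and the overwritten rows of duplicates, so
  that `restore_truth()` reproduces the clean study bitwise.

What the generator deliberately does **not** emulate: array
normalization artifacts and batch effects, partial sample mixtures
(two individuals in one well — such rows can only end up `unfixable`),
segregation distortion, and genotype-informative relatedness structure
(all F2 genotypes are independent draws). Passing tests on simulated
data therefore demonstrate the correctness of the machinery and its
statistical behaviour under the stated model, not robustness to every
artifact of a real laboratory study.

## Numerical and design choices

- Inverse Carter–Falconer by bracketed root finding to 1e-12 (no
  closed form); Haldane and Kosambi inverses in closed form.
- Pseudomarker placement: `ceiling(gap/spacing) - 1` evenly spaced
  points per gap, so no grid gap exceeds the maximum spacing; ties in
  nearest-position lookup break toward the proximal index.
- Rank-deficient Haley–Knott designs (a genotype class absent, a
  collinear covariate) are fitted by pivoting; a perfect alternative
  fit returns `Inf` with a warning, a perfect *null* fit (constant
  phenotype) returns LOD 0.
- Normal-quantile transform uses average ranks for ties.
- 2-LOD support intervals take the contiguous run around the peak with
  `LOD > peak - 2`, extended one grid position outward — a common
  convention where the endpoint rule is otherwise unspecified.
- The k-NN vote is strict (`> 0.8k`); with fewer than k training
  points all are used with the proportional rule and a warning.
- Diagnosis thresholds (expression: 0.75/0.8/0.1 on the correlation
  scale; DNA: 0.8/0.8/0.1 on the match-proportion scale) are exposed
  in `run_config()`; the decision rule, not the numbers, is the
  method's substance, and real studies with different probe panels may
  need different values.
- All randomness flows from the single seed in `sim_config()`;
  identical configuration implies bitwise-identical studies.

## Problem sizes

The packaged default scenario (300 mice, 3 tissues, 1000 probes per
tissue, 110 markers) runs the full pipeline in well under a minute on
one core; the test suite's end-to-end checks (planted scenario, null
scenario, idempotent re-run) and the acceptance script each complete in
a few minutes. These sizes are the package's chosen study conditions
for a fully self-contained demonstration; the algorithms themselves
are vectorized over samples and scale to the dimensions of real
studies (hundreds of samples, tens of thousands of probes, thousands
of markers).

## Known limitations

- With two tissues, expression swaps cannot be localized to a tissue;
  with one, cross-tissue alignment is undefined.
- A DNA sample whose true mRNA was never assayed can at best be
  declared unfixable or unverifiable — its identity is not recoverable
  from these data.
- The DNA diagnosis assumes most samples are correct (the classifiers
  are trained on the labeled data); the 0.7 match filter recovers
  moderate contamination of the training set, but a study where most
  labels are wrong would need an external anchor.
- Sample *mixtures* are flagged at best as unfixable; resolving them
  is out of scope.
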