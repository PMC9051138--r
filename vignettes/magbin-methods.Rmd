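---
title: "How magbin bins metagenomic contigs: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How magbin bins metagenomic contigs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Metagenomic assembly yields contigs from many genomes mixed together.
Binning groups contigs so that each bin approximates one genome (a
metagenome-assembled genome, MAG). Classical unsupervised binners cluster
contigs on two signals: oligonucleotide composition (genomes have
characteristic tetranucleotide usage) and read coverage (contigs from one
genome have correlated depth across samples). `magbin` adds a third,
semi-supervised signal: pairwise constraints that say two contigs must or
cannot belong to the same genome, and a neural embedding trained to respect
them.

## Features

Each contig passing the length filter is represented by:

* **Canonical 4-mer frequencies** `K` (136 dimensions). A k-mer and its
  reverse complement are pooled, because sequencing strand is arbitrary.
  Counts over all overlapping windows (windows containing `N` are skipped,
  deterministically) receive a pseudo-count of `1e-5` and are normalized to
  sum to one, so `K` is a proper composition and every entry is strictly
  positive. The pseudo-count is added to every canonical count before the
  denominator is formed; this keeps the vector an exact distribution, which
  the Euclidean distances downstream implicitly assume.
* **Abundance** `a`: mean per-base read depth per sample, with its per-base
  variance. With `N >= 5` samples the scaled abundances `a_s / s` are
  appended to `K` (input dimension `136 + N`); the scale
  `s = 100 * ceiling(mean(a) / 100)` per sample brings depths to the order
  of magnitude of the frequencies. With fewer samples the network input is
  `K` alone and abundance instead enters the similarity through a
  distributional divergence (below). A sample with zero mean depth maps to
  `s = 100` rather than dividing by zero.

The length filter defaults to 2500 bp, relaxed to 1000 bp when contigs of
1000–2500 bp hold less than 5% of the basepairs among contigs of at least
1000 bp — short contigs are only worth binning when they are a negligible
risk but a non-negligible fraction of the assembly.

## Constraints

* **Must-link** pairs come from splitting every contig above a data-driven
  threshold into two halves (`ceiling(L/2)` and `floor(L/2)` bp): the halves
  provably come from one genome. The threshold is the largest observed
  length such that contigs at or above it still hold 98% of the basepairs,
  floored at 4000 bp so halves remain informative. Fragments are used only
  for training; the intact contig is what gets binned.
* **Cannot-link** pairs come from two sources. Taxonomy: contigs whose
  annotations disagree at species level with both confidence scores above
  0.95, or at genus level with both above 0.80 (strict inequalities, exact
  label comparison). Marker genes: the single-copy marker family observed on
  the most contigs defines seed contigs that must lie in distinct genomes;
  all seed pairs are cannot-link. Both sources are pooled and capped at four
  million pairs by seeded uniform subsampling.

Fragments of split contigs inherit their parent's taxonomy annotation and
participate in cannot-link generation (two halves share labels, so they can
never be declared cannot-link to each other). Marker-based seeding uses
original contigs only; letting fragments carry markers would declare the two
halves of one contig different genomes.

## The siamese embedding

The encoder maps the input `Z` through two hidden layers (default 512, 512)
to a 100-dimensional embedding; a mirror decoder reconstructs `Z`. The first
two layers of each are followed by batch normalization, leaky ReLU and
dropout (rate 0.2); the encoder output is linear. Two weight-shared branches
form the siamese pair. Training minimizes, with Adam (learning rate `1e-3`,
20 epochs):

* the **contrastive loss** over constraint pairs,
  `mean(y d^2 + (1 - y) max(1 - d, 0)^2)` with `d` the Euclidean embedding
  distance and `y = 1` for must-link — same-genome pairs are pulled
  together, different-genome pairs pushed beyond unit margin;
* plus the **reconstruction loss** `mean((Z - Zhat)^2)` over *all* profiled
  contigs (originals and fragments), weighted 1:1, which regularizes the
  embedding toward structure shared by all genomes rather than only the
  constrained ones.

Batch construction: each epoch visits every must-link pair and a fresh
uniform sample of cannot-link pairs up to `pairs_per_epoch` (default 4096),
shuffled into batches of 1024 pairs; alongside each batch one chunk of the
shuffled contig set passes through the autoencoder, so reconstruction sees
every contig once per epoch. The cannot-link set is usually far larger than
the must-link set and highly redundant (all inter-species pairs); resampling
it per epoch covers it across epochs at a fraction of the cost of full
passes, and raising the budget did not change recovery on the bundled
communities. All stochastic pieces — initialization, dropout, batch order,
subsampling — draw from one seeded RNG stream, so training is exactly
reproducible on one device.

The whole network is implemented in R with BLAS matrix products and a few
single-pass C++ kernels for the elementwise layer operations; gradients are
hand-derived and verified against finite differences in the test suite.

Trained models are serializable (`save_embedder()` / `load_embedder()`, a
self-describing container with a format version, the config and the feature
regime) and transferable: a model trained on one or several samples can be
applied unchanged to new samples with the same feature regime
(`run_pipeline(..., model = )`), skipping annotation and training.

## From embeddings to bins

With fewer than five samples, per-contig depth in each sample is modeled as
a normal distribution with the recorded mean and variance, and the
divergence between two contigs is the symmetrized Kullback–Leibler
divergence averaged over samples, clamped to `[1e-6, 1 - 1e-6]`. The clamp
matters at both ends: unclamped, coinciding coverages would make every pair
maximally similar regardless of composition, and extreme divergences add
nothing beyond severing the pair. Variances are floored at
`1e-4 * mean + 1e-6` because simulated or constant-depth contigs can carry
zero variance, which breaks the closed form.

Similarity is `S = 1 - min(d, 1)` with five or more samples (abundance is
already inside the embedding) and `S = 1 - min(d * a, 1)` otherwise, where
`d` is the embedding distance and `a` the clamped divergence. From the
implicit complete graph, each node nominates its `max_edges` (default 200)
strongest edges (ties broken toward the lexicographically smaller neighbor
id); the kept edge set is the union of nominations, zero-weight edges are
dropped. A node can end up with degree above `max_edges` through incoming
nominations. The same construction on the raw feature vectors gives a second
graph, and only edges present in both survive — removing artefacts the
embedding might have introduced. Infomap (two-level map equation, 10 seeded
trials) partitions the result.

**Reclustering.** Bins whose mean single-copy marker copy number exceeds one
likely mix genomes. Such bins are split by weighted k-means on the
concatenation of embedding and scaled abundance features, with contig length
as the sample weight; `k` is the maximum copy number of any single marker in
the bin and the initial centers are the `k` carriers of the most-duplicated
marker (ties by descending length, then id). The k-means runs to a `1e-4`
center-shift tolerance or 300 iterations; empty clusters keep their previous
center. Finally bins below 200 kbp are dissolved and their contigs reported
unbinned.

At the bundled desk scale (a few hundred contigs), `max_edges` exceeds the
node count, so the pruning step keeps every positive-similarity edge and
Infomap is deliberately conservative, returning coarse communities;
reclustering then performs the genome-level separation, and it is the
quality of the embedding (plus marker evidence) that decides whether that
separation succeeds. This division of labor is visible in the bundled
experiments: with reclustering the full pipeline recovers all 20 planted
genomes, the unsupervised ablation only 9–13 under identical settings. On
assemblies with tens of thousands of contigs the pruning is a real
sparsification and Infomap carries more of the work.

**Variants.** `nosemi` skips training and clusters the raw `Z` vectors;
`m` / `c` / `mc` also skip training but inject the constraints directly into
the graph (must-link pairs as weight-1 edges, cannot-link pairs as edge
deletions). These exist to isolate the contribution of the learned
embedding. Because every must-link pair involves split fragments, which are
not clustering nodes, the `m` injection is typically a no-op and `m`
behaves like `nosemi`; `c` and `mc` do delete real edges.

**Modes.** `single` and `coassembly` bin one catalog (they differ only in
how the assembly was produced); `multi` splits a concatenated catalog by the
sample prefix of each contig id, bins each sample separately, and lets every
sample's coverage inform every catalog — bins never span samples.

## The synthetic community

`simulate_community()` plants a ground-truthed community that exercises
every input contract:

* **Genomes** are sampled from genome-specific order-2 Markov chains whose
  transition rows are Dirichlet(6) perturbations of uniform — strong enough
  that 10 kb windows of different genomes are farther apart in 4-mer space
  than windows of the same genome, which is precisely the assumption
  composition-based binning rests on. Defaults: 20 genomes of 300 kb
  (desk-scale on purpose; the suite and the acceptance script re-simulate
  everything at run time).
* **Contigs**: lengths log-normal (median 15 kb, sdlog 0.45, clipped to
  2.5–60 kb), cut sequentially so member lengths sum exactly to the genome
  length.
* **Coverage**: per genome and sample, mean depth is log-normal
  (median 20x, sdlog 1) — independent across samples, giving each genome a
  coverage profile; per contig a log-normal jitter (sdlog 0.15) is applied
  and the variance follows a Poisson-like model `mean +
  (0.1 * mean)^2`.
* **Taxonomy**: distinct species per genome, genera shared in pairs, scores
  uniform on [0.85, 1]; with probability 0.05 (the default noise rate) a
  contig is mislabeled with another genome's species and genus, emulating
  annotation error.
* **Markers**: 40 single-copy families, each on exactly one uniformly
  chosen contig (>= 2500 bp) per genome.
* The **hard preset** adds two strain pairs: genomes copied with 1% random
  substitutions, sharing the parent's species label but drawing independent
  abundances. Composition cannot separate strains at 1% divergence; only
  the marker-guided reclustering over abundance features can, which is what
  the preset is for.

What the generator does **not** emulate: assembly artifacts (chimeras,
repeats collapsed across genomes), uneven within-genome coverage (GC bias,
origin-of-replication gradients), relative-abundance compositionality, or
real taxonomic structure. Passing on these communities demonstrates that the
machinery is correct and that the semi-supervised signal helps when the
planted assumptions hold — not that the tool matches its behavior on real
assemblies.

## Numerical and design choices

* Pseudo-count placement in the k-mer normalization keeps frequencies an
  exact distribution (see above).
* The KL divergence is symmetrized; an undirected graph weight needs a
  symmetric dissimilarity, and the closed form is cheap in both directions.
* The contrastive gradient at coincident embeddings uses a `1e-12` distance
  floor (the must-link branch is exact; the cannot-link branch has no
  gradient at zero distance anyway).
* Ties are broken lexicographically by contig id everywhere (graph
  nomination, bin naming, k-means seeding by length-then-id, plurality
  genome mapping), which together with seeded RNG makes the whole pipeline
  byte-reproducible.
* Degenerate inputs: catalogs with fewer than two contigs after filtering
  return everything unbinned; an empty marker table yields no seed
  constraints (not an error); training refuses to start without at least one
  pair of each kind, since the contrastive loss would be vacuous.
* Evaluation is basepair-weighted: each bin maps to the genome with the
  largest basepair overlap, completeness is overlap over genome size, purity
  overlap over bin size, and tiers follow the usual MAG conventions (high:
  completeness > 90% and contamination < 5%; medium: completeness >= 50%
  and contamination < 10%; low: completeness < 50% and contamination <
  10%). Unbinned contigs never penalize purity.
* Problem sizes in the test suite: unit tests run on 2–6 genome communities
  with reduced network sizes (nothing in the method depends on the hidden
  widths); the acceptance properties run the default 20-genome community
  across five seeds and the hard preset once.

## Known limitations

* The marker-seed rule uses the single most prevalent marker family; the
  established seeding heuristics are more elaborate (median copy counts, EM
  refinement). The rule is isolated behind `scg_seed_cannot_link()`.
* Infomap is run two-level only, single seeded configuration of 10 trials.
* Coverage enters as summary statistics; a BAM-level adapter would need to
  pile up depths itself (`depth_array_to_record()` defines the reduction,
  over 0-based half-open coordinates).
* With exactly 2–4 samples the abundance signal acts only through the
  scalar divergence multiplier, not inside the embedding; the regime switch
  at five samples is a step, not a blend.
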