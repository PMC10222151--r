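---
title: "Oligonucleotide distances for phage lifestyle inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oligonucleotide distances for phage lifestyle inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagesig)
```

## The model

Two biological signals connect a phage genome to the genome of the
bacterium it infects:

1. **Amelioration.** DNA residing long-term in a host converges to the
   host's compositional dialect (codon and oligonucleotide usage). Temperate
   phages, which spend generations integrated as prophages, therefore have
   short-word frequency profiles close to their host's; obligately lytic
   phages drift or arrive with a foreign dialect.
2. **Shared sequence.** A temperate phage's DNA is literally present in
   lysogenized strains of the host clade, and prophage remnants and
   horizontally exchanged genes spread phage-derived words through the host
   population.

`phagesig` quantifies each signal with one distance.

**k4freq** measures amelioration. The genomic signature of genome $X$ at
word length $k$ is the vector of relative frequencies $f_w(X) = X_w /
\sum_w X_w$ over all $4^k$ words $w$; the distance between genomes is the
Euclidean norm $Eu(X,Y) = \sqrt{\sum_w (f_w(X) - f_w(Y))^2}$. Signatures
sum to 1, so $Eu \le \sqrt{2}$, with equality only for disjoint single-word
indicators. $k = 4$ is the default for phage/plasmid work: shorter genomes
(tens of kb) populate the 256-cell tetramer table densely enough for stable
frequencies, which is not true of longer words.

**k14exact (DSW)** measures shared sequence. With totals $S_X \le S_Y$,

$$\mathrm{SIM}(X,Y) = \sum_{w \,:\, Y_w > 0} \frac{X_w}{S_X}, \qquad
  \mathrm{DSW}(X,Y) = 1 - \mathrm{SIM}(X,Y).$$

SIM weights each query word by its occurrence count but tests only
*presence* in the larger genome — it is not a Jaccard index on distinct
words. DSW is 0 when the smaller genome occurs verbatim inside the larger
(an integrated prophage) and 1 when no $k$-word is shared. Choosing $k$
trades specificity against chance: a fixed word hits an i.i.d. uniform
genome of length $L$ with probability $1 - (1 - 4^{-k})^{L - k + 1}$
(`expected_random_match_rate()`). At $k = 14$ and $L = 5\,\mathrm{Mb}$ this
is about 1.8% — below a 2% chance-match budget — while $k = 13$ exceeds 7%;
`choose_k()` automates the scan. Counting at $k = 14$ uses a sparse sorted
representation of integer-encoded words, never a dense $4^{14}$ table.

A lifestyle call is made from the *mean* distance of a phage to all genomes
of its candidate host group: lysogenic when the mean is at or below a
threshold, lytic above. The threshold is learned from labelled phage–host
pairs as the ROC candidate point closest to the ideal classifier $(0,1)$,
with lysogenic as the positive class and "distance $\le t$" as the positive
prediction. The midpoint of the two class means is reported alongside as a
cruder estimator for comparison; the ROC point is canonical.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `k` (k4freq) | 4 | nt | signature word length for phage/plasmid–host distances |
| `k` (k14exact) | 14 | nt | exact-match word length; keeps chance matches < 2% at ~5 Mb |
| `k` (clustering) | 6 | nt | hexamer signatures used to group host genomes |
| `strand_mode` | `forward` | — | count the deposited strand only, or both strands |
| `eps` | 0.50 | projection units | DBSCAN neighbourhood radius |
| `min_pts` | 10 | genomes | DBSCAN minimum neighbourhood size |
| `n_components` | 2 | — | principal components retained before DBSCAN |
| `threshold` | learned | distance | lysogenic/lytic boundary, method-specific |

Strand handling deserves a note: double-stranded genomes have nearly
strand-symmetric signatures, so `forward` (the default) is adequate and the
cheapest reading of the formulas above; `both` is provided for users who
want strand-averaged signatures, and the option makes the choice testable.

## Host clustering

Host genomes are grouped by hexamer signature: the $n \times 4096$
signature matrix is mean-centred (no column scaling — unit-variance scaling
would inflate the noise of rare words across 4096 mostly-small columns),
projected onto the leading two principal components, and clustered with
DBSCAN. Genomes in no dense region are *noise* and are removed before
distance work, since a phage-to-group mean over a compositionally
incoherent group is meaningless.

Determinism: rows are sorted by genome id before clustering, so the
partition cannot depend on input order (DBSCAN border-point assignment is
order-sensitive in general); each component's sign is fixed so its
largest-magnitude loading is positive, making projections bit-reproducible.
`eps` is a radius in the projected coordinate system, whose scale depends
on the dataset; `rescale = TRUE` normalizes the projection to unit total
variance so that `eps = 0.50` marks "half the typical spread" regardless of
the absolute magnitude of signature differences. The package's own test
panels use `rescale = TRUE` for exactly this reason. DBSCAN is implemented
in the package (classic algorithm, full distance matrix) because no
suitable implementation ships with the supporting libraries used here;
panels of reference genomes are small enough (hundreds to thousands) that
the $O(n^2)$ neighbourhood construction is not a concern.

## The synthetic-data generator

The generator produces the structures the method assumes, so the entire
pipeline is testable from code alone:

* **Host groups** emulate bacterial genera. Each group gets a base
  composition with GC content on an evenly spaced ladder over 32–68% — the
  realistic span of bacterial GC — plus mild seeded jitter and AT/GC strand
  skews. One *ancestral backbone* genome (200 kb by default) is drawn per
  group and every strain is that backbone with independent substitutions at
  rate 2%, mirroring the fact that congeneric reference strains share most
  of their exact sequence, not just their composition.
* **Lysogenic-like phages** (50 kb) are drawn from their group's
  composition model and carry one contiguous segment copied verbatim from
  the group backbone, 10% of the phage length. The segment models the
  prophage-derived DNA a temperate phage shares with its host clade, and
  its size is anchored to the reported scale of exact-word sharing between
  temperate phages and their hosts (SIM of roughly 0.1 against a single
  strain). Without it, exact long-word matching would see ameliorated and
  foreign phages as equally unrelated — composition alone barely moves the
  14-mer match rate.
* **Lytic-like phages** are purely compositional: their base composition is
  pulled from the host's toward a random foreign composition with mixing
  weight `composition_divergence` (default 0.5).
* **`insert_prophage()`** splices a phage into a host verbatim (the DSW = 0
  extreme); **`make_disjoint_pair()`** builds genomes over the \{A,C\} and
  \{G,T\} alphabets whose word sets are provably disjoint at any $k$
  (the DSW = 1 extreme), and re-verifies the disjointness by brute-force
  intersection.

Every generator is a pure function of its config and seed.

What the generator does *not* emulate: gene structure and codon-level
periodicity, repeats and mobile elements, GC skew along the replichore,
rearrangements, and within-genome compositional heterogeneity beyond the
optional first-order Markov chain. Passing tests therefore demonstrate that
the estimators recover planted compositional/homology structure — not that
real phage lifestyles are this cleanly separable; on real panels the two
classes overlap and the learned threshold carries real error.

## Numerical choices

* Words are integer-encoded base-4 with A<C<G<T (lexicographic), so
  signature vectors are bit-comparable across runs; codes fit exactly in
  doubles for any practical $k$ ($4^{14} \approx 2.7\times10^8 \ll 2^{53}$).
* Windows containing any non-ACGT character are skipped and tallied, never
  imputed; the signature denominator renormalizes automatically. No window
  spans a contig junction.
* `SIM` tie-break: the definition assigns the smaller-total genome the role
  of $X$; on exact ties the first argument is $X$. Ties are practically
  impossible in the intended use (phage vs bacterial genome) but the rule
  makes the function total and symmetric-by-rule.
* Classification boundary: a mean distance exactly at the threshold is
  called lysogenic. Calls are hard; no abstention band is emitted for
  near-threshold values.
* ROC candidates are midpoints between consecutive sorted unique distances
  plus sentinels below the minimum and above the maximum; ties in distance
  to $(0,1)$ resolve to the smallest threshold. AUC is the trapezoid over
  the sorted curve and equals the Mann–Whitney concordance probability.
* Degenerate inputs fail loudly: zero-total k-mer counts (genome shorter
  than $k$ or all-ambiguous) are an error at signature/SIM time, and
  clustering a panel smaller than `min_pts` warns and labels everything
  noise rather than fabricating a cluster.
* Ranking ties (equal means) break lexicographically by element id.

## Scales used by the test suite

Unit tests run on toy sequences and scaled-down panels (tens of kb). The
full-scale behavioural checks use the generator defaults — 3 groups × 20
hosts of 200 kb and 100 phages of 50 kb — for threshold recovery, a 1 Mb
host with a 40 kb prophage for the insertion identity, and a 5 Mb random
genome for the chance-match rate. These sizes keep every distance estimate
in the regime the method targets (dense tetramer tables, sparse 14-mer
sets) while remaining fast to regenerate from seeds.

## Known limitations

* Thresholds are dataset-dependent: a boundary learned on one host panel
  does not transfer to taxa with different amelioration dynamics, and
  phyla differ in how separable their lytic and temperate phages are.
* Group-mean distances have genus/cluster-level, not strain-level,
  resolution: all strains of a coherent group sit at similar distances to a
  given phage.
* DSW is asymmetric in information content: it asks how much of the
  *smaller* genome is covered, so a plasmid sharing one operon with a huge
  genome can still look close; the association screen's contrast against
  the cluster's own associated elements is the guard against over-reading
  single low values.
* The DBSCAN implementation materializes the full pairwise distance matrix;
  for panels beyond ~10⁴ genomes a spatial index would be needed.
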