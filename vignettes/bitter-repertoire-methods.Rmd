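---
title: "Characterizing bitter taste receptor repertoires from capture summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing bitter taste receptor repertoires from capture summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitterfam)
```

## The problem

TAS2R bitter taste receptors form a tandemly clustered, intronless
multigene family (~900 bp coding regions) that gains members by
duplication ("births") and loses them by pseudogenization or deletion
("deaths"). Characterizing a species' repertoire from targeted-capture
short-read data runs into two confounds: paralogous copies capture and
map onto one reference, inflating apparent sequencing depth and SNP
density, and heterozygous individuals can carry an intact and a disrupted
allele at one locus (a *segregating pseudogene*), which shallow assembly
data misreport. `bitterfam` implements the full inference chain on
summary-level inputs -- per-locus depth and SNP tables, haplotype pairs,
a dated species tree -- and pairs it with a forward simulator so every
stage can be validated against a known truth.

## The stages and their models

### Locus calling from depth and SNP density

Depth is treated as a ploidy meter, calibrated by single-copy
non-coding neutral references: autosomal references (NR-A) sit at the
diploid expectation, X references (NR-X) at half of it in males. The
screens are, in order:

1. *Absence*: mean per-site depth < 10 (strict) marks a locus absent.
2. *Round-3 exclusions*: genes below half the lower whisker of the
   per-species gene-depth boxplot or shorter than 750 bp; neutral
   references shorter than 1000 bp; NR-A loci 1.5x above the upper
   whisker (possibly duplicated references).
3. *Candidate flagging*: a gene whose mean depth or SNP density is
   strictly above the upper whisker of the corresponding per-species
   boxplot is a duplication candidate; SNP density alone routes it to the
   undecided high-SNP class (category 4).
4. *Resolution*: if more than 10% of read-length windows are identical
   between the two putative haplotype references, reads cannot be
   separated and the locus stays a congregated paralog mixture
   (category 1). Otherwise the locus splits into `-1`/`-2` children,
   which are re-screened: clean children are separated single loci
   (category 2); a child again above the depth whisker is congregated at
   the next round (category 3); SNP-only children fall to category 4.

Quartiles are median-inclusive Tukey hinges (both halves of an
odd-length sorted sample include the median element) and whiskers are
the most extreme *data points* within 1.5 IQR of the hinges -- not the
fences themselves. `stats::quantile()` offers nine types but none is
exactly this rule, so it is implemented directly and checked in the test
suite against a brute-force sorted-array oracle. All threshold
comparisons are strict, and every constant (10, 0.5x, 1.5x, 750, 1000,
0.10) is an explicit default that can be overridden.

The "roughly 10%" shared-read criterion is operationalized as a fixed
constant 0.10 applied to the fraction of non-overlapping read-length
(150 nt) windows in which the two haplotype references are identical.
Read-level multi-mapping happens upstream of this package's interface;
the window fraction is the deterministic, testable surrogate.

### Intact/disrupted classification

A sequence is *intact* iff its maximal forward-strand, ATG-initiated,
stop-terminated ORF is at least 750 bp (250 codons, counting the start
through the last sense codon) **and** the encoded protein is predicted
to span the membrane exactly seven times. The transmembrane test is a
deterministic Kyte-Doolittle hydropathy scan (window 19, threshold 1.6,
minimum inter-segment gap 3 windows); it replaces neural topology
predictors so the criterion is reproducible without model weights, and
the constants are declared defaults, configurable, not fitted to
anything. The ORF scan is forward-strand only and requires ATG: capture
output is emitted in gene orientation, and the 250-amino-acid reading of
the threshold implies a translated product. "Exactly 7" segments is the
default; a `>= 7` mode is available.

Unphased heterozygous sites carry two-fold IUPAC codes in both
haplotypes. Because a single amino acid can break the ORF or the TM
architecture regardless of phase, all 2^k per-site combinations would
need testing; instead exactly two resolved pairs are built -- H1-1/H2-1
with H1 taking the alphabetically first nucleotide at every degenerate
site, and H1-2/H2-2 with the opposite assignment at every site. Genes
whose resolved sequences are all intact are intact; all disrupted,
disrupted; mixed verdicts give a segregating pseudogene at single loci
and the indeterminate "intact and disrupted" state at congregated or
undecided loci (categories 1, 3, 4).

### Gene trees

Pairwise distances use the Tamura-Nei (1993) closed form with the two
transition classes separated, computed from the pair's retained sites
only: gaps *and* ambiguity codes are excluded pairwise (the conservative
extension of gap-only exclusion), and base frequencies are empirical
averages over those retained sites. Saturated pairs (a log argument
at or below zero) are flagged `NaN` and refused by tree building rather
than silently ceiled. Neighbor joining follows the canonical Saitou-Nei
agglomeration with ties in the Q-criterion broken by the lowest
label-index pair and negative branch estimates clamped to zero.
Bootstrap support resamples alignment columns, rebuilds each replicate
tree, and maps the fraction of replicates containing each original
internal bipartition onto the full-data tree (no consensus topology);
replicates with saturated distances are dropped and counted. `ape`
provides the tree containers and Newick I/O; its independent TN93 and NJ
implementations serve as cross-checks in the test suite, not as the
implementation.

### Birth and death events

Presence evolves under Dollo parsimony: a gene originates exactly once
and absences are explained by losses. Births are placed to minimize
births + deaths under the assumption that paralogs homogenize frequently
by gene conversion, so within-species sequence similarity of duplicates
carries no placement information: each duplication is placed once at the
stem of the most recent common ancestor of its bearing species rather
than as repeated lineage-specific births. Capture-detected duplications
(categories 1-3) contribute one birth each; category-4 loci none.
Ancient paralog families -- distinct probed loci descending from one
ancestral gene -- are declared in a families table with one ancestral
member; each derived member costs one birth at the MRCA of its bearers.

Losses are the minimal cover: one loss on the stem of every maximal
all-absent subtree below the gene's origin. Disruptions are placed at a
common ancestor *only* when annotated as shared (the disruptive mutation
itself was checked to be identical across species); otherwise they are
independent terminal events. Segregating pseudogenes generate no death
events.

Counting weights: births +1; disruption or loss of single-locus,
category-2 or category-4 genes -1; disruption of a category-1/3
congregated locus -2 when all its sequences are disrupted and -1 when
intact and disrupted coexist; category-4 mixed loci 0. Losses are
weighted -1 regardless of category: the -2 rule is stated for
disruptions of congregated loci, and every loss handled here is a single
gene copy. Node totals propagate parent + births - deaths from a count
above the root stem; leaf totals therefore include segregating
pseudogenes.

Root polarity comes from the root stem: the species tree carries a root
edge, and a duplication borne by every sampled species is placed on that
stem (the move an outgroup would license). Placements that leaf patterns
genuinely underdetermine -- e.g. a copy born on the deepest stem but
subsequently lost in an entire subfamily, where the minimizer would
instead choose a shallower birth without the loss -- enter as
prior-knowledge events with their provenance retained, and win over
inferred placements only under an explicit override. In the packaged
cercopithecid analysis this mechanism carries the two deep births whose
copies were lost in the colobines and the literature-derived
birth+loss pair that is invisible to leaf-only inference.

## The simulator: what it emulates, and what it does not

`simulate_history()` runs a Gillespie birth/disruption/loss/conversion
process along every branch, evolving sequences between events under a
TN93-style kernel. Defaults (all per gene per million years on the dated
tree): birth 0.01, disruption 0.02, loss 0.01, conversion 0.1 per
duplicate pair, substitution 0.002/site with purifying scaling 0.4 inside
intact coding regions, heterozygosity 0.004/site, segregating probability
0.3 for terminal-branch disruptions, 10% of heterozygous sites unphased.
These are one-time choices pitched at primate-like divergence scales;
none is estimated from data.

Design choices worth knowing:

* Genes are 900 nt coding + 100 nt flanks. The ancestral coding template
  encodes seven strongly hydrophobic stretches, its hydrophilic linkers
  contain stop codons in both shifted frames (so any frameshift
  truncates the ORF within about one linker), and intact lineages reject
  substitutions that would create an in-frame stop or destroy the start
  codon -- a purifying-selection surrogate that keeps the intact/disrupted
  ground truth crisp.
* Disruptions are premature stops (codon replaced by TAA, placed so both
  flanking fragments stay under 750 bp) or 1-bp deletions (coding
  offsets 150-600); both defeat the ORF test deterministically.
* Conversion homogenizes the whole sequence of one intact duplicate with
  its partner's and is drawn only for pairs with both copies intact, so
  conversions never change copy number or the intact count.
* Depth is negative-binomial per site (size 10 by default; Poisson is
  too tight for capture data) around depth_mean x copy_number/2, scaled
  0.5 for male X loci, with a lognormal per-locus capture-efficiency
  effect (sd 0.1, normalized to mean 1). The paralog pair born on the
  tree is emitted as one congregated locus -- summed depth, union SNP
  sites including inter-paralog differences -- because a capture design
  probes it through a single ancestral reference.
* Neutral references draw SNPs at the full neutral rate, so their SNP
  density stochastically dominates intact genes (purifying scaling < 1),
  reproducing the expected functional-constraint ordering.

What the simulator does **not** model: read-level data (no FASTQ, no
mapping, no base qualities), reference bias and chimera construction,
indel realignment, and the genotype-quality filters that act on reads.
Passing tests therefore validate the decision logic downstream of the
mapping interface, not the mapping itself. The depth dispersion of real
capture experiments is unknown to us; the default is a free parameter,
not an estimate.

## Numerical and degenerate-input choices

* Distances: ambiguity codes excluded pairwise; saturated distances are
  `NaN`, reported, and fatal for tree building unless handled.
* NJ ties broken deterministically (lowest index pair); duplicate rows
  produce zero-length cherries.
* `boxplot_stats()` on a constant vector returns zero IQR with both
  whiskers at the constant; single observations are legal.
* Empty depth vectors, unknown sex labels, unknown record kinds, unknown
  config keys, and three/four-fold IUPAC codes are rejected with
  explicit errors rather than coerced.
* Every stochastic entry point requires a seed; there is no implicit
  entropy, and equal seeds give bit-identical histories, emissions and
  pipeline outputs.

## Problem sizes used in the packaged analyses and tests

The bundled drivers simulate 6 species with 12-gene root repertoires at
depth 1000 and 1000 bootstrap replicates. The test suite exercises the
closed-form Yule expectation over 2000 seeds, the conservation identity
over 500 simulated histories, exhaustive parsimony enumeration on
4-leaf instances, 500 random additive 6-leaf trees, 1000 TN93 oracle
pairs, and 200 seeded replicates for duplicated-locus recall at 2.5%
paralog divergence and depth 600 -- sizes chosen so the whole suite runs
in about a minute while keeping Monte-Carlo standard errors well inside
the asserted bounds.

## Known limitations

* The caller judges split children against the parent species' whiskers
  rather than re-deriving boxplots per mapping round; with summary-level
  inputs there is no new data at round 4 beyond the child records.
* Shared-disruption grouping trusts its annotation; the package does not
  itself compare disruptive mutations across species (the simulator's
  truth tags make that comparison trivial for simulated data).
* Gene-tree/species-tree incongruence is not used to posit hidden
  duplications; placements that need such evidence must arrive as prior
  events.
* The hydropathy scan is a stand-in for learned topology predictors; its
  agreement with them on borderline real sequences is untested here, and
  the 7-TM criterion on real data should be read with that in mind.
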