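---
title: "Curating long-read metagenome assemblies: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating long-read metagenome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magcurate)
```

## The problem

HiFi (high-fidelity long read) metagenome assembly of a complex community —
the motivating case is the microbiota of the five intestinal compartments of
the chicken gut — produces an assembly graph whose components fall into
three recognisable shapes: single circular contigs (complete replicons),
tangled multi-segment components containing cycles (several co-assembled
strains of one species sharing genomic stretches), and linear paths
(incomplete genomes, usually from low coverage). Downstream of assembly, a
curation pipeline has to (i) triage the graph, (ii) collapse the genome set
to nonredundant strain- and species-level representatives using average
nucleotide identity (ANI), (iii) rank assembly quality and assess RNA-gene
completeness, (iv) flag genomes novel relative to reference sets, and (v)
build a nonredundant gene catalog. `magcurate` implements that curation
computation as a tested, reusable package, together with a
synthetic-community generator that provides ground truth for every step.

## Graph topology triage

Components are connected components of the undirected segment adjacency;
link orientation is ignored because the three classes are topological
shapes, not constrained walks. The rules are:

* **circular** — exactly one segment whose only incident link is a
  self-link with matching orientation signs, `(+,+)` or `(-,-)`;
* **tangled** — the undirected multigraph of the component contains a
  cycle. For a connected multigraph this is equivalent to
  `edges >= vertices`, counting self-links and parallel links;
* **linear** — everything else (acyclic components, including isolated
  segments).

A deliberate edge case: a single segment closed by a `(+,-)` self-link
joins the sequence onto its own reverse complement. That is not a circular
chromosome, so it is called linear — a conservative circularity rule.
Where exactly the boundary runs between a "tangled circular" and a large
linear aggregate is not observable from topology alone; the cycle rule is
one consistent reading, and the per-component FASTA export exists precisely
so tangled components can be re-examined (e.g. reassembled) independently.

Per-segment depth is read from GFA tags with precedence `rd:i:` (the
integer read-depth tag emitted by HiFi metagenome assemblers) over `dp:f:`
over 0, so graphs from other producers still load; depth is never inferred
from reads.

## ANI estimation and dereplication

The ANI estimator is fragment-based. The query is cut into non-overlapping
3 kb fragments (the conventional fragment size for this family of
estimators); each fragment is located in the reference by diagonal voting
over shared 16-mers on both strands, then scored by a global alignment of
the fragment against the candidate reference window. Identity is
matches / alignment columns; a fragment counts as mapped when its identity
reaches 80%, mirroring the detectability floor of fragment-based ANI
tools, and ANI is the mean identity over mapped fragments. The estimate is
directional; pairs sharing no seeds report an undefined ANI.

Numerical choices: alignment scoring is match +1 / mismatch −1 with affine
gaps (opening 4, extension 2), which keeps alignments gapless on
substitution-only inputs so the estimate coincides with the exact
positional identity there — the property the test suite checks to within
0.3 percentage points at 0.5/2/5% substitution rates. The diagonal vote
uses 48 seeds per fragment binned at 30 bp, tolerant of the small indels
the generator introduces.

Dereplication follows the published procedure: identities are converted to
distances by `(100 − identity)/100` and clustered by complete-linkage
agglomeration with a stop distance — 0.01 for the strain level (99% ANI)
and 0.05 for the species level (95% ANI). Three decisions the procedure's
written description leaves open are resolved as follows:

* **Symmetrisation** — the two directional estimates are combined by their
  minimum: conservative, never under-reporting divergence.
* **Undefined pairs** — distance 1.0 (maximal), since such pairs are below
  the estimator's floor (~80% identity), far beyond both stop distances.
* **Stop semantics** — merging continues while the closest pair is
  *strictly* below the stop distance. Under this reading two genomes at
  exactly 99.0% ANI are not merged at strain level, which is consistent
  with retained representatives being allowed to share up to 99% ANI.

Ties in the merge order are broken by the lexicographically smallest pair
of cluster labels (a cluster's label is its smallest member id), which
makes the clustering bit-for-bit reproducible and invariant to input
order; the suite verifies equivalence against a naive re-computing oracle
on hundreds of random matrices.

Within each cluster the representative is chosen by: circular before
noncircular, then larger CheckM score (completeness − 5 × contamination),
then larger assembly size, then smallest id. The first two keys are the
published rule; the last two are documented tie-breaks added for
determinism.

## Quality ranks and RNA completeness

Quality tiers are `near_complete` (completeness ≥ 90%, contamination
< 5%), `high_quality` (≥ 70%, < 10%) and `medium_quality` (≥ 50%, < 10%).
Published descriptions of these tiers circulate with both `<` and `≤` on
contamination; the strict form is the default here and the inclusive form
is available via `contamination_inclusive = TRUE`. Completeness and
contamination are consumed as inputs — computing them from marker genes is
out of scope.

"RNA complete" requires at least one full-length rRNA operon encoding all
three rRNA types (5S, 16S, 23S) and at least 18 full-length tRNA genes.
Operons are detected by chaining rRNA features on the same contig and
strand with inter-gene gaps up to 5 kb — a configurable colocation rule
chosen because typical bacterial rRNA operons span about 5–7 kb in total.
The tRNA criterion counts total copies by default, per the criterion's
literal wording; a distinct-isotype mode is provided because
completeness standards elsewhere count distinct tRNAs.

## Novelty calling

Against a reference genome set, a query's best symmetrised ANI decides
strain (> 99%) and species (> 95%) matches, strictly, so a query at
exactly the threshold is novel. Against a reference 16S set, the best
local-alignment identity is thresholded at the conventional 16S
demarcations: below 95% (or no alignment of at least 100 columns) —
novel genus; below 97% — novel species; otherwise known. The 16S
alignment uses a simple +1/−1/−2/−1 scoring; at these identity ranges the
calls are insensitive to the exact scheme, and the scoring is exposed as
parameters of the estimator rather than hard-coded constants elsewhere.

## Gene catalogs

Catalog construction is greedy incremental clustering in the CD-HIT-EST
style (`-c 0.95 -n 10 -G 0 -aS 0.9`): genes sorted by descending length
join the *first* existing representative (in creation order) whose best
local alignment reaches 95% identity over alignment columns and covers at
least 90% of the shorter sequence, else found a new cluster. Join-first —
not join-best — is deliberate, matching the greedy behaviour of the
reference tool; a join-best mode exists for sensitivity analysis. A
shared-word prefilter (word size 10) skips hopeless comparisons; the suite
verifies it changes nothing relative to an all-pairs oracle. Catalog
comparison applies the same criteria inclusively (≥ 95% / ≥ 90%) and calls
a gene shared if *any* gene of the other catalog qualifies; reciprocity is
not required. The structure-completeness ratio is the fraction of genes
whose partial flags are `"00"` (both ORF edges present); gene prediction
itself is out of scope and flags are inputs.

## The synthetic community

The generator provides ground truth, not realism. Species ancestors are
independent uniform-random genomes, so between-species identity is random
background, far below the 95% species threshold — deep-divergence
simulation would add nothing for threshold testing. Strains derive from
their ancestor by per-site substitutions at rate
`(100 − intra_species_ani)/100` plus short indels (1–5 bp) at one tenth of
that rate; the indels exist so the ANI estimator is exercised on
non-trivially alignable sequences, and a substitution-only mode provides
closed-form expected identities for exact checks. Graph simulation
realises each planned topology by construction (tangled components share
one segment among the strains of a species and close cycles through it);
segment depth is abundance × 300 (an arbitrary, documented scale no test
depends on). rRNA/tRNA annotations are positional fixtures with realistic
counts (1–6 operons, 35–65 tRNAs in community fixtures), not homologous
sequences. Gene families derive members at half the target pairwise
divergence from a family ancestor and vary length by end-trimming up to
10%, so within-family coverage of the shorter gene stays complete.

What passing tests therefore show: the pipeline's decision rules recover
known structure under the stated noise model. What they do not show:
robustness to chimeric contigs, mobile elements, uneven intra-genome
coverage, or real rRNA sequence divergence — limitations shared by any
fixture-based validation.

## Problem sizes and determinism

Validation runs use deliberately modest problem sizes chosen to probe each
property at adequate statistical resolution: 50 kb genomes for estimator
accuracy (binomial noise on realized identity ≈ 0.04 percentage points),
30 kb genomes for the 5-species × 3-strain end-to-end recovery (partition
recovery at 99.3% intra-species ANI against random background needs no
more), 200 random matrices up to n = 12 for clustering-oracle equivalence,
and 100 random gene sets of up to 60 genes for the prefilter oracle. All
randomness flows through explicit seeds; every `simulate_*` function
restores the caller's RNG state.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <s> --out <path>` recomputes, from scratch
against the installed package: the sequencing-run totals and every printed
percentage from the count tables shipped under `inst/extdata/`, the
oracle-agreement and parameter-recovery rates described above, and the
catalog quantities. The run-stat and count tables are inputs from the
published chicken-gut HiFi study the pipeline is designed around; all
other quantities are measured on freshly generated synthetic data.
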