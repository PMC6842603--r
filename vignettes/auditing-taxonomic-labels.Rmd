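---
title: "Auditing taxonomic labels in sequence reference databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing taxonomic labels in sequence reference databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Metabarcoding and eDNA studies identify animals by comparing query reads
against reference databases of mitochondrial gene sequences. Those
references are only as good as their taxonomic annotations, and a database
entry can carry the wrong taxon for many reasons: specimen
misidentification, laboratory contamination, nuclear mitochondrial
pseudogenes (numts), data-entry slips, sequences of gut contents or
parasites attributed to the host, and names made obsolete by taxonomic
revision. `seqTaxAudit` implements a clustering-based audit of such
databases: sequences of one gene are clustered at high identity
thresholds, clusters whose members disagree at phylum, class, order,
family or genus rank are flagged, and the number of mislabeled sequences
is bracketed, resolved, and attributed to likely causes. A synthetic
database generator with planted, fully known mislabels supports
validation of every stage.

The core assumption is biological: for fast-evolving mitochondrial genes,
clusters of sequences at 97% identity or more should essentially contain
conspecifics. Two genera in one such cluster therefore signal a labeling
problem (or, rarely, a genuinely slow-evolving group — see *Limitations*).
Species-level disagreement is deliberately not audited: multispecies
clusters are often legitimate (recent divergence, introgression,
insufficient marker resolution).

# Pipeline stages and their models

## Gene classification

Records are assigned to one of 15 mitochondrial genes (13 protein-coding,
2 rRNA) by optimal Smith–Waterman local alignment against small per-gene
reference panels — a deliberate, exact stand-in for a BLAST search.
Protein-coding panels hold amino-acid references and are searched with
the best of the six translated frames (mitochondrial genetic codes;
invertebrate code 5 by default, configurable), because amino acids
separate homologous mitochondrial genes more cleanly than nucleotides.
Raw scores are converted to bit scores and E-values through the ungapped
Karlin–Altschul parameters: \(\lambda\) is solved numerically from
\(\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1\) under the scheme's background
composition (uniform bases, or uniform over the 20 residues for
BLOSUM62), and \(K\) defaults to 0.41 (nucleotide) / 0.134 (amino acid).
A hit is significant when E-value \(< 10^{-10}\) **and** bit score
\(> 70\), both strict; a record with significant hits to two or more
genes is discarded as multi-gene (putative chimera or misassembly), and a
record with none is discarded as below-threshold. The E-value search
space is query length times total panel length, in the panel's alphabet.
Assigned records then pass a per-gene length window (inclusive bounds;
e.g. 12S 200–2000 bp, CO1 100–2000 bp, ND1 50–1200 bp), which prevents
very short fragments from seeding spurious clusters.

The default nucleotide scheme is match +2, mismatch −3, gap open 5, gap
extend 2 (a gap of length \(L\) costs \(5 + 2L\)) — ordinary BLASTN-style
parameters. Gapped-statistics estimation is out of scope; the ungapped
\(\lambda\) and \(K\) are used for gapped scores, which is conservative
at these thresholds because the panels are small and genuine hits exceed
the bit cutoff by a wide margin.

## Clustering

Each gene's sequences are clustered by greedy, length-sorted centroid
clustering at fixed identity thresholds (0.97, 0.98, 0.99, 1.00),
emulating `vsearch --sortbylength --cluster_fast`: records are processed
longest first (ties by accession so runs are reproducible), and each
record joins the *first* existing centroid whose pairwise identity
reaches the threshold, else founds a new cluster. First-acceptance, not
best-match, is used, matching `cluster_fast` defaults; membership can
therefore differ from best-match semantics, which is documented rather
than hidden. The comparison against centroids is exhaustive — no k-mer
prescreening — which is the scalability boundary of this implementation:
it is meant for databases of hundreds to tens of thousands of sequences,
not for a full GenBank-scale run.

Pairwise identity is matching columns divided by alignment columns
between the first and last aligned residue pair of a full global
(Needleman–Wunsch, affine-gap) alignment: terminal gaps are excluded from
the denominator, so a 3'-truncated record is not penalized against a
full-length centroid, while internal gaps count as mismatches. Alignment
ties are broken deterministically (diagonal preferred; gap extension
preferred; trailing gaps reported terminally so they are excluded as
terminal, not counted as internal).

## Flagging and the min/max bracket

Within every multisequence (≥ 2 member) cluster, the distinct named taxa
at each audited rank are counted; members unranked at a rank are excluded
there rather than treated as a taxon of their own, which would fabricate
discordance. For a discordant rank with counts \(c_1 \ge c_2 \ge \dots\)
and \(n = \sum c_i\), assuming at least one annotation is correct:

* minimum mislabeled \(= n - \max_i c_i\) (the largest group is right),
* maximum mislabeled \(= n - \min_i c_i\) (only the smallest group is
  right).

A cluster of six sequences labeled A, A, A, B, B, C thus brackets between
3 and 5 mislabels. Per-rank totals are *cumulative*: a sequence whose
labels first disagree at the order rank is counted at order, family and
genus ("mislabeled at or above the rank"); an exclusive per-rank view is
available via `cumulative = FALSE`. Rates divide by the total number of
sequences in multisequence clusters at the same threshold — solitary
sequences cannot be audited by this design and are excluded from the
denominator. The headline table is reported at the 0.97 threshold, the
most inclusive of the data; other thresholds are computed independently
alongside.

## Resolving individual mislabels

For large discordant clusters (≥ 100 members by default) the bracket is
replaced by an exact count when a similarity-consensus resolver settles
every member. The resolver is a deterministic stand-in for manual
phylogenetic inspection: for each member, the mean pairwise identity to
every taxon group (excluding itself) is compared with margin
\(\varepsilon = 0.005\). Members of the plurality label are correct. A
non-plurality member is mislabeled when its own-label group gives it no
support (it is that group's only member) or when another group's mean
identity beats its own by more than \(\varepsilon\); it is correct when
its own group wins by more than \(\varepsilon\). When similarity is
uninformative (all group means within \(\varepsilon\) — e.g. two
data-entry duplicates carrying the same wrong genus inside an otherwise
homogeneous cluster), a clear plurality decides: the member is called
mislabeled if the plurality group is at least twice its own group's
size, else unresolved. This plurality fallback reflects the empirical
situation that in the vast majority of flagged clusters the most common
taxon is the correct one; symmetric or tied configurations remain
unresolved, and clusters with any unresolved member fall back wholesale
to the count-based bracket so the bracket's validity is never diluted.

The \(\varepsilon\) margin is an identity difference, dimensionless, and
should stay well below the conspecific-versus-congener identity gap
(≈ 0.05 for these genes); 0.005 separates "same cluster, same species"
noise from genuine group structure.

## Cause classification

Each resolved mislabel is passed through an ordered decision tree — first
match wins, and the order encodes evidence strength:

1. **data-entry** — another cluster member of a different labeled genus
   has a nearly consecutive accession (same prefix, numeric difference
   ≤ 2), or the labeled genus is within Levenshtein distance 2 of the
   consensus genus (autofill/typo slips);
2. **lab-contaminant** — the cluster's consensus genus is a common
   laboratory contaminant (humans, lab rodents, model organisms, common
   food, mosquitos, pets; configurable list);
3. **pseudogene** — "pseudogene"/"numt" in the record definition, or a
   chimeric windowed-identity profile against the nearest cluster member:
   a near-identical region (window identity ≥ 0.9) coexisting with a
   drop of more than 0.30 elsewhere (window 60 bp, step 30 bp);
4. **host-or-diet** — gut-content/parasite keywords in the definition;
5. **bacterial** — closer to a local bacterial reference panel than to
   the cluster consensus;
6. **taxonomic-revision** — the labeled genus maps to the consensus genus
   in a local synonym table (a reproducible stand-in for querying online
   nomenclators);
7. otherwise **other**.

Members of Porifera and Cnidaria are explicitly *not assessed*
(mitochondrial resolution in these phyla is too low for the cluster
assumption), returning `"not-assessed"` rather than an error. The
"nearly consecutive" window (2) and name-edit threshold (2) are
operational choices where only narrative guidance exists; both are
configurable in `causeConfig()`.

## Sampling-strategy evaluation

`simulateStrategy()` compares three ways of estimating the database error
rate at fixed auditing effort (clusters checked): drawing *sequences*
uniformly and auditing their clusters, drawing *clusters* uniformly, and
exhaustively auditing all large clusters while bracketing the rest.
Sequence draws hit large clusters preferentially (size-biased inclusion),
so when errors concentrate in small clusters the ratio estimate is biased
low; uniform cluster draws with the expansion estimator
\(100 \cdot (N/k)\sum \text{mislabeled} / N_{\text{seq}}\) are exactly
unbiased; the large-cluster-exhaustive strategy always brackets the truth
on minority-mislabel data. Comparisons are qualitative (bias sign,
coverage), not numeric reproductions of any external figure.

# The synthetic generator

`simulateDatabase()` emulates the statistical structure the audit relies
on, not mitochondrial biology. A ranked taxonomy of configurable shape
(default 2 phyla × 2 classes × 2 orders × 2 families × 2 genera ×
1 species × 15 sequences = 480 ordinary records, plus a correctly labeled
contaminant block of *Homo*/*Mus*/*Rattus*) is built with random genus
names kept pairwise Levenshtein distance ≥ 3 apart, so the data-entry
name rule cannot fire by accident. Sequences evolve down the taxonomy
under a uniform (Jukes–Cantor-style) substitution process: independent
random family roots; genus models at a branch divergence hitting an
expected inter-genus pairwise difference of 0.15; species models hitting
0.08; and individuals with an *exact* substitution count drawn uniformly
in \([0, L \cdot 0.01]\) plus a random 0–9 bp 3' truncation. The exact
count (rather than binomial site sampling) bounds conspecific pairs at
≤ 2% difference *by construction*, so conspecifics always co-cluster at
0.97 and congeners (≥ 8% apart) never do — the generator's divergence
invariant `conspecific < 1 − 0.97 ≤ intragenus` is enforced at
construction. The default gene is CO1 at 350 bp, the scale of the widely
used CO1 mini-barcode fragments; full-length 658 bp barcodes only change
runtime, not structure.

Mislabels are planted per cause class at configurable rates (defaults:
plain swaps 2% with rank weights favouring genus; data-entry 0.5%;
lab-contaminant 0.5%; pseudogene 0.3%; host/diet 0.3%; revision 0.4%)
and recorded in a truth table (true and labeled lineages, flag, cause,
rank). Plants are constructed so each signature is unambiguous: swap
targets differ at exactly the planted rank; data-entry plants get an
accession adjacent to an unplanted conspecific (background accessions are
spaced ≥ 4 apart); contaminant and host/diet plants replace the sequence
with one from the contaminant block or a foreign genus while keeping the
label; revision plants are relabeled to a legacy genus listed in the
generated synonym table. The bacterial rate defaults to 0: bacterial
contaminants form clusters that are mislabeled in their entirety, outside
the minority-mislabel regime in which the min/max bracket is valid, so
they are exercised by dedicated fixtures instead of the default
conditions.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: realistic branch-length heterogeneity,
codon structure and selection, rate variation across sites, indel-rich
markers (an indel mode exists but defaults off), slow-evolving groups
that legitimately share clusters across genera, ragged taxonomies with
missing ranks, and GenBank-scale depth. The audit's accuracy on real data
hinges on the conspecific-cluster assumption, which the generator builds
in rather than tests.

# Numerical and design choices

* **Alignment** is exact affine-gap DP (Gotoh) with integer scoring and
  fixed tie-breaking; the production aligner is verified against an
  independent full-matrix R implementation and against
  `Biostrings::pairwiseAlignment` scores in the test suite.
* **Identity for clustering** penalizes terminal gaps in the score but
  excludes them from the identity denominator, which reproduces the
  behaviour of end-gap-penalized global aligners used by clustering
  tools; with truly free end gaps a shifted alignment can paradoxically
  score higher and report identity 1.0 for `AAAA` vs `AAAT`.
* **Thresholds** are applied strictly (`E < 1e-10`, `bits > 70`,
  identity `>=` threshold with a 1e-12 floating guard).
* **Large-cluster cutoff** is inclusive (size ≥ 100).
* **Determinism**: every stochastic step takes a seed; the pipeline with
  a fixed seed produces byte-identical report bundles, and RNG state is
  restored after each seeded call.
* **Problem sizes** used by the test-suite and validation runs are
  deliberately desk-scale: ~500-sequence databases, 50 replicate
  databases for the recovery checks, 500 Monte-Carlo replicates for the
  sampling comparisons, 350 bp CO1 fragments. These sizes are the
  package's own validation conditions; nothing in the method depends on
  them.

# Limitations

The audit counts *label incongruence within clusters*; it cannot see
mislabels in solitary clusters (every sequence of a rare taxon), cannot
separate mislabels from genuine trans-generic clusters in slow-evolving
groups (hence the Porifera/Cnidaria exclusion from cause assessment), and
its maximum bound deliberately overestimates by assuming the rarest
in-cluster taxon correct. The exhaustive centroid scan is quadratic at
low thresholds; a k-mer prescreen would be required at database scale.
Real taxdump inputs with merged or deleted taxon ids must be
pre-resolved; unknown ids are hard errors by design.
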