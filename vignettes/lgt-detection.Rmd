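---
title: "Detecting lateral gene transfer in metagenome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lateral gene transfer in metagenome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgtscout)
```

## The problem

Lateral (horizontal) gene transfer moves genes between lineages outside
vertical descent. In engineered microbial communities — the motivating case
is Enhanced Biological Phosphorus Removal (EBPR) sludge, where
phosphate-accumulating organisms such as *Candidatus* Accumulibacter
(Betaproteobacteria) compete with glycogen-accumulating organisms from other
proteobacterial classes — transfers of core metabolic enzymes can reshape
who does what in the community. Detecting such transfers from a metagenome
is hard: assemblies are fragmentary, most detection methods assume complete
genomes, and chimeric contigs can mimic transfer signals.

`lgtscout` implements two complementary class-level detection analyses plus
the screens and syntheses around them:

1. **Classification discordance.** Every contig and every ORF receives a
   class-level taxonomic assignment that combines homology evidence with a
   k-mer naive-Bayes composition score. An ORF whose class disagrees with
   its parent contig's class suggests a transfer, oriented from the ORF's
   class (donor) into the contig's class (recipient).
2. **Phylogenetic incongruence.** Proteins are clustered into homology
   networks, trees are built per cluster, and a community protein whose
   nearest neighbour by patristic distance belongs to a different class —
   within 0.3 substitutions/site — is called as an (undirected) transfer.
   No reference species tree is required, which matters because likely
   donors may simply be absent from the sample.

Candidates from both analyses are screened for homology to mobile genetic
elements (MGEs), intersected into a high-confidence set, mapped onto six
energy-related KEGG pathways, summarised as directed genetic-exchange
networks, and validated by mapping reads across the putatively transferred
ORFs and their neighbours.

## The composition model

Class composition is modelled as an order-(k-1) Markov chain over
nucleotides (default `kmer_order = 4`, i.e. trinucleotide context). Training
counts k-mers on both strands with additive smoothing, so models are
reverse-complement symmetric; scoring returns the mean per-base natural-log
likelihood, skipping windows that contain `N`. Contigs are unoriented and
are scored on both strands (the better strand wins); ORFs are scored on
their coding strand.

Classifications are tiered into four confidence groups, evaluated in order:

* **Group I** — homology-based class equals composition-based class;
* **Group II** — the best homology e-value is at least 10 orders of
  magnitude smaller than the best hit from any other class;
* **Group III** — the naive-Bayes likelihood of the best class is at least
  1.5 times the runner-up's;
* **Group IV** — best naive-Bayes likelihood alone.

Two readings in this tier system are genuinely open and we fixed them as
follows. The Group III "1.5 times greater" likelihood criterion does not
specify a scale; we read it as a likelihood *ratio*, i.e. a difference of at
least `ln 1.5` in **total** log-likelihood, because that is the only
scale-free interpretation (a per-base reading would make the criterion
depend on sequence length in the opposite direction). Zero e-values are
floored at `1e-200` so order-of-magnitude arithmetic stays defined.

## Discordance calling

Only ORFs in Groups I–II are eligible (their classifications are treated as
reliable); the contig may sit in any group, and the contig's group is
recorded in the output for downstream filtering. A call requires the ORF's
composition score under its own class to be at least 15 % better than under
the contig's class. The comparison arithmetic is again unspecified in
prose; we compute a relative improvement of mean per-base log-likelihoods,

\[(s_\text{orf class} - s_\text{contig class}) / |s_\text{contig class}| \ge 0.15,\]

which is scale-free and sign-safe for negative log-likelihoods. ORFs
shorter than `3 * kmer_order` nt are never called: with a handful of k-mer
windows the composition score is essentially noise. We apply the 15 % test
to the ORF's assigned class; an alternative reading would additionally
require the ORF's homology class to equal its composition-best class, which
is stricter and, on the synthetic communities, nearly always coincides.

## Phylogenetic incongruence

Network edges require 70 % identity, 60 % query coverage, and e ≤ 1e-5 (all
inclusive). Connected components become clusters; clusters are decomposed
through supported subtrees (support ≥ 70 %, iterating until each cluster
holds at most 200 leaves). Where a region cannot be split below the cap it
is emitted whole with a warning — the iteration rule gives no other
termination, and silently discarding sequences would bias the tally.

The built-in tree path computes Poisson-corrected distances
(`d = -ln(1 - p)`) over aligned (equal-length) sequences, builds a
neighbour-joining tree (negative NJ branch lengths are clamped to zero, a
standard repair), and attaches bootstrap support by column resampling.
Likelihood trees from external software (e.g. WAG-model trees) are the
fidelity route and enter through `read_newick()`; every downstream result
is identical given the same tree, which the test suite asserts.

Calls apply the 0.3 substitutions/site cutoff to the **patristic** distance
between the focal community leaf and its nearest neighbour among
same-community leaves and reference leaves; a single-branch reading of the
cutoff was rejected because the quantity actually computed throughout is
the patristic distance. Out-of-class nearest neighbours beyond the cutoff
are tallied but not called; ties break lexicographically by leaf id so runs
are deterministic. Direction is never inferred for these calls.

## Screens and synthesis

* **MGE screen**: a candidate survives if some MGE hit has e ≤ 1e-30, comes
  from a different class than the candidate, and covers ≥ 60 % of *both*
  query and subject.
* **Functional annotation**: top hit with ≥ 60 % of the query aligned,
  e ≤ 1e-5, and neither sequence more than 1.2× the other's length.
* **Reference-genome self-screen**: sequences with an out-of-class hit at
  the same e-value as the best hit and ≥ 60 % coverage. Which sequence the
  60 % refers to is unstated; we measure coverage on the query, the common
  convention for tabular search output.
* **Mobility genes** are found by case-insensitive keyword match
  ("transposase", "integrase") on product text — no method for their
  identification is prescribed, and the keyword list is configurable.
* **Exchange networks** keep witnesses itemised: a directed edge's
  multiplicity is exactly its number of witnessing discordance calls, and
  undirected phylogenetic calls form a separate layer that never becomes an
  arrow.
* **Read validation** retains read-to-contig alignments covering ≥ 70 % of
  the read at e ≤ 1e-30 and classifies each retained alignment as
  `into_neighbor`, `full_orf`, `intergenic_bounded`, or `partial` (in that
  precedence), mirroring the categories used to argue against misassembly.

## The synthetic-data generator

Every stage is exercised on generated communities with machine-readable
ground truth. The generator emulates:

* class-specific nucleotide composition — per-class base biases of ±0.12
  around uniform (Jensen–Shannon divergence ≈ 0.12 between two classes,
  comfortably above the 0.1 floor used in the recovery checks) with small
  seeded context jitter, making the models genuine order-3 chains;
* contigs carrying ORFs — backgrounds sampled from the class chain with
  proper reading frames (ATG … stop, no internal stops) overwritten on the
  layout spans;
* planted transfers — an ORF slot regenerated from the donor class's model,
  with an EC number from the packaged toy pathway table, a lightly mutated
  MGE homolog labelled with the recipient's class, and optionally a
  transposase-annotated neighbour;
* reads — error-free uniform substrings on both strands by default
  (a configurable substitution rate exists), so read-validation logic is
  tested separately from aligner sensitivity;
* protein families — two clades 0.6 substitutions/site apart under a
  Poisson substitution process, with a community leaf optionally re-simulated
  0.1 (or 0.5) from a donor-clade reference;
* homology hit tables — emitted directly from the true pairwise identities
  of the simulated families, standing in for an external all-versus-all
  search run.

What the generator does **not** emulate: real sequencing error models,
strain-level microdiversity, misassembled chimeras, indels in protein
families, compositional heterogeneity within a genome (GC skew, recent
amelioration), or a realistic reference database. Passing the planted-
transfer checks therefore demonstrates that the *decision rules* recover
transfers whose signal matches their assumptions — not that real
communities would yield the same precision.

## Numerical choices and problem sizes

* The built-in aligner reports Karlin–Altschul e-values with fixed
  constants (K = 0.13, λ = 0.32) rather than composition-adjusted ones;
  both sides of every comparison use the same constants, so thresholds act
  consistently.
* Validation reads are 250 nt: under the fixed-constant e-value, a perfect
  alignment must span roughly 125 nt before it can reach the 1e-30
  mapping threshold, so the generator emulates long (Sanger-length)
  fragments like those the read-validation protocol was designed around.
* Recovery experiments use 50 contigs of 2–10 kb with 20 planted ORFs for
  discordance, 100 protein families (10 % grafted) for incongruence, and a
  20-contig, 8-plant community for the end-to-end demo — sizes chosen so a
  full run completes on a laptop in about a minute while keeping enough
  events for stable recall/precision estimates.
* Pairwise distances cap the observed difference proportion so the Poisson
  correction stays finite for saturated pairs.

## Limitations

Class-level resolution precludes within-class transfers by construction.
The discordance method needs the donor's composition signature to survive
amelioration; old transfers fade. The phylogenetic method cannot orient
transfers and inherits any bias of the supplied trees. The MGE screen is
only as good as the MGE database it is given. The packaged EC-to-pathway
table is a toy subset of six pathways for demonstration; real analyses
should supply their own table.
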