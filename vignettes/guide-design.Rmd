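---
title: "Designing and scoring base-editing guide libraries with bedesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and scoring base-editing guide libraries with bedesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

CRISPR base editors (BEs) are dCas9–deaminase fusions that convert one base
into another without a double-strand break: cytosine base editors (CBEs such
as BE3 and Target-AID) convert C•G to T•A, adenine base editors (ABEs such
as ABE7.10) convert A•T to G•C. Editing is efficient only when the target
base falls inside the editor's *activity window*, a short stretch of spacer
positions, and only when a protospacer-adjacent motif (PAM) flanks the
protospacer. Designing a guide library against hundreds of desired mutations
therefore means solving, per mutation, a small geometric puzzle — which
spacer placements put the target base on the editable strand, adjacent to a
matching PAM — and then ranking the candidates by their expected specificity.

`bedesign` does both steps against any local FASTA + GFF3 genome, for
arbitrary user-defined editors (conversion chemistry + window) and IUPAC PAM
patterns on either side of the spacer, and attaches to every guide an
a-priori multiplicative score described below.

## Inputs and modes

Mutation requests come as TSV in one of two dialects:

* **nucleotide**: `chromosome`, `position`, `ref_base`, `alt_base`;
* **amino acid**: `transcript_id`, `residue_position`, `ref_residue`,
  `alt_residue`.

Each run is either in **model** mode (introduce the mutation on the
reference background: design the edit ref → alt) or **correct** mode (revert
an alternative allele: the design context carries the alternative allele at
the target and the designed edit is alt → ref). For amino-acid requests in
correct mode the mutant codon is not given by the input; it is reconstructed
as the codon encoding the alternative residue at minimal Hamming distance
from the reference codon, ties broken lexicographically. This is the
simplest reconstruction consistent with a single-nucleotide-variant origin
of the allele; when the true mutant codon is known, supplying the request in
nucleotide format sidesteps the heuristic.

Amino-acid requests are expanded into *codon edit plans*: for both
presentation strands of the codon (a C→T editor acts as G→A on the opposite
strand), every nonempty subset of source-base positions is converted and
plans whose edited codon translates to the requested residue are kept. We
enumerate subsets, not only single positions, because a deaminase converts
every source base inside its window at once; a plan records exactly which
conversions it assumes. A candidate guide for a multi-position plan must
hold all assumed positions in its spacer, and its `in_window` flag requires
all of them inside the window. In-window source bases *not* part of the plan
are reported as `bystander_offsets` and never filtered silently.

## Guide enumeration

For each (request, editor, PAM) combination the designer enumerates every
spacer placement in which the target base(s) occupy spacer positions, the
strand presents the editor's source base at the target, and the adjacent PAM
matches its IUPAC pattern (a genomic `N` never satisfies a PAM, and spacers
containing `N` are discarded — an ambiguous base cannot guarantee the edit).
Placements whose editable base falls outside the activity window are
*emitted and flagged*, not suppressed: the window penalty of the scoring
system exists precisely to rank them down, and suppressing them would hide
usable (if less efficient) guides. Requests for which no configured editor
offers the chemistry, or no placement offers a PAM, are reported in an
unreachable table with a reason code; nothing is dropped silently.

Spacer coordinates are reported 1-based from the PAM-distal end (for a 3'
PAM, position 1 is the spacer's 5' terminus — the common CBE/ABE windowing
convention). Window defaults for the built-in editors (Target-AID 2–4, BE3
4–8, ABE7.10 4–7) are literature-based defaults and freely overridable; so
is everything else about an editor or PAM.

Every guide also carries the length of its longest poly-T run, because four
or more consecutive T can terminate RNA polymerase III transcription of the
gRNA; the run length is indicated, never auto-filtered.

**Controls.** Positive-control guides introduce in-window nonsense edits
(codon → stop) into a transcript of interest, scanning residues in
ascending order. Negative controls are PAM-valid placements whose window
contains zero source bases, so editing them should have a null effect; they
are drawn with a fixed seed from the deterministic genome-wide enumeration.

## The scoring system

Off-target alignments of each spacer are searched genome-wide on both
strands with a Hamming-distance budget (default: at most 2 mismatches,
indels not considered) and a hard PAM requirement: the PAM must match its
degenerate pattern exactly and PAM positions never count toward the
mismatch budget, since a mismatched PAM abolishes recognition rather than
merely weakening binding. The search runs on `Biostrings::matchPattern()`;
its contract — exact equivalence with a naive position-by-position scan — is
enforced in the test suite against an independently coded oracle.

Each alignment *a* contributes two multiplicative penalties:

* **Mismatch-position penalty** `P_a = prod_i P_i` over the `M_max`
  mismatched positions *i*. `P_i` is read from a third-degree polynomial
  fitted by least squares to a position-wise mismatch-tolerance table
  (distance from PAM vs mean tolerance of Cas9 binding), clamped into
  `[P_min, P_max]`. Mismatches adjacent to the PAM are poorly tolerated, so
  they indicate a *less* active off-target site and receive the small
  multiplier `P_min`; PAM-distal mismatches retain activity and receive up
  to `P_max`. All penalties are multipliers in (0, 1]: smaller = worse
  guide. For spacers of non-reference length the fitted curve is evaluated
  at the rescaled distance `d × 20 / guide_length`, which stretches the
  curve over any spacer. For 5' PAMs the position-wise penalty vector is
  read in reversed order; storing offsets PAM-distally makes this a single
  uniform formula (`distance = guide_length − offset + 1`). An alignment
  with zero mismatches has the empty product `P_a = 1`; its presence still
  penalizes through the region term.
* **Region penalty** `G_a`: `G_g` if the alignment overlaps any annotated
  gene by at least 1 bp, `G_ig` otherwise. `G_g < G_ig` because off-target
  edits in genic regions confound the intended mutational effect more than
  intergenic ones.

The guide's final score is

\[ B = \Big(\prod_{a=1}^{n} P_a \, G_a\Big) \times A \]

where `A` is `A_in` (default 1) when the editable base lies inside the
activity window and `A_out` otherwise, and the product runs over all
alignments *except the intended target site itself*. Excluding the intended
site is forced by the score semantics: an optimal guide — in-window, no
off-target alignment — must score exactly 1, which would be impossible if
its own (genic, exact) site entered the product. The intended site is
matched by coordinates and strand rather than by zero mismatches, because
in correct mode the spacer carries the alternative allele and aligns to the
reference genome with one mismatch at its own locus. Because every factor
lies in (0, 1], any violated requirement strictly decreases `B`, and
`0 < B ≤ 1` always.

### Default penalty values

Large-scale base-editing data sets from which penalties could be estimated
do not yet exist, so the defaults encode the relative importance of each
requirement and are all exposed in the configuration:

| parameter | default | meaning |
|---|---|---|
| `P_min` | 0.01 | multiplier for a PAM-adjacent mismatch |
| `P_max` | 1.0 | multiplier for the most PAM-distal mismatch |
| `G_g` | 0.5 | genic off-target alignment |
| `G_ig` | 0.9 | intergenic off-target alignment |
| `A_in` | 1.0 | editable base inside the window |
| `A_out` | 0.5 | editable base outside the window |
| `max_mismatches` | 2 | off-target Hamming budget |
| `guide_length` | 20 nt | spacer length |

The bundled tolerance table is likewise a monotone synthetic stand-in with
the empirically established shape (`tolerance(d) = P_min + (P_max − P_min)
((d−1)/19)^2` for `d = 1..20`); substituting a measured table re-fits the
cubic automatically. The fit requires at least four distinct distances.

## The synthetic fixture generator

All tests and worked examples run on genomes produced by `generate_genome()`
from a `fixture_recipe()`: random background sequence at a configurable GC
content (default 40%, yeast-like) carrying non-overlapping single-exon genes
whose CDS is a valid ATG…stop open reading frame, written as FASTA + GFF3.
`generate_mutations()` assigns uniformly random nucleotide or amino-acid
mutations whose reference fields are read back from the genome, emulating
randomly assigned mutation sets at the scale of a few dozen to a few hundred
requests, and `plant_offtarget_sites()` writes spacer+PAM copies with an
exact number of seeded mismatches (never in the PAM) as ground truth for the
off-target search. Everything is bit-for-bit reproducible from
`(recipe, seed)`, and the seed is recorded in file headers.

What the fixtures deliberately do **not** emulate: repeat families,
segmental duplications, realistic codon usage, isochore structure, multi-exon
genes (the coordinate mapper supports junction-split codons, exercised with
hand-built transcripts, but generated genes are single-exon), or genome-scale
sequence length. Passing tests therefore demonstrate correctness of the
geometry, search and scoring logic — not performance or editability rates on
real genomes, where repeats will inflate off-target counts and annotation
density will shift the genic/intergenic balance.

Test problem sizes were chosen to exercise the contracts comfortably at desk
scale: oracle-equivalence runs use 50 random fixtures of 10–100 kb across
mismatch budgets 0–2, and the edit-replay property uses 500 requests split
over both input formats and both modes.

## Numerical and degenerate-input choices

* Candidate ordering is fully deterministic: by request, then descending
  score, then coordinate, then strand; ties cannot survive because the
  guide id embeds coordinates.
* `reverse_complement` maps N↔N; any other character is a contract error.
* A chromosome position whose spacer or PAM would run past either end is
  skipped, never clamped.
* An off-target search that fails to recover a guide's own site raises an
  integrity error instead of returning a silently wrong score (the one
  exception — an intended site beyond the mismatch budget, possible in
  correct mode with a budget of 0 — is appended explicitly).
* Empty inputs degrade gracefully: a gene-free annotation classifies
  everything intergenic; an empty library writes header-only outputs.

## Worked example

```{r, eval = FALSE}
library(bedesign)

r  <- fixture_recipe(seed = 7, n_chromosomes = 2, chromosome_length = 8000,
                     n_genes = 4, gene_length = 300, n_mutations = 15)
fx <- generate_genome(r, "fixture")
write_mutation_table(generate_mutations(fx$genome, r),
                     "fixture/mutations.tsv", seed = 7)

cfg <- run_config(genome_fasta = fx$fasta, annotation_gff = fx$gff,
                  mutation_table = "fixture/mutations.tsv", random_seed = 7)
res <- run_pipeline(cfg, "out")
res$summary
#> <editability_summary> 6/15 requests editable (40.0%), 7.67 guides per editable request
```

About 40% editability is expected here: the built-in editors cover 4 of the
12 possible nucleotide substitutions (C>T, G>A, A>G, T>C), and a PAM must
land correctly besides.

## Known limitations

* Off-target search is substitution-only; bulged (gapped) alignments are
  not found.
* On-target efficiency beyond the binary window penalty (position-specific
  activity, sequence context, chromatin) is out of scope, as is learning
  penalties from data.
* "Genic" means overlap with any `gene` feature; UTR/intron distinctions
  are not made.
* Editor chemistry is a single base-to-base conversion; dual editors or
  context-restricted deaminases need one `base_editor` entry per behaviour.
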