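# bedesign

Design and a-priori scoring of CRISPR base-editing guide RNA libraries
against locally annotated genomes.

CRISPR base editors (BEs) — dCas9–deaminase fusions such as the cytosine
editors BE3 and Target-AID (C•G→T•A) and the adenine editor ABE7.10
(A•T→G•C) — install point mutations without double-strand breaks, but only
when the target base sits inside the editor's *activity window* of the
spacer and a PAM flanks the protospacer. `bedesign` is for researchers
building guide libraries against many mutations at once: it takes a genome
(FASTA + GFF3), a table of desired mutations at nucleotide level
(coordinate + desired base) or amino-acid level (transcript, residue
position, desired residue), and any combination of user-defined editors
(conversion chemistry + window) and IUPAC PAM patterns (either side of the
spacer), and emits every candidate guide on both strands — in "model" mode
(introduce a mutation on the reference background) or "correct" mode
(revert an alternative allele to the reference) — plus positive (nonsense)
and negative (nothing editable in-window) control guides and a poly-T
annotation per spacer.

Each guide is scored a priori by a multiplicative penalty system. With
off-target alignments *a* = 1…*n* of the spacer (Hamming distance ≤ 2 by
default, hard IUPAC PAM match, intended site excluded):

    P_i = cubic fit of position-wise mismatch tolerance,  clamped to [P_min, P_max]
    P_a = ∏_{i=1}^{M_max} P_i          (over the mismatched positions of alignment a)
    G_a = G_g  if genic,  G_ig  if intergenic
    B   = ( ∏_{a=1}^{n} P_a · G_a ) · A

where `A` penalizes guides whose editable base lies outside the activity
window. All factors are multipliers in (0, 1], so an optimal guide scores
exactly **B = 1** and every violated requirement — more off-targets,
PAM-distal mismatches, genic off-target placement, out-of-window edit —
strictly decreases B. Defaults: `P_min = 0.01`, `P_max = 1`, `G_g = 0.5`,
`G_ig = 0.9`, `A_in = 1`, `A_out = 0.5`, 20-nt spacers. See the
`guide-design` vignette for the model, its assumptions and every tunable.

## Worked example

Everything below runs on a synthetic fixture genome built by the package's
own deterministic generator (no downloads):

```r
library(bedesign)

r  <- fixture_recipe(seed = 7, n_chromosomes = 2, chromosome_length = 8000,
                     n_genes = 4, gene_length = 300, n_mutations = 15)
fx <- generate_genome(r, "fixture")                       # FASTA + GFF3 + bundle
write_mutation_table(generate_mutations(fx$genome, r),
                     "fixture/mutations.tsv", seed = 7)

cfg <- run_config(genome_fasta = fx$fasta, annotation_gff = fx$gff,
                  mutation_table = "fixture/mutations.tsv", random_seed = 7)
res <- run_pipeline(cfg, "out")

res$summary
#> <editability_summary> 6/15 requests editable (40.0%), 7.67 guides per editable request

head(res$library[, c("guide_id", "spacer", "edited_offset", "in_window",
                     "guide_score", "n_offtargets")], 3)
#>                                   guide_id               spacer edited_offset in_window guide_score n_offtargets
#> 1  m0001|ABE7.10|NG|chr2:3448-3467(-)t3462 CTTGCATTAGGGCTCGCATT             6      TRUE         1.0            0
#> 2 m0001|ABE7.10|NGG|chr2:3443-3462(-)t3462 ATTAGGGCTCGCATTCGTCC             1     FALSE         0.5            0
#> 3  m0001|ABE7.10|NG|chr2:3443-3462(-)t3462 ATTAGGGCTCGCATTCGTCC             1     FALSE         0.5            0
```

Reading the output: request `m0001` is an A>G-class edit reachable by
ABE7.10 on the minus strand. The first guide holds the target at spacer
position 6, inside ABE7.10's window (4–7), and has no off-target alignment,
so it scores 1.0; the next placements put the target at position 1, outside
the window, and drop to `A_out = 0.5`. Six of the fifteen random mutations
are editable at all — the built-in chemistries cover 4 of the 12 possible
substitutions, and a PAM must land correctly besides. `run_pipeline()` also
writes `library.tsv`, `summary.tsv` (per-substitution % editability and
strand coverage), `unreachable.tsv` (each failed request with a reason),
`by_combination.tsv` (guides per editor × PAM × strand) and an optional
alignment dump and BED6 into the output directory, all byte-reproducible
for a fixed seed.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/bedesign.R fixtures --recipe recipe.yml --out fixture
Rscript inst/cli/bedesign.R design --cfg params.yml --out out --stop-after score
Rscript inst/cli/bedesign.R score --library out/library.tsv --genome fixture/genome.fa \
    --gff fixture/genome.gff3 --cfg params.yml --out rescored
```

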