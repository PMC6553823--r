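SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
STOP_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]

#' Recipe for a synthetic genome fixture
#'
#' Describes a deterministic synthetic genome (random background sequence
#' with non-overlapping protein-coding genes), the companion annotation, and
#' a table of randomly assigned mutations. Defaults emulate a small
#' yeast-like test genome: one 10 kb chromosome at 40% GC carrying a handful
#' of single-exon genes, with mutations drawn uniformly across the genome.
#' Everything downstream of a recipe is reproducible bit-for-bit from
#' `(recipe, seed)`.
#'
#' @param seed integer PRNG seed recorded in all generated file headers.
#' @param n_chromosomes,chromosome_length genome shape.
#' @param n_genes,gene_length gene count and CDS length in nt (must be a
#'   multiple of 3; every gene gets an ATG...stop CDS with no internal stop).
#' @param n_mutations rows in the generated mutation table.
#' @param mutation_format `"nucleotide"` or `"amino_acid"`.
#' @param mode `"model"` or `"correct"`.
#' @param gc_content background GC fraction.
#' @return object of class `fixture_recipe`.
#' @export
fixture_recipe <- function(seed = 1L, n_chromosomes = 1L, chromosome_length = 10000L,
                           n_genes = 3L, gene_length = 300L, n_mutations = 20L,
                           mutation_format = c("nucleotide", "amino_acid"),
                           mode = c("model", "correct"), gc_content = 0.4) {
  mutation_format <- match.arg(mutation_format)
  mode <- match.arg(mode)
  if (gene_length %% 3L != 0L || gene_length < 9L) {
    abort("gene_length must be a multiple of 3 and >= 9", "bedesign_recipe_error")
  }
  if (gc_content < 0 || gc_content > 1) {
    abort("gc_content must lie in [0, 1]", "bedesign_recipe_error")
  }
  r <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
            chromosome_length = as.integer(chromosome_length),
            n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
            n_mutations = as.integer(n_mutations), mutation_format = mutation_format,
            mode = mode, gc_content = gc_content)
  # feasibility of gene packing (slot layout used by generate_genome)
  margin <- 20L
  per_chrom <- tabulate((seq_len(r$n_genes) - 1L) %% r$n_chromosomes + 1L,
                        nbins = r$n_chromosomes)
  for (k in per_chrom[per_chrom > 0L]) {
    if (r$chromosome_length %/% k < r$gene_length + 2L * margin) {
      abort(sprintf("genes do not fit: %d gene(s) of %d nt cannot be packed into a %d nt chromosome",
                    k, r$gene_length, r$chromosome_length), "bedesign_recipe_error")
    }
  }
  structure(r, class = "fixture_recipe")
}

#' Generate a synthetic genome, annotation files and bundle
#'
#' Builds the genome described by a [fixture_recipe()], writes it as FASTA +
#' GFF3 (plus a manifest recording the seed), and returns the parsed bundle.
#' Output is byte-identical across runs with the same recipe.
#'
#' @param recipe a [fixture_recipe()].
#' @param dir output directory (created if needed).
#' @return list with `genome` (a [genome_bundle()]), `fasta`, `gff`,
#'   `manifest` paths and `genes` placement table.
#' @export
generate_genome <- function(recipe, dir = tempfile("bedesign_fixture_")) {
  stopifnot(inherits(recipe, "fixture_recipe"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  margin <- 20L
  out <- with_seed(recipe$seed, {
    chrom_names <- sprintf("chr%d", seq_len(recipe$n_chromosomes))
    seqs <- setNames(vapply(chrom_names, function(nm) {
      random_dna(recipe$chromosome_length, recipe$gc_content)
    }, character(1L)), chrom_names)
    genes <- empty_gene_table()
    transcripts <- list()
    if (recipe$n_genes > 0L) {
      chrom_of <- (seq_len(recipe$n_genes) - 1L) %% recipe$n_chromosomes + 1L
      slot_index <- stats::ave(seq_along(chrom_of), chrom_of, FUN = seq_along)
      rows <- vector("list", recipe$n_genes)
      for (g in seq_len(recipe$n_genes)) {
        ci <- chrom_of[g]
        k <- sum(chrom_of == ci)
        slot <- recipe$chromosome_length %/% k
        play <- slot - recipe$gene_length - 2L * margin
        off <- if (play > 0L) sample.int(play + 1L, 1L) - 1L else 0L
        start <- (slot_index[g] - 1L) * slot + margin + off + 1L
        end <- start + recipe$gene_length - 1L
        strand <- sample(c("+", "-"), 1L)
        n_codons <- recipe$gene_length %/% 3L
        body <- if (n_codons > 2L) {
          sample(SENSE_CODONS, n_codons - 2L, replace = TRUE)
        } else character(0L)
        cds <- paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
        insert <- if (strand == "+") cds else reverse_complement(cds)
        seqs[[ci]] <- substr_replace(seqs[[ci]], start:end,
                                     strsplit(insert, "", fixed = TRUE)[[1L]])
        gid <- sprintf("gene%04d", g)
        txid <- sprintf("tx%04d", g)
        rows[[g]] <- data.frame(chromosome = chrom_names[ci], start = start, end = end,
                                strand = strand, gene_id = gid,
                                transcript_id = txid, stringsAsFactors = FALSE)
        transcripts[[txid]] <- transcript_model(txid, chrom_names[ci], strand,
                                                data.frame(start = start, end = end))
      }
      genes <- do.call(rbind, rows)
    }
    list(seqs = seqs, genes = genes, transcripts = transcripts)
  })
  fasta <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "genome.gff3")
  manifest <- file.path(dir, "manifest.tsv")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(out$seqs), fasta, width = 70L)
  write_fixture_gff3(out$genes, gff)
  writeLines(c("# bedesign fixture manifest",
               sprintf("seed\t%d", recipe$seed),
               sprintf("n_chromosomes\t%d", recipe$n_chromosomes),
               sprintf("chromosome_length\t%d", recipe$chromosome_length),
               sprintf("n_genes\t%d", recipe$n_genes),
               sprintf("gene_length\t%d", recipe$gene_length)),
             manifest)
  bundle <- genome_bundle(out$seqs,
                          if (nrow(out$genes)) out$genes[, c("chromosome", "start", "end",
                                                            "strand", "gene_id")]
                          else empty_gene_table(),
                          out$transcripts)
  list(genome = bundle, fasta = fasta, gff = gff, manifest = manifest, genes = out$genes)
}

# hand-formatted GFF3 so fixture output is byte-stable for a fixed seed
write_fixture_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  if (!is.null(genes) && nrow(genes)) {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      lines <- c(lines,
        sprintf("%s\tbedesign\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                g$chromosome, g$start, g$end, g$strand, g$gene_id),
        sprintf("%s\tbedesign\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                g$chromosome, g$start, g$end, g$strand, g$transcript_id, g$gene_id),
        sprintf("%s\tbedesign\tCDS\t%d\t%d\t.\t%s\t0\tID=cds_%s;Parent=%s",
                g$chromosome, g$start, g$end, g$strand, g$transcript_id, g$transcript_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate a random mutation table for a fixture genome
#'
#' Nucleotide rows carry the true reference base read from the genome and a
#' desired base drawn from the three alternatives; amino-acid rows carry the
#' translated reference residue of a random internal codon and a different
#' desired residue. Deterministic for a fixed recipe.
#'
#' @param genome a [genome_bundle()].
#' @param recipe the [fixture_recipe()] (supplies seed, count, format).
#' @return data.frame in the corresponding mutation-table dialect.
#' @export
generate_mutations <- function(genome, recipe) {
  stopifnot(inherits(recipe, "fixture_recipe"))
  n <- recipe$n_mutations
  with_seed(recipe$seed + 1L, {
    if (recipe$mutation_format == "nucleotide") {
      chroms <- sample(names(genome$sequences), n, replace = TRUE,
                       prob = genome$lengths / sum(genome$lengths))
      pos <- vapply(chroms, function(ch) sample.int(genome$lengths[[ch]], 1L), integer(1L))
      ref <- vapply(seq_len(n), function(i) {
        substr(genome$sequences[[chroms[i]]], pos[i], pos[i])
      }, character(1L))
      alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), character(1L))
      data.frame(request_id = sprintf("m%04d", seq_len(n)),
                 chromosome = chroms, position = as.integer(pos),
                 ref_base = ref, alt_base = unname(alt),
                 stringsAsFactors = FALSE, row.names = NULL)
    } else {
      if (!length(genome$transcripts)) {
        abort("amino_acid mutation format requires a genome with transcripts",
              "bedesign_recipe_error")
      }
      txids <- sample(names(genome$transcripts), n, replace = TRUE)
      aa20 <- setdiff(AA_SYMBOLS, "*")
      rows <- lapply(seq_len(n), function(i) {
        tx <- genome$transcripts[[txids[i]]]
        n_codons <- tx$cds_length %/% 3L
        # internal codons only: keep the start codon and the stop codon intact
        rp <- if (n_codons > 2L) sample(2:(n_codons - 1L), 1L) else 1L
        ref <- translate_codon(codon_at(genome, tx, rp))
        alt <- sample(setdiff(aa20, ref), 1L)
        data.frame(request_id = sprintf("m%04d", i), transcript_id = txids[i],
                   residue_position = rp, ref_residue = ref, alt_residue = alt,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
  })
}

#' Write a mutation table as TSV
#'
#' @param mutations data.frame from [generate_mutations()] or compatible.
#' @param path output file.
#' @param seed optional seed recorded in the header comment.
#' @return the path, invisibly.
#' @export
write_mutation_table <- function(mutations, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# bedesign mutation table", con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  write.table(mutations, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plant off-target sites for a protospacer into a fixture genome
#'
#' Writes copies of `spacer` + `pam_seq` into the genome at the requested
#' placements, each copy carrying exactly `n_mismatches` substitutions at
#' seeded random spacer positions (never inside the PAM). Minus-strand
#' placements insert the reverse complement on the plus strand. Ground truth
#' for off-target search tests.
#'
#' @param genome a [genome_bundle()].
#' @param spacer protospacer sequence (guide strand).
#' @param pam_seq concrete PAM sequence to plant (e.g. `"AGG"`).
#' @param placements data.frame with columns `chromosome`, `position`
#'   (plus-strand protospacer start), `strand`, `n_mismatches`.
#' @param pam_side `"three_prime"` or `"five_prime"`.
#' @param seed seed controlling mismatch positions and substituted bases.
#' @param protect_cds error if a planted block overlaps any transcript CDS.
#' @return list with the modified `genome` and a `sites` table giving exact
#'   planted protospacer coordinates and mismatch offsets (spacer 5'-end
#'   1-based on the guide strand).
#' @export
plant_offtarget_sites <- function(genome, spacer, pam_seq, placements,
                                  pam_side = "three_prime", seed = 1L,
                                  protect_cds = FALSE) {
  assert_dna(spacer, allow_n = FALSE, what = "spacer")
  assert_dna(pam_seq, allow_n = FALSE, what = "PAM sequence")
  L <- nchar(spacer); pl <- nchar(pam_seq)
  placements <- as.data.frame(placements)
  sites <- vector("list", nrow(placements))
  with_seed(seed, {
    for (i in seq_len(nrow(placements))) {
      p <- placements[i, ]
      check_chromosome(genome, p$chromosome)
      mm <- as.integer(p$n_mismatches)
      if (mm > L) abort("n_mismatches exceeds spacer length", "bedesign_recipe_error")
      mm_off <- if (mm > 0L) sort(sample.int(L, mm)) else integer(0L)
      sp <- spacer
      for (o in mm_off) {
        sp <- substr_replace(sp, o, sample(setdiff(DNA_BASES, substr(spacer, o, o)), 1L))
      }
      block <- if (pam_side == "three_prime") paste0(sp, pam_seq) else paste0(pam_seq, sp)
      ps <- as.integer(p$position)
      pe <- ps + L - 1L
      if (p$strand == "+") {
        bs <- if (pam_side == "three_prime") ps else ps - pl
        plus_block <- block
      } else {
        bs <- if (pam_side == "three_prime") ps - pl else ps
        plus_block <- reverse_complement(block)
      }
      be <- bs + L + pl - 1L
      if (bs < 1L || be > genome$lengths[[p$chromosome]]) {
        abort(sprintf("placement %d runs off chromosome '%s'", i, p$chromosome),
              "bedesign_placement_error")
      }
      if (protect_cds && length(genome$transcripts)) {
        for (tx in genome$transcripts) {
          if (tx$chromosome == p$chromosome &&
              any(tx$cds_exons$start <= be & tx$cds_exons$end >= bs)) {
            abort(sprintf("placement %d collides with CDS of %s", i, tx$transcript_id),
                  "bedesign_placement_error")
          }
        }
      }
      genome$sequences[[p$chromosome]] <- substr_replace(
        genome$sequences[[p$chromosome]], bs:be,
        strsplit(plus_block, "", fixed = TRUE)[[1L]])
      sites[[i]] <- data.frame(chromosome = p$chromosome,
                               protospacer_start = ps, protospacer_end = pe,
                               strand = p$strand, n_mismatches = mm,
                               mismatch_offsets = paste(mm_off, collapse = ","),
                               site_spacer = sp, stringsAsFactors = FALSE)
    }
  })
  list(genome = genome, sites = do.call(rbind, c(sites, list(make.row.names = FALSE))))
}
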