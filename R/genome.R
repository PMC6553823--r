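#' Transcript model
#'
#' CDS exons are genomic 1-based inclusive intervals listed in TRANSLATION
#' order (descending genomic coordinates for minus-strand transcripts). The
#' concatenated CDS length must be divisible by 3.
#'
#' @param transcript_id label.
#' @param chromosome chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds_exons data.frame with columns `start`, `end`, one row per CDS
#'   exon, in translation order.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, chromosome, strand, cds_exons) {
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'", "bedesign_contract_error")
  cds_exons <- as.data.frame(cds_exons)[, c("start", "end")]
  cds_exons$start <- as.integer(cds_exons$start)
  cds_exons$end <- as.integer(cds_exons$end)
  if (any(cds_exons$start > cds_exons$end)) {
    abort("CDS exon with start > end", "bedesign_contract_error")
  }
  len <- sum(cds_exons$end - cds_exons$start + 1L)
  if (len %% 3L != 0L) {
    abort(sprintf("CDS length %d of %s not divisible by 3", len, transcript_id),
          "bedesign_contract_error")
  }
  o <- order(cds_exons$start)
  so <- cds_exons[o, , drop = FALSE]
  if (nrow(so) > 1L && any(so$start[-1L] <= so$end[-nrow(so)])) {
    abort(sprintf("overlapping CDS exons in %s", transcript_id), "bedesign_contract_error")
  }
  # translation order check: ascending for +, descending for -
  expected <- if (strand == "+") o else rev(o)
  if (!identical(expected, seq_len(nrow(cds_exons)))) {
    abort(sprintf("CDS exons of %s not in translation order", transcript_id),
          "bedesign_contract_error")
  }
  structure(list(transcript_id = transcript_id, chromosome = chromosome,
                 strand = strand, cds_exons = cds_exons, cds_length = len),
            class = "transcript_model")
}

#' Assemble a genome bundle
#'
#' The in-memory genome representation shared by all stages: plain-text
#' chromosome sequences, the gene interval table used for genic/intergenic
#' classification, and transcript CDS models for amino-acid level requests.
#'
#' @param sequences named character vector, chromosome name -> DNA string.
#' @param genes data.frame with columns `chromosome`, `start`, `end`,
#'   `strand`, `gene_id` (may have zero rows).
#' @param transcripts named list of [transcript_model()] objects.
#' @return object of class `genome_bundle`.
#' @export
genome_bundle <- function(sequences,
                          genes = empty_gene_table(),
                          transcripts = list()) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    abort("sequences must be a named character vector", "bedesign_contract_error")
  }
  sequences <- vapply(sequences, toupper, character(1L))
  lens <- setNames(nchar(sequences), names(sequences))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes)) {
    bad <- !genes$chromosome %in% names(sequences) |
      genes$start < 1L | genes$end > lens[genes$chromosome]
    if (any(bad)) {
      abort(sprintf("gene %s outside its chromosome", genes$gene_id[bad][1L]),
            "bedesign_coordinate_error")
    }
  }
  for (tx in transcripts) {
    if (!tx$chromosome %in% names(sequences) ||
        any(tx$cds_exons$start < 1L) || any(tx$cds_exons$end > lens[tx$chromosome])) {
      abort(sprintf("transcript %s outside its chromosome", tx$transcript_id),
            "bedesign_coordinate_error")
    }
  }
  structure(list(sequences = sequences, lengths = lens, genes = genes,
                 transcripts = transcripts),
            class = "genome_bundle")
}

empty_gene_table <- function() {
  data.frame(chromosome = character(), start = integer(), end = integer(),
             strand = character(), gene_id = character(), stringsAsFactors = FALSE)
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("<genome_bundle> %d chromosome(s), %s nt total, %d gene(s), %d transcript(s)\n",
              length(x$sequences), format(sum(x$lengths), big.mark = ","),
              nrow(x$genes), length(x$transcripts)))
  invisible(x)
}

#' Read a genome from FASTA (+ optional GFF3 annotation)
#'
#' FASTA is read with Biostrings; the GFF3 is read with rtracklayer and
#' features of type `gene` populate the gene-interval table while
#' `CDS` features grouped by their mRNA parent populate transcript models.
#' Sequence names are truncated at the first whitespace (Ensembl-style
#' headers).
#'
#' @param fasta path to a (multi-)FASTA file.
#' @param gff optional path to a GFF3 annotation.
#' @return a [genome_bundle()].
#' @export
read_genome <- function(fasta, gff = NULL) {
  if (!file.exists(fasta)) abort(sprintf("FASTA not found: %s", fasta), "bedesign_input_error")
  ss <- Biostrings::readDNAStringSet(fasta)
  names(ss) <- sub("\\s.*$", "", names(ss))
  sequences <- setNames(as.character(ss), names(ss))
  genes <- empty_gene_table()
  transcripts <- list()
  if (!is.null(gff)) {
    if (!file.exists(gff)) abort(sprintf("GFF3 not found: %s", gff), "bedesign_input_error")
    ann <- as.data.frame(rtracklayer::readGFF(gff))
    first_parent <- function(p) vapply(p, function(v) if (length(v)) v[[1L]] else NA_character_,
                                       character(1L))
    g <- ann[ann$type == "gene", , drop = FALSE]
    if (nrow(g)) {
      genes <- data.frame(chromosome = as.character(g$seqid),
                          start = as.integer(g$start), end = as.integer(g$end),
                          strand = as.character(g$strand),
                          gene_id = as.character(g$ID), stringsAsFactors = FALSE)
    }
    mrna <- ann[ann$type == "mRNA", , drop = FALSE]
    cds <- ann[ann$type == "CDS", , drop = FALSE]
    if (nrow(cds)) {
      cds$tx <- first_parent(cds$Parent)
      for (txid in unique(cds$tx)) {
        rows <- cds[cds$tx == txid, , drop = FALSE]
        strand <- as.character(rows$strand[1L])
        rows <- rows[order(rows$start, decreasing = (strand == "-")), , drop = FALSE]
        transcripts[[txid]] <- transcript_model(
          txid, as.character(rows$seqid[1L]), strand,
          data.frame(start = rows$start, end = rows$end)
        )
      }
    } else if (nrow(mrna)) {
      # annotation with mRNA but no CDS rows: treat whole mRNA as CDS
      for (i in seq_len(nrow(mrna))) {
        transcripts[[as.character(mrna$ID[i])]] <- transcript_model(
          as.character(mrna$ID[i]), as.character(mrna$seqid[i]),
          as.character(mrna$strand[i]),
          data.frame(start = mrna$start[i], end = mrna$end[i])
        )
      }
    }
  }
  genome_bundle(sequences, genes, transcripts)
}

check_chromosome <- function(genome, chromosome) {
  if (!chromosome %in% names(genome$sequences)) {
    abort(sprintf("unknown chromosome '%s' (known: %s)", chromosome,
                  paste(names(genome$sequences), collapse = ", ")),
          "bedesign_coordinate_error")
  }
}

#' Fetch a strand-aware genomic subsequence
#'
#' @param genome a [genome_bundle()].
#' @param chromosome chromosome name.
#' @param start,end 1-based inclusive coordinates on the plus strand.
#' @param strand `"+"` returns the plus-strand substring; `"-"` returns its
#'   reverse complement.
#' @return DNA string of length `end - start + 1`.
#' @export
fetch_sequence <- function(genome, chromosome, start, end, strand = "+") {
  check_chromosome(genome, chromosome)
  start <- as.integer(start); end <- as.integer(end)
  len <- genome$lengths[[chromosome]]
  if (is.na(start) || is.na(end) || start < 1L || end < start || end > len) {
    abort(sprintf("coordinates [%d, %d] out of range for chromosome '%s' (1..%d)",
                  start, end, chromosome, len),
          "bedesign_coordinate_error")
  }
  s <- substr(genome$sequences[[chromosome]], start, end)
  if (strand == "-") reverse_complement(s) else s
}

# genomic positions (plus-strand coordinates) of the CDS bases of a
# transcript, in translation order
cds_positions <- function(tx) {
  unlist(lapply(seq_len(nrow(tx$cds_exons)), function(i) {
    s <- tx$cds_exons$start[i]; e <- tx$cds_exons$end[i]
    if (tx$strand == "+") s:e else e:s
  }), use.names = FALSE)
}

#' Genomic location of a codon
#'
#' Maps a 1-based residue position of a transcript to the genomic positions
#' of the codon's three bases, in translation order (descending plus-strand
#' coordinates for minus-strand transcripts). Codons split across exon
#' junctions are supported.
#'
#' @param tx a [transcript_model()].
#' @param residue_position 1-based codon index within the CDS.
#' @return data.frame with columns `chromosome`, `position`, `strand` (three
#'   rows, codon order).
#' @export
codon_genomic_location <- function(tx, residue_position) {
  residue_position <- as.integer(residue_position)
  n_codons <- tx$cds_length %/% 3L
  if (is.na(residue_position) || residue_position < 1L || residue_position > n_codons) {
    abort(sprintf("residue position %d outside CDS of %s (1..%d)",
                  residue_position, tx$transcript_id, n_codons),
          "bedesign_validation_error")
  }
  pos <- cds_positions(tx)[(3L * residue_position - 2L):(3L * residue_position)]
  data.frame(chromosome = tx$chromosome, position = pos, strand = tx$strand,
             stringsAsFactors = FALSE)
}

# spliced CDS sequence of a transcript in translation orientation
spliced_cds <- function(genome, tx) {
  paste(vapply(seq_len(nrow(tx$cds_exons)), function(i) {
    fetch_sequence(genome, tx$chromosome, tx$cds_exons$start[i], tx$cds_exons$end[i],
                   tx$strand)
  }, character(1L)), collapse = "")
}

# sense-strand codon of a transcript at a residue position
codon_at <- function(genome, tx, residue_position) {
  loc <- codon_genomic_location(tx, residue_position)
  paste(vapply(loc$position, function(p) {
    fetch_sequence(genome, tx$chromosome, p, p, tx$strand)
  }, character(1L)), collapse = "")
}

#' Classify a genomic interval as genic or intergenic
#'
#' An interval is genic iff it overlaps any annotated gene interval by at
#' least 1 bp (strand-agnostic); otherwise intergenic. This is the binary
#' predicate behind the off-target region penalty.
#'
#' @param genome a [genome_bundle()].
#' @param chromosome chromosome name.
#' @param start,end 1-based inclusive interval.
#' @return `"genic"` or `"intergenic"`.
#' @export
classify_region <- function(genome, chromosome, start, end) {
  check_chromosome(genome, chromosome)
  if (end < start) abort("end < start", "bedesign_coordinate_error")
  g <- genome$genes
  hit <- nrow(g) > 0L && any(g$chromosome == chromosome & g$start <= end & g$end >= start)
  if (hit) "genic" else "intergenic"
}
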