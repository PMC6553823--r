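# Independent reference implementations used as oracles. Everything here is
# deliberately written from scratch (own complement table, own IUPAC classes,
# position-by-position scanning) so the tests never share code paths with the
# package functions they check.

oracle_rc <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_pam_ok <- function(pattern, observed) {
  pc <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  oc <- strsplit(observed, "", fixed = TRUE)[[1L]]
  if (length(pc) != length(oc)) return(FALSE)
  all(vapply(seq_along(pc), function(i) oc[i] %in% oracle_iupac[[pc[i]]], logical(1L)))
}

# Naive both-strand scan: every placement with Hamming distance <= max_mm on
# the spacer and an adjacent PAM satisfying the IUPAC pattern. Offsets are
# spacer 5'-end 1-based on the guide strand.
oracle_scan <- function(sequences, spacer, pam_pattern, pam_side, max_mm) {
  L <- nchar(spacer)
  pl <- nchar(pam_pattern)
  sp <- strsplit(spacer, "", fixed = TRUE)[[1L]]
  rows <- list()
  for (chrom in names(sequences)) {
    seq <- sequences[[chrom]]
    clen <- nchar(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    if (clen < L) next
    starts <- seq_len(clen - L + 1L)
    for (strand in c("+", "-")) {
      target <- if (strand == "+") sp else strsplit(oracle_rc(spacer), "", fixed = TRUE)[[1L]]
      mm <- integer(length(starts))
      for (i in seq_len(L)) mm <- mm + (chars[starts + i - 1L] != target[i])
      for (a in starts[mm <= max_mm]) {
        e <- a + L - 1L
        pr <- if ((pam_side == "three_prime") == (strand == "+")) {
          c(e + 1L, e + pl)
        } else {
          c(a - pl, a - 1L)
        }
        if (pr[1L] < 1L || pr[2L] > clen) next
        pam_obs <- substr(seq, pr[1L], pr[2L])
        if (strand == "-") pam_obs <- oracle_rc(pam_obs)
        if (grepl("N", pam_obs) || !oracle_pam_ok(pam_pattern, pam_obs)) next
        site <- substr(seq, a, e)
        if (strand == "-") site <- oracle_rc(site)
        off5 <- which(strsplit(site, "", fixed = TRUE)[[1L]] != sp)
        rows[[length(rows) + 1L]] <- data.frame(
          chromosome = chrom, start = a, end = e, strand = strand,
          n_mismatches = length(off5),
          offsets5 = paste(off5, collapse = ","), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chromosome = character(), start = integer(), end = integer(),
                      strand = character(), n_mismatches = integer(),
                      offsets5 = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$chromosome, out$start, out$strand), , drop = FALSE]
}

# canonical comparable form of a find_alignments() result: PAM-distal offsets
# converted back to spacer 5'-end numbering
alignment_key <- function(aln, guide_length, pam_side) {
  off5 <- vapply(aln$mismatch_offsets, function(s) {
    if (!nzchar(s)) return("")
    off <- as.integer(strsplit(s, ",")[[1L]])
    if (pam_side != "three_prime") off <- guide_length - off + 1L
    paste(sort(off), collapse = ",")
  }, character(1L), USE.NAMES = FALSE)
  k <- paste(aln$chromosome, aln$start, aln$end, aln$strand, aln$n_mismatches, off5)
  sort(k)
}

oracle_key <- function(orc) {
  k <- paste(orc$chromosome, orc$start, orc$end, orc$strand, orc$n_mismatches,
             vapply(orc$offsets5, function(s) {
               if (!nzchar(s)) "" else paste(sort(as.integer(strsplit(s, ",")[[1L]])),
                                             collapse = ",")
             }, character(1L), USE.NAMES = FALSE))
  sort(k)
}

# brute-force enumeration of codon edits reachable by converting any nonempty
# same-strand subset of source bases (oracle for aa_edit_candidates)
oracle_codon_edits <- function(codon, editor_source, editor_target) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(codon, "", fixed = TRUE)[[1L]]
  out <- list()
  for (strand in c("+", "-")) {
    src <- if (strand == "+") editor_source else comp[[editor_source]]
    tgt <- if (strand == "+") editor_target else comp[[editor_target]]
    pos <- which(chars == src)
    if (!length(pos)) next
    for (mask in seq_len(2^length(pos) - 1L)) {
      subset <- pos[bitwAnd(mask, 2^(seq_along(pos) - 1L)) > 0L]
      edited <- chars
      edited[subset] <- tgt
      out[[length(out) + 1L]] <- list(strand = strand, positions = subset,
                                      edited = paste(edited, collapse = ""))
    }
  }
  out
}

# small hand-made genome bundle
tiny_bundle <- function(seqs, genes = NULL, transcripts = list()) {
  if (is.null(genes)) {
    genome_bundle(seqs, transcripts = transcripts)
  } else {
    genome_bundle(seqs, genes = genes, transcripts = transcripts)
  }
}

# substitute plus-strand bases into a bundle copy (for edit replay)
replay_edit <- function(genome, chrom, positions, bases) {
  chars <- strsplit(genome$sequences[[chrom]], "", fixed = TRUE)[[1L]]
  chars[positions] <- bases
  genome$sequences[[chrom]] <- paste(chars, collapse = "")
  genome
}

# design the unique guide sitting exactly on a planted protospacer (plus
# strand, NGG) for a C>T request at the spacer's first C
planted_guide <- function(genome, spacer, start, chrom = "chr1") {
  cfg <- run_config(editors = list(base_editor("Target-AID", "C", "T", 2, 4)),
                    pams = list(pam_spec("NGG", "NGG")))
  coff <- regexpr("C", spacer)[1]
  req <- data.frame(request_id = "r1", chromosome = chrom,
                    position = start + coff - 1L,
                    ref_base = "C", alt_base = "T", format = "nucleotide",
                    stringsAsFactors = FALSE)
  des <- design_guides(req, genome, cfg)
  lib <- des$library
  lib[lib$protospacer_start == start & lib$strand == "+", ][1, ]
}

# spliced CDS translation using only exported accessors
translate_cds_str <- function(genome, tx) {
  cds <- paste(vapply(seq_len(nrow(tx$cds_exons)), function(i) {
    fetch_sequence(genome, tx$chromosome, tx$cds_exons$start[i], tx$cds_exons$end[i],
                   tx$strand)
  }, character(1L)), collapse = "")
  n <- nchar(cds)
  unname(Biostrings::GENETIC_CODE[substring(cds, seq(1, n, 3), seq(3, n, 3))])
}

split_ints <- function(s) {
  if (is.na(s) || !nzchar(s)) integer(0L) else as.integer(strsplit(s, ",")[[1L]])
}

split_chars <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0L) else strsplit(s, ",")[[1L]]
}
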