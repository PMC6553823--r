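empty_alignment_table <- function() {
  data.frame(guide_id = character(), chromosome = character(), start = integer(),
             end = integer(), strand = character(), n_mismatches = integer(),
             mismatch_offsets = character(), region = character(),
             is_intended_target = logical(), stringsAsFactors = FALSE)
}

# convert spacer 5'-end 1-based offsets to PAM-distal 1-based numbering
to_pam_distal <- function(off5, guide_length, pam_side) {
  if (pam_side == "three_prime") off5 else guide_length - off5 + 1L
}

#' Distance from the PAM of mismatched spacer positions
#'
#' Spacer offsets are stored PAM-distal 1-based throughout, so the distance
#' of position `i` from the PAM is `guide_length - i + 1` for either PAM
#' side: for a 5' PAM the position-wise penalty vector is thereby read in
#' reversed order relative to a 3' PAM, as the scoring system requires.
#'
#' @param mismatch_offsets integer vector, PAM-distal 1-based.
#' @param guide_length spacer length.
#' @param pam_side `"three_prime"` or `"five_prime"` (the offset convention
#'   already encodes the side; the argument documents intent).
#' @return integer distances, 1 = adjacent to the PAM.
#' @export
mismatch_distances <- function(mismatch_offsets, guide_length,
                               pam_side = "three_prime") {
  guide_length - as.integer(mismatch_offsets) + 1L
}

# observed PAM at a placement, read on the guide strand; NULL if off-limits
observed_pam <- function(seq, chrom_len, a, e, strand, side, pl) {
  r <- if ((side == "three_prime") == (strand == "+")) c(e + 1L, e + pl) else c(a - pl, a - 1L)
  if (r[1L] < 1L || r[2L] > chrom_len) return(NULL)
  s <- substr(seq, r[1L], r[2L])
  if (strand == "-") reverse_complement(s) else s
}

#' Genome-wide off-target search for one guide
#'
#' Returns every placement, on both strands of every chromosome, where the
#' adjacent PAM matches its IUPAC pattern exactly (PAM mismatches are never
#' tolerated nor counted towards the budget) and the spacer differs from the
#' site by at most `max_mismatches` substitutions (Hamming distance; no
#' indels). The search runs on `Biostrings::matchPattern()`. The placement
#' at the guide's own coordinates and strand is flagged
#' `is_intended_target = TRUE` and is excluded from scoring downstream; if
#' the search fails to recover it an integrity error is raised (unless its
#' mismatch count exceeds the budget, e.g. a correct-mode guide carrying the
#' alternative allele under a zero budget, in which case it is appended
#' explicitly).
#'
#' @param genome a [genome_bundle()].
#' @param guide single-row guide data.frame (needs `guide_id`, `spacer`,
#'   `chromosome`, `protospacer_start`, `protospacer_end`, `strand`).
#' @param pam the [pam_spec()] the guide was designed with.
#' @param max_mismatches spacer mismatch budget (PAM excluded).
#' @return data.frame of alignments: `guide_id`, `chromosome`, `start`,
#'   `end` (protospacer, 1-based inclusive), `strand`, `n_mismatches`,
#'   `mismatch_offsets` (comma-joined, PAM-distal 1-based), `region`,
#'   `is_intended_target`.
#' @export
find_alignments <- function(genome, guide, pam, max_mismatches = 2L) {
  spacer <- guide$spacer
  L <- nchar(spacer)
  if (L < 1L) abort("empty spacer", "bedesign_contract_error")
  pl <- pam_length(pam)
  spacer_chars <- strsplit(spacer, "", fixed = TRUE)[[1L]]
  rc_spacer <- reverse_complement(spacer)
  rows <- list()
  for (chrom in names(genome$sequences)) {
    seq <- genome$sequences[[chrom]]
    clen <- genome$lengths[[chrom]]
    subject <- Biostrings::DNAString(seq)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") spacer else rc_spacer
      hits <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mismatches,
                                       with.indels = FALSE, fixed = TRUE)
      for (h in seq_along(hits)) {
        a <- Biostrings::start(hits)[h]
        e <- Biostrings::end(hits)[h]
        pam_obs <- observed_pam(seq, clen, a, e, strand, pam$side, pl)
        if (is.null(pam_obs) || grepl("N", pam_obs) || !pam_matches(pam$pattern, pam_obs)) next
        site <- substr(seq, a, e)
        site_guide <- if (strand == "-") reverse_complement(site) else site
        off5 <- which(strsplit(site_guide, "", fixed = TRUE)[[1L]] != spacer_chars)
        rows[[length(rows) + 1L]] <- data.frame(
          guide_id = guide$guide_id, chromosome = chrom, start = a, end = e,
          strand = strand, n_mismatches = length(off5),
          mismatch_offsets = paste(to_pam_distal(off5, L, pam$side), collapse = ","),
          region = classify_region(genome, chrom, a, e),
          is_intended_target = (chrom == guide$chromosome &&
                                  a == guide$protospacer_start &&
                                  e == guide$protospacer_end &&
                                  strand == guide$strand),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else empty_alignment_table()
  if (!any(out$is_intended_target)) {
    # recover the intended placement directly and decide whether the search
    # legitimately missed it (over-budget) or is inconsistent
    site <- fetch_sequence(genome, guide$chromosome, guide$protospacer_start,
                           guide$protospacer_end, guide$strand)
    off5 <- which(strsplit(site, "", fixed = TRUE)[[1L]] != spacer_chars)
    if (length(off5) <= max_mismatches) {
      abort(sprintf("intended target of guide %s not recovered by the search (internal inconsistency)",
                    guide$guide_id), "bedesign_integrity_error")
    }
    out <- rbind(out, data.frame(
      guide_id = guide$guide_id, chromosome = guide$chromosome,
      start = guide$protospacer_start, end = guide$protospacer_end,
      strand = guide$strand, n_mismatches = length(off5),
      mismatch_offsets = paste(to_pam_distal(off5, L, pam$side), collapse = ","),
      region = classify_region(genome, guide$chromosome, guide$protospacer_start,
                               guide$protospacer_end),
      is_intended_target = TRUE, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
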