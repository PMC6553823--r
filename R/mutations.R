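NUC_COLUMNS <- c("chromosome", "position", "ref_base", "alt_base")
AA_COLUMNS <- c("transcript_id", "residue_position", "ref_residue", "alt_residue")

#' Parse a mutation request table
#'
#' Reads one of the two tab-separated mutation dialects. Nucleotide format
#' columns: `request_id` (optional), `chromosome`, `position`, `ref_base`,
#' `alt_base`. Amino-acid format columns: `request_id` (optional),
#' `transcript_id`, `residue_position`, `ref_residue`, `alt_residue`. Lines
#' starting with `#` are ignored. Malformed rows are not silently dropped:
#' they are collected into a rejects table with a reason per row.
#'
#' @param path TSV file path.
#' @param format `"nucleotide"` or `"amino_acid"`.
#' @return list with `requests` (valid rows, with `format` column and
#'   row-derived `request_id` when none given) and `rejects`
#'   (`row`, `request_id`, `reason`).
#' @export
parse_mutation_table <- function(path, format = c("nucleotide", "amino_acid")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("mutation table not found: %s", path),
                                "bedesign_input_error")
  # all-character read: base columns holding a bare "T" must not turn logical
  df <- tryCatch(read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                            colClasses = "character"),
                 error = function(e) abort(sprintf("cannot read mutation table: %s",
                                                   conditionMessage(e)),
                                           "bedesign_format_error"))
  if (nrow(df) == 0L && ncol(df) == 0L) {
    abort("mutation table is empty", "bedesign_format_error")
  }
  need <- if (format == "nucleotide") NUC_COLUMNS else AA_COLUMNS
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("mutation table missing required column(s): %s",
                  paste(miss, collapse = ", ")), "bedesign_format_error")
  }
  if (!"request_id" %in% names(df)) df$request_id <- sprintf("row%d", seq_len(nrow(df)))
  df$request_id <- as.character(df$request_id)

  reasons <- character(nrow(df))
  if (format == "nucleotide") {
    df$ref_base <- toupper(as.character(df$ref_base))
    df$alt_base <- toupper(as.character(df$alt_base))
    pos <- suppressWarnings(as.integer(df$position))
    bad_pos <- is.na(pos) | pos < 1L
    reasons[bad_pos] <- "invalid position"
    bad_base <- !(df$ref_base %in% DNA_BASES) | !(df$alt_base %in% DNA_BASES)
    reasons[bad_base & reasons == ""] <- "invalid base"
    noop <- df$ref_base == df$alt_base
    reasons[noop & reasons == ""] <- "no-op substitution"
    df$position <- pos
  } else {
    df$ref_residue <- toupper(as.character(df$ref_residue))
    df$alt_residue <- toupper(as.character(df$alt_residue))
    rp <- suppressWarnings(as.integer(df$residue_position))
    bad_pos <- is.na(rp) | rp < 1L
    reasons[bad_pos] <- "invalid residue position"
    bad_res <- !(df$ref_residue %in% AA_SYMBOLS) | !(df$alt_residue %in% AA_SYMBOLS)
    reasons[bad_res & reasons == ""] <- "invalid residue"
    noop <- df$ref_residue == df$alt_residue
    reasons[noop & reasons == ""] <- "no-op substitution"
    df$residue_position <- rp
  }
  keep <- reasons == ""
  requests <- df[keep, c("request_id", need), drop = FALSE]
  requests$format <- format
  rownames(requests) <- NULL
  rejects <- data.frame(row = which(!keep),
                        request_id = df$request_id[!keep],
                        reason = reasons[!keep], stringsAsFactors = FALSE)
  list(requests = requests, rejects = rejects)
}

#' Validate a mutation request against the genome
#'
#' Nucleotide form: the genome base at the stated coordinate must equal
#' `ref_base`. Amino-acid form: the transcript must exist and its translated
#' codon at `residue_position` must equal `ref_residue`.
#'
#' @param req single-row data.frame (one parsed request).
#' @param genome a [genome_bundle()].
#' @return list with `ok` (logical) and, on failure, `reason`.
#' @export
validate_request <- function(req, genome) {
  fail <- function(reason) list(ok = FALSE, reason = reason)
  if (req$format == "nucleotide") {
    if (!req$chromosome %in% names(genome$sequences)) {
      return(fail(sprintf("unknown chromosome '%s'", req$chromosome)))
    }
    if (req$position > genome$lengths[[req$chromosome]]) {
      return(fail(sprintf("position %d beyond chromosome '%s'", req$position, req$chromosome)))
    }
    obs <- substr(genome$sequences[[req$chromosome]], req$position, req$position)
    if (obs != req$ref_base) {
      return(fail(sprintf("reference mismatch: expected %s observed %s", req$ref_base, obs)))
    }
  } else {
    tx <- genome$transcripts[[req$transcript_id]]
    if (is.null(tx)) return(fail(sprintf("transcript not found: %s", req$transcript_id)))
    n_codons <- tx$cds_length %/% 3L
    if (req$residue_position > n_codons) {
      return(fail(sprintf("residue position %d beyond CDS (%d codons)",
                          req$residue_position, n_codons)))
    }
    obs <- translate_codon(codon_at(genome, tx, req$residue_position))
    if (obs != req$ref_residue) {
      return(fail(sprintf("reference mismatch: expected %s observed %s",
                          req$ref_residue, obs)))
    }
  }
  list(ok = TRUE)
}

#' Enumerate codon edits reaching a target residue with one base editor
#'
#' A base editor converts its source base wherever it sits in the activity
#' window, so a codon containing several source bases may have any nonempty
#' subset of them converted at once. This enumerates, for both presentation
#' strands of the codon, every such subset, applies the conversion, and
#' keeps the plans whose edited codon translates to `target_residue`. On the
#' `"+"` (sense) presentation a C->T editor converts codon Cs to T; on the
#' `"-"` presentation it acts on the antisense strand, i.e. G->A on the
#' sense codon.
#'
#' @param codon sense-strand codon (3-mer over A/C/G/T).
#' @param target_residue desired residue symbol (may be `"*"`).
#' @param editor a [base_editor()].
#' @return data.frame of plans with columns `positions` (comma-joined codon
#'   positions 1..3 assumed converted), `strand` (presentation strand
#'   relative to the codon's sense strand), `original_codon`, `edited_codon`,
#'   `resulting_residue`. Zero rows when the residue is unreachable.
#' @export
aa_edit_candidates <- function(codon, target_residue, editor) {
  assert_dna(codon, allow_n = FALSE, what = "codon")
  if (nchar(codon) != 3L) abort("codon must have length 3", "bedesign_contract_error")
  if (!target_residue %in% AA_SYMBOLS) {
    abort(sprintf("invalid residue '%s'", target_residue), "bedesign_contract_error")
  }
  chars <- strsplit(codon, "", fixed = TRUE)[[1L]]
  plans <- list()
  for (strand in c("+", "-")) {
    src <- if (strand == "+") editor$source_base else complement_base(editor$source_base)
    tgt <- if (strand == "+") editor$target_base else complement_base(editor$target_base)
    editable <- which(chars == src)
    if (!length(editable)) next
    # nonempty subsets of editable codon positions, all converted on one strand
    for (k in seq_along(editable)) {
      # combn() over indices: a length-1 `editable` must not be read as 1:n
      combos <- lapply(utils::combn(seq_along(editable), k, simplify = FALSE),
                       function(ix) editable[ix])
      for (subset in combos) {
        edited <- chars
        edited[subset] <- tgt
        edited_codon <- paste(edited, collapse = "")
        if (translate_codon(edited_codon) == target_residue) {
          plans[[length(plans) + 1L]] <- data.frame(
            positions = paste(subset, collapse = ","), strand = strand,
            original_codon = codon, edited_codon = edited_codon,
            resulting_residue = target_residue, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(plans)) {
    return(data.frame(positions = character(), strand = character(),
                      original_codon = character(), edited_codon = character(),
                      resulting_residue = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(plans, list(make.row.names = FALSE)))
}

#' Filter codon edit plans by substitution matrix and mutation class
#'
#' @param plans data.frame from [aa_edit_candidates()].
#' @param ref_residue the residue being edited away from (the reference
#'   residue in model mode, the alternative residue in correct mode).
#' @param matrix optional allow-list: data.frame with columns `from`, `to`;
#'   plans whose (`ref_residue`, `resulting_residue`) pair is absent are
#'   dropped.
#' @param mutation_class `"any"`, `"nonsynonymous"` (resulting residue must
#'   differ from `ref_residue`) or `"synonymous"` (must be identical).
#' @return the filtered plans.
#' @export
apply_filters <- function(plans, ref_residue, matrix = NULL,
                          mutation_class = c("any", "nonsynonymous", "synonymous")) {
  mutation_class <- match.arg(mutation_class)
  if (!is.null(matrix)) {
    matrix <- as.data.frame(matrix)
    if (!all(c("from", "to") %in% names(matrix))) {
      abort("substitution matrix needs columns 'from' and 'to'", "bedesign_config_error")
    }
    bad <- !(matrix$from %in% AA_SYMBOLS) | !(matrix$to %in% AA_SYMBOLS)
    if (any(bad)) {
      abort(sprintf("substitution matrix references invalid residue ('%s' -> '%s')",
                    matrix$from[bad][1L], matrix$to[bad][1L]), "bedesign_config_error")
    }
  }
  if (!nrow(plans)) return(plans)
  keep <- rep(TRUE, nrow(plans))
  if (!is.null(matrix)) {
    keep <- keep & paste(ref_residue, plans$resulting_residue) %in%
      paste(matrix$from, matrix$to)
  }
  if (mutation_class == "synonymous") {
    keep <- keep & plans$resulting_residue == ref_residue
  } else if (mutation_class == "nonsynonymous") {
    keep <- keep & plans$resulting_residue != ref_residue
  }
  plans[keep, , drop = FALSE]
}

#' Reconstruct the mutant codon carried by an alternative allele
#'
#' In "correct" mode amino-acid input the genome holds the reference codon
#' but the background to be reverted carries `alt_residue`. The mutant codon
#' is taken as the codon encoding `alt_residue` at minimal Hamming distance
#' from the reference codon, ties broken lexicographically.
#'
#' @param ref_codon sense-strand reference codon.
#' @param alt_residue residue encoded by the alternative allele.
#' @return the reconstructed 3-mer.
#' @export
reconstruct_mutant_codon <- function(ref_codon, alt_residue) {
  assert_dna(ref_codon, allow_n = FALSE, what = "codon")
  cands <- sort(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == alt_residue])
  if (!length(cands)) {
    abort(sprintf("no codon encodes residue '%s'", alt_residue), "bedesign_contract_error")
  }
  rc <- strsplit(ref_codon, "", fixed = TRUE)[[1L]]
  dist <- vapply(cands, function(cd) {
    sum(strsplit(cd, "", fixed = TRUE)[[1L]] != rc)
  }, integer(1L))
  cands[which.min(dist)]  # ties: first of the lexicographic sort
}
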