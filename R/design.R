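flip_strand <- function(s) ifelse(s == "+", "-", "+")

empty_guide_table <- function() {
  data.frame(guide_id = character(), request_id = character(), editor = character(),
             pam = character(), chromosome = character(), protospacer_start = integer(),
             protospacer_end = integer(), strand = character(), spacer = character(),
             pam_observed = character(), edited_offset = integer(), in_window = logical(),
             bystander_offsets = character(), polyT_length = integer(),
             target_positions = character(), edited_bases_plus = character(),
             original_codon = character(), edited_codon = character(),
             resulting_residue = character(), stringsAsFactors = FALSE)
}

# A design context: the local genomic sequence a request is designed
# against (reference flank in model mode, allele-substituted flank in
# correct mode), plus the plus-strand positions that must be edited, their
# pre-/post-edit plus-strand bases, and the genomic strand presenting the
# editor's source base.
design_context <- function(chromosome, ctx_start, ctx_seq, edit_strand, targets,
                           request_id, editor_name,
                           original_codon = NA_character_,
                           edited_codon = NA_character_,
                           resulting_residue = NA_character_) {
  structure(list(chromosome = chromosome, ctx_start = as.integer(ctx_start),
                 ctx_seq = ctx_seq, edit_strand = edit_strand,
                 targets = targets, request_id = request_id,
                 editor_name = editor_name, original_codon = original_codon,
                 edited_codon = edited_codon, resulting_residue = resulting_residue),
            class = "design_context")
}

# strand on which `editor` presents the conversion from -> to (plus-strand
# bases); NULL when the chemistry cannot produce it
conversion_strand <- function(editor, from, to) {
  if (from == editor$source_base && to == editor$target_base) return("+")
  if (complement_base(from) == editor$source_base &&
      complement_base(to) == editor$target_base) return("-")
  NULL
}

#' Build design context(s) for a validated mutation request
#'
#' In `"model"` mode the context is the reference flank around the target
#' and the designed edit is ref -> alt; in `"correct"` mode the context is
#' the reference flank with the alternative allele substituted at the
#' target, and the designed edit is alt -> ref. For amino-acid requests one
#' context is produced per reachable codon edit plan (see
#' [aa_edit_candidates()]); in correct mode the mutant codon is first
#' reconstructed with [reconstruct_mutant_codon()].
#'
#' @param req single-row parsed request.
#' @param genome a [genome_bundle()].
#' @param cfg a [run_config()].
#' @param editor the [base_editor()] being designed for.
#' @return list with `contexts` (possibly empty list of design contexts)
#'   and `reason` (character reason when empty).
#' @export
build_design_context <- function(req, genome, cfg, editor) {
  fl <- cfg$guide_length + max_pam_length(cfg$pams) + 2L
  if (req$format == "nucleotide") {
    pos <- req$position
    if (cfg$mode == "model") {
      from <- req$ref_base; to <- req$alt_base
    } else {
      from <- req$alt_base; to <- req$ref_base
    }
    strand <- conversion_strand(editor, from, to)
    if (is.null(strand)) {
      return(list(contexts = list(),
                  reason = "conversion not offered by any configured editor"))
    }
    clen <- genome$lengths[[req$chromosome]]
    cs <- max(1L, pos - fl); ce <- min(clen, pos + fl)
    ctx <- fetch_sequence(genome, req$chromosome, cs, ce, "+")
    if (cfg$mode == "correct") {
      ctx <- substr_replace(ctx, pos - cs + 1L, from)
    }
    targets <- data.frame(position = pos, expected_base_plus = from,
                          edited_base_plus = to, stringsAsFactors = FALSE)
    return(list(contexts = list(design_context(req$chromosome, cs, ctx, strand,
                                               targets, req$request_id, editor$name)),
                reason = NULL))
  }
  # amino-acid request
  tx <- genome$transcripts[[req$transcript_id]]
  loc <- codon_genomic_location(tx, req$residue_position)
  ref_codon <- codon_at(genome, tx, req$residue_position)
  if (cfg$mode == "model") {
    start_codon <- ref_codon
    plans <- aa_edit_candidates(start_codon, req$alt_residue, editor)
    plans <- apply_filters(plans, req$ref_residue, cfg$substitution_matrix,
                           cfg$mutation_class)
  } else {
    start_codon <- reconstruct_mutant_codon(ref_codon, req$alt_residue)
    plans <- aa_edit_candidates(start_codon, req$ref_residue, editor)
    plans <- apply_filters(plans, req$alt_residue, cfg$substitution_matrix,
                           cfg$mutation_class)
  }
  if (!nrow(plans)) {
    return(list(contexts = list(),
                reason = "conversion not offered by any configured editor"))
  }
  clen <- genome$lengths[[tx$chromosome]]
  span <- range(loc$position)
  contexts <- list()
  junction_dropped <- FALSE
  for (i in seq_len(nrow(plans))) {
    plan <- plans[i, ]
    idx <- as.integer(strsplit(plan$positions, ",")[[1L]])
    gpos <- loc$position[idx]
    if (max(gpos) - min(gpos) + 1L > cfg$guide_length) {
      junction_dropped <- TRUE  # split codon too wide for a contiguous spacer
      next
    }
    cs <- max(1L, span[1L] - fl); ce <- min(clen, span[2L] + fl)
    ctx <- fetch_sequence(genome, tx$chromosome, cs, ce, "+")
    # place the designed-against codon (mutant in correct mode) into the context
    sc <- strsplit(start_codon, "", fixed = TRUE)[[1L]]
    ec <- strsplit(plan$edited_codon, "", fixed = TRUE)[[1L]]
    for (k in 1:3) {
      plus_base <- if (tx$strand == "+") sc[k] else complement_base(sc[k])
      ctx <- substr_replace(ctx, loc$position[k] - cs + 1L, plus_base)
    }
    strand <- if (tx$strand == "+") plan$strand else flip_strand(plan$strand)
    targets <- data.frame(
      position = gpos,
      expected_base_plus = vapply(idx, function(k) {
        if (tx$strand == "+") sc[k] else complement_base(sc[k])
      }, character(1L)),
      edited_base_plus = vapply(idx, function(k) {
        if (tx$strand == "+") ec[k] else complement_base(ec[k])
      }, character(1L)),
      stringsAsFactors = FALSE)
    contexts[[length(contexts) + 1L]] <- design_context(
      tx$chromosome, cs, ctx, strand, targets, req$request_id, editor$name,
      original_codon = start_codon, edited_codon = plan$edited_codon,
      resulting_residue = plan$resulting_residue)
  }
  if (!length(contexts)) {
    return(list(contexts = list(),
                reason = if (junction_dropped) {
                  "codon split across exons cannot host a contiguous protospacer"
                } else "conversion not offered by any configured editor"))
  }
  list(contexts = contexts, reason = NULL)
}

#' Enumerate candidate protospacer placements for a design context
#'
#' Returns every spacer placement where (a) all target bases occupy spacer
#' positions, (b) the adjacent PAM matches its IUPAC pattern on the same
#' strand, and (c) the strand presents the editor's source base at every
#' target. Out-of-window placements are emitted too, flagged
#' `in_window = FALSE`: the score, not the enumerator, penalizes them.
#' Placements whose spacer or PAM contains an ambiguous genome base (N) are
#' discarded.
#'
#' @param genome a [genome_bundle()] (for chromosome bounds).
#' @param context a design context from [build_design_context()].
#' @param editor the [base_editor()].
#' @param pam a [pam_spec()].
#' @param guide_length spacer length.
#' @return list with `candidates` (guide table rows) and `reason` (set when
#'   empty).
#' @export
scan_protospacers <- function(genome, context, editor, pam, guide_length) {
  L <- guide_length
  pl <- pam_length(pam)
  ctx <- context$ctx_seq
  cs <- context$ctx_start
  ce <- cs + nchar(ctx) - 1L
  strand <- context$edit_strand
  tg <- context$targets
  src_plus <- if (strand == "+") editor$source_base else complement_base(editor$source_base)
  local <- function(p) p - cs + 1L
  obs <- vapply(tg$position, function(p) substr(ctx, local(p), local(p)), character(1L))
  if (any(obs != src_plus)) {
    return(list(candidates = empty_guide_table(), reason = "no editable presentation"))
  }
  g_min <- min(tg$position); g_max <- max(tg$position)
  rows <- list()
  for (a in (g_max - L + 1L):g_min) {
    e <- a + L - 1L
    if (a < cs || e > ce) next
    spacer_plus <- substr(ctx, local(a), local(e))
    if (grepl("N", spacer_plus)) next
    pam_obs <- observed_pam_ctx(ctx, cs, ce, a, e, strand, pam$side, pl)
    if (is.null(pam_obs) || grepl("N", pam_obs) || !pam_matches(pam$pattern, pam_obs)) next
    spacer <- if (strand == "-") reverse_complement(spacer_plus) else spacer_plus
    off5 <- if (strand == "+") tg$position - a + 1L else e - tg$position + 1L
    off_pd <- to_pam_distal(off5, L, pam$side)
    in_window <- all(off_pd >= editor$window_start & off_pd <= editor$window_end)
    sp_chars <- strsplit(spacer, "", fixed = TRUE)[[1L]]
    src_at5 <- which(sp_chars == editor$source_base)
    by_pd <- setdiff(to_pam_distal(src_at5, L, pam$side), off_pd)
    by_pd <- sort(by_pd[by_pd >= editor$window_start & by_pd <= editor$window_end])
    rows[[length(rows) + 1L]] <- data.frame(
      guide_id = sprintf("%s|%s|%s|%s:%d-%d(%s)t%s", context$request_id, editor$name,
                         pam$name, context$chromosome, a, e, strand,
                         paste(tg$position, collapse = "+")),
      request_id = context$request_id, editor = editor$name, pam = pam$name,
      chromosome = context$chromosome, protospacer_start = a, protospacer_end = e,
      strand = strand, spacer = spacer, pam_observed = pam_obs,
      edited_offset = off_pd[1L], in_window = in_window,
      bystander_offsets = paste(by_pd, collapse = ","),
      polyT_length = annotate_polyT(spacer),
      target_positions = paste(tg$position, collapse = ","),
      edited_bases_plus = paste(tg$edited_base_plus, collapse = ","),
      original_codon = context$original_codon, edited_codon = context$edited_codon,
      resulting_residue = context$resulting_residue,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(list(candidates = empty_guide_table(),
                reason = "no protospacer placement with a matching PAM"))
  }
  list(candidates = do.call(rbind, c(rows, list(make.row.names = FALSE))), reason = NULL)
}

# PAM read from the context string (honours allele substitutions near the
# protospacer in correct mode); NULL when the PAM falls outside the context
observed_pam_ctx <- function(ctx, cs, ce, a, e, strand, side, pl) {
  r <- if ((side == "three_prime") == (strand == "+")) c(e + 1L, e + pl) else c(a - pl, a - 1L)
  if (r[1L] < cs || r[2L] > ce) return(NULL)
  s <- substr(ctx, r[1L] - cs + 1L, r[2L] - cs + 1L)
  if (strand == "-") reverse_complement(s) else s
}

#' Design guides for a set of validated requests
#'
#' Runs [build_design_context()] and [scan_protospacers()] for every
#' (request, editor, PAM) combination. Every input request lands either in
#' the returned library (at least one guide) or in the unreachable report
#' with a reason code; nothing is silently dropped.
#'
#' @param requests parsed request table (see [parse_mutation_table()]).
#' @param genome a [genome_bundle()].
#' @param cfg a [run_config()].
#' @return list with `library` (guide candidate table) and `unreachable`
#'   (`request_id`, `reason`).
#' @export
design_guides <- function(requests, genome, cfg) {
  lib <- list()
  unreach <- list()
  for (i in seq_len(nrow(requests))) {
    req <- requests[i, ]
    v <- validate_request(req, genome)
    if (!v$ok) {
      unreach[[length(unreach) + 1L]] <- data.frame(
        request_id = req$request_id, reason = v$reason, stringsAsFactors = FALSE)
      next
    }
    cand <- list()
    reasons <- character(0L)
    for (editor in cfg$editors) {
      bc <- build_design_context(req, genome, cfg, editor)
      if (!length(bc$contexts)) {
        reasons <- c(reasons, bc$reason)
        next
      }
      for (ctx in bc$contexts) {
        for (pam in cfg$pams) {
          sc <- scan_protospacers(genome, ctx, editor, pam, cfg$guide_length)
          if (nrow(sc$candidates)) {
            cand[[length(cand) + 1L]] <- sc$candidates
          } else {
            reasons <- c(reasons, sc$reason)
          }
        }
      }
    }
    if (length(cand)) {
      rows <- do.call(rbind, c(cand, list(make.row.names = FALSE)))
      lib[[length(lib) + 1L]] <- rows[!duplicated(rows$guide_id), , drop = FALSE]
    } else {
      # most informative reason wins: chemistry mismatch < presentation < geometry
      reason <- if ("no editable presentation" %in% reasons) {
        "no editable presentation"
      } else if ("no protospacer placement with a matching PAM" %in% reasons) {
        "no protospacer placement with a matching PAM"
      } else if (length(reasons)) reasons[1L] else "no candidate guides"
      unreach[[length(unreach) + 1L]] <- data.frame(
        request_id = req$request_id, reason = reason, stringsAsFactors = FALSE)
    }
  }
  library <- if (length(lib)) do.call(rbind, c(lib, list(make.row.names = FALSE)))
             else empty_guide_table()
  unreachable <- if (length(unreach)) do.call(rbind, c(unreach, list(make.row.names = FALSE)))
                 else data.frame(request_id = character(), reason = character(),
                                 stringsAsFactors = FALSE)
  list(library = library, unreachable = unreachable)
}

#' Design positive-control guides (nonsense mutations)
#'
#' Positive controls convert a codon of the transcript of interest to a stop
#' codon with an in-window edit, so successful editing truncates the protein
#' and gives a measurable phenotype. Residues are scanned in ascending
#' position order; up to `n` in-window guides are returned.
#'
#' @param tx a [transcript_model()].
#' @param genome a [genome_bundle()].
#' @param editor,pam the editor/PAM combination to design for.
#' @param cfg a [run_config()].
#' @param n maximum number of control guides.
#' @return guide table (possibly empty, with a message when no
#'   stop-reachable codon has a usable PAM).
#' @export
design_positive_controls <- function(tx, genome, editor, pam, cfg, n = 10L) {
  out <- list()
  n_codons <- tx$cds_length %/% 3L
  for (rp in seq_len(max(0L, n_codons - 1L))) {
    if (length(out) >= n) break
    codon <- codon_at(genome, tx, rp)
    if (translate_codon(codon) == "*") next
    plans <- aa_edit_candidates(codon, "*", editor)
    if (!nrow(plans)) next
    loc <- codon_genomic_location(tx, rp)
    fl <- cfg$guide_length + max_pam_length(cfg$pams) + 2L
    for (i in seq_len(nrow(plans))) {
      if (length(out) >= n) break
      plan <- plans[i, ]
      idx <- as.integer(strsplit(plan$positions, ",")[[1L]])
      gpos <- loc$position[idx]
      if (max(gpos) - min(gpos) + 1L > cfg$guide_length) next
      clen <- genome$lengths[[tx$chromosome]]
      cs <- max(1L, min(loc$position) - fl); ce <- min(clen, max(loc$position) + fl)
      strand <- if (tx$strand == "+") plan$strand else flip_strand(plan$strand)
      sc3 <- strsplit(codon, "", fixed = TRUE)[[1L]]
      ec3 <- strsplit(plan$edited_codon, "", fixed = TRUE)[[1L]]
      targets <- data.frame(
        position = gpos,
        expected_base_plus = vapply(idx, function(k) {
          if (tx$strand == "+") sc3[k] else complement_base(sc3[k])
        }, character(1L)),
        edited_base_plus = vapply(idx, function(k) {
          if (tx$strand == "+") ec3[k] else complement_base(ec3[k])
        }, character(1L)),
        stringsAsFactors = FALSE)
      ctxobj <- design_context(tx$chromosome, cs,
                               fetch_sequence(genome, tx$chromosome, cs, ce, "+"),
                               strand, targets,
                               sprintf("posctrl_%s_r%d", tx$transcript_id, rp),
                               editor$name, codon, plan$edited_codon, "*")
      sc <- scan_protospacers(genome, ctxobj, editor, pam, cfg$guide_length)
      keep <- sc$candidates[sc$candidates$in_window, , drop = FALSE]
      if (nrow(keep)) out[[length(out) + 1L]] <- keep[1L, , drop = FALSE]
    }
  }
  if (!length(out)) {
    message(sprintf("no stop-reachable codon with a usable PAM in %s for editor %s",
                    tx$transcript_id, editor$name))
    return(empty_guide_table())
  }
  do.call(rbind, c(head(out, n), list(make.row.names = FALSE)))
}

# regex for PAM occurrences on the plus strand presenting a minus-strand PAM
revcomp_iupac <- function(pattern) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", pattern)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Design negative-control guides (no editable base in window)
#'
#' Negative controls are genome placements with a valid PAM whose activity
#' window contains zero occurrences of the editor's source base, so the
#' editor has nothing to edit and a null effect is expected. Candidate sites
#' are enumerated deterministically over the whole genome and `n` of them
#' are drawn with the given seed.
#'
#' @param genome a [genome_bundle()].
#' @param editor,pam the editor/PAM combination.
#' @param cfg a [run_config()].
#' @param n number of controls requested.
#' @param seed sampling seed.
#' @return guide table with up to `n` rows (fewer, with a warning, when the
#'   genome does not offer enough window-free sites).
#' @export
design_negative_controls <- function(genome, editor, pam, cfg, n = 10L, seed = 1L) {
  L <- cfg$guide_length
  pl <- pam_length(pam)
  win <- editor$window_start:editor$window_end
  found <- list()
  for (chrom in names(genome$sequences)) {
    seq <- genome$sequences[[chrom]]
    clen <- genome$lengths[[chrom]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pam$pattern else revcomp_iupac(pam$pattern)
      rx <- sub("\\$$", "", sub("^\\^", "", pam_pattern_regex(pat)))
      m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      for (p in as.integer(m)) {
        # protospacer coordinates implied by a PAM starting at plus position p
        a <- if ((pam$side == "three_prime") == (strand == "+")) p - L else p + pl
        e <- a + L - 1L
        if (a < 1L || e > clen) next
        spacer_plus <- substr(seq, a, e)
        if (grepl("N", spacer_plus)) next
        spacer <- if (strand == "-") reverse_complement(spacer_plus) else spacer_plus
        sp_chars <- strsplit(spacer, "", fixed = TRUE)[[1L]]
        src5 <- which(sp_chars == editor$source_base)
        if (any(to_pam_distal(src5, L, pam$side) %in% win)) next
        pam_obs <- observed_pam(seq, clen, a, e, strand, pam$side, pl)
        found[[length(found) + 1L]] <- data.frame(
          chromosome = chrom, protospacer_start = a, protospacer_end = e,
          strand = strand, spacer = spacer, pam_observed = pam_obs,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(found)) {
    warning(sprintf("no window-free site for editor %s with PAM %s in this genome",
                    editor$name, pam$name))
    return(empty_guide_table())
  }
  all <- do.call(rbind, c(found, list(make.row.names = FALSE)))
  all <- all[order(all$chromosome, all$protospacer_start, all$strand), , drop = FALSE]
  take <- min(n, nrow(all))
  if (take < n) {
    warning(sprintf("only %d of %d requested negative controls available", take, n))
  }
  sel <- with_seed(seed, all[sort(sample.int(nrow(all), take)), , drop = FALSE])
  out <- empty_guide_table()
  for (i in seq_len(nrow(sel))) {
    s <- sel[i, ]
    out <- rbind(out, data.frame(
      guide_id = sprintf("negctrl_%04d|%s|%s|%s:%d-%d(%s)", i, editor$name, pam$name,
                         s$chromosome, s$protospacer_start, s$protospacer_end, s$strand),
      request_id = sprintf("negctrl_%04d", i), editor = editor$name, pam = pam$name,
      chromosome = s$chromosome, protospacer_start = s$protospacer_start,
      protospacer_end = s$protospacer_end, strand = s$strand, spacer = s$spacer,
      pam_observed = s$pam_observed, edited_offset = NA_integer_, in_window = NA,
      bystander_offsets = "", polyT_length = annotate_polyT(s$spacer),
      target_positions = "", edited_bases_plus = "",
      original_codon = NA_character_, edited_codon = NA_character_,
      resulting_residue = NA_character_, stringsAsFactors = FALSE))
  }
  out
}
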