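#' Default mismatch-tolerance table
#'
#' Position-wise mean mismatch tolerance of Cas9 binding as a function of
#' distance from the PAM, used to fit the cubic position-penalty curve. The
#' bundled table is a monotone synthetic stand-in with the empirically
#' established shape: mismatches adjacent to the PAM are poorly tolerated
#' (small multiplier) and tolerance grows nonlinearly towards the PAM-distal
#' end. Substitute your own `(distance, tolerance)` table to re-fit.
#'
#' @param p_min,p_max tolerance at distance 1 / at the distal end.
#' @param reference_guide_length number of distances tabulated.
#' @return data.frame with columns `distance`, `tolerance`.
#' @export
default_tolerance_table <- function(p_min = 0.01, p_max = 1.0,
                                    reference_guide_length = 20L) {
  d <- seq_len(reference_guide_length)
  data.frame(
    distance = d,
    tolerance = p_min + (p_max - p_min) * ((d - 1) / (reference_guide_length - 1))^2
  )
}

#' Fit the cubic position-penalty curve
#'
#' Least-squares fit of a third-degree polynomial in distance-from-PAM to a
#' mismatch-tolerance table. The fitted curve, clamped into
#' `[P_min, P_max]`, supplies the per-position mismatch penalty; fitting
#' (rather than table lookup) lets the curve be interpolated for guide
#' lengths other than the tabulated one.
#'
#' @param table data.frame with columns `distance`, `tolerance` (at least 4
#'   distinct distances).
#' @return numeric coefficient vector of length 4 (intercept, d, d^2, d^3).
#' @export
fit_penalty_curve <- function(table) {
  table <- as.data.frame(table)
  if (!all(c("distance", "tolerance") %in% names(table))) {
    abort("tolerance table needs columns 'distance' and 'tolerance'",
          "bedesign_config_error")
  }
  if (length(unique(table$distance)) < 4L) {
    abort("need >= 4 distinct distances to fit a cubic", "bedesign_fit_error")
  }
  fit <- lm(tolerance ~ distance + I(distance^2) + I(distance^3), data = table)
  unname(coef(fit))
}

#' Penalty model
#'
#' Holds every tunable of the multiplicative scoring system. All penalties
#' are MULTIPLIERS in (0, 1]: `P_min` is the small multiplier for
#' PAM-proximal mismatches (strongly penalized, since they are poorly
#' tolerated and the site stays active) and `P_max` the large multiplier for
#' PAM-distal ones. `G_g < G_ig` because genic off-target edits confound
#' downstream interpretation more than intergenic ones. `A_out` multiplies
#' guides whose editable base falls outside the activity window; `A_in`
#' (default 1) applies otherwise.
#'
#' @param position_tolerance_table `(distance, tolerance)` table fed to
#'   [fit_penalty_curve()]; defaults to [default_tolerance_table()].
#' @param P_min,P_max clamp bounds for the position penalty, in (0, 1].
#' @param G_g,G_ig genic / intergenic region multipliers, in (0, 1].
#' @param A_in,A_out in-window / out-of-window multipliers.
#' @param reference_guide_length spacer length the table refers to.
#' @return object of class `penalty_model`.
#' @export
penalty_model <- function(position_tolerance_table = NULL,
                          P_min = 0.01, P_max = 1.0,
                          G_g = 0.5, G_ig = 0.9,
                          A_in = 1.0, A_out = 0.5,
                          reference_guide_length = 20L) {
  for (v in c(P_min = P_min, P_max = P_max, G_g = G_g, G_ig = G_ig,
              A_in = A_in, A_out = A_out)) {
    if (!is.numeric(v) || v <= 0 || v > 1) {
      abort("all penalty multipliers must lie in (0, 1]", "bedesign_config_error")
    }
  }
  if (P_min > P_max) abort("P_min must be <= P_max", "bedesign_config_error")
  if (G_g > G_ig) {
    abort("G_g must be <= G_ig (genic off-targets are penalized harder)",
          "bedesign_config_error")
  }
  if (is.null(position_tolerance_table)) {
    position_tolerance_table <- default_tolerance_table(P_min, P_max,
                                                        reference_guide_length)
  }
  coefficients <- fit_penalty_curve(position_tolerance_table)
  structure(list(position_tolerance_table = as.data.frame(position_tolerance_table),
                 coefficients = coefficients,
                 P_min = P_min, P_max = P_max, G_g = G_g, G_ig = G_ig,
                 A_in = A_in, A_out = A_out,
                 reference_guide_length = as.integer(reference_guide_length)),
            class = "penalty_model")
}

#' @export
print.penalty_model <- function(x, ...) {
  cat(sprintf(paste0("<penalty_model> P in [%g, %g], G_g=%g, G_ig=%g, A_in=%g, A_out=%g\n",
                     "  cubic coefficients: %s\n"),
              x$P_min, x$P_max, x$G_g, x$G_ig, x$A_in, x$A_out,
              paste(signif(x$coefficients, 6), collapse = ", ")))
  invisible(x)
}

#' Position penalty for a mismatch at a given distance from the PAM
#'
#' Evaluates the fitted cubic at the distance, rescaled by
#' `reference_guide_length / guide_length` when the spacer is not the
#' tabulated length (so the curve spans any spacer), then clamps into
#' `[P_min, P_max]`.
#'
#' @param distance distance from the PAM, 1 = adjacent. Vectorised.
#' @param model a [penalty_model()].
#' @param guide_length spacer length in force.
#' @return penalty multiplier(s) in `[P_min, P_max]`.
#' @export
position_penalty <- function(distance, model, guide_length = model$reference_guide_length) {
  if (any(distance < 1 | distance > guide_length)) {
    abort(sprintf("distance out of range 1..%d", guide_length), "bedesign_contract_error")
  }
  d <- distance * model$reference_guide_length / guide_length
  co <- model$coefficients
  val <- co[1L] + co[2L] * d + co[3L] * d^2 + co[4L] * d^3
  pmin(pmax(val, model$P_min), min(model$P_max, 1))
}

#' Per-alignment mismatch penalty P_a
#'
#' Product of the position penalties of every mismatched nucleotide in an
#' off-target alignment; an alignment with zero mismatches has the empty
#' product 1 (its presence still penalizes through the region multiplier).
#'
#' @param mismatch_offsets integer vector of mismatched spacer positions,
#'   PAM-distal 1-based.
#' @param model a [penalty_model()].
#' @param guide_length spacer length.
#' @param pam_side PAM side of the spacer (kept for interface symmetry; the
#'   PAM-distal offset convention already absorbs the 5'-PAM reversal).
#' @return P_a in (0, 1].
#' @export
alignment_penalty <- function(mismatch_offsets, model, guide_length,
                              pam_side = "three_prime") {
  if (!length(mismatch_offsets)) return(1)
  d <- mismatch_distances(mismatch_offsets, guide_length, pam_side)
  prod(position_penalty(d, model, guide_length))
}

#' Region penalty G_a
#'
#' @param region `"genic"` or `"intergenic"` (vectorised).
#' @param model a [penalty_model()].
#' @return `G_g` for genic alignments, `G_ig` for intergenic ones.
#' @export
region_penalty <- function(region, model) {
  ifelse(region == "genic", model$G_g, model$G_ig)
}

#' Final multiplicative guide score
#'
#' The a priori guide quality score: over all off-target alignments `a`
#' other than the intended target, `B = prod(P_a * G_a) * A`, where `A` is
#' `A_in` when the editable base lies inside the editor's activity window
#' and `A_out` otherwise. An in-window guide with no off-target alignment
#' besides its own site scores exactly 1; every additional alignment and
#' every violated requirement multiplies the score down, so any suboptimal
#' criterion lowers it.
#'
#' @param guide single-row guide data.frame (needs `guide_id`, `in_window`).
#' @param alignments data.frame from [find_alignments()] for this guide.
#' @param model a [penalty_model()].
#' @param guide_length spacer length.
#' @param pam_side PAM side of the spacer.
#' @return object of class `score_breakdown`: list with `guide_id`,
#'   `n_alignments` (scored, intended site excluded), `per_alignment`
#'   (data.frame with `P_a`, `G_a`), `A_applied` and the final score `B`.
#' @export
guide_score <- function(guide, alignments, model, guide_length,
                        pam_side = "three_prime") {
  if (!any(alignments$is_intended_target)) {
    abort(sprintf("intended target of guide %s missing from its alignments (search inconsistency)",
                  guide$guide_id), "bedesign_integrity_error")
  }
  scored <- alignments[!alignments$is_intended_target, , drop = FALSE]
  P_a <- vapply(scored$mismatch_offsets, function(off) {
    alignment_penalty(parse_offsets(off), model, guide_length, pam_side)
  }, numeric(1L), USE.NAMES = FALSE)
  G_a <- region_penalty(scored$region, model)
  A <- if (isTRUE(guide$in_window)) model$A_in else model$A_out
  B <- prod(P_a * G_a) * A
  structure(list(guide_id = guide$guide_id, n_alignments = nrow(scored),
                 per_alignment = cbind(scored, P_a = P_a, G_a = G_a),
                 A_applied = A, B = B),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("<score_breakdown> %s: B = %.6g (%d scored alignment(s), A = %g)\n",
              x$guide_id, x$B, x$n_alignments, x$A_applied))
  invisible(x)
}

parse_offsets <- function(s) {
  if (is.na(s) || !nzchar(s)) integer(0L) else as.integer(strsplit(s, ",")[[1L]])
}

#' Score every guide of a library
#'
#' Runs the off-target search and [guide_score()] for each guide and appends
#' the scoring columns `n_offtargets`, `guide_score`, `A_applied`, `min_Pa`,
#' `worst_region` to the library table.
#'
#' @param library guide library data.frame from [design_guides()].
#' @param genome a [genome_bundle()].
#' @param cfg a [run_config()].
#' @return list with the scored `library` (sorted by request, descending
#'   score, coordinate, strand) and `alignments` (the full dump).
#' @export
score_library <- function(library, genome, cfg) {
  if (!nrow(library)) {
    library$n_offtargets <- integer(0L)
    library$guide_score <- numeric(0L)
    library$A_applied <- numeric(0L)
    library$min_Pa <- numeric(0L)
    library$worst_region <- character(0L)
    return(list(library = library, alignments = empty_alignment_table()))
  }
  aln_all <- vector("list", nrow(library))
  for (i in seq_len(nrow(library))) {
    g <- library[i, ]
    pam <- cfg$pams[[g$pam]]
    aln <- find_alignments(genome, g, pam, cfg$max_mismatches)
    br <- guide_score(g, aln, cfg$penalty_model, cfg$guide_length, pam$side)
    library$n_offtargets[i] <- br$n_alignments
    library$guide_score[i] <- br$B
    library$A_applied[i] <- br$A_applied
    scored <- br$per_alignment
    library$min_Pa[i] <- if (nrow(scored)) min(scored$P_a) else NA_real_
    library$worst_region[i] <- if (nrow(scored)) {
      if (any(scored$region == "genic")) "genic" else "intergenic"
    } else NA_character_
    aln_all[[i]] <- aln
  }
  o <- order(library$request_id, -library$guide_score, library$chromosome,
             library$protospacer_start, library$strand)
  library <- library[o, , drop = FALSE]
  rownames(library) <- NULL
  list(library = library,
       alignments = do.call(rbind, c(aln_all, list(make.row.names = FALSE))))
}
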