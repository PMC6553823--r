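#' Summarize editability of a request set
#'
#' Editability is the fraction of requested substitutions for which at least
#' one guide could be designed. Counts are reported per substitution pair
#' (e.g. `C>T` or `Q>*`) with the strand coverage of the designed guides
#' (`+`, `-` or `±`), plus an overall row including the mean number of
#' guides per editable request.
#'
#' @param requests parsed request table.
#' @param library designed guide table (any stage; only `request_id` and
#'   `strand` are consulted).
#' @return object of class `editability_summary`: list with
#'   `per_substitution` (data.frame) and `overall` (list).
#' @export
summarize_editability <- function(requests, library) {
  if (nrow(requests) && requests$format[1L] == "nucleotide") {
    pair <- paste0(requests$ref_base, ">", requests$alt_base)
  } else if (nrow(requests)) {
    pair <- paste0(requests$ref_residue, ">", requests$alt_residue)
  } else {
    pair <- character(0L)
  }
  guides_of <- split(library$strand, library$request_id)
  n_guides <- vapply(requests$request_id, function(id) {
    length(guides_of[[id]]) }, integer(1L), USE.NAMES = FALSE)
  editable <- n_guides > 0L
  per <- lapply(sort(unique(pair)), function(p) {
    sel <- pair == p
    strands <- sort(unique(unlist(guides_of[requests$request_id[sel & editable]])))
    data.frame(substitution = p,
               n_requested = sum(sel),
               n_editable = sum(sel & editable),
               pct_editability = 100 * sum(sel & editable) / sum(sel),
               strands_covered = if (!length(strands)) "" else
                 if (length(strands) == 2L) "±" else strands,
               stringsAsFactors = FALSE)
  })
  per <- if (length(per)) do.call(rbind, c(per, list(make.row.names = FALSE)))
         else data.frame(substitution = character(), n_requested = integer(),
                         n_editable = integer(), pct_editability = numeric(),
                         strands_covered = character(), stringsAsFactors = FALSE)
  overall <- list(
    n_requests = nrow(requests),
    n_editable = sum(editable),
    pct_editability = if (nrow(requests)) 100 * sum(editable) / nrow(requests) else 0,
    guides_per_mutation = if (any(editable)) mean(n_guides[editable]) else NA_real_)
  structure(list(per_substitution = per, overall = overall),
            class = "editability_summary")
}

#' @export
print.editability_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<editability_summary> %d/%d requests editable (%.1f%%), %.2f guides per editable request\n",
              o$n_editable, o$n_requests, o$pct_editability,
              o$guides_per_mutation))
  invisible(x)
}

# tidy per-(editor, PAM, strand) guide counts
summarize_by_combination <- function(library) {
  if (!nrow(library)) {
    return(data.frame(editor = character(), pam = character(), strand = character(),
                      n_guides = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(n_guides = library$guide_id),
                   by = list(editor = library$editor, pam = library$pam,
                             strand = library$strand),
                   FUN = length)
  agg[order(agg$editor, agg$pam, agg$strand), , drop = FALSE]
}

write_tsv_with_header <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write run outputs
#'
#' Writes the guide library, editability summary, unreachable-request
#' report, per-combination counts, optional alignment dump and optional
#' BED6 of protospacer intervals, each with `#`-prefixed provenance lines
#' (tool version, seed, config hash). Identical inputs yield byte-identical
#' files.
#'
#' @param result list from [run_pipeline()] (or compatible pieces).
#' @param dir output directory.
#' @param cfg the [run_config()] used.
#' @param bed also write `library.bed` (BED6, 0-based half-open).
#' @return named character vector of written paths.
#' @export
write_outputs <- function(result, dir, cfg, bed = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- c(sprintf("# bedesign %s", as.character(utils::packageVersion("bedesign"))),
            sprintf("# seed: %d", cfg$random_seed),
            sprintf("# config: %s", config_hash(cfg)))
  paths <- c(library = file.path(dir, "library.tsv"),
             summary = file.path(dir, "summary.tsv"),
             unreachable = file.path(dir, "unreachable.tsv"),
             combinations = file.path(dir, "by_combination.tsv"),
             log = file.path(dir, "run_log.txt"))
  write_tsv_with_header(result$library, paths[["library"]], prov)
  summ <- result$summary
  if (!is.null(summ)) {
    per <- summ$per_substitution
    overall_row <- data.frame(substitution = "overall",
                              n_requested = summ$overall$n_requests,
                              n_editable = summ$overall$n_editable,
                              pct_editability = summ$overall$pct_editability,
                              strands_covered = "", stringsAsFactors = FALSE)
    write_tsv_with_header(rbind(per, overall_row), paths[["summary"]], prov)
  }
  write_tsv_with_header(result$unreachable, paths[["unreachable"]], prov)
  write_tsv_with_header(summarize_by_combination(result$library),
                        paths[["combinations"]], prov)
  if (!is.null(result$alignments)) {
    paths[["alignments"]] <- file.path(dir, "alignments.tsv")
    write_tsv_with_header(result$alignments, paths[["alignments"]], prov)
  }
  if (bed && nrow(result$library)) {
    paths[["bed"]] <- file.path(dir, "library.bed")
    score_col <- if ("guide_score" %in% names(result$library)) {
      round(result$library$guide_score * 1000)
    } else rep(0L, nrow(result$library))
    bed_df <- data.frame(result$library$chromosome,
                         result$library$protospacer_start - 1L,
                         result$library$protospacer_end,
                         result$library$guide_id, score_col, result$library$strand)
    con <- file(paths[["bed"]], "w")
    write.table(bed_df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    close(con)
  }
  writeLines(c(prov,
               sprintf("stage: %s", result$stage),
               sprintf("n_requests_parsed: %d", nrow(result$requests)),
               sprintf("n_rows_rejected: %d", nrow(result$rejects)),
               sprintf("n_requests_unreachable: %d", nrow(result$unreachable)),
               sprintf("n_guides: %d", nrow(result$library))),
             paths[["log"]])
  paths
}

#' Run the full design pipeline
#'
#' Executes parse -> validate -> design -> off-target search -> score ->
#' summarize and writes all outputs. Every input request ends up either in
#' the library (>= 1 guide) or in the unreachable report with a reason;
#' reruns with identical config and inputs are byte-identical. Later stages
#' can be skipped with `stop_after`.
#'
#' @param cfg a [run_config()] (needs `genome_fasta`, `mutation_table`, and
#'   `annotation_gff` for amino-acid input or region classification).
#' @param output_dir directory for output files (created).
#' @param stop_after last stage to execute: `"parse"`, `"design"`,
#'   `"offtarget"` or `"score"` (default, full run).
#' @param bed also emit a BED6 of protospacer intervals.
#' @return (invisibly) list with `requests`, `rejects`, `library`,
#'   `unreachable`, `alignments`, `summary`, `paths`, `stage`.
#' @export
run_pipeline <- function(cfg, output_dir,
                         stop_after = c("score", "offtarget", "design", "parse"),
                         bed = FALSE) {
  stop_after <- match.arg(stop_after)
  if (is.null(cfg$genome_fasta) || is.null(cfg$mutation_table)) {
    abort("config must provide genome_fasta and mutation_table", "bedesign_config_error")
  }
  genome <- read_genome(cfg$genome_fasta, cfg$annotation_gff)
  parsed <- parse_mutation_table(cfg$mutation_table, cfg$mutation_format)
  result <- list(requests = parsed$requests, rejects = parsed$rejects,
                 library = empty_guide_table(),
                 unreachable = data.frame(request_id = character(),
                                          reason = character(),
                                          stringsAsFactors = FALSE),
                 alignments = NULL, summary = NULL, stage = stop_after)
  if (stop_after != "parse") {
    des <- design_guides(parsed$requests, genome, cfg)
    result$library <- des$library
    result$unreachable <- des$unreachable
    if (stop_after %in% c("offtarget", "score")) {
      sc <- score_library(des$library, genome, cfg)
      result$alignments <- sc$alignments
      if (stop_after == "score") {
        result$library <- sc$library
      } else {
        # off-target stage only: keep the dump, drop the score columns
        result$library <- des$library
      }
    }
    result$summary <- summarize_editability(parsed$requests, result$library)
  }
  result$paths <- write_outputs(result, output_dir, cfg, bed = bed)
  invisible(result)
}
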