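#' Run configuration
#'
#' Collects everything a design run needs: input paths, the editor and PAM
#' registries, guide geometry, the off-target mismatch budget, the penalty
#' model and the request filters. The guide length must accommodate the
#' activity window of every configured editor.
#'
#' @param genome_fasta,annotation_gff,mutation_table input file paths.
#' @param editors named list of [base_editor()] objects.
#' @param pams named list of [pam_spec()] objects.
#' @param guide_length spacer length in nt (default 20).
#' @param mutation_format `"nucleotide"` or `"amino_acid"`.
#' @param mode `"model"` (introduce mutations on the reference background)
#'   or `"correct"` (revert an alternative allele to the reference).
#' @param max_mismatches off-target search mismatch budget (default 2).
#' @param penalty_model a [penalty_model()].
#' @param substitution_matrix optional residue-pair allow-list (`from`,`to`).
#' @param mutation_class `"any"`, `"nonsynonymous"` or `"synonymous"`.
#' @param random_seed integer seed for the run's seeded stages.
#' @return object of class `run_config`.
#' @export
run_config <- function(genome_fasta = NULL, annotation_gff = NULL, mutation_table = NULL,
                       editors = builtin_editors(), pams = builtin_pams(),
                       guide_length = 20L,
                       mutation_format = c("nucleotide", "amino_acid"),
                       mode = c("model", "correct"),
                       max_mismatches = 2L,
                       penalty_model = NULL,
                       substitution_matrix = NULL,
                       mutation_class = c("any", "nonsynonymous", "synonymous"),
                       random_seed = 1L) {
  mutation_format <- match.arg(mutation_format)
  mode <- match.arg(mode)
  mutation_class <- match.arg(mutation_class)
  guide_length <- as.integer(guide_length)
  max_mismatches <- as.integer(max_mismatches)
  if (is.na(guide_length) || guide_length < 1L) {
    abort("guide_length must be a positive integer", "bedesign_config_error")
  }
  if (is.na(max_mismatches) || max_mismatches < 0L) {
    abort("max_mismatches must be >= 0", "bedesign_config_error")
  }
  if (!length(editors)) abort("at least one editor is required", "bedesign_config_error")
  if (!length(pams)) abort("at least one PAM is required", "bedesign_config_error")
  for (e in editors) {
    if (!inherits(e, "base_editor")) abort("editors must be base_editor objects",
                                           "bedesign_config_error")
    if (e$window_end > guide_length) {
      abort(sprintf("guide_length %d < window_end %d of editor %s",
                    guide_length, e$window_end, e$name), "bedesign_config_error")
    }
  }
  for (p in pams) {
    if (!inherits(p, "pam_spec")) abort("pams must be pam_spec objects",
                                        "bedesign_config_error")
  }
  if (is.null(penalty_model)) penalty_model <- penalty_model()
  names(editors) <- vapply(editors, `[[`, character(1L), "name")
  names(pams) <- vapply(pams, `[[`, character(1L), "name")
  structure(list(genome_fasta = genome_fasta, annotation_gff = annotation_gff,
                 mutation_table = mutation_table, editors = editors, pams = pams,
                 guide_length = guide_length, mutation_format = mutation_format,
                 mode = mode, max_mismatches = max_mismatches,
                 penalty_model = penalty_model,
                 substitution_matrix = substitution_matrix,
                 mutation_class = mutation_class,
                 random_seed = as.integer(random_seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys mirror the [run_config()] arguments. `editors`
#' and `pams` may each be either a path to a registry TSV (see
#' [write_editor_table()]) or an inline list of records; omitted, the
#' built-in registries are used. A `penalties` block may override
#' `P_min`, `P_max`, `G_g`, `G_ig`, `A_in`, `A_out`. Relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path), "bedesign_config_error")
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) return(p)
    file.path(base, p)
  }
  editors <- builtin_editors()
  if (!is.null(y$editors)) {
    editors <- if (is.character(y$editors)) {
      read_editor_table(resolve(y$editors))
    } else {
      eds <- lapply(y$editors, function(e) {
        base_editor(e$name, e$source_base, e$target_base, e$window_start, e$window_end)
      })
      setNames(eds, vapply(eds, `[[`, character(1L), "name"))
    }
  }
  pams <- builtin_pams()
  if (!is.null(y$pams)) {
    pams <- if (is.character(y$pams)) {
      read_pam_table(resolve(y$pams))
    } else {
      ps <- lapply(y$pams, function(p) pam_spec(p$name, p$pattern, p$side))
      setNames(ps, vapply(ps, `[[`, character(1L), "name"))
    }
  }
  pm_args <- if (is.null(y$penalties)) list() else y$penalties
  pm <- do.call(penalty_model, pm_args)
  matrix <- NULL
  if (!is.null(y$substitution_matrix)) {
    matrix <- read.delim(resolve(y$substitution_matrix), stringsAsFactors = FALSE,
                         comment.char = "#")
  }
  run_config(
    genome_fasta = resolve(y$genome_fasta),
    annotation_gff = resolve(y$annotation_gff),
    mutation_table = resolve(y$mutation_table),
    editors = editors, pams = pams,
    guide_length = y$guide_length %||% 20L,
    mutation_format = y$mutation_format %||% "nucleotide",
    mode = y$mode %||% "model",
    max_mismatches = y$max_mismatches %||% 2L,
    penalty_model = pm,
    substitution_matrix = matrix,
    mutation_class = y$mutation_class %||% "any",
    random_seed = y$random_seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable hash of the run configuration for output provenance lines
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  flat <- cfg
  flat$penalty_model$fit <- NULL  # lm object carries environments; coefficients suffice
  writeLines(paste(deparse(flat, control = "all"), collapse = ""), f)
  unname(tools::md5sum(f))
}
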