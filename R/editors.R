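#' Define a base editor
#'
#' A base editor is described by its conversion chemistry (one source base
#' converted to one target base) and its activity window along the spacer.
#' Window positions are 1-based and counted from the PAM-DISTAL end of the
#' spacer: for a 3' PAM (NGG-style) position 1 is the spacer's 5' terminus,
#' the usual convention in the CBE/ABE literature. Edits outside the window
#' are still designed but penalized at scoring time.
#'
#' @param name editor label.
#' @param source_base,target_base the conversion chemistry, e.g. `"C"`,`"T"`
#'   for a cytosine base editor. Must differ.
#' @param window_start,window_end activity window bounds (inclusive),
#'   PAM-distal 1-based spacer positions.
#' @param compatible_pams advisory character vector of PAM names this editor
#'   is known to work with; never enforced (users may combine freely).
#' @return object of class `base_editor`.
#' @export
base_editor <- function(name, source_base, target_base,
                        window_start, window_end, compatible_pams = character()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("editor name must be a non-empty string", "bedesign_config_error")
  }
  if (!source_base %in% DNA_BASES || !target_base %in% DNA_BASES) {
    abort("source_base and target_base must be one of A/C/G/T", "bedesign_config_error")
  }
  if (source_base == target_base) {
    abort("source_base and target_base must differ", "bedesign_config_error")
  }
  window_start <- as.integer(window_start)
  window_end <- as.integer(window_end)
  if (is.na(window_start) || is.na(window_end) ||
      window_start < 1L || window_start > window_end) {
    abort("require 1 <= window_start <= window_end", "bedesign_config_error")
  }
  structure(
    list(name = name, source_base = source_base, target_base = target_base,
         window_start = window_start, window_end = window_end,
         compatible_pams = as.character(compatible_pams)),
    class = "base_editor"
  )
}

#' @export
print.base_editor <- function(x, ...) {
  cat(sprintf("<base_editor> %s: %s->%s, window %d-%d (PAM-distal 1-based)\n",
              x$name, x$source_base, x$target_base, x$window_start, x$window_end))
  invisible(x)
}

#' Define a PAM recognition pattern
#'
#' @param name PAM label.
#' @param pattern IUPAC pattern (e.g. `"NGG"`, `"TTTV"`).
#' @param side which side of the spacer the PAM sits on: `"three_prime"`
#'   (downstream, Cas9-style) or `"five_prime"` (upstream, Cas12a-style).
#' @return object of class `pam_spec`.
#' @export
pam_spec <- function(name, pattern, side = c("three_prime", "five_prime")) {
  side <- match.arg(side)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("PAM name must be a non-empty string", "bedesign_config_error")
  }
  pam_pattern_regex(pattern)  # validates IUPAC alphabet, non-empty
  structure(list(name = name, pattern = pattern, side = side), class = "pam_spec")
}

#' @export
print.pam_spec <- function(x, ...) {
  cat(sprintf("<pam_spec> %s: %s (%s of spacer)\n", x$name, x$pattern,
              if (x$side == "three_prime") "3'" else "5'"))
  invisible(x)
}

#' Built-in base editors
#'
#' Default registry of common editors. The windows are literature-based
#' defaults and can be overridden freely via [base_editor()] or the
#' editor-table config file: Target-AID (C->T, window 2-4), BE3 (C->T,
#' window 4-8), ABE7.10 (A->G, window 4-7), all under the PAM-distal
#' 1-based window convention.
#'
#' @return named list of `base_editor` objects.
#' @export
builtin_editors <- function() {
  eds <- list(
    base_editor("Target-AID", "C", "T", 2L, 4L, c("NGG", "NG")),
    base_editor("BE3",        "C", "T", 4L, 8L, c("NGG", "NG")),
    base_editor("ABE7.10",    "A", "G", 4L, 7L, "NGG")
  )
  setNames(eds, vapply(eds, `[[`, character(1L), "name"))
}

#' Built-in PAM patterns
#'
#' NGG (canonical SpCas9) and the relaxed NG, both 3' of the spacer. Any
#' custom IUPAC pattern on either side can be added via [pam_spec()].
#'
#' @return named list of `pam_spec` objects.
#' @export
builtin_pams <- function() {
  ps <- list(pam_spec("NGG", "NGG", "three_prime"),
             pam_spec("NG", "NG", "three_prime"))
  setNames(ps, vapply(ps, `[[`, character(1L), "name"))
}

#' Serialize / read editor and PAM registries as TSV tables
#'
#' Columns: `name, source_base, target_base, window_start, window_end` for
#' editors; `name, pattern, side` for PAMs. Round-trips unchanged.
#'
#' @param editors,pams lists of specs as returned by [builtin_editors()] /
#'   [builtin_pams()].
#' @param path file path.
#' @return the written path, or the parsed registry list.
#' @export
write_editor_table <- function(editors, path) {
  df <- do.call(rbind, lapply(editors, function(e) {
    data.frame(name = e$name, source_base = e$source_base, target_base = e$target_base,
               window_start = e$window_start, window_end = e$window_end,
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_editor_table
#' @export
read_editor_table <- function(path) {
  # all-character read: a column of bare T/F bases must never become logical
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   colClasses = "character")
  need <- c("name", "source_base", "target_base", "window_start", "window_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("editor table missing column(s): %s", paste(miss, collapse = ", ")),
          "bedesign_format_error")
  }
  eds <- lapply(seq_len(nrow(df)), function(i) {
    base_editor(df$name[i], df$source_base[i], df$target_base[i],
                df$window_start[i], df$window_end[i])
  })
  setNames(eds, df$name)
}

#' @rdname write_editor_table
#' @export
write_pam_table <- function(pams, path) {
  df <- do.call(rbind, lapply(pams, function(p) {
    data.frame(name = p$name, pattern = p$pattern, side = p$side,
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_editor_table
#' @export
read_pam_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   colClasses = "character")
  need <- c("name", "pattern", "side")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("PAM table missing column(s): %s", paste(miss, collapse = ", ")),
          "bedesign_format_error")
  }
  ps <- lapply(seq_len(nrow(df)), function(i) pam_spec(df$name[i], df$pattern[i], df$side[i]))
  setNames(ps, df$name)
}

pam_length <- function(pam) nchar(pam$pattern)

# largest PAM length among configured PAMs (for flank sizing)
max_pam_length <- function(pams) max(vapply(pams, pam_length, integer(1L)))
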