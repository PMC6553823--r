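#' @keywords internal
"_PACKAGE"

#' @importFrom methods is
#' @importFrom stats lm coef setNames
#' @importFrom utils read.delim write.table head
NULL

# IUPAC nucleotide code -> set of concrete bases it stands for
IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

DNA_BASES <- c("A", "C", "G", "T")
AA_SYMBOLS <- c(sort(unique(as.character(Biostrings::GENETIC_CODE))))  # 20 AAs + "*"

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "bedesign_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_dna <- function(seq, allow_n = TRUE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort(sprintf("%s must be a single character string", what), "bedesign_contract_error")
  }
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  if (grepl(pat, seq)) {
    abort(sprintf("invalid character in %s '%s' (expected %s)",
                  what, seq, if (allow_n) "A/C/G/T/N" else "A/C/G/T"),
          "bedesign_contract_error")
  }
  invisible(seq)
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick reverse complement over the alphabet A/C/G/T/N, with N mapping
#' to itself. Used throughout for minus-strand spacer and PAM geometry.
#'
#' @param seq single DNA string over A/C/G/T/N.
#' @return the reverse-complemented string.
#' @examples
#' reverse_complement("ACGT")  # "ACGT" (palindromic)
#' reverse_complement("AAA")   # "TTT"
#' @export
reverse_complement <- function(seq) {
  assert_dna(seq)
  if (nchar(seq) == 0L) return(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Complement of single bases
#'
#' @param base character vector of single bases over A/C/G/T/N.
#' @return complement bases.
#' @export
complement_base <- function(base) {
  bad <- !base %in% c(DNA_BASES, "N")
  if (any(bad)) {
    abort(sprintf("invalid base '%s'", base[bad][1L]), "bedesign_contract_error")
  }
  chartr("ACGTN", "TGCAN", base)
}

# regex character-class form of an IUPAC pattern, anchored
pam_pattern_regex <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern)) {
    abort("PAM pattern must be a single non-empty string", "bedesign_contract_error")
  }
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- !chars %in% names(IUPAC_CODES)
  if (any(bad)) {
    abort(sprintf("invalid IUPAC code '%s' in PAM pattern '%s'", chars[bad][1L], pattern),
          "bedesign_contract_error")
  }
  paste0("^", paste(vapply(chars, function(ch) {
    set <- IUPAC_CODES[[ch]]
    if (nchar(set) == 1L) set else paste0("[", set, "]")
  }, character(1L)), collapse = ""), "$")
}

#' Match an observed genomic sequence against an IUPAC PAM pattern
#'
#' Every observed base must fall in the IUPAC class of the corresponding
#' pattern symbol. An observed `N` (ambiguous genome base) matches nothing:
#' an ambiguous base can never be guaranteed to satisfy a PAM requirement.
#'
#' @param pattern IUPAC pattern string (e.g. `"NGG"`, `"TTTV"`).
#' @param observed observed genomic sequence over A/C/G/T/N, same length as
#'   `pattern`. May be a vector; the result is vectorised over it.
#' @return logical vector, `TRUE` where the observed sequence satisfies the
#'   pattern.
#' @examples
#' pam_matches("NGG", "AGG")   # TRUE
#' pam_matches("NGG", "AGA")   # FALSE
#' pam_matches("TTTV", "TTTC") # TRUE
#' @export
pam_matches <- function(pattern, observed) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) == 0L) {
    abort("PAM pattern must be a single non-empty string", "bedesign_contract_error")
  }
  if (any(nchar(observed) != nchar(pattern))) {
    abort(sprintf("observed sequence length != PAM pattern length (%d)", nchar(pattern)),
          "bedesign_contract_error")
  }
  bad <- grepl("[^ACGTN]", observed)
  if (any(bad)) {
    abort(sprintf("invalid character in observed sequence '%s'", observed[bad][1L]),
          "bedesign_contract_error")
  }
  grepl(pam_pattern_regex(pattern), observed)
}

#' Translate one codon with the standard genetic code
#'
#' @param codon DNA string of length 3 over A/C/G/T (no ambiguity codes).
#' @return single amino-acid symbol, `"*"` for stop.
#' @examples
#' translate_codon("ATG") # "M"
#' translate_codon("TAA") # "*"
#' @export
translate_codon <- function(codon) {
  assert_dna(codon, allow_n = FALSE, what = "codon")
  if (nchar(codon) != 3L) {
    abort(sprintf("codon must have length 3, got '%s'", codon), "bedesign_contract_error")
  }
  unname(Biostrings::GENETIC_CODE[[codon]])
}

# translate a CDS string (length divisible by 3) into a residue vector
translate_cds <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    abort(sprintf("CDS length %d not divisible by 3", n), "bedesign_contract_error")
  }
  if (n == 0L) return(character(0L))
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Length of the longest poly-T stretch in a spacer
#'
#' Runs of four or more T can act as RNA polymerase III transcriptional
#' terminators and truncate the expressed gRNA, so the longest run is
#' reported for every designed guide. It is reported, never auto-filtered.
#'
#' @param spacer spacer sequence.
#' @return integer run length (0 when the spacer contains no T).
#' @examples
#' annotate_polyT("GTTTTGACGTACGTACGTAC") # 4
#' @export
annotate_polyT <- function(spacer) {
  assert_dna(spacer, what = "spacer")
  m <- gregexpr("T+", spacer)[[1L]]
  if (m[1L] == -1L) 0L else max(attr(m, "match.length"))
}

# run code with a private, restored RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# random DNA string with a given GC content
random_dna <- function(n, gc = 0.5) {
  at <- (1 - gc) / 2
  paste(sample(DNA_BASES, n, replace = TRUE, prob = c(at, gc / 2, gc / 2, at)),
        collapse = "")
}

# replace characters of a string at 1-based positions
substr_replace <- function(seq, positions, bases) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  chars[positions] <- bases
  paste(chars, collapse = "")
}
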