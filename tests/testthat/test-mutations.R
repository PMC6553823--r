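write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("mutation tables parse with per-row reject reporting", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(chromosome = "chr1", position = c(10, 20, 30),
                       ref_base = c("C", "A", "G"), alt_base = c("T", "G", "A")), f)
  p <- parse_mutation_table(f, "nucleotide")
  expect_identical(nrow(p$requests), 3L)
  expect_identical(nrow(p$rejects), 0L)
  expect_identical(p$requests$request_id, c("row1", "row2", "row3"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(chromosome = "chr1", position = c(10, 20),
                       ref_base = c("C", "A"), alt_base = c("C", "G")), f2)
  p2 <- parse_mutation_table(f2, "nucleotide")
  expect_identical(nrow(p2$requests), 1L)
  expect_identical(p2$rejects$reason, "no-op substitution")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(transcript_id = "tx1", residue_position = c(2, 3),
                       ref_residue = c("B", "Q"), alt_residue = c("A", "*")), f3)
  p3 <- parse_mutation_table(f3, "amino_acid")
  expect_identical(p3$rejects$reason, "invalid residue")
  expect_identical(nrow(p3$requests), 1L)

  f4 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(chromosome = "chr1", position = 1), f4)
  expect_error(parse_mutation_table(f4, "nucleotide"), class = "bedesign_format_error")
})

test_that("requests are validated against genome content", {
  g <- tiny_bundle(c(chr1 = "AACGTACGTT"),
                   transcripts = list(tx1 = transcript_model(
                     "tx1", "chr1", "+", data.frame(start = 2, end = 10))))
  req <- data.frame(request_id = "r1", chromosome = "chr1", position = 3L,
                    ref_base = "C", alt_base = "T", format = "nucleotide",
                    stringsAsFactors = FALSE)
  expect_true(validate_request(req, g)$ok)
  req$ref_base <- "T"
  v <- validate_request(req, g)
  expect_false(v$ok)
  expect_match(v$reason, "expected T observed C")
  aa <- data.frame(request_id = "r2", transcript_id = "nope", residue_position = 1L,
                   ref_residue = "M", alt_residue = "V", format = "amino_acid",
                   stringsAsFactors = FALSE)
  expect_match(validate_request(aa, g)$reason, "transcript not found")
  aa$transcript_id <- "tx1"
  aa$ref_residue <- translate_codon("ACG")
  expect_true(validate_request(aa, g)$ok)
  aa$residue_position <- 9L
  expect_match(validate_request(aa, g)$reason, "beyond CDS")
})

test_that("codon edit enumeration finds known single-edit routes", {
  cbe <- base_editor("CBE", "C", "T", 2, 4)
  abe <- base_editor("ABE", "A", "G", 4, 7)
  p1 <- aa_edit_candidates("CAA", "*", cbe)
  expect_identical(nrow(p1), 1L)
  expect_identical(p1$edited_codon, "TAA")
  expect_identical(p1$positions, "1")
  expect_identical(p1$strand, "+")
  p2 <- aa_edit_candidates("AAA", "E", abe)
  expect_true(any(p2$edited_codon == "GAA" & p2$strand == "+" & p2$positions == "1"))
  expect_identical(nrow(aa_edit_candidates("TTT", "G", cbe)), 0L)
})

test_that("codon edit enumeration agrees with a brute-force oracle", {
  cbe <- base_editor("CBE", "C", "T", 2, 4)
  abe <- base_editor("ABE", "A", "G", 4, 7)
  withr::with_seed(31, {
    codons <- unique(replicate(30, paste(sample(c("A", "C", "G", "T"), 3,
                                                replace = TRUE), collapse = "")))
    for (codon in codons) {
      for (ed in list(cbe, abe)) {
        all_edits <- oracle_codon_edits(codon, ed$source_base, ed$target_base)
        for (target in c("*", "K", "E", "L", "S")) {
          got <- aa_edit_candidates(codon, target, ed)
          want <- Filter(function(x) {
            unname(Biostrings::GENETIC_CODE[x$edited]) == target
          }, all_edits)
          expect_identical(nrow(got), length(want))
          if (length(want)) {
            want_keys <- sort(vapply(want, function(x) {
              paste(x$strand, paste(x$positions, collapse = ","), x$edited)
            }, character(1)))
            got_keys <- sort(paste(got$strand, got$positions, got$edited_codon))
            expect_identical(got_keys, want_keys)
          }
        }
      }
    }
  })
})

test_that("edit plans replay exactly onto the original codon", {
  cbe <- base_editor("CBE", "C", "T", 2, 4)
  withr::with_seed(32, {
    for (i in 1:20) {
      codon <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
      target <- sample(c("*", "L", "F", "I", "V"), 1)
      plans <- aa_edit_candidates(codon, target, cbe)
      for (j in seq_len(nrow(plans))) {
        pl <- plans[j, ]
        pos <- split_ints(pl$positions)
        chars <- strsplit(codon, "")[[1]]
        chars[pos] <- if (pl$strand == "+") "T" else "A"
        expect_identical(paste(chars, collapse = ""), pl$edited_codon)
        expect_identical(translate_codon(pl$edited_codon), pl$resulting_residue)
      }
    }
  })
})

test_that("substitution-matrix and class filters apply as set operations", {
  cbe <- base_editor("CBE", "C", "T", 2, 4)
  plans <- aa_edit_candidates("CAA", "*", cbe)
  expect_identical(nrow(apply_filters(plans, "Q", mutation_class = "synonymous")), 0L)
  expect_identical(nrow(apply_filters(plans, "Q",
                                      matrix = data.frame(from = "Q", to = "*"))), 1L)
  expect_identical(nrow(apply_filters(plans, "Q",
                                      matrix = data.frame(from = "Q", to = "L"))), 0L)
  expect_identical(apply_filters(plans, "Q"), plans)
  expect_error(apply_filters(plans, "Q", matrix = data.frame(from = "Z", to = "*")),
               class = "bedesign_config_error")
})

test_that("mutant codon reconstruction is minimal-Hamming with lexicographic ties", {
  # Q codon CAA, alt residue K: AAA distance 1 beats AAG distance 2
  expect_identical(reconstruct_mutant_codon("CAA", "K"), "AAA")
  # L from GGG: CTA/CTC/CTG/CTT/TTA/TTG all distance >= 2; CTG distance 2 is
  # the lexicographically first among the minimal set {CTG, TTG}
  expect_identical(reconstruct_mutant_codon("GGG", "L"), "CTG")
  # already encoding the residue: unchanged codon is distance 0
  expect_identical(reconstruct_mutant_codon("AAA", "K"), "AAA")
})
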