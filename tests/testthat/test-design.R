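cbe_only_cfg <- function(...) {
  run_config(editors = list(base_editor("Target-AID", "C", "T", 2, 4)),
             pams = list(pam_spec("NGG", "NGG")), ...)
}

test_that("a hand-built context yields exactly the expected in-window candidate", {
  # one NGG in the whole sequence, placed so the target C sits at window
  # position 3 of a 20-nt spacer (prefix 10 nt | spacer 20 nt | AGG | tail)
  spacer <- "ATCATTATTATTATTATTAT"
  seq <- paste0("ATATATATAT", spacer, "AGG", "ATTATTA")
  g <- tiny_bundle(c(chr1 = seq))
  cfg <- cbe_only_cfg()
  req <- data.frame(request_id = "r1", chromosome = "chr1", position = 13L,
                    ref_base = "C", alt_base = "T", format = "nucleotide",
                    stringsAsFactors = FALSE)
  des <- design_guides(req, g, cfg)
  expect_identical(nrow(des$library), 1L)
  cand <- des$library[1, ]
  expect_identical(cand$protospacer_start, 11L)
  expect_identical(cand$protospacer_end, 30L)
  expect_identical(cand$strand, "+")
  expect_identical(cand$spacer, spacer)
  expect_identical(cand$pam_observed, "AGG")
  expect_identical(cand$edited_offset, 3L)
  expect_true(cand$in_window)
  expect_identical(cand$bystander_offsets, "")  # no other window C

  # ablate the PAM: no candidate, request reported unreachable
  g2 <- tiny_bundle(c(chr1 = sub("AGG", "ATT", seq)))
  des2 <- design_guides(req, g2, cfg)
  expect_identical(nrow(des2$library), 0L)
  expect_identical(des2$unreachable$reason, "no protospacer placement with a matching PAM")
})

test_that("an A>G style request with T on the plus strand designs on the minus strand", {
  # minus-strand NGG: plus strand carries CC at the PAM positions
  seq <- paste0("ATTATTATTA", "CCT", "ATTATTATTTATTATTATTA", "ATTATTATTA")
  g <- tiny_bundle(c(chr1 = seq))
  cfg <- run_config(editors = list(base_editor("ABE7.10", "A", "G", 4, 7)),
                    pams = list(pam_spec("NGG", "NGG")))
  tpos <- 14L + which(strsplit(substr(seq, 14, 33), "")[[1]] == "T")[3] - 1L
  req <- data.frame(request_id = "r1", chromosome = "chr1", position = tpos,
                    ref_base = "T", alt_base = "C", format = "nucleotide",
                    stringsAsFactors = FALSE)
  des <- design_guides(req, g, cfg)
  expect_gt(nrow(des$library), 0L)
  expect_true(all(des$library$strand == "-"))
  expect_identical(unique(des$library$protospacer_start), 14L)
})

test_that("chemistry mismatches are reported as unreachable, not dropped", {
  g <- tiny_bundle(c(chr1 = "ATATACGGATATATATATATATATATATAT"))
  cfg <- cbe_only_cfg()
  # T -> C cannot be produced by a C->T editor on either strand
  req <- data.frame(request_id = "r1", chromosome = "chr1", position = 2L,
                    ref_base = "T", alt_base = "C", format = "nucleotide",
                    stringsAsFactors = FALSE)
  des <- design_guides(req, g, cfg)
  expect_identical(nrow(des$library), 0L)
  expect_identical(des$unreachable$reason,
                   "conversion not offered by any configured editor")
})

test_that("designing against the mirrored genome yields the mirrored library", {
  r <- fixture_recipe(seed = 41, chromosome_length = 4000, n_genes = 0,
                      n_mutations = 12)
  fx <- generate_genome(r, withr::local_tempdir())
  mut <- generate_mutations(fx$genome, r)
  cfg <- run_config()
  reqs <- mut
  reqs$format <- "nucleotide"
  des <- design_guides(reqs, fx$genome, cfg)
  L <- fx$genome$lengths[["chr1"]]
  mirrored <- tiny_bundle(c(chr1 = reverse_complement(fx$genome$sequences[["chr1"]])))
  mreqs <- reqs
  mreqs$position <- L - reqs$position + 1L
  mreqs$ref_base <- complement_base(reqs$ref_base)
  mreqs$alt_base <- complement_base(reqs$alt_base)
  mdes <- design_guides(mreqs, mirrored, cfg)
  expect_identical(nrow(mdes$library), nrow(des$library))
  key <- function(lib, flip) {
    s <- if (flip) ifelse(lib$strand == "+", "-", "+") else lib$strand
    a <- if (flip) L - lib$protospacer_end + 1L else lib$protospacer_start
    e <- if (flip) L - lib$protospacer_start + 1L else lib$protospacer_end
    sort(paste(lib$request_id, lib$editor, lib$pam, a, e, s, lib$spacer))
  }
  expect_identical(key(mdes$library, flip = TRUE), key(des$library, flip = FALSE))
})

test_that("predicted edits replay to the requested base (model and correct mode)", {
  r <- fixture_recipe(seed = 42, chromosome_length = 6000, n_genes = 3,
                      gene_length = 300, n_mutations = 25)
  fx <- generate_genome(r, withr::local_tempdir())
  mut <- generate_mutations(fx$genome, r)
  for (mode in c("model", "correct")) {
    cfg <- run_config(mode = mode)
    reqs <- mut
    reqs$format <- "nucleotide"
    des <- design_guides(reqs, fx$genome, cfg)
    expect_gt(nrow(des$library), 0L)
    for (i in seq_len(nrow(des$library))) {
      gd <- des$library[i, ]
      m <- mut[mut$request_id == gd$request_id, ]
      edited <- replay_edit(fx$genome, gd$chromosome,
                            split_ints(gd$target_positions),
                            split_chars(gd$edited_bases_plus))
      got <- fetch_sequence(edited, m$chromosome, m$position, m$position, "+")
      expect_identical(got, if (mode == "model") m$alt_base else m$ref_base)
    }
  }
})

test_that("positive controls create stop codons that replay on translation", {
  cds <- paste0("ATG", "CAA", "ATT", "ATT", "ATT", "ATT", "ATT", "GGA", "ATT", "TAA")
  seq <- paste0(strrep("AT", 10), cds, strrep("TA", 10))
  tx <- transcript_model("tx1", "chr1", "+", data.frame(start = 21, end = 50))
  g <- tiny_bundle(c(chr1 = seq),
                   genes = data.frame(chromosome = "chr1", start = 21, end = 50,
                                      strand = "+", gene_id = "g1"),
                   transcripts = list(tx1 = tx))
  cfg <- cbe_only_cfg()
  ed <- cfg$editors[[1]]
  ctrl <- design_positive_controls(tx, g, ed, cfg$pams[[1]], cfg, n = 3)
  expect_gt(nrow(ctrl), 0L)
  expect_true(all(ctrl$resulting_residue == "*"))
  expect_true(all(ctrl$in_window))
  for (i in seq_len(nrow(ctrl))) {
    edited <- replay_edit(g, ctrl$chromosome[i],
                          split_ints(ctrl$target_positions[i]),
                          split_chars(ctrl$edited_bases_plus[i]))
    aa <- translate_cds_str(edited, tx)
    expect_true("*" %in% aa[-length(aa)])  # premature stop introduced
  }
})

test_that("adenine editors cannot create nonsense codons from any sense codon", {
  abe <- base_editor("ABE", "A", "G", 4, 7)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (codon in sense) {
    expect_identical(nrow(aa_edit_candidates(codon, "*", abe)), 0L)
  }
  # hence positive-control design with an ABE finds nothing
  r <- fixture_recipe(seed = 43, chromosome_length = 2000, n_genes = 1,
                      gene_length = 120)
  fx <- generate_genome(r, withr::local_tempdir())
  cfg <- run_config()
  expect_message(
    ctrl <- design_positive_controls(fx$genome$transcripts[[1]], fx$genome,
                                     base_editor("ABE", "A", "G", 4, 7),
                                     cfg$pams[["NGG"]], cfg, n = 3),
    "no stop-reachable codon")
  expect_identical(nrow(ctrl), 0L)
})

test_that("n = 0 positive controls yield an empty table", {
  r <- fixture_recipe(seed = 44, chromosome_length = 2000, n_genes = 1,
                      gene_length = 120)
  fx <- generate_genome(r, withr::local_tempdir())
  cfg <- cbe_only_cfg()
  ctrl <- design_positive_controls(fx$genome$transcripts[[1]], fx$genome,
                                   cfg$editors[[1]], cfg$pams[[1]], cfg, n = 0)
  expect_identical(nrow(ctrl), 0L)
})

test_that("negative controls have no editable base in window and are seed-stable", {
  r <- fixture_recipe(seed = 45, chromosome_length = 8000, n_genes = 0)
  fx <- generate_genome(r, withr::local_tempdir())
  cfg <- run_config()
  ed <- cfg$editors[["Target-AID"]]
  pam <- cfg$pams[["NGG"]]
  nc <- design_negative_controls(fx$genome, ed, pam, cfg, n = 8, seed = 7)
  expect_identical(nrow(nc), 8L)
  for (i in seq_len(nrow(nc))) {
    win <- substr(nc$spacer[i], ed$window_start, ed$window_end)
    expect_identical(lengths(regmatches(win, gregexpr("C", win))), 0L)
    expect_true(pam_matches(pam$pattern, nc$pam_observed[i]))
  }
  nc2 <- design_negative_controls(fx$genome, ed, pam, cfg, n = 8, seed = 7)
  expect_identical(nc, nc2)
  nc3 <- design_negative_controls(fx$genome, ed, pam, cfg, n = 8, seed = 8)
  expect_false(identical(nc$guide_id, nc3$guide_id))
})

test_that("a PAM-free genome yields no negative controls, with a warning", {
  g <- tiny_bundle(c(chr1 = strrep("AT", 200)))
  cfg <- run_config()
  expect_warning(
    nc <- design_negative_controls(g, cfg$editors[[1]], cfg$pams[["NGG"]], cfg, n = 5),
    "no window-free site")
  expect_identical(nrow(nc), 0L)
})
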