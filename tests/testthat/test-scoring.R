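test_that("the cubic fit recovers polynomials it can represent exactly", {
  # 4 exact points of a known cubic
  d <- c(1, 5, 12, 20)
  y <- 0.2 + 0.01 * d - 0.002 * d^2 + 0.0004 * d^3
  co <- fit_penalty_curve(data.frame(distance = d, tolerance = y))
  expect_equal(co, c(0.2, 0.01, -0.002, 0.0004), tolerance = 1e-8)
  # constant table -> constant curve
  co2 <- fit_penalty_curve(data.frame(distance = 1:20, tolerance = 0.5))
  pm <- penalty_model(data.frame(distance = 1:20, tolerance = 0.5),
                      P_min = 0.01, P_max = 1)
  expect_true(all(abs(position_penalty(1:20, pm) - 0.5) < 1e-10))
  expect_error(fit_penalty_curve(data.frame(distance = 1:3, tolerance = 1:3 / 4)),
               class = "bedesign_fit_error")
})

test_that("default position penalties run from P_min at the PAM to P_max distally", {
  pm <- penalty_model()
  expect_equal(position_penalty(1, pm), pm$P_min, tolerance = 1e-9)
  expect_equal(position_penalty(20, pm), pm$P_max, tolerance = 1e-9)
  v <- position_penalty(1:20, pm)
  expect_true(all(diff(v) >= -1e-12))          # nondecreasing with distance
  expect_true(all(v >= pm$P_min & v <= pm$P_max))
  expect_error(position_penalty(21, pm), class = "bedesign_contract_error")
})

test_that("short guides interpolate on the rescaled reference curve", {
  pm <- penalty_model()
  expect_equal(position_penalty(5, pm, guide_length = 10),
               position_penalty(10, pm, guide_length = 20))
  expect_equal(position_penalty(3, pm, guide_length = 30),
               position_penalty(2, pm, guide_length = 20))
})

test_that("alignment penalties multiply per mismatched position", {
  pm <- penalty_model()
  expect_identical(alignment_penalty(integer(0), pm, 20), 1)
  d7 <- mismatch_distances(7L, 20L, "three_prime")
  expect_equal(alignment_penalty(7L, pm, 20), position_penalty(d7, pm, 20))
  d <- mismatch_distances(c(3L, 15L), 20L, "three_prime")
  expect_equal(alignment_penalty(c(3L, 15L), pm, 20),
               prod(position_penalty(d, pm, 20)))
})

test_that("region penalties select the configured multipliers", {
  pm <- penalty_model()
  expect_identical(region_penalty("genic", pm), 0.5)
  expect_identical(region_penalty("intergenic", pm), 0.9)
  expect_error(penalty_model(G_g = 0.9, G_ig = 0.5), class = "bedesign_config_error")
  expect_error(penalty_model(P_min = 0), class = "bedesign_config_error")
})

mk_aln <- function(n_mm_offsets, region, intended = FALSE) {
  data.frame(guide_id = "g", chromosome = "chr1", start = 1L, end = 20L,
             strand = "+", n_mismatches = lengths(list(n_mm_offsets)),
             mismatch_offsets = paste(n_mm_offsets, collapse = ","),
             region = region, is_intended_target = intended,
             stringsAsFactors = FALSE)
}

test_that("the final score multiplies alignment, region and window penalties", {
  pm <- penalty_model()
  guide <- data.frame(guide_id = "g", in_window = TRUE, stringsAsFactors = FALSE)
  own <- mk_aln(integer(0), "genic", intended = TRUE)
  # in-window guide with no off-target alignment besides its own site: exactly 1
  br <- guide_score(guide, own, pm, 20)
  expect_identical(br$B, 1)
  expect_identical(br$n_alignments, 0L)
  # out-of-window, no off-targets: the window multiplier alone
  guide_out <- data.frame(guide_id = "g", in_window = FALSE, stringsAsFactors = FALSE)
  expect_identical(guide_score(guide_out, own, pm, 20)$B, 0.5)
  # one exact genic duplicate: empty mismatch product, genic multiplier
  br2 <- guide_score(guide, rbind(own, mk_aln(integer(0), "genic")), pm, 20)
  expect_identical(br2$B, 0.5)
  # intergenic 1-mismatch duplicate: P_a * G_ig
  aln3 <- rbind(own, mk_aln(10L, "intergenic"))
  br3 <- guide_score(guide, aln3, pm, 20)
  expect_equal(br3$B, alignment_penalty(10L, pm, 20) * 0.9)
  # missing intended target is an integrity error
  expect_error(guide_score(guide, mk_aln(integer(0), "genic"), pm, 20),
               class = "bedesign_integrity_error")
})

test_that("appending any scored alignment never increases the score", {
  pm <- penalty_model()
  guide <- data.frame(guide_id = "g", in_window = TRUE, stringsAsFactors = FALSE)
  withr::with_seed(71, {
    for (i in 1:30) {
      n <- sample(0:5, 1)
      aln <- mk_aln(integer(0), "genic", intended = TRUE)
      prev <- guide_score(guide, aln, pm, 20)$B
      for (j in seq_len(n)) {
        off <- sort(sample(1:20, sample(0:2, 1)))
        aln <- rbind(aln, mk_aln(off, sample(c("genic", "intergenic"), 1)))
        cur <- guide_score(guide, aln, pm, 20)$B
        expect_lte(cur, prev + 1e-15)
        expect_gt(cur, 0)
        expect_lte(cur, 1)
        prev <- cur
      }
    }
  })
})

test_that("scores rank-correlate with an independent product-of-tolerance score", {
  # CFD-style check: an independently coded product of table tolerances over
  # mismatch distances must rank guides the same way as the package score
  pm <- penalty_model()
  tab <- pm$position_tolerance_table
  withr::with_seed(72, {
    B <- numeric(40)
    indep <- numeric(40)
    guide <- data.frame(guide_id = "g", in_window = TRUE, stringsAsFactors = FALSE)
    for (i in 1:40) {
      aln <- mk_aln(integer(0), "intergenic", intended = TRUE)
      ind <- 1
      for (j in seq_len(sample(0:4, 1))) {
        off <- sort(sample(1:20, sample(0:2, 1)))
        aln <- rbind(aln, mk_aln(off, "intergenic"))
        d <- 20 - off + 1
        ind <- ind * prod(tab$tolerance[match(d, tab$distance)])
      }
      B[i] <- guide_score(guide, aln, pm, 20)$B
      indep[i] <- ind
    }
    expect_gt(cor(B, indep, method = "spearman"), 0.9)
  })
})
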