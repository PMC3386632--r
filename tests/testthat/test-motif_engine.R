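test_that("a minimal flanked motif is found with exact coordinates", {
  m <- scan_sequence(list(id = "s1", residues = "CRGDC"), "RGD")
  expect_equal(nrow(m), 1L)
  expect_equal(m$motif_start, 2L)
  expect_equal(m$left_cys_pos, 1L)
  expect_equal(m$right_cys_pos, 5L)
  expect_equal(m$left_spacer, 0L)
  expect_equal(m$right_spacer, 0L)
})

test_that("the spacer bound of 16 is inclusive and 17 is out", {
  at16 <- paste0("C", strrep("A", 16), "RGD", strrep("A", 16), "C")
  m <- scan_sequence(list(id = "s", residues = at16), "RGD")
  expect_equal(nrow(m), 1L)
  expect_equal(m$left_spacer, 16L)
  expect_equal(m$right_spacer, 16L)

  at17 <- paste0("C", strrep("A", 17), "RGD", "C")
  expect_equal(nrow(scan_sequence(list(id = "s", residues = at17), "RGD")), 0L)

  # no cysteines at all
  expect_equal(nrow(scan_sequence(list(id = "s", residues = "ARGDA"), "RGD")),
               0L)
})

test_that("one cysteine can flank two motifs, innermost flank reported", {
  m <- scan_sequence(list(id = "s", residues = "CRGDCRGDC"), "RGD")
  expect_equal(nrow(m), 2L)
  expect_equal(m$motif_start, c(2L, 6L))
  expect_equal(m$left_cys_pos, c(1L, 5L))
  expect_equal(m$right_cys_pos, c(5L, 9L))

  # several qualifying cysteines: the innermost wins on both sides
  m <- scan_sequence(list(id = "s", residues = "CCARGDACC"), "RGD")
  expect_equal(m$left_cys_pos, 2L)
  expect_equal(m$right_cys_pos, 8L)
})

test_that("X never matches and is rejected inside a pattern", {
  expect_equal(nrow(scan_sequence(list(id = "s", residues = "CRGXC"), "RGD")),
               0L)
  expect_error(motif_pattern("RXD"), "outside the amino-acid alphabet")
  expect_error(scan_sequence(list(id = "s", residues = "CRGDC"), "R1D"),
               "outside the amino-acid alphabet")
  # X in a spacer is fine
  expect_equal(nrow(scan_sequence(list(id = "s", residues = "CXRGDXC"),
                                  "RGD")), 1L)
})

test_that("matches inside the predicted signal peptide are flagged", {
  sig <- data.frame(seq_id = "s", has_signal = TRUE, cleavage_pos = 10L,
                    score = 0.5)
  m <- scan_sequence(list(id = "s", residues = "CRGDCAAAAAAAACRGDC"), "RGD",
                     signal = sig)
  expect_equal(m$overlaps_signal, c(TRUE, FALSE))
})

test_that("scanner output equals the brute-force triple enumeration", {
  rec <- random_protein_records(300, length_range = c(20, 400),
                                cys_freq = 0.08, seed = 202)
  got <- scan_collection(rec)$matches
  want <- enumerate_flanked_motifs(rec)
  cols <- c("seq_id", "tripeptide", "motif_start", "left_cys_pos",
            "right_cys_pos", "left_spacer", "right_spacer")
  ord <- function(d) {
    d <- d[do.call(order, c(unname(d[cols]), method = "radix")), cols]
    rownames(d) <- NULL
    d
  }
  expect_identical(ord(got), ord(want))
  expect_gt(nrow(got), 0L)
})

test_that("every emitted match satisfies the match invariants", {
  rec <- random_protein_records(100, length_range = c(20, 300),
                                cys_freq = 0.1, seed = 9)
  m <- scan_collection(rec)$matches
  res <- setNames(rec$residues, rec$id)
  expect_true(all(substr(res[m$seq_id], m$motif_start, m$motif_start + 2) ==
                    m$tripeptide))
  expect_true(all(substr(res[m$seq_id], m$left_cys_pos, m$left_cys_pos) == "C"))
  expect_true(all(substr(res[m$seq_id], m$right_cys_pos, m$right_cys_pos) ==
                    "C"))
  expect_true(all(m$left_cys_pos < m$motif_start))
  expect_true(all(m$right_cys_pos > m$motif_start + 2))
  expect_equal(m$left_spacer, m$motif_start - m$left_cys_pos - 1L)
  expect_equal(m$right_spacer, m$right_cys_pos - (m$motif_start + 2L) - 1L)
  expect_true(all(m$left_spacer >= 0 & m$left_spacer <= 16))
  expect_true(all(m$right_spacer >= 0 & m$right_spacer <= 16))
})

test_that("enlarging spacers never removes a match", {
  rec <- random_protein_records(60, length_range = c(30, 200),
                                cys_freq = 0.08, seed = 31)
  tight <- scan_collection(rec, default_patterns(max_left_spacer = 4,
                                                 max_right_spacer = 4))$matches
  wide <- scan_collection(rec)$matches
  expect_true(all(match_key(tight) %in% match_key(wide)))

  # with unbounded spacers every occurrence with >= 1 Cys on each side shows
  L <- max(nchar(rec$residues))
  unbounded <- scan_collection(rec, default_patterns(max_left_spacer = L,
                                                     max_right_spacer = L))
  want <- enumerate_flanked_motifs(rec, default_patterns(
    max_left_spacer = L, max_right_spacer = L))
  expect_setequal(match_key(unbounded$matches), match_key(want))
})

test_that("results do not depend on pattern order", {
  rec <- random_protein_records(40, length_range = c(50, 250),
                                cys_freq = 0.1, seed = 77)
  a <- scan_collection(rec, default_motifs())$matches
  b <- scan_collection(rec, rev(default_motifs()))$matches
  expect_identical(a, b)
})

test_that("per-sequence counts include zero-match records", {
  rec <- make_records(c("AAACRGDCAAA", "MKKLMKKL", "DDDDDDDD"))
  mt <- scan_collection(rec, "RGD")
  expect_equal(mt$counts$n_matches, c(1L, 0L, 0L))
  expect_equal(nrow(mt$matches), 1L)

  empty <- scan_collection(make_records(character()))
  expect_equal(nrow(empty$matches), 0L)
  expect_equal(nrow(empty$counts), 0L)
})

test_that("duplicate pattern tripeptides are rejected", {
  expect_error(scan_collection(make_records("CRGDC"), c("RGD", "RGD")),
               "distinct")
})
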