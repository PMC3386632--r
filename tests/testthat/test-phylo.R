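random_alignment <- function(n_taxa, n_cols, seed, gap_frac = 0.1) {
  withr::with_seed(seed, {
    m <- matrix(sample(c(strsplit("ACDEFG", "")[[1]], "-"), n_taxa * n_cols,
                       replace = TRUE,
                       prob = c(rep((1 - gap_frac) / 6, 6), gap_frac)),
                nrow = n_taxa,
                dimnames = list(sprintf("t%d", seq_len(n_taxa)), NULL))
    rows <- apply(m, 1, paste, collapse = "")
    aln_text <- as.vector(rbind(paste0(">", names(rows)), rows))
    aln_text
  })
}

test_that("aligned FASTA and Clustal input give the same alignment", {
  fa <- write_tmp_fasta(c(">sA", "MK-LLV", ">sB", "MKALLV", ">sC", "MKALLI"))
  a1 <- read_alignment(fa, "fasta")
  cl <- write_tmp_fasta(c("CLUSTAL W (1.83) multiple sequence alignment", "",
                          "sA      MK-", "sB      MKA", "sC      MKA",
                          "",
                          "sA      LLV", "sB      LLV", "sC      LLI"))
  a2 <- read_alignment(cl, "clustal")
  expect_equal(a1$ids, a2$ids)
  expect_equal(a1$rows, a2$rows)
  expect_equal(a1$n_cols, 6L)
})

test_that("ragged alignments are rejected naming the offending row", {
  fa <- write_tmp_fasta(c(">sA", strrep("A", 50), ">sB", strrep("A", 49)))
  expect_error(read_alignment(fa, "fasta"), "sB")
})

test_that("p-distance implements pairwise gap deletion", {
  aln <- function(rows, ids = sprintf("r%d", seq_along(rows)))
    read_alignment(write_tmp_fasta(as.vector(rbind(paste0(">", ids), rows))),
                   "fasta")
  expect_equal(p_distance(aln(c("AAAA", "AAAA")))["r1", "r2"], 0)
  expect_equal(p_distance(aln(c("AAAA", "AATT")))["r1", "r2"], 0.5)
  expect_equal(p_distance(aln(c("A-AA", "AAAA")))["r1", "r2"], 0)
  expect_error(p_distance(aln(c("A---", "-AAA"))), "r1.*r2")
})

test_that("p-distance agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  txt <- random_alignment(8, 120, seed = 5)
  aln <- read_alignment(write_tmp_fasta(txt), "fasta")
  d <- p_distance(aln)
  pd <- phangorn::as.phyDat(disintegrindb:::alignment_matrix(aln),
                            type = "AA")
  ref <- as.matrix(phangorn::dist.hamming(pd, exclude = "pairwise"))
  expect_equal(d, ref[rownames(d), colnames(d)], tolerance = 1e-12)
})

test_that("three-taxon branch lengths follow the closed-form formulas", {
  d <- matrix(c(0, 0.2, 0.3, 0.2, 0, 0.4, 0.3, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  tip_edge <- function(lab)
    tr$edge.length[tr$edge[, 2] == match(lab, tr$tip.label)]
  expect_equal(tip_edge("A"), (0.2 + 0.3 - 0.4) / 2, tolerance = 1e-12)
  expect_equal(tip_edge("B"), (0.2 + 0.4 - 0.3) / 2, tolerance = 1e-12)
  expect_equal(tip_edge("C"), (0.3 + 0.4 - 0.2) / 2, tolerance = 1e-12)
})

test_that("NJ recovers additive matrices exactly", {
  for (seed in 1:20) {
    tr <- withr::with_seed(seed, {
      t0 <- ape::rtree(sample(5:12, 1), rooted = FALSE)
      t0$edge.length <- runif(nrow(t0$edge), 0.01, 0.5)
      t0
    })
    dm <- cophenetic(tr)
    rec <- neighbor_joining(dm)
    expect_equal(ape::dist.topo(tr, rec), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    expect_lt(max(abs(cophenetic(rec)[rownames(dm), colnames(dm)] - dm)),
              1e-9)
  }
})

test_that("NJ is deterministic under total tie degeneracy", {
  d <- matrix(0.3, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_true(all(t1$edge.length >= 0))
})

test_that("negative NJ branch lengths are clamped with raw values kept", {
  # a non-additive matrix known to produce a negative NJ branch
  d <- matrix(c(0, 0.1, 0.5, 0.55,
                0.1, 0, 0.45, 0.55,
                0.5, 0.45, 0, 0.05,
                0.55, 0.55, 0.05, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 0.9  # force distortion
  tr <- neighbor_joining(d)
  raw <- attr(tr, "raw_edge_lengths")
  expect_true(all(tr$edge.length >= 0))
  expect_equal(pmax(raw, 0), tr$edge.length)
})

test_that("a perfectly separating alignment gets 100% support", {
  aln <- generate_alignment_fixture(
    list(taxa = c("A", "B", "C", "D"),
         splits = list(list(side = c("A", "B"), weight = 1))),
    n_cols = 60, seed = 2)
  tr <- bootstrap_support(aln, replicates = 100, seed = 4)
  internal <- setdiff(tr$node.label, "")
  expect_equal(internal, "100")
})

test_that("bootstrap supports are seeded, bounded, and leaf-order invariant", {
  aln <- generate_alignment_fixture(
    list(taxa = LETTERS[1:6],
         splits = list(list(side = c("A", "B"), weight = 2),
                       list(side = c("A", "C"), weight = 1),
                       list(side = c("E", "F"), weight = 2))),
    n_cols = 60, seed = 8)
  t1 <- bootstrap_support(aln, replicates = 150, seed = 99)
  t2 <- bootstrap_support(aln, replicates = 150, seed = 99)
  expect_identical(t1$node.label, t2$node.label)
  sup <- as.integer(setdiff(t1$node.label, ""))
  expect_true(all(sup >= 0 & sup <= 100))
  # conflicting column classes keep at least one edge away from certainty
  expect_true(any(sup > 0 & sup < 100))

  # leaf-order invariance: replicates whose Q criterion ties exactly may
  # resolve differently under a permuted taxon order, so supports of the
  # shared bipartitions must agree up to those few tied replicates
  perm <- rev(aln$ids)
  aln2 <- structure(list(ids = perm, rows = aln$rows[perm],
                         n_cols = aln$n_cols), class = "protein_alignment")
  t3 <- bootstrap_support(aln2, replicates = 150, seed = 99)
  sup_of <- function(tr) {
    parts <- ape::prop.part(tr)
    lab <- attr(parts, "labels")
    keys <- vapply(parts, function(p) paste(sort(lab[p]), collapse = ","), "")
    vals <- suppressWarnings(as.integer(tr$node.label))
    setNames(vals, keys)[!is.na(vals)]
  }
  s1 <- sup_of(t1)
  s3 <- sup_of(t3)
  shared <- intersect(names(s1), names(s3))
  expect_gt(length(shared), 1L)
  expect_lte(max(abs(s1[shared] - s3[shared])), 3L)
})

test_that("Newick output has 6-decimal lengths and parses back", {
  d <- matrix(c(0, 0.2, 0.3, 0.2, 0, 0.4, 0.3, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  s <- write_newick(neighbor_joining(d))
  expect_match(s, "^\\([A-C]:0\\.[0-9]{6},[A-C]:0\\.[0-9]{6},[A-C]:0\\.[0-9]{6}\\);$")
  expect_true(grepl("A:0.050000", s, fixed = TRUE))

  for (seed in 1:5) {
    tr <- withr::with_seed(seed, {
      t0 <- ape::rtree(8, rooted = FALSE)
      t0$edge.length <- round(runif(nrow(t0$edge), 0, 1), 4)
      t0
    })
    path <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, path)
    back <- ape::read.tree(path)
    expect_equal(ape::dist.topo(tr, back), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    expect_lt(max(abs(sort(back$edge.length) - sort(tr$edge.length))), 1e-6)
  }

  # supports appear as labels after the closing parenthesis
  aln <- generate_alignment_fixture(
    list(taxa = c("A", "B", "C", "D"),
         splits = list(list(side = c("A", "B"), weight = 1))),
    n_cols = 30, seed = 3)
  s <- write_newick(bootstrap_support(aln, replicates = 50, seed = 1))
  expect_match(s, "\\)100:")
})
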