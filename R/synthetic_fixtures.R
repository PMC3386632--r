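# Synthetic proteomes with planted signal peptides, planted
# cysteine-flanked motifs and decoys, plus a ground-truth ledger, so
# every pipeline stage is testable offline. The ledger is audited with
# a brute-force enumerator before use, so fixture-based counts are
# exact even when the random background creates accidental motifs.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

TAXON_CODES <- c(
  Ixodoidea = "IXODO", Cimicomorpha = "CIMIC", Tabanidae = "TABAN",
  Glossina = "GLOSS", Culicidae = "CULIC", Psychodidae = "PSYCH",
  Simuliidae = "SIMUL", Ceratopogonidae = "CERAT",
  Siphonaptera = "SIPHO", Hirudinea = "HIRUD", Rhabditida = "RHABD")

bg_chars <- function(k, cys_freq) {
  if (k <= 0L) return(character())
  p <- rep((1 - cys_freq) / 19, 20L)
  p[match("C", AA20)] <- cys_freq
  sample(AA20, k, replace = TRUE, prob = p)
}

# background with no cysteine (spacer filler; keeps planted flanks innermost)
bg_no_cys <- function(k) {
  if (k <= 0L) return(character())
  sample(setdiff(AA20, "C"), k, replace = TRUE)
}

# Signal prefix satisfying the gate heuristic by construction:
# M K <h-run from LVIF> A Q A. The run plus the following A gives an
# h-region ending at position 3 + h, and the A.A pattern places the
# (-3,-1) cleavage site exactly at the prefix end.
signal_prefix <- function(h = sample(8:12, 1L)) {
  c("M", "K", sample(c("L", "V", "I", "F"), h, replace = TRUE), "A", "Q", "A")
}

# Signal prefix that carries a motif inside the signal region:
# M K C <trip> C <h-run> A Q A; cleavage lands at the prefix end, so
# the motif (start position 4) overlaps the signal peptide.
signal_prefix_with_motif <- function(tripeptide, h = sample(8:12, 1L)) {
  c("M", "K", "C", strsplit(tripeptide, "")[[1L]], "C",
    sample(c("L", "V", "I", "F"), h, replace = TRUE), "A", "Q", "A")
}

# detectable planted segment: C <sl> TRIP <sr> C, spacers cysteine-free
motif_segment <- function(tripeptide, sl, sr) {
  c("C", bg_no_cys(sl), strsplit(tripeptide, "")[[1L]], bg_no_cys(sr), "C")
}

ledger_row <- function(seq_id, kind, decoy_kind = "", tripeptide = "",
                       motif_start = NA_integer_, left_spacer = NA_integer_,
                       right_spacer = NA_integer_, expected_detection) {
  data.frame(seq_id = seq_id, kind = kind, decoy_kind = decoy_kind,
             tripeptide = tripeptide, motif_start = as.integer(motif_start),
             left_spacer = as.integer(left_spacer),
             right_spacer = as.integer(right_spacer),
             expected_detection = expected_detection,
             stringsAsFactors = FALSE)
}

empty_ledger <- function() {
  ledger_row(character(), character(), character(), character(),
             integer(), integer(), integer(), logical())[0L, ]
}

#' Generate a synthetic proteome with a ground-truth ledger
#'
#' Emulates a downloaded secreted-protein set: each sequence gets a
#' taxon label and organism code from the default blood-feeder taxon
#' list, a planted signal peptide with probability
#' \code{signal_fraction} (sequences without one are constructed to
#' fail the gate's h-region requirement), and possibly one planted
#' item: a detectable cysteine-flanked motif (probability
#' \code{motif_density}, spacers uniform on 0..16), a duodegrin pair of
#' two distinct detectable motifs, or one of three decoys — a motif
#' with no cysteine within the right window (\code{no_flank}), a motif
#' whose left spacer is exactly 17 (\code{spacer17}), or a motif inside
#' the signal region (\code{in_signal}; detectable, flagged as
#' overlapping the signal).
#'
#' The returned ledger lists every planted item with its expected
#' detectability; when \code{audit = TRUE} (default) it is passed
#' through [audit_proteome()] so accidental background motifs are
#' added and planted decoys are verified absent — making ledger-based
#' exact-count tests safe.
#'
#' @param n Number of sequences.
#' @param length_range Min/max sequence length (before planted
#'   segments, which add their own length).
#' @param motif_density Probability of a single planted detectable
#'   motif per sequence.
#' @param signal_fraction Probability of a planted signal peptide.
#' @param decoy_mix Named probabilities for \code{no_flank},
#'   \code{spacer17}, \code{in_signal}.
#' @param duodegrin_fraction Probability of a planted pair of distinct
#'   detectable motifs.
#' @param cys_freq Background cysteine frequency (other residues
#'   uniform).
#' @param motifs Tripeptides to plant (default the eight disintegrin
#'   motifs).
#' @param seed Integer seed; identical seed gives byte-identical
#'   records and ledger.
#' @param audit Run [audit_proteome()] on the result.
#' @return List with \code{records} (sequence-record data.frame) and
#'   \code{ledger}.
#' @export
generate_proteome <- function(n, length_range = c(90, 260),
                              motif_density = 0.45, signal_fraction = 0.7,
                              decoy_mix = c(no_flank = 0.08,
                                            spacer17 = 0.08,
                                            in_signal = 0.08),
                              duodegrin_fraction = 0.06, cys_freq = 0.02,
                              motifs = default_motifs(), seed = 1L,
                              audit = TRUE) {
  stopifnot(n >= 1L, length(length_range) == 2L,
            length_range[[1L]] >= 60L, cys_freq >= 0, cys_freq < 1)
  for (k in c("no_flank", "spacer17", "in_signal"))
    if (is.na(decoy_mix[k])) decoy_mix[k] <- 0
  if (length(motifs) < 2L) duodegrin_fraction <- 0
  p_cat <- c(motif = motif_density, duodegrin = duodegrin_fraction,
             no_flank = unname(decoy_mix["no_flank"]),
             spacer17 = unname(decoy_mix["spacer17"]),
             in_signal = unname(decoy_mix["in_signal"]))
  if (sum(p_cat) > 1) stop("category probabilities exceed 1")
  p_cat <- c(p_cat, none = 1 - sum(p_cat))
  with_local_seed(seed, {
    recs <- vector("list", n)
    ledg <- vector("list", n)
    taxa <- names(TAXON_CODES)
    for (i in seq_len(n)) {
      taxon <- sample(taxa, 1L)
      id <- sprintf("%s_%06d", TAXON_CODES[[taxon]], 100000L + i)
      category <- sample(names(p_cat), 1L, prob = p_cat)
      secreted <- stats::runif(1) < signal_fraction
      if (category == "in_signal") secreted <- TRUE
      len <- sample(seq.int(length_range[[1L]], length_range[[2L]]), 1L)
      rows <- list()

      if (category == "in_signal") {
        trip <- sample(motifs, 1L)
        prefix <- signal_prefix_with_motif(trip)
        rows[[length(rows) + 1L]] <-
          ledger_row(id, "decoy", "in_signal", trip, 4L, 0L, 0L, TRUE)
      } else if (secreted) {
        prefix <- signal_prefix()
      } else {
        prefix <- character()
      }

      segments <- list()
      if (category == "motif" || category == "duodegrin") {
        k <- if (category == "motif") 1L else 2L
        trips <- sample(motifs, k)
        for (t in trips) {
          sl <- sample(0:16, 1L)
          sr <- sample(0:16, 1L)
          segments[[length(segments) + 1L]] <-
            list(chars = motif_segment(t, sl, sr), trip = t,
                 motif_off = 1L + sl, sl = sl, sr = sr, expected = TRUE,
                 kind = "motif", decoy_kind = "")
        }
      } else if (category == "no_flank") {
        trip <- sample(motifs, 1L)
        sl <- sample(0:16, 1L)
        segments[[1L]] <- list(
          chars = c("C", bg_no_cys(sl), strsplit(trip, "")[[1L]],
                    bg_no_cys(17L)),
          trip = trip, motif_off = 1L + sl, sl = sl, sr = NA_integer_,
          expected = FALSE, kind = "decoy", decoy_kind = "no_flank")
      } else if (category == "spacer17") {
        trip <- sample(motifs, 1L)
        sr <- sample(0:16, 1L)
        segments[[1L]] <- list(
          chars = c("C", bg_no_cys(17L), strsplit(trip, "")[[1L]],
                    bg_no_cys(sr), "C"),
          trip = trip, motif_off = 18L, sl = 17L, sr = sr,
          expected = FALSE, kind = "decoy", decoy_kind = "spacer17")
      }

      bg_len <- max(len - length(prefix) -
                      sum(vapply(segments, function(s) length(s$chars), 1L)),
                    40L)
      bg <- bg_chars(bg_len, cys_freq)
      # sequences without a planted signal must fail the h-region rule;
      # break any hydrophobic run inside the 1..30 window
      if (!length(prefix)) bg[c(8L, 16L, 24L)] <- "G"
      min_cut <- if (length(prefix)) 0L else 30L
      n_seg <- length(segments)
      chars <- prefix
      if (n_seg) {
        cuts <- sort(sample(seq.int(min_cut, bg_len - 1L), n_seg))
        prev <- 0L
        for (s in seq_len(n_seg)) {
          chars <- c(chars, bg[seq_len(cuts[[s]] - prev) + prev])
          g0 <- length(chars) + 1L
          seg <- segments[[s]]
          chars <- c(chars, seg$chars)
          rows[[length(rows) + 1L]] <-
            ledger_row(id, seg$kind, seg$decoy_kind, seg$trip,
                       g0 + seg$motif_off, seg$sl, seg$sr, seg$expected)
          prev <- cuts[[s]]
        }
        if (prev < bg_len) chars <- c(chars, bg[seq.int(prev + 1L, bg_len)])
      } else {
        chars <- c(chars, bg)
      }
      rows[[length(rows) + 1L]] <-
        ledger_row(id, "signal", "", "", NA, NA, NA, length(prefix) > 0L)

      recs[[i]] <- new_sequence_records(
        id = id, organism_code = TAXON_CODES[[taxon]],
        taxon_label = taxon, description = taxon,
        residues = paste(chars, collapse = ""))
      ledg[[i]] <- do.call(rbind, rows)
    }
    records <- do.call(rbind, recs)
    ledger <- do.call(rbind, ledg)
    rownames(records) <- rownames(ledger) <- NULL
    out <- list(records = records, ledger = ledger)
    if (audit) out$ledger <- audit_proteome(records, ledger,
                                            default_patterns(motifs))
    out
  })
}

#' Random protein sequences with elevated cysteine frequency
#'
#' Plain random background records (no planting), used for
#' oracle-equivalence stress tests of the motif scanner.
#'
#' @param n Number of sequences.
#' @param length_range Min/max length.
#' @param cys_freq Cysteine frequency (default 0.08; other residues
#'   uniform).
#' @param seed Integer seed.
#' @return A sequence-record data.frame.
#' @export
random_protein_records <- function(n, length_range = c(20, 400),
                                   cys_freq = 0.08, seed = 1L) {
  with_local_seed(seed, {
    lens <- sample(seq.int(length_range[[1L]], length_range[[2L]]), n,
                   replace = TRUE)
    new_sequence_records(
      id = sprintf("RND%05d_%d", seq_len(n), lens),
      organism_code = "", taxon_label = "", description = "",
      residues = vapply(lens, function(L)
        paste(bg_chars(L, cys_freq), collapse = ""), ""))
  })
}

#' Brute-force reference enumeration of cysteine-flanked motifs
#'
#' Independent of the scanner's windowed search: for every tripeptide
#' occurrence it enumerates every (left cysteine, occurrence, right
#' cysteine) triple, filters the triples on the spacer-bound
#' definition, and keeps the innermost cysteine on each side. Used to
#' audit fixture ledgers and as the reference in equivalence tests.
#'
#' @param records Sequence-record data.frame.
#' @param patterns As for [scan_sequence()].
#' @return A match data.frame with the same columns as
#'   [scan_sequence()] (without signal flags; \code{overlaps_signal}
#'   is FALSE throughout).
#' @export
enumerate_flanked_motifs <- function(records, patterns = default_patterns()) {
  patterns <- as_pattern_list(patterns)
  out <- list()
  for (i in seq_len(nrow(records))) {
    chars <- strsplit(records$residues[[i]], "")[[1L]]
    cys <- which(chars == "C")
    n <- length(chars)
    for (p in patterns) {
      t <- strsplit(p$tripeptide, "")[[1L]]
      if (n < 3L) next
      occ <- Filter(function(s) all(chars[s:(s + 2L)] == t),
                    seq_len(n - 2L))
      for (s in occ) {
        if (!length(cys)) next
        triples <- expand.grid(lc = cys, rc = cys)
        triples$ls <- s - triples$lc - 1L
        triples$rs <- triples$rc - (s + 2L) - 1L
        keep <- triples$lc < s & triples$rc > s + 2L &
          triples$ls >= 0L & triples$ls <= p$max_left_spacer &
          triples$rs >= 0L & triples$rs <= p$max_right_spacer
        triples <- triples[keep, , drop = FALSE]
        if (!nrow(triples)) next
        lc <- max(triples$lc)
        rc <- min(triples$rc)
        out[[length(out) + 1L]] <- data.frame(
          seq_id = records$id[[i]], tripeptide = p$tripeptide,
          motif_start = s, left_cys_pos = lc, right_cys_pos = rc,
          left_spacer = s - lc - 1L, right_spacer = rc - (s + 2L) - 1L,
          overlaps_signal = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_match_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Audit a fixture ledger against the brute-force enumerator
#'
#' Verifies that every planted detectable motif is found by
#' [enumerate_flanked_motifs()], that no planted decoy is found, and
#' appends any accidental background motif as a ledger entry of kind
#' \code{"accidental"}. After auditing, the set of
#' \code{expected_detection} motif entries equals the scanner's exact
#' expected output.
#'
#' @param records Generated records.
#' @param ledger Planted ledger from [generate_proteome()].
#' @param patterns Patterns the fixture targets.
#' @return The augmented ledger.
#' @export
audit_proteome <- function(records, ledger, patterns = default_patterns()) {
  enum <- enumerate_flanked_motifs(records, patterns)
  key <- function(d) paste(d$seq_id, d$tripeptide, d$motif_start)
  motif_rows <- ledger$kind %in% c("motif", "decoy")
  planted_true <- ledger[motif_rows & ledger$expected_detection, ,
                         drop = FALSE]
  planted_false <- ledger[motif_rows & !ledger$expected_detection, ,
                          drop = FALSE]
  miss <- setdiff(key(planted_true), key(enum))
  if (length(miss))
    stop("fixture audit: planted motif not detectable: ", miss[[1L]])
  leak <- intersect(key(planted_false), key(enum))
  if (length(leak))
    stop("fixture audit: planted decoy is detectable: ", leak[[1L]])
  extra <- enum[!key(enum) %in% key(planted_true), , drop = FALSE]
  if (nrow(extra)) {
    acc <- ledger_row(extra$seq_id, "accidental", "", extra$tripeptide,
                      extra$motif_start, extra$left_spacer,
                      extra$right_spacer, TRUE)
    ledger <- rbind(ledger, acc)
    rownames(ledger) <- NULL
  }
  ledger
}

#' Generate an alignment fixture with known separating columns
#'
#' Columns are built to support stated bipartitions: each split gets a
#' share of columns (by weight) in which the taxa on one side carry one
#' residue and the rest another. Used to exercise the phylogenetics
#' module with predictable bootstrap behavior.
#'
#' @param tree_spec List with \code{taxa} (character vector) and
#'   \code{splits}, a list of \code{list(side = <taxa subset>, weight =
#'   <positive number>)}.
#' @param n_cols Total alignment columns.
#' @param seed Integer seed.
#' @return A \code{protein_alignment}.
#' @export
generate_alignment_fixture <- function(tree_spec, n_cols, seed = 1L) {
  taxa <- tree_spec$taxa
  splits <- tree_spec$splits
  stopifnot(length(taxa) >= 3L, length(splits) >= 1L, n_cols >= 1L)
  w <- vapply(splits, `[[`, numeric(1), "weight")
  alloc <- floor(n_cols * w / sum(w))
  rem <- n_cols - sum(alloc)
  if (rem > 0L) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  with_local_seed(seed, {
    m <- matrix("", nrow = length(taxa), ncol = n_cols,
                dimnames = list(taxa, NULL))
    col <- 1L
    for (s in seq_along(splits)) {
      side <- splits[[s]]$side
      if (!all(side %in% taxa)) stop("split side not a subset of taxa")
      for (k in seq_len(alloc[[s]])) {
        pair <- sample(AA20, 2L)
        m[, col] <- ifelse(taxa %in% side, pair[[1L]], pair[[2L]])
        col <- col + 1L
      }
    }
    matrix_as_alignment(m)
  })
}
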