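# The disintegrin search pattern: a literal tripeptide motif flanked on
# both sides by a cysteine, with 0..16 intervening spacer residues on
# each side (C-x(0,16)-X-Y-Z-x(0,16)-C). This is the core of the
# package and is implemented here, not delegated.

#' The eight default disintegrin tripeptide motifs
#'
#' @return Character vector: RGD, MLD, KGD, VGD, KTS, RTS, WGD, RED.
#' @export
default_motifs <- function() {
  c("RGD", "MLD", "KGD", "VGD", "KTS", "RTS", "WGD", "RED")
}

#' Construct a motif pattern
#'
#' A pattern is a literal tripeptide plus bounded spacer windows to the
#' innermost flanking cysteines. Matching is exact-literal: a tripeptide
#' never matches a position containing the unknown residue X, so X is
#' not allowed in a pattern.
#'
#' @param tripeptide String of exactly 3 residues from the 20-letter
#'   amino-acid alphabet (no X).
#' @param max_left_spacer,max_right_spacer Maximum number of residues
#'   allowed strictly between the flanking cysteine and the motif
#'   (default 16 on both sides).
#' @param require_flanks If TRUE (default) a motif occurrence is only
#'   reported when a qualifying cysteine exists on both sides.
#' @return A list of class \code{motif_pattern}.
#' @export
motif_pattern <- function(tripeptide, max_left_spacer = 16L,
                          max_right_spacer = 16L, require_flanks = TRUE) {
  if (!is.character(tripeptide) || length(tripeptide) != 1L ||
      nchar(tripeptide) != 3L)
    stop("pattern tripeptide must be a single 3-residue string")
  tripeptide <- toupper(tripeptide)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", tripeptide))
    stop("pattern tripeptide '", tripeptide,
         "' contains a character outside the amino-acid alphabet")
  if (!is.numeric(max_left_spacer) || !is.numeric(max_right_spacer) ||
      max_left_spacer < 0 || max_right_spacer < 0)
    stop("spacer bounds must be non-negative")
  structure(list(tripeptide = tripeptide,
                 max_left_spacer = as.integer(max_left_spacer),
                 max_right_spacer = as.integer(max_right_spacer),
                 require_flanks = isTRUE(require_flanks)),
            class = "motif_pattern")
}

#' Build the default pattern set
#'
#' @param motifs Character vector of tripeptides (default the eight
#'   disintegrin motifs).
#' @param max_left_spacer,max_right_spacer Spacer bounds applied to all.
#' @return List of \code{motif_pattern} objects.
#' @export
default_patterns <- function(motifs = default_motifs(),
                             max_left_spacer = 16L,
                             max_right_spacer = 16L) {
  lapply(motifs, motif_pattern, max_left_spacer = max_left_spacer,
         max_right_spacer = max_right_spacer)
}

as_pattern_list <- function(patterns) {
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  patterns <- lapply(patterns, function(p) {
    if (inherits(p, "motif_pattern")) p else motif_pattern(p)
  })
  trips <- vapply(patterns, `[[`, character(1), "tripeptide")
  if (anyDuplicated(trips))
    stop("pattern tripeptides must be distinct")
  patterns
}

empty_match_table <- function() {
  data.frame(seq_id = character(), tripeptide = character(),
             motif_start = integer(), left_cys_pos = integer(),
             right_cys_pos = integer(), left_spacer = integer(),
             right_spacer = integer(), overlaps_signal = logical(),
             stringsAsFactors = FALSE)
}

#' Scan one sequence for cysteine-flanked tripeptide motifs
#'
#' Every occurrence of every pattern tripeptide is examined
#' (occurrences may overlap each other). An occurrence is reported iff
#' a cysteine lies within the left spacer window and one lies within
#' the right spacer window; the innermost qualifying cysteine is
#' reported on each side. Flanking cysteines lie strictly outside the
#' tripeptide; a single cysteine may serve as the right flank of one
#' match and the left flank of another. Coordinates are 1-based.
#' Matches are sorted by motif start, then tripeptide.
#'
#' Scanning runs on the full precursor: matches inside a predicted
#' signal peptide are kept but flagged \code{overlaps_signal}.
#'
#' @param record One-row sequence-record data.frame (or list with
#'   \code{id} and \code{residues}).
#' @param patterns A list of [motif_pattern()] objects or a character
#'   vector of tripeptides (default spacer bounds applied).
#' @param signal Optional one-row signal prediction for this record;
#'   when present and positive, matches with
#'   \code{motif_start <= cleavage_pos} are flagged.
#' @return A data.frame of matches with columns \code{seq_id},
#'   \code{tripeptide}, \code{motif_start}, \code{left_cys_pos},
#'   \code{right_cys_pos}, \code{left_spacer}, \code{right_spacer},
#'   \code{overlaps_signal}.
#' @examples
#' rec <- list(id = "s1", residues = "CRGDC")
#' scan_sequence(rec, "RGD")
#' @export
scan_sequence <- function(record, patterns = default_patterns(),
                          signal = NULL) {
  patterns <- as_pattern_list(patterns)
  id <- record$id[[1L]]
  residues <- record$residues[[1L]]
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  cys <- which(chars == "C")
  in_signal_to <- 0L
  if (!is.null(signal) && isTRUE(signal$has_signal[[1L]]))
    in_signal_to <- as.integer(signal$cleavage_pos[[1L]])
  out <- list()
  for (p in patterns) {
    if (n < 3L) next
    t <- strsplit(p$tripeptide, "", fixed = TRUE)[[1L]]
    m <- n - 2L
    starts <- which(chars[seq_len(m)] == t[[1L]] &
                    chars[seq_len(m) + 1L] == t[[2L]] &
                    chars[seq_len(m) + 2L] == t[[3L]])
    for (s in starts) {
      lo <- max(1L, s - 1L - p$max_left_spacer)
      lc <- cys[cys >= lo & cys <= s - 1L]
      lc <- if (length(lc)) max(lc) else 0L
      hi <- min(n, s + 3L + p$max_right_spacer)
      rc <- cys[cys >= s + 3L & cys <= hi]
      rc <- if (length(rc)) min(rc) else 0L
      if (p$require_flanks && (lc == 0L || rc == 0L)) next
      out[[length(out) + 1L]] <- data.frame(
        seq_id = id, tripeptide = p$tripeptide, motif_start = s,
        left_cys_pos = lc, right_cys_pos = rc,
        left_spacer = if (lc > 0L) s - lc - 1L else NA_integer_,
        right_spacer = if (rc > 0L) rc - (s + 2L) - 1L else NA_integer_,
        overlaps_signal = in_signal_to > 0L && s <= in_signal_to,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_match_table())
  res <- do.call(rbind, out)
  res <- res[order(res$motif_start, res$tripeptide, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a whole collection
#'
#' Concatenates [scan_sequence()] results in record order and reports a
#' per-sequence match count for every record, including zeros.
#'
#' @param records Sequence-record data.frame.
#' @param patterns As for [scan_sequence()].
#' @param predictions Optional signal-prediction data.frame keyed by
#'   \code{seq_id}; used to flag matches overlapping the signal region.
#' @return A list of class \code{match_table} with \code{matches} (all
#'   match rows) and \code{counts} (data.frame of \code{seq_id},
#'   \code{n_matches} in record order).
#' @export
scan_collection <- function(records, patterns = default_patterns(),
                            predictions = NULL) {
  validate_records(records)
  patterns <- as_pattern_list(patterns)
  per <- lapply(seq_len(nrow(records)), function(i) {
    sig <- NULL
    if (!is.null(predictions)) {
      j <- match(records$id[[i]], predictions$seq_id)
      if (!is.na(j)) sig <- predictions[j, , drop = FALSE]
    }
    scan_sequence(records[i, ], patterns, signal = sig)
  })
  matches <- if (length(per)) do.call(rbind, per) else empty_match_table()
  rownames(matches) <- NULL
  counts <- data.frame(
    seq_id = records$id,
    n_matches = vapply(per, nrow, integer(1)),
    stringsAsFactors = FALSE)
  if (nrow(records) == 0L)
    counts <- data.frame(seq_id = character(), n_matches = integer(),
                         stringsAsFactors = FALSE)
  structure(list(matches = matches, counts = counts), class = "match_table")
}
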