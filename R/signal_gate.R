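# Secretion gate: a transparent, deterministic signal-peptide heuristic
# plus an import path for externally computed predictions (e.g. from a
# SignalP run), which take precedence when both exist.

SIGNAL_BASIC <- c("K", "R")
SIGNAL_HYDROPHOBIC <- c("A", "I", "L", "M", "F", "V", "W")
SIGNAL_SMALL <- c("A", "G", "S", "C", "T")
SIGNAL_MAX_CLEAVAGE <- 45L

new_signal_prediction <- function(seq_id, has_signal, cleavage_pos, score) {
  data.frame(seq_id = seq_id, has_signal = has_signal,
             cleavage_pos = as.integer(cleavage_pos), score = score,
             stringsAsFactors = FALSE)
}

# First run of >= min_len consecutive hydrophobic residues whose span
# lies within positions 1..window; returns c(start, end) or NULL.
first_hydrophobic_run <- function(chars, window = 30L, min_len = 8L) {
  w <- chars[seq_len(min(window, length(chars)))]
  r <- rle(w %in% SIGNAL_HYDROPHOBIC)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_len)
  if (!length(ok)) return(NULL)
  c(starts[ok[[1L]]], ends[ok[[1L]]])
}

#' Predict an N-terminal signal peptide with a documented heuristic
#'
#' A deterministic stand-in for a full signal-peptide predictor,
#' modelled on the classical tripartite architecture: a positively
#' charged n-region, a hydrophobic h-region, and a cleavage site obeying
#' the von Heijne (-3,-1) small-residue rule. A sequence is called
#' secreted iff (a) positions 1..10 contain at least one K or R, or the
#' sequence starts with M, and (b) positions 1..30 contain a run of at
#' least 8 consecutive residues from the hydrophobic set
#' \{A,I,L,M,F,V,W\}. The cleavage position (1-based position of the
#' last signal-peptide residue) is the first position p after the
#' h-region end, searched up to 45, with small residues
#' \{A,G,S,C,T\} at p-2 and p; if no such site exists it falls back to
#' the h-region end + 5, capped at 45 and at sequence length - 1. The
#' score is the h-run length / 30, capped at 1.
#'
#' @param record A one-row sequence-record data.frame, or a list with
#'   elements \code{id} and \code{residues}.
#' @return A one-row data.frame with columns \code{seq_id},
#'   \code{has_signal}, \code{cleavage_pos} (0 when no signal) and
#'   \code{score}. Sequences shorter than 15 residues are never called
#'   secreted (score 0).
#' @export
predict_signal <- function(record) {
  id <- record$id[[1L]]
  residues <- record$residues[[1L]]
  n <- nchar(residues)
  if (n < 15L) return(new_signal_prediction(id, FALSE, 0L, 0))
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  run <- first_hydrophobic_run(chars)
  score <- if (is.null(run)) 0 else min((run[[2L]] - run[[1L]] + 1L) / 30, 1)
  n_region <- any(chars[1:10] %in% SIGNAL_BASIC) || chars[[1L]] == "M"
  if (!n_region || is.null(run))
    return(new_signal_prediction(id, FALSE, 0L, score))
  h_end <- run[[2L]]
  cap <- min(SIGNAL_MAX_CLEAVAGE, n - 1L)
  cleave <- 0L
  p <- h_end + 1L
  while (p <= cap) {
    if (p - 2L >= 1L && chars[[p - 2L]] %in% SIGNAL_SMALL &&
        chars[[p]] %in% SIGNAL_SMALL) {
      cleave <- p
      break
    }
    p <- p + 1L
  }
  if (cleave == 0L) cleave <- min(h_end + 5L, cap)
  new_signal_prediction(id, TRUE, cleave, score)
}

#' Predict signal peptides for a whole collection
#'
#' @param records A sequence-record data.frame.
#' @return A data.frame of predictions, one row per record, in record
#'   order.
#' @export
predict_signal_collection <- function(records) {
  if (nrow(records) == 0L)
    return(new_signal_prediction(character(), logical(), integer(), numeric()))
  do.call(rbind, lapply(seq_len(nrow(records)),
                        function(i) predict_signal(records[i, ])))
}

#' Load externally computed signal-peptide predictions
#'
#' Reads a TSV with header columns \code{seq_id}, \code{has_signal}
#' (\code{Y}/\code{N}), \code{cleavage_pos} and \code{score}. Rows with
#' \code{has_signal} \code{N} have their cleavage position forced to 0
#' regardless of the column value. Malformed rows and duplicate ids are
#' errors.
#'
#' @param path Path to the TSV file.
#' @return A prediction data.frame keyed by \code{seq_id}.
#' @export
load_external_predictions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("seq_id", "has_signal", "cleavage_pos", "score")
  if (!all(req %in% names(tab)))
    stop("prediction table needs columns: ", paste(req, collapse = ", "))
  if (nrow(tab) == 0L)
    return(new_signal_prediction(character(), logical(), integer(), numeric()))
  for (i in seq_len(nrow(tab))) {
    line <- i + 1L  # header is line 1
    if (!tab$has_signal[[i]] %in% c("Y", "N"))
      stop(sprintf("line %d: has_signal must be Y or N", line))
    if (is.na(suppressWarnings(as.integer(tab$cleavage_pos[[i]]))))
      stop(sprintf("line %d: cleavage_pos is not an integer", line))
    sc <- suppressWarnings(as.numeric(tab$score[[i]]))
    if (is.na(sc) || sc < 0 || sc > 1)
      stop(sprintf("line %d: score must be a number in [0,1]", line))
  }
  dup <- tab$seq_id[duplicated(tab$seq_id)]
  if (length(dup)) stop("duplicate seq_id in prediction table: ", dup[[1L]])
  has <- tab$has_signal == "Y"
  new_signal_prediction(tab$seq_id, has,
                        ifelse(has, as.integer(tab$cleavage_pos), 0L),
                        as.numeric(tab$score))
}

#' Filter a collection on predicted secretion
#'
#' Implements the secretion gate: under policy \code{"require"} only
#' records predicted to carry a signal peptide are kept and a drop log
#' records each removal; under policy \code{"annotate"} every record is
#' kept and the verdict is carried as metadata. External predictions
#' take precedence over the heuristic when both exist.
#'
#' @param records A sequence-record data.frame.
#' @param predictions Optional prediction data.frame (e.g. from
#'   [load_external_predictions()]); records absent from it are resolved
#'   with [predict_signal()].
#' @param policy \code{"require"} or \code{"annotate"}.
#' @return A list with \code{kept} (records plus columns
#'   \code{has_signal}, \code{cleavage_pos}, \code{score}),
#'   \code{drop_log} (data.frame of \code{seq_id}, \code{reason}) and
#'   \code{predictions} (the resolved per-record predictions).
#' @export
filter_secreted <- function(records, predictions = NULL,
                            policy = c("require", "annotate")) {
  policy <- match.arg(policy)
  validate_records(records)
  resolved <- predict_signal_collection(records)
  if (!is.null(predictions) && nrow(predictions) > 0L) {
    idx <- match(records$id, predictions$seq_id)
    ext <- which(!is.na(idx))
    resolved[ext, c("has_signal", "cleavage_pos", "score")] <-
      predictions[idx[ext], c("has_signal", "cleavage_pos", "score")]
  }
  annotated <- cbind(records,
                     resolved[, c("has_signal", "cleavage_pos", "score")])
  if (policy == "annotate") {
    kept <- annotated
    drop_log <- data.frame(seq_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  } else {
    keep <- annotated$has_signal
    kept <- annotated[keep, , drop = FALSE]
    rownames(kept) <- NULL
    drop_log <- data.frame(seq_id = annotated$id[!keep],
                           reason = rep("no predicted signal peptide",
                                        sum(!keep)),
                           stringsAsFactors = FALSE)
  }
  list(kept = kept, drop_log = drop_log, predictions = resolved)
}
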