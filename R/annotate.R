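# Putative integrin/cell-target annotation per motif class, duodegrin
# flagging, and the output sialogenin database table.

#' Default tripeptide-to-integrin annotation table
#'
#' The mapping records the integrin specificities reported for each
#' motif class in characterized disintegrins: RGD and WGD with the
#' aIIbb3/avb3/a5b1 group of platelet and endothelial receptors, KGD
#' selective for the platelet fibrinogen receptor aIIbb3, MLD with the
#' leukocyte integrins a4b1/a4b7/a9b1, KTS and RTS selective for the
#' collagen-IV receptor a1b1, VGD with the fibronectin receptor a5b1,
#' and RED (as in disagregin, where RED replaces RGD on the
#' Kunitz-fold loop) with aIIbb3. The targets are putative for any
#' sequence found by motif scanning alone; the table is data, editable
#' or replaceable via [load_annotation_table()].
#'
#' @return A data.frame with columns \code{tripeptide},
#'   \code{integrin_targets}, \code{cell_targets} (comma-joined, fixed
#'   canonical order) and \code{provenance_note}.
#' @export
default_annotation_table <- function() {
  data.frame(
    tripeptide = c("RGD", "KGD", "WGD", "MLD", "KTS", "RTS", "VGD", "RED"),
    integrin_targets = c(
      "αIIbβ3,αvβ3,α5β1",
      "αIIbβ3",
      "αIIbβ3,αvβ3,α5β1",
      "α4β1,α4β7,α9β1",
      "α1β1",
      "α1β1",
      "α5β1",
      "αIIbβ3"),
    cell_targets = c(
      "platelets,endothelial cells", "platelets",
      "platelets,endothelial cells", "leukocytes",
      "endothelial cells", "endothelial cells",
      "endothelial cells", "platelets"),
    provenance_note = c(
      "RGD class: platelet fibrinogen, vitronectin, fibronectin receptors",
      "KGD: aIIbb3-selective (barbourin class)",
      "WGD grouped with the aIIbb3/avb3/a5b1 class",
      "MLD: leukocyte a4/a9 integrins",
      "KTS: a1b1-selective (obtustatin class)",
      "RTS: a1b1-selective (jerdostatin class)",
      "VGD: a5 integrins (fibronectin receptor)",
      "RED: aIIbb3 (disagregin, Kunitz fold)"),
    stringsAsFactors = FALSE)
}

#' Load an annotation table from TSV
#'
#' Same schema as [default_annotation_table()]; lets users edit the
#' putative target mapping without touching code.
#'
#' @param path TSV file with header \code{tripeptide},
#'   \code{integrin_targets}, \code{cell_targets},
#'   \code{provenance_note}.
#' @return Annotation data.frame.
#' @export
load_annotation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("tripeptide", "integrin_targets", "cell_targets",
           "provenance_note")
  if (!all(req %in% names(tab)))
    stop("annotation table needs columns: ", paste(req, collapse = ", "))
  tab$tripeptide <- toupper(tab$tripeptide)
  if (anyDuplicated(tab$tripeptide))
    stop("duplicate tripeptide in annotation table")
  tab
}

#' Annotate one motif match with its putative targets
#'
#' @param match One-row match data.frame (from [scan_sequence()]).
#' @param table Annotation table (default [default_annotation_table()]).
#' @return A list with \code{tripeptide}, \code{integrin_targets} and
#'   \code{cell_targets} (character vectors) and
#'   \code{provenance_note}. An unmapped tripeptide yields empty target
#'   sets and the note \code{"unmapped"}.
#' @export
classify_match <- function(match, table = default_annotation_table()) {
  trip <- match$tripeptide[[1L]]
  i <- match(trip, table$tripeptide)
  if (is.na(i))
    return(list(tripeptide = trip, integrin_targets = character(),
                cell_targets = character(), provenance_note = "unmapped"))
  split1 <- function(x) strsplit(x, ",", fixed = TRUE)[[1L]]
  list(tripeptide = trip,
       integrin_targets = split1(table$integrin_targets[[i]]),
       cell_targets = split1(table$cell_targets[[i]]),
       provenance_note = table$provenance_note[[i]])
}

#' Summarize the matches of one sequence; flag duodegrins
#'
#' A duodegrin is a sequence carrying more than one tripeptide motif of
#' distinct types (e.g. VGD together with RTS). Two occurrences of the
#' same motif raise the match count but do not flag the sequence.
#'
#' @param matches Match rows all sharing one \code{seq_id} (possibly
#'   zero rows, in which case \code{seq_id} must be supplied).
#' @param seq_id Identifier, required when \code{matches} is empty.
#' @return A one-row data.frame with \code{seq_id}, \code{n_matches},
#'   \code{distinct_tripeptides} (comma-joined, sorted) and
#'   \code{is_duodegrin}.
#' @export
summarize_sequence <- function(matches, seq_id = NULL) {
  if (nrow(matches) == 0L) {
    if (is.null(seq_id)) stop("seq_id required for an empty match set")
    return(data.frame(seq_id = seq_id, n_matches = 0L,
                      distinct_tripeptides = "", is_duodegrin = FALSE,
                      stringsAsFactors = FALSE))
  }
  ids <- unique(matches$seq_id)
  if (length(ids) != 1L)
    stop("summarize_sequence: matches mix seq_ids: ",
         paste(ids, collapse = ", "))
  trips <- sort(unique(matches$tripeptide), method = "radix")
  data.frame(seq_id = ids, n_matches = nrow(matches),
             distinct_tripeptides = paste(trips, collapse = ","),
             is_duodegrin = nrow(matches) >= 2L && length(trips) >= 2L,
             stringsAsFactors = FALSE)
}

#' Summarize every sequence of a scan
#'
#' @param match_table Result of [scan_collection()].
#' @return One summary row per scanned sequence, in record order.
#' @export
summarize_collection <- function(match_table) {
  counts <- match_table$counts
  matches <- match_table$matches
  rows <- lapply(counts$seq_id, function(id)
    summarize_sequence(matches[matches$seq_id == id, , drop = FALSE],
                       seq_id = id))
  if (!length(rows))
    return(data.frame(seq_id = character(), n_matches = integer(),
                      distinct_tripeptides = character(),
                      is_duodegrin = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

database_columns <- function() {
  c("seq_id", "organism_code", "taxon_label", "tripeptide", "motif_start",
    "left_spacer", "right_spacer", "overlaps_signal", "integrin_targets",
    "cell_targets", "is_duodegrin", "sequence_length")
}

#' Build the sialogenin database table
#'
#' One row per motif match, joining record metadata, match coordinates,
#' putative integrin/cell targets and the duodegrin flag; rows sorted by
#' (organism_code, seq_id, motif_start).
#'
#' @param match_table Result of [scan_collection()].
#' @param records The scanned sequence-record data.frame.
#' @param annotations Annotation table (default
#'   [default_annotation_table()]).
#' @return Data.frame with the 12 database columns (see
#'   \code{disintegrindb:::database_columns}).
#' @export
build_database <- function(match_table, records,
                           annotations = default_annotation_table()) {
  matches <- match_table$matches
  empty <- stats::setNames(
    data.frame(character(), character(), character(), character(),
               integer(), integer(), integer(), logical(), character(),
               character(), logical(), integer(), stringsAsFactors = FALSE),
    database_columns())
  if (nrow(matches) == 0L) return(empty)
  ri <- match(matches$seq_id, records$id)
  if (anyNA(ri))
    stop("match seq_id not found among records: ",
         matches$seq_id[which(is.na(ri))[[1L]]])
  summaries <- summarize_collection(match_table)
  si <- match(matches$seq_id, summaries$seq_id)
  ai <- match(matches$tripeptide, annotations$tripeptide)
  db <- data.frame(
    seq_id = matches$seq_id,
    organism_code = records$organism_code[ri],
    taxon_label = records$taxon_label[ri],
    tripeptide = matches$tripeptide,
    motif_start = matches$motif_start,
    left_spacer = matches$left_spacer,
    right_spacer = matches$right_spacer,
    overlaps_signal = matches$overlaps_signal,
    integrin_targets = ifelse(is.na(ai), "", annotations$integrin_targets[ai]),
    cell_targets = ifelse(is.na(ai), "", annotations$cell_targets[ai]),
    is_duodegrin = summaries$is_duodegrin[si],
    sequence_length = nchar(records$residues[ri]),
    stringsAsFactors = FALSE)
  db <- db[order(db$organism_code, db$seq_id, db$motif_start,
                 method = "radix"), , drop = FALSE]
  rownames(db) <- NULL
  db
}

#' Write / read the database as TSV
#'
#' UTF-8, tab-separated, fixed header; round-trips through
#' [read_database_tsv()].
#'
#' @param db Database data.frame from [build_database()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_database_tsv <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_database_tsv
#' @export
read_database_tsv <- function(path) {
  db <- utils::read.delim(path, stringsAsFactors = FALSE,
                          encoding = "UTF-8")
  for (col in c("taxon_label", "integrin_targets", "cell_targets"))
    db[[col]] <- ifelse(is.na(db[[col]]), "", as.character(db[[col]]))
  db$organism_code <- ifelse(is.na(db$organism_code), "",
                             as.character(db$organism_code))
  db
}
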