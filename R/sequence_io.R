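# Protein FASTA input/output and the organism-code header convention.
#
# A sequence-record collection is a plain data.frame with columns
#   id, organism_code, taxon_label, description, residues
# one row per protein, order equal to file order.

#' Amino-acid alphabet accepted in input sequences
#'
#' The 20 standard residues plus \code{X} for an unknown residue. Gap
#' characters and ambiguity codes (B, Z, U) are rejected at load time.
#'
#' @return A single string of allowed residue letters.
#' @export
residue_alphabet <- function() "ACDEFGHIKLMNPQRSTVWYX"

#' Parse a FASTA description line
#'
#' Salivary-protein collections in this field often name entries with a
#' five-letter uppercase organism code, an underscore and a numeric
#' identifier (for example \code{TRIIN_155029178} for a Triatoma
#' infestans protein). When the first whitespace-delimited token of the
#' header matches that convention, the code is extracted as organism
#' metadata; otherwise the whole first token is the identifier and the
#' organism code is empty. The convention is opportunistic metadata,
#' never a requirement.
#'
#' @param header A FASTA description line, without the leading \code{>}.
#' @return A list with elements \code{id}, \code{organism_code},
#'   \code{taxon_label} and \code{description}. The remainder of the
#'   header after the first token becomes both the description and the
#'   taxon label.
#' @examples
#' parse_header("TRIIN_155029178 Triatoma infestans")
#' parse_header("gi|12345|random protein")
#' @export
parse_header <- function(header) {
  stopifnot(is.character(header), length(header) == 1L)
  header <- trimws(header)
  if (!nzchar(header)) stop("empty FASTA header")
  first <- sub("\\s.*$", "", header)
  rest <- trimws(substring(header, nchar(first) + 1L))
  code <- if (grepl("^[A-Z]{5}_[0-9]+$", first)) substr(first, 1L, 5L) else ""
  list(id = first, organism_code = code, taxon_label = rest,
       description = rest)
}

new_sequence_records <- function(id = character(), organism_code = character(),
                                 taxon_label = character(),
                                 description = character(),
                                 residues = character()) {
  data.frame(id = id, organism_code = organism_code,
             taxon_label = taxon_label, description = description,
             residues = residues, stringsAsFactors = FALSE)
}

#' Validate a sequence-record collection
#'
#' Checks the invariants every downstream module relies on: non-empty
#' unique identifiers, non-empty residue strings over the allowed
#' alphabet (see [residue_alphabet()]).
#'
#' @param records A sequence-record data.frame.
#' @return The records, invisibly, if valid; otherwise an error.
#' @export
validate_records <- function(records) {
  req <- c("id", "organism_code", "taxon_label", "description", "residues")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  if (anyNA(records$id) || any(!nzchar(records$id)))
    stop("every record needs a non-empty id")
  dup <- records$id[duplicated(records$id)]
  if (length(dup))
    stop("duplicate sequence id: ", dup[[1L]])
  empty <- records$id[!nzchar(records$residues)]
  if (length(empty))
    stop("record '", empty[[1L]], "' has an empty sequence")
  bad_re <- sprintf("[^%s]", residue_alphabet())
  off <- regexpr(bad_re, records$residues)
  hit <- which(off > 0L)
  if (length(hit)) {
    i <- hit[[1L]]
    stop(sprintf("record '%s' has illegal residue '%s' at position %d",
                 records$id[[i]],
                 substr(records$residues[[i]], off[[i]], off[[i]]),
                 off[[i]]))
  }
  invisible(records)
}

#' Read a protein FASTA file
#'
#' Entries are returned in file order. Residues are upper-cased,
#' terminal \code{*} stop characters are stripped, and any character
#' outside the accepted alphabet (including gap characters) raises an
#' error naming the record and offset. Duplicate identifiers are an
#' error; an empty file yields an empty collection.
#'
#' @param path Path to a FASTA file.
#' @return A sequence-record data.frame (see [validate_records()] for
#'   the schema).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(new_sequence_records())
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(new_sequence_records())
  headers <- names(set)
  meta <- lapply(headers, parse_header)
  residues <- toupper(as.character(set))
  residues <- sub("\\*+$", "", residues)
  rec <- new_sequence_records(
    id = vapply(meta, `[[`, character(1), "id"),
    organism_code = vapply(meta, `[[`, character(1), "organism_code"),
    taxon_label = vapply(meta, `[[`, character(1), "taxon_label"),
    description = vapply(meta, `[[`, character(1), "description"),
    residues = unname(residues)
  )
  validate_records(rec)
  rec
}

#' Write a sequence-record collection as FASTA
#'
#' Round-trip property: reading the written file reproduces ids and
#' residues exactly.
#'
#' @param records A valid sequence-record data.frame.
#' @param path Output file path.
#' @param wrap Line width for the sequence lines (positive integer).
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  stopifnot(is.numeric(wrap), wrap >= 1L)
  validate_records(records)
  headers <- ifelse(nzchar(records$description),
                    paste(records$id, records$description),
                    records$id)
  set <- Biostrings::BStringSet(stats::setNames(records$residues, headers))
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(wrap))
  invisible(path)
}
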