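# Family phylograms: p-distances from a supplied protein alignment,
# neighbor-joining tree, percent bootstrap supports, Newick output.
# Alignments are consumed, never computed here.

#' Read a protein multiple alignment
#'
#' Supports aligned FASTA and Clustal block format. Rows are
#' upper-cased and must all have equal length; '-' is the gap
#' character.
#'
#' @param path Alignment file.
#' @param format \code{"fasta"} or \code{"clustal"}.
#' @return A list of class \code{protein_alignment} with \code{ids},
#'   \code{rows} (named character vector) and \code{n_cols}.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    ids <- vapply(names(set), function(h) sub("\\s.*$", "", trimws(h)), "",
                  USE.NAMES = FALSE)
    rows <- toupper(as.character(set))
  } else {
    lines <- readLines(path)
    if (!length(lines) || !grepl("^CLUSTAL", lines[[1L]], ignore.case = TRUE))
      stop("not a Clustal file (missing CLUSTAL header line): ", path)
    body <- lines[-1L]
    seq_line <- grepl("^\\S+\\s+[A-Za-z.*-]+\\s*\\d*\\s*$", body)
    ids <- character()
    parts <- list()
    for (ln in body[seq_line]) {
      toks <- strsplit(trimws(ln), "\\s+")[[1L]]
      id <- toks[[1L]]
      if (!id %in% ids) {
        ids <- c(ids, id)
        parts[[id]] <- character()
      }
      parts[[id]] <- c(parts[[id]], toks[[2L]])
    }
    if (!length(ids)) stop("no sequence lines found in Clustal file: ", path)
    rows <- toupper(vapply(parts[ids], paste, "", collapse = ""))
  }
  if (anyDuplicated(ids)) stop("duplicate alignment id: ",
                               ids[duplicated(ids)][[1L]])
  lens <- nchar(rows)
  if (length(unique(lens)) > 1L) {
    off <- ids[lens != lens[[1L]]][[1L]]
    stop("ragged alignment: row '", off, "' has length ",
         lens[[which(ids == off)]], ", expected ", lens[[1L]])
  }
  structure(list(ids = ids, rows = stats::setNames(unname(rows), ids),
                 n_cols = lens[[1L]]),
            class = "protein_alignment")
}

alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$rows, "", fixed = TRUE))
  rownames(m) <- alignment$ids
  m
}

matrix_as_alignment <- function(m) {
  structure(list(ids = rownames(m),
                 rows = stats::setNames(apply(m, 1L, paste, collapse = ""),
                                        rownames(m)),
                 n_cols = ncol(m)),
            class = "protein_alignment")
}

#' Uncorrected p-distance with pairwise gap deletion
#'
#' d(i,j) is the proportion of mismatched residues over the columns in
#' which neither row has a gap. A pair with zero comparable columns is
#' an error naming the pair. This raw proportion matches the "% amino
#' acid divergence" scale used for phylogram scale bars.
#'
#' @param alignment A \code{protein_alignment} (>= 2 rows).
#' @return A symmetric numeric matrix in [0,1] with zero diagonal and
#'   the alignment ids as dimnames.
#' @export
p_distance <- function(alignment) {
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("p_distance needs at least 2 rows")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  ng <- m != "-"
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- ng[i, ] & ng[j, ]
      ns <- sum(ok)
      if (ns == 0L)
        stop("no comparable columns between '", rownames(m)[[i]],
             "' and '", rownames(m)[[j]], "'")
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / ns
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \code{ape::nj}); negative
#' branch lengths are clamped to zero afterwards, with the raw lengths
#' retained in the \code{"raw_edge_lengths"} attribute. On an additive
#' matrix the tree's leaf-to-leaf path lengths reproduce the matrix.
#'
#' @param dm Symmetric distance matrix with dimnames (>= 3 taxa).
#' @return An unrooted \code{ape::phylo} tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(dm))) stop("distance matrix needs dimnames")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix is not symmetric")
  tr <- ape::nj(dm)
  raw <- tr$edge.length
  tr$edge.length <- pmax(raw, 0)
  attr(tr, "raw_edge_lengths") <- raw
  tr
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Neighbor-joining tree with percent bootstrap supports
#'
#' Builds the NJ tree of the full alignment, then resamples alignment
#' columns with replacement \code{replicates} times, rebuilds an NJ
#' tree from each pseudo-alignment, and annotates each internal
#' bipartition of the full-data tree with the percentage of replicate
#' trees containing it (rounded to the nearest integer). A replicate
#' whose p-distance is undefined (a pair with zero comparable columns)
#' is resampled; the number of such resamples is reported in the
#' \code{"n_degenerate_resampled"} attribute.
#'
#' @param alignment A \code{protein_alignment} with >= 4 rows for
#'   non-trivial internal edges (>= 3 accepted).
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; same seed and input give identical
#'   supports.
#' @return The full-data NJ tree with integer percent supports in
#'   \code{node.label} (empty for the root).
#' @export
bootstrap_support <- function(alignment, replicates = 1000L, seed = 1L) {
  stopifnot(replicates >= 1L)
  m <- alignment_matrix(alignment)
  if (nrow(m) < 3L) stop("bootstrap_support needs at least 3 taxa")
  full <- neighbor_joining(p_distance(alignment))
  n_bad <- 0L
  reps <- with_local_seed(seed, {
    lapply(seq_len(replicates), function(b) {
      repeat {
        cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
        d <- tryCatch(p_distance(matrix_as_alignment(m[, cols, drop = FALSE])),
                      error = function(e) NULL)
        if (!is.null(d)) return(neighbor_joining(d))
        n_bad <<- n_bad + 1L
      }
    })
  })
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- as.integer(round(100 * counts / replicates))
  labels <- as.character(support)
  labels[[1L]] <- ""  # root of the unrooted representation, not a bipartition
  full$node.label <- labels
  attr(full, "bootstrap_replicates") <- replicates
  attr(full, "n_degenerate_resampled") <- n_bad
  full
}

newick_token <- function(x) {
  # quote labels that would break Newick syntax
  if (grepl("[ \t(),:;\\[\\]']", x))
    paste0("'", gsub("'", "''", x), "'")
  else x
}

#' Serialize a tree to Newick
#'
#' Branch lengths are written with six decimals and integer bootstrap
#' supports appear as internal-node labels after the closing
#' parenthesis. Re-parsing (e.g. with \code{ape::read.tree}) yields an
#' identical topology and lengths within 1e-6.
#'
#' @param tree An \code{ape::phylo} tree.
#' @param path Output file, or NULL to return the string only.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- function(node, edge_i) {
    lab <- if (node <= ntip) {
      newick_token(tree$tip.label[[node]])
    } else {
      own <- kids[[as.character(node)]]
      sub <- paste(vapply(own, function(e) fmt(tree$edge[e, 2L], e), ""),
                   collapse = ",")
      nl <- ""
      if (!is.null(tree$node.label)) {
        nl <- tree$node.label[[node - ntip]]
        if (is.na(nl)) nl <- ""
      }
      paste0("(", sub, ")", newick_token_or_empty(nl))
    }
    if (is.null(edge_i)) lab
    else paste0(lab, ":", sprintf("%.6f", tree$edge.length[[edge_i]]))
  }
  s <- paste0(fmt(root, NULL), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

newick_token_or_empty <- function(x) {
  if (!nzchar(x)) "" else newick_token(x)
}
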