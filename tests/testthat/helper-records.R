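# shared fixture builders

make_records <- function(seqs, ids = sprintf("s%d", seq_along(seqs)),
                         organism_code = "", taxon_label = "",
                         description = "") {
  n <- length(seqs)
  data.frame(id = ids, organism_code = rep_len(organism_code, n),
             taxon_label = rep_len(taxon_label, n),
             description = rep_len(description, n),
             residues = seqs, stringsAsFactors = FALSE)
}

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# a sequence that satisfies the signal-gate heuristic by construction:
# M K + 10xL h-region + A Q A cleavage site, then the payload
secreted_seq <- function(payload) {
  paste0("MKLLLLLLLLLLAQA", payload)
}

# fails the gate: no hydrophobic run of 8 within positions 1..30
nonsecreted_seq <- function(payload) {
  paste0("MKGDEGRSGNDEGRSGNDEGRSGNDEGRSG", payload)
}

match_key <- function(d) sort(paste(d$seq_id, d$tripeptide, d$motif_start))
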