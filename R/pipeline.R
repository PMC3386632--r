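# End-to-end flow: load -> taxon scope -> signal gate -> motif scan ->
# annotate/summarize -> report. All output orderings and number formats
# are pinned so repeated runs are byte-identical.

#' The default taxon allow-list
#'
#' The eleven blood-feeding taxa scoped by the original search:
#' Ixodoidea, Cimicomorpha, Tabanidae, Glossina, Culicidae,
#' Psychodidae, Simuliidae, Ceratopogonidae, Siphonaptera, Hirudinea
#' and Rhabditida.
#'
#' @return Character vector of taxon terms.
#' @export
default_taxon_terms <- function() names(TAXON_CODES)

#' Build a run configuration
#'
#' @param input Path to the input protein FASTA.
#' @param output_dir Directory for the output bundle (created if
#'   absent).
#' @param motifs Tripeptide motif set (default the eight disintegrin
#'   motifs).
#' @param max_left_spacer,max_right_spacer Spacer bounds (default 16).
#' @param taxa Taxon allow-list matched against the organism code and
#'   taxon label; an empty vector keeps all records.
#' @param signal_policy \code{"require"} (drop non-secreted) or
#'   \code{"annotate"} (keep all, carry the verdict).
#' @param signal_predictions Optional path to an external TSV of
#'   signal predictions (see [load_external_predictions()]); these
#'   override the heuristic.
#' @param annotation_table Optional path to a TSV replacing
#'   [default_annotation_table()].
#' @param seed Integer seed recorded in the run summary.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(input = NULL, output_dir = NULL,
                       motifs = default_motifs(),
                       max_left_spacer = 16L, max_right_spacer = 16L,
                       taxa = default_taxon_terms(),
                       signal_policy = c("require", "annotate"),
                       signal_predictions = NULL,
                       annotation_table = NULL, seed = 1L) {
  signal_policy <- match.arg(signal_policy)
  if (!length(motifs)) stop("motif set must be non-empty")
  if (max_left_spacer < 0 || max_right_spacer < 0)
    stop("spacer bounds must be >= 0")
  structure(list(input = input, output_dir = output_dir,
                 motifs = toupper(motifs),
                 max_left_spacer = as.integer(max_left_spacer),
                 max_right_spacer = as.integer(max_right_spacer),
                 taxa = taxa, signal_policy = signal_policy,
                 signal_predictions = signal_predictions,
                 annotation_table = annotation_table,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys are the arguments of [run_config()]; unknown keys
#' are an error.
#'
#' @param path YAML file.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

taxon_keep <- function(records, taxa) {
  if (!length(taxa)) return(rep(TRUE, nrow(records)))
  hay <- paste(records$taxon_label, records$description)
  keep <- records$organism_code %in% unname(TAXON_CODES[taxa])
  for (term in taxa)
    keep <- keep | grepl(term, hay, ignore.case = TRUE, fixed = FALSE)
  keep
}

#' Run the discovery pipeline
#'
#' Stage order is fixed: read FASTA, taxon filter, signal gate, motif
#' scan, annotate/summarize, write outputs. The output bundle contains
#' \code{database.tsv} (the sialogenin table), one
#' \code{motif_<XYZ>.fasta} per configured motif with the sequences
#' carrying that motif, \code{drop_log.tsv}, and \code{summary.txt}
#' with per-stage counts and a config echo. Outputs are byte-identical
#' across repeated runs on identical inputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with \code{records}, \code{kept},
#'   \code{match_table}, \code{summaries}, \code{db},
#'   \code{drop_log} and \code{stage_counts}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input)) stop("config$input is required")
  if (is.null(config$output_dir)) stop("config$output_dir is required")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  records <- read_fasta(config$input)
  n_loaded <- nrow(records)

  keep <- taxon_keep(records, config$taxa)
  drop_taxon <- data.frame(seq_id = records$id[!keep],
                           stage = rep("taxon", sum(!keep)),
                           reason = rep("taxon not in allow-list", sum(!keep)),
                           stringsAsFactors = FALSE)
  records <- records[keep, , drop = FALSE]
  rownames(records) <- NULL
  n_taxon <- nrow(records)

  ext <- NULL
  if (!is.null(config$signal_predictions))
    ext <- load_external_predictions(config$signal_predictions)
  gated <- if (n_taxon)
    filter_secreted(records, ext, policy = config$signal_policy)
  else
    list(kept = cbind(records, has_signal = logical(), cleavage_pos = integer(),
                      score = numeric()),
         drop_log = data.frame(seq_id = character(), reason = character(),
                               stringsAsFactors = FALSE),
         predictions = NULL)
  kept <- gated$kept
  n_secreted <- if (n_taxon) sum(gated$predictions$has_signal[
    match(kept$id, gated$predictions$seq_id)]) else 0L
  drop_signal <- data.frame(seq_id = gated$drop_log$seq_id,
                            stage = rep("signal", nrow(gated$drop_log)),
                            reason = gated$drop_log$reason,
                            stringsAsFactors = FALSE)
  drop_log <- rbind(drop_taxon, drop_signal)

  patterns <- default_patterns(config$motifs,
                               max_left_spacer = config$max_left_spacer,
                               max_right_spacer = config$max_right_spacer)
  preds <- if (n_taxon) gated$predictions else NULL
  mt <- scan_collection(kept[, c("id", "organism_code", "taxon_label",
                                 "description", "residues")],
                        patterns, predictions = preds)
  summaries <- summarize_collection(mt)
  ann <- if (is.null(config$annotation_table)) default_annotation_table()
         else load_annotation_table(config$annotation_table)
  db <- build_database(mt, kept, annotations = ann)

  stage_counts <- c(loaded = n_loaded, taxon_kept = n_taxon,
                    secreted = as.integer(n_secreted),
                    matched_sequences = sum(mt$counts$n_matches > 0L),
                    total_matches = nrow(mt$matches),
                    duodegrins = sum(summaries$is_duodegrin))

  write_database_tsv(db, file.path(config$output_dir, "database.tsv"))
  utils::write.table(drop_log, file.path(config$output_dir, "drop_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in config$motifs) {
    ids <- unique(mt$matches$seq_id[mt$matches$tripeptide == m])
    sub <- kept[kept$id %in% ids,
                c("id", "organism_code", "taxon_label", "description",
                  "residues"), drop = FALSE]
    write_fasta(sub, file.path(config$output_dir,
                               sprintf("motif_%s.fasta", m)))
  }
  writeLines(pipeline_summary_text(config, stage_counts),
             file.path(config$output_dir, "summary.txt"))

  invisible(list(records = records, kept = kept, match_table = mt,
                 summaries = summaries, db = db, drop_log = drop_log,
                 stage_counts = stage_counts))
}

pipeline_summary_text <- function(config, counts) {
  c("disintegrin discovery run summary",
    "",
    sprintf("%-18s %d", names(counts), counts),
    "",
    "configuration:",
    sprintf("  motifs: %s", paste(config$motifs, collapse = ",")),
    sprintf("  spacer bounds: %d,%d", config$max_left_spacer,
            config$max_right_spacer),
    sprintf("  taxa: %s", paste(config$taxa, collapse = ",")),
    sprintf("  signal policy: %s", config$signal_policy),
    sprintf("  seed: %d", config$seed))
}

#' Pipeline self-test against a ledger-audited fixture
#'
#' Generates a synthetic proteome, writes it to FASTA, runs the full
#' pipeline (signal policy \code{annotate}, so no ground-truth motif is
#' dropped before scanning), and checks that the database rows agree
#' exactly with the audited ledger and that the signal gate reproduces
#' the planted secretion status of every sequence.
#'
#' @param seed Integer seed.
#' @param n Fixture size (number of sequences).
#' @param scan_fun Scanner used for the ledger comparison; exposed so a
#'   harness can inject a faulty scanner and verify the self-test
#'   notices.
#' @return A list with \code{pass} and a \code{checks} data.frame
#'   (check name, expected, observed, ok).
#' @export
selftest <- function(seed = 1L, n = 100L, scan_fun = scan_collection) {
  fix <- generate_proteome(n = n, seed = seed)
  dir <- tempfile("selftest_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  fasta <- file.path(dir, "proteome.fasta")
  write_fasta(fix$records, fasta)
  config <- run_config(input = fasta, output_dir = file.path(dir, "out"),
                       signal_policy = "annotate", seed = seed)
  res <- run_pipeline(config)

  ledger <- fix$ledger
  expected_rows <- ledger[ledger$expected_detection &
                            ledger$kind %in% c("motif", "decoy", "accidental"), ]
  mt <- scan_fun(fix$records, default_patterns(),
                 predictions = predict_signal_collection(fix$records))
  key <- function(d) sort(paste(d$seq_id, d$tripeptide, d$motif_start))
  sig <- ledger[ledger$kind == "signal", ]
  preds <- predict_signal_collection(fix$records)
  gate_ok <- identical(preds$has_signal[match(sig$seq_id, preds$seq_id)],
                       sig$expected_detection)
  checks <- data.frame(
    check = c("database rows = ledger detectable entries",
              "scanner matches = ledger detectable entries",
              "signal gate reproduces planted secretion status"),
    expected = c(nrow(expected_rows), nrow(expected_rows), nrow(sig)),
    observed = c(if (identical(key(res$db), key(expected_rows)))
                   nrow(expected_rows) else nrow(res$db) + 0.5,
                 if (identical(key(mt$matches), key(expected_rows)))
                   nrow(expected_rows) else nrow(mt$matches) + 0.5,
                 if (gate_ok) nrow(sig) else 0L),
    stringsAsFactors = FALSE)
  checks$ok <- checks$expected == checks$observed
  list(pass = all(checks$ok), checks = checks)
}
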