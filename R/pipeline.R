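# Run-configuration handling: a config is a plain named list (or a YAML
# file parsed into one). Unknown keys are an error so typos surface
# instead of silently falling back to defaults.

config_defaults <- list(
  importome = list(
    experiment_name = "experiment",
    quant_table = NULL, design = NULL,
    ratio_columns = NULL, evidence_columns = NULL,
    id_column = "protein_id", description_column = NULL,
    peptides_column = "n_peptides",
    unique_peptides_column = "n_unique_peptides",
    positive_ref = NULL, negative_ref = NULL,
    filter = list(), mode = "f1_threshold",
    fold = NULL, alpha = 0.05, grid_step = 0.01,
    start_rule = "literal", candidates = "grid",
    outdir = NULL
  ),
  mia_scan = list(
    fasta = NULL, mass_cutoff_da = 50000, min_motifs = 2L,
    count_mode = "same_type", outdir = NULL
  ),
  enrichment = list(
    hit_set = NULL, background = NULL, annotations = NULL,
    ancestor_map = NULL, slim_terms = NULL, alpha = 0.05, outdir = NULL
  ),
  simulate = list(
    quant = list(), proteome = list(), outdir = NULL
  )
)

resolve_config <- function(config, stage) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- config_defaults[[stage]]
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    abort(paste0("unknown config key(s) for stage '", stage, "': ",
                 paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, config)
}

require_keys <- function(config, keys, stage) {
  missing <- keys[vapply(keys, function(k) is.null(config[[k]]), logical(1))]
  if (length(missing) > 0L) {
    abort(paste0("config for stage '", stage, "' is missing key(s): ",
                 paste(missing, collapse = ", ")))
  }
}

read_design_file <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  replicate_design(df$replicate_id, df$induced_channel,
                   df$labeling_scheme[1] %||% "silac")
}

write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full importome analysis from a configuration
#'
#' Reads the quantification table, applies the filter policy, computes
#' per-protein statistics, derives the depletion threshold (dual-reference
#' F1 scan in `mode = "f1_threshold"`, or a fixed fold-change in
#' `mode = "fixed_fold"`), calls the importome, flags new candidates,
#' tabulates reference-set overlap and writes all result tables plus a
#' machine-readable run manifest to `outdir`. Reruns on identical inputs
#' produce identical outputs.
#'
#' @param config A named list or path to a YAML file. Required keys:
#'   `quant_table`, `design` (path to a design TSV with columns
#'   `replicate_id`, `induced_channel` or a design tibble),
#'   `ratio_columns`, `positive_ref`, `negative_ref` (paths). Optional:
#'   `experiment_name`, `evidence_columns`, column-name keys, `filter`
#'   (list of [filter_policy()] arguments), `mode`, `fold`, `alpha`,
#'   `grid_step`, `start_rule`, `candidates`, `outdir`.
#' @return A list with `stats`, `scan` (or `NULL` in fixed-fold mode),
#'   `threshold`, `calls`, `new_candidates`, `overlap`, `volcano`,
#'   `manifest`, invisibly when `outdir` is set.
#' @export
run_importome <- function(config) {
  cfg <- resolve_config(config, "importome")
  require_keys(cfg, c("quant_table", "design", "ratio_columns",
                      "positive_ref", "negative_ref"), "importome")

  design <- if (is.data.frame(cfg$design)) cfg$design else
    read_design_file(cfg$design)
  ratio_columns <- unlist(cfg$ratio_columns)
  evidence_columns <- if (is.null(cfg$evidence_columns)) NULL else
    unlist(cfg$evidence_columns)

  records <- read_quant_table(
    cfg$quant_table, design, ratio_columns, evidence_columns,
    id_column = cfg$id_column, description_column = cfg$description_column,
    peptides_column = cfg$peptides_column,
    unique_peptides_column = cfg$unique_peptides_column
  )
  positive_ref <- read_reference_set(cfg$positive_ref, "positive")
  negative_ref <- read_reference_set(cfg$negative_ref, "negative")
  policy <- do.call(filter_policy, cfg$filter)
  stats <- apply_identification_filter(records, policy)

  if (cfg$mode == "f1_threshold") {
    scan <- scan_f1(stats, positive_ref, negative_ref,
                    grid_step = cfg$grid_step, start_rule = cfg$start_rule,
                    candidates = cfg$candidates)
    threshold <- scan$chosen_threshold
    calls <- call_importome(stats, threshold, alpha = cfg$alpha)
  } else if (cfg$mode == "fixed_fold") {
    require_keys(cfg, "fold", "importome")
    scan <- NULL
    threshold <- -log2(cfg$fold)
    calls <- call_fixed_fold(stats, cfg$fold, alpha = cfg$alpha)
  } else {
    abort(paste0("unknown mode: ", cfg$mode))
  }

  new_candidates <- identify_new_candidates(calls, positive_ref)
  if (inherits(calls, "importome_calls")) {
    calls <- flag_new_candidates(calls, positive_ref)
  }
  overlap <- reference_overlap_summary(calls, positive_ref, negative_ref)
  volcano <- volcano_table(stats, calls, positive_ref, negative_ref)

  manifest <- list(
    experiment_name = cfg$experiment_name,
    inputs = list(quant_table = if (is.character(cfg$quant_table))
      cfg$quant_table else "in-memory",
      positive_ref = cfg$positive_ref, negative_ref = cfg$negative_ref),
    parameters = list(mode = cfg$mode, alpha = cfg$alpha,
                      fold = cfg$fold, grid_step = cfg$grid_step,
                      start_rule = cfg$start_rule,
                      filter = unclass(policy)),
    thresholds = if (is.null(scan)) list(chosen = threshold) else
      list(t1 = scan$t1, t2 = scan$t2, chosen = threshold),
    counts = list(
      n_proteins = nrow(stats),
      n_passed_filter = sum(stats$passed_filter),
      n_imported = sum(calls$call == "imported"),
      n_unaffected = sum(calls$call == "unaffected"),
      n_new_candidates = length(new_candidates)
    )
  )

  result <- list(stats = stats, scan = scan, threshold = threshold,
                 calls = calls, new_candidates = new_candidates,
                 overlap = overlap, volcano = volcano, manifest = manifest)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    write_results_table(stats, file.path(cfg$outdir, "protein_stats.tsv"))
    if (!is.null(scan)) {
      write_results_table(scan$curves, file.path(cfg$outdir, "f1_curves.tsv"))
    }
    write_results_table(as_tibble(calls),
                        file.path(cfg$outdir, "importome_calls.tsv"))
    writeLines(new_candidates, file.path(cfg$outdir, "new_candidates.txt"))
    write_results_table(overlap, file.path(cfg$outdir, "overlap_summary.tsv"))
    write_results_table(volcano, file.path(cfg$outdir, "volcano.tsv"))
    write_manifest(manifest, cfg$outdir)
    return(invisible(result))
  }
  result
}

#' Run the MIA substrate scan from a configuration
#'
#' @param config Named list or YAML path with keys `fasta` (required),
#'   `mass_cutoff_da`, `min_motifs`, `count_mode`, `outdir`.
#' @return The predictions tibble (see [predict_mia_substrates()]) with
#'   motif coordinates flattened to a `motif_coords` string column.
#' @export
run_mia_scan <- function(config) {
  cfg <- resolve_config(config, "mia_scan")
  require_keys(cfg, "fasta", "mia_scan")
  sequences <- read_fasta(cfg$fasta)
  pred <- predict_mia_substrates(sequences, cfg$mass_cutoff_da,
                                 cfg$min_motifs, cfg$count_mode)
  flat <- pred |>
    dplyr::mutate(motif_coords = vapply(.data$hits, function(h) {
      paste(sprintf("%s:%d-%d", h$motif_type, h$start, h$end),
            collapse = ";")
    }, character(1))) |>
    dplyr::select(-"hits")
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    write_results_table(flat, file.path(cfg$outdir, "mia_predictions.tsv"))
    write_manifest(list(
      parameters = cfg[c("mass_cutoff_da", "min_motifs", "count_mode")],
      counts = list(n_proteins = nrow(pred),
                    n_predicted = sum(pred$is_predicted_substrate))
    ), cfg$outdir)
    return(invisible(flat))
  }
  flat
}

#' Run term enrichment from a configuration
#'
#' @param config Named list or YAML path with keys `hit_set`, `background`
#'   (ID-list paths), `annotations` (TSV `protein_id`, `term_id`),
#'   optional `ancestor_map` (TSV `term_id`, `ancestor_id`) and
#'   `slim_terms` (ID-list path) for slim reduction, `alpha`, `outdir`.
#' @return The enrichment tibble (see [term_enrichment()]).
#' @export
run_enrichment <- function(config) {
  cfg <- resolve_config(config, "enrichment")
  require_keys(cfg, c("hit_set", "background", "annotations"), "enrichment")
  hit_set <- read_reference_set(cfg$hit_set, "hit_set")
  background <- read_reference_set(cfg$background, "background")
  ann <- readr::read_tsv(cfg$annotations,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!is.null(cfg$ancestor_map) && !is.null(cfg$slim_terms)) {
    anc <- readr::read_tsv(cfg$ancestor_map,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    slim <- read_reference_set(cfg$slim_terms, "slim_terms")
    ann <- reduce_to_slim(ann, anc, slim)
  }
  enr <- term_enrichment(hit_set, ann, background, alpha = cfg$alpha)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    write_results_table(enr, file.path(cfg$outdir, "enrichment.tsv"))
    write_manifest(list(
      parameters = list(alpha = cfg$alpha,
                        method = "classic per-term Fisher + BH"),
      counts = list(n_terms_tested = nrow(enr),
                    n_terms_skipped = attr(enr, "n_terms_skipped"),
                    n_enriched = sum(enr$enriched))
    ), cfg$outdir)
    return(invisible(enr))
  }
  enr
}

#' Generate a synthetic fixture bundle on disk
#'
#' Writes the wide quantification TSV, replicate design, reference lists,
#' ground-truth table, a planted-motif proteome FASTA and its truth, in
#' exactly the dialects the reading functions consume, so a simulate run
#' chains into [run_importome()] and [run_mia_scan()] without edits.
#'
#' @param config Named list or YAML path with keys `quant` (arguments for
#'   [synthetic_quant_config()]), `proteome` (arguments for
#'   [simulate_proteome_sequences()]) and `outdir` (required).
#' @return Invisibly, a list of the written paths plus an importome
#'   sub-config ready for [run_importome()].
#' @export
run_simulate <- function(config) {
  cfg <- resolve_config(config, "simulate")
  require_keys(cfg, "outdir", "simulate")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  sim <- simulate_quant_dataset(do.call(synthetic_quant_config, cfg$quant))
  paths <- list(
    quant_table = file.path(cfg$outdir, "quant_table.tsv"),
    design = file.path(cfg$outdir, "design.tsv"),
    positive_ref = file.path(cfg$outdir, "positive_ref.txt"),
    negative_ref = file.path(cfg$outdir, "negative_ref.txt"),
    truth = file.path(cfg$outdir, "truth.tsv"),
    fasta = file.path(cfg$outdir, "proteome.fasta"),
    planted = file.path(cfg$outdir, "planted_motifs.tsv")
  )
  write_results_table(sim$table, paths$quant_table)
  write_results_table(sim$design, paths$design)
  writeLines(sim$positive_ref, paths$positive_ref)
  writeLines(sim$negative_ref, paths$negative_ref)
  write_results_table(sim$truth, paths$truth)

  prot <- do.call(simulate_proteome_sequences, cfg$proteome)
  writeLines(paste0(">", prot$sequences$protein_id, "\n",
                    prot$sequences$sequence), paths$fasta)
  write_results_table(prot$planted, paths$planted)

  importome_config <- list(
    quant_table = paths$quant_table, design = paths$design,
    ratio_columns = as.list(sim$ratio_columns),
    evidence_columns = as.list(sim$evidence_columns),
    positive_ref = paths$positive_ref, negative_ref = paths$negative_ref
  )
  write_manifest(list(paths = paths,
                      importome_config = importome_config), cfg$outdir)
  invisible(list(paths = paths, importome_config = importome_config,
                 sim = sim, proteome = prot))
}
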