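#' Describe the replicate design of a knockdown experiment
#'
#' A replicate design records, for every biological replicate, which isotope
#' channel received the inducer (tetracycline). Label-switched replicates
#' carry the induced condition in the light channel, so their raw
#' heavy/light ratios must be inverted to obtain +Tet/-Tet ratios.
#'
#' @param replicate_id Character vector of unique replicate labels.
#' @param induced_channel Character vector, one of `"heavy"` or `"light"`
#'   per replicate: the channel carrying the induced (+Tet) condition.
#' @param labeling_scheme `"silac"` or `"dimethyl"` (metadata only; both
#'   schemes yield heavy/light ratios and are treated identically).
#'
#' @return A tibble with columns `replicate_id`, `induced_channel`,
#'   `labeling_scheme`, one row per replicate.
#' @examples
#' replicate_design(c("r1", "r2", "r3", "r4"),
#'                  c("heavy", "light", "heavy", "light"))
#' @export
replicate_design <- function(replicate_id, induced_channel,
                             labeling_scheme = "silac") {
  replicate_id <- as.character(replicate_id)
  if (length(replicate_id) < 1L) {
    abort("a replicate design needs at least one replicate")
  }
  if (anyDuplicated(replicate_id)) {
    abort("replicate_id values must be unique")
  }
  induced_channel <- match.arg(induced_channel, c("heavy", "light"),
                               several.ok = TRUE)
  induced_channel <- rep_len(induced_channel, length(replicate_id))
  labeling_scheme <- match.arg(labeling_scheme, c("silac", "dimethyl"))
  tibble(
    replicate_id = replicate_id,
    induced_channel = induced_channel,
    labeling_scheme = labeling_scheme
  )
}

#' Read a protein quantification table and orient its ratios
#'
#' Reads a tab-separated protein-level quantification table (MaxQuant
#' proteinGroups dialect: one row per protein group, per-replicate raw
#' heavy/light ratio columns) and converts every raw ratio to an oriented
#' log2 (+Tet over -Tet) value using the replicate design: for replicates
#' whose induced channel is heavy the oriented ratio is `log2(H/L)`, for
#' label-switched replicates (induced light) it is `-log2(H/L)`.
#'
#' Column names vary between search-engine versions, so all columns are
#' named explicitly. Missing or non-numeric ratio cells become missing
#' oriented ratios; zero or negative raw ratios are rejected as table
#' corruption rather than silently transformed.
#'
#' @param path Path to a TSV file with one header row.
#' @param design A [replicate_design()] tibble.
#' @param ratio_columns Named character vector mapping `replicate_id` to the
#'   raw ratio column name in the file.
#' @param evidence_columns Optional named character vector mapping
#'   `replicate_id` to per-replicate identification evidence columns
#'   (values `"msms"`, `"match_between_runs"` or `"absent"`/empty). When
#'   absent, quantified replicates are assumed MS/MS-identified.
#' @param id_column,description_column,peptides_column,unique_peptides_column
#'   Column names for the protein accession, free-text description, total
#'   peptide count and unique peptide count. `description_column` may be
#'   `NULL`.
#'
#' @return A tibble in long (tidy) form with one row per protein and
#'   replicate: `protein_id`, `description`, `n_peptides`,
#'   `n_unique_peptides`, `replicate_id`, `oriented_log2_ratio`, `evidence`.
#'   Row order follows the input file; replicates follow the design.
#' @seealso [apply_identification_filter()] for the downstream filter and
#'   per-protein statistics.
#' @export
read_quant_table <- function(path, design, ratio_columns,
                             evidence_columns = NULL,
                             id_column = "protein_id",
                             description_column = NULL,
                             peptides_column = "n_peptides",
                             unique_peptides_column = "n_unique_peptides") {
  if (!file.exists(path)) abort(paste0("quantification table not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  orient_quant_frame(raw, design, ratio_columns, evidence_columns,
                     id_column, description_column,
                     peptides_column, unique_peptides_column)
}

# Orientation core shared by read_quant_table() and the synthetic generator:
# takes an already-parsed wide data frame of character/numeric columns.
orient_quant_frame <- function(raw, design, ratio_columns,
                               evidence_columns = NULL,
                               id_column = "protein_id",
                               description_column = NULL,
                               peptides_column = "n_peptides",
                               unique_peptides_column = "n_unique_peptides") {
  stopifnot(is.data.frame(design))
  needed <- c(id_column, peptides_column, unique_peptides_column,
              description_column, unname(ratio_columns),
              unname(evidence_columns))
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    abort(paste0("column(s) not found in quantification table: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(design$replicate_id %in% names(ratio_columns))) {
    abort("ratio_columns must name a column for every replicate in the design")
  }

  n <- nrow(raw)
  base <- tibble(
    protein_id = as.character(raw[[id_column]]),
    description = if (is.null(description_column)) NA_character_ else
      as.character(raw[[description_column]]),
    n_peptides = as.integer(raw[[peptides_column]]),
    n_unique_peptides = as.integer(raw[[unique_peptides_column]]),
    .row = seq_len(n)
  )
  bad_pep <- which(!is.na(base$n_peptides) & !is.na(base$n_unique_peptides) &
                     base$n_unique_peptides > base$n_peptides)
  if (length(bad_pep) > 0L) {
    abort(paste0("n_unique_peptides exceeds n_peptides at row(s) ",
                 paste(head(bad_pep, 5L), collapse = ", ")))
  }

  per_rep <- purrr::map(seq_len(nrow(design)), function(i) {
    rid <- design$replicate_id[i]
    raw_ratio <- suppressWarnings(as.numeric(raw[[ratio_columns[[rid]]]]))
    present <- !is.na(raw_ratio)
    if (any(present & raw_ratio <= 0)) {
      bad <- which(present & raw_ratio <= 0)
      abort(paste0("non-positive raw ratio in column '", ratio_columns[[rid]],
                   "' at row(s) ", paste(head(bad, 5L), collapse = ", ")))
    }
    oriented <- if (design$induced_channel[i] == "heavy") {
      log2(raw_ratio)
    } else {
      -log2(raw_ratio)
    }
    if (is.null(evidence_columns) || !rid %in% names(evidence_columns)) {
      evid <- ifelse(present, "msms", "absent")
    } else {
      evid <- as.character(raw[[evidence_columns[[rid]]]])
      evid[is.na(evid) | evid == ""] <- "absent"
      bad_evid <- setdiff(unique(evid), c("msms", "match_between_runs", "absent"))
      if (length(bad_evid) > 0L) {
        abort(paste0("unknown evidence value(s): ",
                     paste(bad_evid, collapse = ", ")))
      }
      # an identified-but-unquantified replicate is legal; the reverse is not
      inconsistent <- present & evid == "absent"
      if (any(inconsistent)) {
        warn(paste0(sum(inconsistent), " replicate cell(s) carry a ratio but ",
                    "evidence 'absent'; evidence coerced to 'msms'"))
        evid[inconsistent] <- "msms"
      }
    }
    tibble(.row = seq_len(n), replicate_id = rid,
           oriented_log2_ratio = oriented, evidence = evid)
  })

  out <- dplyr::left_join(base, dplyr::bind_rows(per_rep), by = ".row")
  out <- dplyr::arrange(out, .data$.row)
  dplyr::select(out, -".row")
}

#' Read a reference-proteome accession list
#'
#' One accession per line; blank lines and `#` comments are ignored.
#' Duplicates are collapsed with a warning. Reference sets (e.g. the
#' curated organellar and non-organellar proteomes used to calibrate the
#' depletion threshold) must be non-empty.
#'
#' @param path Path to a plain-text ID list.
#' @param name Label for the set (used in summaries and error messages).
#' @return A character vector of unique accessions with attribute `name`.
#' @export
read_reference_set <- function(path, name = basename(path)) {
  if (!file.exists(path)) abort(paste0("reference set not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("#.*$", "", lines)
  ids <- trimws(lines)
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0L) {
    abort(paste0("reference set '", name, "' is empty"))
  }
  if (anyDuplicated(ids)) {
    warn(paste0("reference set '", name, "': ",
                sum(duplicated(ids)), " duplicate ID(s) collapsed"))
    ids <- unique(ids)
  }
  structure(ids, name = name)
}

#' Read protein sequences from a FASTA file
#'
#' The accession is the first whitespace-delimited token of each header;
#' sequences are upper-cased and restricted to the 20 standard amino acids
#' plus `X` (unknown residue).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein_id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(aa))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate accession(s) in FASTA: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(!nzchar(seqs))) {
    abort(paste0("empty sequence for: ",
                 paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  bad <- grepl(sprintf("[^%s]", paste0(names(residue_masses()), collapse = "")),
               seqs)
  if (any(bad)) {
    abort(paste0("sequence with letters outside the standard alphabet: ",
                 paste(ids[bad], collapse = ", ")))
  }
  tibble(protein_id = unname(ids), sequence = unname(seqs))
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row; missing values are written as empty
#' fields; column order is the order of the input tibble.
#'
#' @param records A data frame of results.
#' @param path Output path.
#' @return `records`, invisibly.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  readr::write_tsv(records, path, na = "", progress = FALSE)
  invisible(records)
}
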