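#' Configuration for a synthetic knockdown-proteomics dataset
#'
#' Describes the two-population ratio structure of a knockdown experiment:
#' organellar proteins are depleted on knockdown (per-protein true effect
#' drawn from Normal(`effect_mean`, `effect_sd`^2) on the log2 scale),
#' non-organellar proteins are unaffected (true effect 0). Replicate
#' ratios add Normal(0, `replicate_sd`^2) noise; `label_switch_replicates`
#' carry the induced condition in the light channel so their emitted raw
#' heavy/light ratios are inverted; cells go missing independently with
#' `missing_rate`. Peptide counts follow 1 + NegBinomial(`peptide_mu`,
#' `peptide_size`) (discrete and heavy-tailed, so single-peptide proteins
#' occur and exercise the rescue path). Each class contributes a fraction
#' `reference_coverage` of its members to the corresponding reference set;
#' the uncovered remainder forms the unlabeled pool the pipeline must
#' classify, mimicking contaminants and unannotated proteins.
#'
#' @param n_organellar,n_other Class sizes.
#' @param n_replicates Number of biological replicates.
#' @param effect_mean Expected log2 depletion of organellar proteins
#'   (negative; default -1.5).
#' @param effect_sd Between-protein spread of the true effect.
#' @param replicate_sd Within-protein replicate noise (log2 scale).
#' @param label_switch_replicates Indices of label-switched replicates.
#' @param missing_rate Per-cell probability of a missing ratio.
#' @param peptide_mu,peptide_size Negative-binomial parameters of the
#'   peptide-count law (counts are 1 + NB(mu, size)).
#' @param reference_coverage Fraction of each class entering its
#'   reference set.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list of class `synthetic_quant_config`.
#' @export
synthetic_quant_config <- function(n_organellar = 800L, n_other = 800L,
                                   n_replicates = 4L,
                                   effect_mean = -1.5, effect_sd = 0.5,
                                   replicate_sd = 0.4,
                                   label_switch_replicates = c(2L, 4L),
                                   missing_rate = 0.05,
                                   peptide_mu = 5, peptide_size = 1.5,
                                   reference_coverage = 0.6,
                                   seed = 1L) {
  if (n_organellar < 0L || n_other < 0L || n_replicates < 1L) {
    abort("counts must be non-negative and n_replicates at least 1")
  }
  if (missing_rate < 0 || missing_rate > 1 ||
      reference_coverage < 0 || reference_coverage > 1) {
    abort("missing_rate and reference_coverage must lie in [0, 1]")
  }
  if (effect_mean >= 0) {
    abort("effect_mean must be negative for a depletion scenario")
  }
  label_switch_replicates <- intersect(as.integer(label_switch_replicates),
                                       seq_len(n_replicates))
  structure(
    list(n_organellar = as.integer(n_organellar),
         n_other = as.integer(n_other),
         n_replicates = as.integer(n_replicates),
         effect_mean = effect_mean, effect_sd = effect_sd,
         replicate_sd = replicate_sd,
         label_switch_replicates = label_switch_replicates,
         missing_rate = missing_rate,
         peptide_mu = peptide_mu, peptide_size = peptide_size,
         reference_coverage = reference_coverage,
         seed = as.integer(seed)),
    class = "synthetic_quant_config"
  )
}

#' Simulate a knockdown quantification dataset with known truth
#'
#' Generates a raw wide quantification table in the dialect
#' [read_quant_table()] reads (raw heavy/light ratio and evidence columns
#' per replicate), the matching replicate design, reference sets sampled
#' from each class, and a ground-truth table.
#'
#' @param config A [synthetic_quant_config()].
#' @return A list: `table` (wide raw tibble), `design`
#'   ([replicate_design()] tibble), `ratio_columns`, `evidence_columns`
#'   (named vectors for [read_quant_table()]), `positive_ref`,
#'   `negative_ref` (accession vectors), `truth` (tibble `protein_id`,
#'   `class`, `true_effect`).
#' @export
simulate_quant_dataset <- function(config = synthetic_quant_config()) {
  stopifnot(inherits(config, "synthetic_quant_config"))
  set.seed(config$seed)
  n_org <- config$n_organellar
  n_oth <- config$n_other
  n <- n_org + n_oth
  r <- config$n_replicates

  design <- replicate_design(
    sprintf("r%d", seq_len(r)),
    ifelse(seq_len(r) %in% config$label_switch_replicates, "light", "heavy")
  )
  ratio_columns <- stats::setNames(sprintf("ratio_hl_r%d", seq_len(r)),
                                   design$replicate_id)
  evidence_columns <- stats::setNames(sprintf("evidence_r%d", seq_len(r)),
                                      design$replicate_id)

  protein_id <- c(sprintf("ORG%04d", seq_len(n_org)),
                  sprintf("OTH%04d", seq_len(n_oth)))
  class <- rep(c("organellar", "other"), c(n_org, n_oth))
  true_effect <- c(rnorm(n_org, config$effect_mean, config$effect_sd),
                   rep(0, n_oth))

  n_peptides <- 1L + rnbinom(n, mu = config$peptide_mu,
                             size = config$peptide_size)
  n_unique <- pmax(1L, rbinom(n, n_peptides, 0.8))

  oriented <- matrix(true_effect, n, r) +
    matrix(rnorm(n * r, 0, config$replicate_sd), n, r)
  missing <- matrix(rbinom(n * r, 1L, config$missing_rate) == 1L, n, r)
  oriented[missing] <- NA_real_
  evidence <- matrix(ifelse(missing, "absent",
                            ifelse(matrix(rbinom(n * r, 1L, 0.9) == 1L, n, r),
                                   "msms", "match_between_runs")),
                     n, r)

  tab <- tibble(
    protein_id = protein_id,
    description = paste0("synthetic ", class, " protein"),
    n_peptides = n_peptides,
    n_unique_peptides = n_unique
  )
  for (j in seq_len(r)) {
    raw <- if (design$induced_channel[j] == "heavy") 2^oriented[, j] else
      2^(-oriented[, j])
    tab[[ratio_columns[[j]]]] <- raw
    tab[[evidence_columns[[j]]]] <- evidence[, j]
  }

  org_ids <- protein_id[class == "organellar"]
  oth_ids <- protein_id[class == "other"]
  positive_ref <- structure(
    sort(sample(org_ids, floor(config$reference_coverage * n_org))),
    name = "organellar_reference")
  negative_ref <- structure(
    sort(sample(oth_ids, floor(config$reference_coverage * n_oth))),
    name = "non_organellar_reference")

  list(
    table = tab,
    design = design,
    ratio_columns = ratio_columns,
    evidence_columns = evidence_columns,
    positive_ref = positive_ref,
    negative_ref = negative_ref,
    truth = tibble(protein_id = protein_id, class = class,
                   true_effect = true_effect)
  )
}

#' Long oriented records from a simulated dataset
#'
#' Convenience wrapper applying the same orientation logic as
#' [read_quant_table()] to the in-memory wide table of
#' [simulate_quant_dataset()].
#'
#' @param sim Result of [simulate_quant_dataset()].
#' @return Long quantification tibble (see [read_quant_table()]).
#' @export
as_quant_records <- function(sim) {
  orient_quant_frame(sim$table, sim$design, sim$ratio_columns,
                     sim$evidence_columns, id_column = "protein_id",
                     description_column = "description")
}

# 19-letter alphabet excluding cysteine, used for motif-free stretches.
NON_CYS <- setdiff(c("A", "R", "N", "D", "Q", "E", "G", "H", "I", "L",
                     "K", "M", "F", "P", "S", "T", "W", "Y", "V"), "C")

random_non_cys <- function(n) {
  paste0(sample(NON_CYS, n, replace = TRUE), collapse = "")
}

make_motif <- function(spacing) {
  paste0("C", random_non_cys(spacing), "C")
}

#' Simulate a proteome with planted twin CxnC motifs
#'
#' Substrate proteins carry two planted, disjoint motifs of the same type
#' (Cx3C or Cx9C) with cysteine-free flanks and mass below 50 kDa;
#' non-substrates carry at most one motif by construction (all other
#' cysteines are suppressed). Planted coordinates are recorded so scanner
#' output can be checked exactly.
#'
#' @param n_proteins Number of proteins.
#' @param substrate_fraction Fraction of substrate proteins.
#' @param mean_length Mean sequence length (lengths are Poisson around
#'   this, bounded to keep substrates under the mass gate).
#' @param seed Integer seed.
#' @return A list: `sequences` (tibble `protein_id`, `sequence`), `truth`
#'   (tibble `protein_id`, `is_substrate`, `motif_type`), `planted`
#'   (tibble `protein_id`, `motif_type`, `start`, `end`).
#' @export
simulate_proteome_sequences <- function(n_proteins = 100L,
                                        substrate_fraction = 0.3,
                                        mean_length = 150L, seed = 1L) {
  if (substrate_fraction < 0 || substrate_fraction > 1) {
    abort("substrate_fraction must lie in [0, 1]")
  }
  set.seed(seed)
  n_sub <- round(substrate_fraction * n_proteins)
  is_substrate <- rep(c(TRUE, FALSE), c(n_sub, n_proteins - n_sub))
  protein_id <- sprintf("SYN%04d", seq_len(n_proteins))

  rows <- purrr::map(seq_len(n_proteins), function(i) {
    len <- max(40L, min(400L, stats::rpois(1, mean_length)))
    if (is_substrate[i]) {
      spacing <- sample(c(3L, 9L), 1)
      motif_type <- sprintf("Cx%dC", spacing)
      flank1 <- random_non_cys(sample(5:30, 1))
      # linker length 9 would let the two inner cysteines of a Cx3C pair
      # form an unplanned Cx9C motif; keep planted hits the only ones
      linker <- random_non_cys(sample(setdiff(5:30, 9L), 1))
      flank2 <- random_non_cys(max(0L, len - 2L * (spacing + 2L) -
                                     nchar(flank1) - nchar(linker)))
      seqn <- paste0(flank1, make_motif(spacing), linker,
                     make_motif(spacing), flank2)
      s1 <- nchar(flank1) + 1L
      s2 <- nchar(flank1) + spacing + 2L + nchar(linker) + 1L
      planted <- tibble(protein_id = protein_id[i],
                        motif_type = motif_type,
                        start = c(s1, s2),
                        end = c(s1, s2) + spacing + 1L)
    } else {
      motif_type <- NA_character_
      if (stats::runif(1) < 0.5) {
        spacing <- sample(c(3L, 9L), 1)
        flank1 <- random_non_cys(sample(5:30, 1))
        flank2 <- random_non_cys(max(5L, len - spacing - 2L - nchar(flank1)))
        seqn <- paste0(flank1, make_motif(spacing), flank2)
      } else {
        seqn <- random_non_cys(len)
      }
      planted <- NULL
    }
    list(
      sequence = tibble(protein_id = protein_id[i], sequence = seqn),
      truth = tibble(protein_id = protein_id[i],
                     is_substrate = is_substrate[i],
                     motif_type = motif_type),
      planted = planted
    )
  })

  list(
    sequences = dplyr::bind_rows(purrr::map(rows, "sequence")),
    truth = dplyr::bind_rows(purrr::map(rows, "truth")),
    planted = dplyr::bind_rows(purrr::compact(purrr::map(rows, "planted")))
  )
}
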