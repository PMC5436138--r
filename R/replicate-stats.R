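#' Identification and quantification filter policy
#'
#' Controls which proteins are considered reliably quantified. The default
#' rule requires at least two peptides (one unique) and quantification in
#' at least two biological replicates. The optional single-peptide rescue
#' admits proteins identified with only one unique peptide when they are
#' quantified in every replicate and their identification rests on MS/MS
#' spectra (rather than match-between-runs transfer) in at least
#' `rescue_min_msms_replicates` replicates — the policy used for
#' gradient-purified organelle data, where genuine low-abundance residents
#' would otherwise be discarded.
#'
#' @param min_peptides Minimum total peptides (default 2).
#' @param min_unique_peptides Minimum unique peptides (default 1).
#' @param min_quantified_replicates Minimum replicates with a ratio
#'   (default 2).
#' @param single_peptide_rescue Enable the rescue clause (default `FALSE`).
#' @param rescue_requires_all_replicates Rescue requires quantification in
#'   every replicate of the design (default `TRUE`).
#' @param rescue_min_msms_replicates Minimum replicates with MS/MS evidence
#'   for a rescued protein (default 2).
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(min_peptides = 2L,
                          min_unique_peptides = 1L,
                          min_quantified_replicates = 2L,
                          single_peptide_rescue = FALSE,
                          rescue_requires_all_replicates = TRUE,
                          rescue_min_msms_replicates = 2L) {
  if (min_unique_peptides > min_peptides) {
    abort("min_unique_peptides must not exceed min_peptides")
  }
  if (min_peptides < 0L || min_quantified_replicates < 0L ||
      rescue_min_msms_replicates < 0L) {
    abort("filter policy counts must be non-negative")
  }
  structure(
    list(
      min_peptides = as.integer(min_peptides),
      min_unique_peptides = as.integer(min_unique_peptides),
      min_quantified_replicates = as.integer(min_quantified_replicates),
      single_peptide_rescue = isTRUE(single_peptide_rescue),
      rescue_requires_all_replicates = isTRUE(rescue_requires_all_replicates),
      rescue_min_msms_replicates = as.integer(rescue_min_msms_replicates)
    ),
    class = "filter_policy"
  )
}

#' @export
print.filter_policy <- function(x, ...) {
  cat("<filter_policy>\n")
  cat("  peptides >=", x$min_peptides,
      "(unique >=", paste0(x$min_unique_peptides, ");"),
      "quantified replicates >=", x$min_quantified_replicates, "\n")
  if (x$single_peptide_rescue) {
    cat("  single-peptide rescue: quantified in",
        if (x$rescue_requires_all_replicates) "all" else "any",
        "replicates, MS/MS evidence in >=",
        x$rescue_min_msms_replicates, "replicates\n")
  } else {
    cat("  single-peptide rescue: off\n")
  }
  invisible(x)
}

# One-sample two-sided t-test of log2 ratios against 0, vectorised over
# proteins. Degenerate-variance convention: sd 0 with mean 0 -> p = 1,
# sd 0 with mean != 0 -> p = 0 (limit of the t statistic); fewer than two
# values -> NA. Cross-checked against stats::t.test in the test suite.
one_sample_t_pvalue <- function(mean_x, sd_x, n) {
  p <- rep(NA_real_, length(mean_x))
  ok <- !is.na(n) & n >= 2L
  degen <- ok & sd_x == 0
  p[degen & mean_x == 0] <- 1
  p[degen & mean_x != 0] <- 0
  reg <- ok & !degen
  tstat <- mean_x[reg] / (sd_x[reg] / sqrt(n[reg]))
  p[reg] <- 2 * pt(-abs(tstat), df = n[reg] - 1L)
  p
}

#' Summarise one protein's oriented log2 ratios
#'
#' Mean over non-missing oriented log2 (+Tet/-Tet) ratios and the p-value of
#' a one-sample two-sided Student's t-test against 0 (df = n_quantified - 1).
#' With fewer than two ratios the p-value is missing; with all ratios
#' missing both statistics are missing.
#'
#' @param ratios Numeric vector of oriented log2 ratios, `NA` for
#'   unquantified replicates.
#' @return A one-row tibble: `mean_log2`, `p_value`, `n_quantified`.
#' @examples
#' summarize_protein(c(-1.0, -1.2, -0.8))
#' @export
summarize_protein <- function(ratios) {
  x <- ratios[!is.na(ratios)]
  n <- length(x)
  tibble(
    mean_log2 = if (n >= 1L) mean(x) else NA_real_,
    p_value = if (n >= 2L) one_sample_t_pvalue(mean(x), sd(x), n) else NA_real_,
    n_quantified = n
  )
}

#' Filter proteins and compute per-protein statistics
#'
#' Applies a [filter_policy()] to oriented quantification records and
#' computes, for every protein, the mean log2 (+Tet/-Tet) ratio across
#' replicates and the two-sided one-sample t-test p-value. Failing proteins
#' are retained with `passed_filter = FALSE` — filtering never drops rows,
#' so counts are conserved for downstream accounting.
#'
#' @param records Long quantification tibble from [read_quant_table()].
#' @param policy A [filter_policy()].
#' @return A tibble with one row per protein, in first-appearance order:
#'   `protein_id`, `n_peptides`, `n_unique_peptides`, `n_quantified`,
#'   `n_msms`, `mean_log2`, `p_value`, `passed_filter`.
#' @export
apply_identification_filter <- function(records, policy = filter_policy()) {
  stopifnot(is.data.frame(records), inherits(policy, "filter_policy"))
  design_size <- dplyr::n_distinct(records$replicate_id)
  if (policy$rescue_min_msms_replicates > design_size) {
    abort("rescue_min_msms_replicates exceeds the design size")
  }

  stats <- records |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_peptides = dplyr::first(.data$n_peptides),
      n_unique_peptides = dplyr::first(.data$n_unique_peptides),
      n_quantified = sum(!is.na(.data$oriented_log2_ratio)),
      n_msms = sum(.data$evidence == "msms"),
      mean_log2 = if (n_quantified >= 1L)
        mean(.data$oriented_log2_ratio, na.rm = TRUE) else NA_real_,
      sd_log2 = if (n_quantified >= 2L)
        sd(.data$oriented_log2_ratio, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    )
  # restore input order (group_by sorts alphabetically)
  stats <- stats[match(unique(records$protein_id), stats$protein_id), ]

  stats <- stats |>
    dplyr::mutate(
      p_value = one_sample_t_pvalue(.data$mean_log2, .data$sd_log2,
                                    .data$n_quantified),
      main_rule = .data$n_peptides >= policy$min_peptides &
        .data$n_unique_peptides >= policy$min_unique_peptides &
        .data$n_quantified >= policy$min_quantified_replicates,
      rescue_rule = policy$single_peptide_rescue &
        .data$n_unique_peptides >= 1L &
        (!policy$rescue_requires_all_replicates |
           .data$n_quantified == design_size) &
        .data$n_msms >= policy$rescue_min_msms_replicates,
      passed_filter = .data$main_rule | .data$rescue_rule
    ) |>
    dplyr::select("protein_id", "n_peptides", "n_unique_peptides",
                  "n_quantified", "n_msms", "mean_log2", "p_value",
                  "passed_filter")
  stats
}
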