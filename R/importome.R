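#' Call the organellar importome from per-protein statistics
#'
#' A protein is called `imported` when it passes the identification filter,
#' its mean log2 (+Tet/-Tet) ratio is less than or equal to the depletion
#' threshold (boundary included) and its t-test p-value is strictly below
#' `alpha`. Quantified, filter-passing proteins not meeting both gates are
#' `unaffected`; proteins failing the filter or lacking a mean or p-value
#' are `unquantifiable`.
#'
#' @param stats Per-protein statistics from [apply_identification_filter()].
#' @param threshold Depletion threshold on the log2 ratio scale (e.g. the
#'   `chosen_threshold` of an [scan_f1()] result).
#' @param alpha Significance level for the per-protein t-test (default
#'   0.05; no multiple-testing correction is applied here — the
#'   dual-reference threshold, not the p-value, carries the specificity).
#' @return A tibble of class `importome_calls` with columns `protein_id`,
#'   `mean_log2`, `p_value`, `call` (factor: imported, unaffected,
#'   unquantifiable) and `is_new_candidate` (all `NA` until
#'   [identify_new_candidates()] is consulted); attributes `threshold` and
#'   `alpha` record the gates.
#' @export
call_importome <- function(stats, threshold, alpha = 0.05) {
  stopifnot(is.data.frame(stats), is.numeric(threshold))
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  calls <- stats |>
    dplyr::mutate(
      quantifiable = .data$passed_filter & !is.na(.data$mean_log2) &
        !is.na(.data$p_value),
      call = factor(
        dplyr::case_when(
          !quantifiable ~ "unquantifiable",
          .data$mean_log2 <= threshold & .data$p_value < alpha ~ "imported",
          TRUE ~ "unaffected"
        ),
        levels = c("imported", "unaffected", "unquantifiable")
      ),
      is_new_candidate = NA
    ) |>
    dplyr::select("protein_id", "mean_log2", "p_value", "call",
                  "is_new_candidate")
  structure(calls, threshold = threshold, alpha = alpha,
            class = c("importome_calls", class(calls)))
}

#' Call abundance changes at a fixed fold-change cutoff
#'
#' For experiments analysed with a fixed fold-change criterion instead of a
#' reference-calibrated threshold (e.g. whole-cell lysates at 1.5-fold, or
#' a disulfide-relay knockdown at 2-fold), a protein is `down` when its
#' mean log2 ratio is at most `-log2(fold)` and its p-value is below
#' `alpha`, `up` in the mirrored case, `none` otherwise.
#'
#' @inheritParams call_importome
#' @param fold Minimum fold change, strictly greater than 1.
#' @return A tibble with columns `protein_id`, `mean_log2`, `p_value`,
#'   `direction` (factor: down, up, none; `NA` for unquantifiable
#'   proteins) and `call` as in [call_importome()] with `imported`
#'   meaning significantly reduced.
#' @export
call_fixed_fold <- function(stats, fold, alpha = 0.05) {
  if (!is.numeric(fold) || fold <= 1) abort("fold must be greater than 1")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  cut <- log2(fold)
  stats |>
    dplyr::mutate(
      quantifiable = .data$passed_filter & !is.na(.data$mean_log2) &
        !is.na(.data$p_value),
      direction = factor(
        dplyr::case_when(
          !quantifiable ~ NA_character_,
          .data$mean_log2 <= -cut & .data$p_value < alpha ~ "down",
          .data$mean_log2 >= cut & .data$p_value < alpha ~ "up",
          TRUE ~ "none"
        ),
        levels = c("down", "up", "none")
      ),
      call = factor(
        dplyr::case_when(
          !quantifiable ~ "unquantifiable",
          direction == "down" ~ "imported",
          TRUE ~ "unaffected"
        ),
        levels = c("imported", "unaffected", "unquantifiable")
      )
    ) |>
    dplyr::select("protein_id", "mean_log2", "p_value", "direction", "call")
}

#' New organellar candidates among the importome
#'
#' Imported proteins absent from the known (positive) reference set are the
#' newly proposed organellar residents.
#'
#' @param calls Result of [call_importome()] (or [call_fixed_fold()]).
#' @param known_ref Accessions with previously reported organellar
#'   localization.
#' @return Character vector of new-candidate accessions, in call order.
#' @export
identify_new_candidates <- function(calls, known_ref) {
  imported <- calls$protein_id[calls$call == "imported"]
  setdiff(imported, known_ref)
}

#' Flag new candidates in a call table
#'
#' Sets `is_new_candidate` to `TRUE` for imported proteins not in
#' `known_ref`, `FALSE` for other imported proteins, `NA` otherwise.
#'
#' @inheritParams identify_new_candidates
#' @return `calls` with `is_new_candidate` filled in.
#' @export
flag_new_candidates <- function(calls, known_ref) {
  calls$is_new_candidate <- ifelse(
    calls$call == "imported", !(calls$protein_id %in% known_ref), NA
  )
  calls
}

#' Reference-set overlap of an importome
#'
#' For each reference set, counts its members among the quantified,
#' filter-passing proteins (the denominator) and among the imported calls,
#' with the imported percentage to one decimal (the unrounded fraction is
#' also returned).
#'
#' @inheritParams call_importome
#' @param calls Result of [call_importome()].
#' @param positive_ref,negative_ref Disjoint reference accession vectors.
#' @return A tibble with one row per reference set: `reference`,
#'   `n_quantified`, `n_imported`, `frac_imported`, `pct_imported`.
#' @export
reference_overlap_summary <- function(calls, positive_ref, negative_ref) {
  check_disjoint_refs(positive_ref, negative_ref)
  one <- function(ids, label) {
    quantifiable <- calls$call != "unquantifiable"
    n_q <- sum(quantifiable & calls$protein_id %in% ids)
    n_i <- sum(calls$call == "imported" & calls$protein_id %in% ids)
    frac <- if (n_q > 0L) n_i / n_q else 0
    tibble(reference = label, n_quantified = n_q, n_imported = n_i,
           frac_imported = frac, pct_imported = round(100 * frac, 1))
  }
  dplyr::bind_rows(
    one(positive_ref, attr(positive_ref, "name") %||% "positive"),
    one(negative_ref, attr(negative_ref, "name") %||% "negative")
  )
}

#' Volcano-ready export table
#'
#' One row per filter-passing protein: mean log2 ratio, -log10 p-value,
#' the importome call and the protein's reference-set membership.
#'
#' @inheritParams reference_overlap_summary
#' @param stats Per-protein statistics aligned with `calls` by
#'   `protein_id`; a mismatch is an error.
#' @return A tibble with columns `protein_id`, `mean_log2`, `neg_log10_p`,
#'   `call`, `reference` (`"positive"`, `"negative"` or `"other"`).
#' @export
volcano_table <- function(stats, calls, positive_ref = character(),
                          negative_ref = character()) {
  if (!setequal(stats$protein_id, calls$protein_id)) {
    abort("stats and calls carry different protein IDs")
  }
  stats |>
    dplyr::filter(.data$passed_filter) |>
    dplyr::select("protein_id", "mean_log2") |>
    dplyr::left_join(
      dplyr::select(as_tibble(calls), "protein_id", "p_value", "call"),
      by = "protein_id"
    ) |>
    dplyr::mutate(
      neg_log10_p = -log10(.data$p_value),
      reference = dplyr::case_when(
        .data$protein_id %in% positive_ref ~ "positive",
        .data$protein_id %in% negative_ref ~ "negative",
        TRUE ~ "other"
      )
    ) |>
    dplyr::select("protein_id", "mean_log2", "neg_log10_p", "call",
                  "reference")
}

#' @rdname call_importome
#' @param object An `importome_calls` tibble.
#' @param ... Unused.
#' @method autoplot importome_calls
#' @export
autoplot.importome_calls <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$call != "unquantifiable")
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_log2, -log10(.data$p_value),
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean log2 ratio (+Tet / -Tet)",
                  y = expression(-log[10] ~ italic(P))) +
    ggplot2::theme_minimal()
}

#' @rdname call_importome
#' @param x An `importome_calls` tibble.
#' @method glance importome_calls
#' @export
glance.importome_calls <- function(x, ...) {
  tibble(
    threshold = attr(x, "threshold"),
    alpha = attr(x, "alpha"),
    n_proteins = nrow(x),
    n_imported = sum(x$call == "imported"),
    n_unaffected = sum(x$call == "unaffected"),
    n_unquantifiable = sum(x$call == "unquantifiable")
  )
}
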