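# Grid values are carried at a fixed decimal precision matching the scan
# step; threshold comparisons add a tiny epsilon so that a mean ratio equal
# to a grid value is counted as <= despite binary-float representation.
GRID_EPS <- 1e-9

grid_digits <- function(grid_step) max(0L, ceiling(-log10(grid_step)))

check_disjoint_refs <- function(reference, opposite) {
  shared <- intersect(reference, opposite)
  if (length(shared) > 0L) {
    abort(paste0("reference sets overlap: ",
                 paste(head(shared, 10L), collapse = ", ")))
  }
}

# Keep only filter-passing proteins with a defined mean ratio.
scan_pool <- function(stats) {
  dplyr::filter(stats, .data$passed_filter, !is.na(.data$mean_log2))
}

f1_from_counts <- function(tp, fp, fn) {
  precision <- ifelse(tp + fp > 0L, tp / (tp + fp), 1)
  sensitivity <- ifelse(tp + fn > 0L, tp / (tp + fn), NA_real_)
  f1 <- ifelse(tp == 0L, 0,
               2 * precision * sensitivity / (precision + sensitivity))
  list(precision = precision, sensitivity = sensitivity, f1 = f1)
}

#' Confusion counts and F1 score at a single ratio threshold
#'
#' Counts true positives, false positives and false negatives for a
#' candidate threshold `theta` on the mean log2 (+Tet/-Tet) ratio, using
#' two disjoint reference proteomes. On the `depleted` side a positive
#' call is `mean_log2 <= theta` (knockdown-sensitive, i.e. imported); the
#' `unaffected` side mirrors this with `mean_log2 > theta` as the positive
#' call. Proteins in neither reference set are the unlabeled pool being
#' classified and never enter the counts.
#'
#' @param theta Threshold on the log2 ratio scale.
#' @param stats Per-protein statistics from [apply_identification_filter()];
#'   only filter-passing proteins with a defined mean enter the counts.
#' @param reference Accessions of the reference set being scored (the
#'   positives).
#' @param opposite Accessions of the opposite reference set.
#' @param side `"depleted"` or `"unaffected"`.
#' @return A one-row tibble: `threshold`, `tp`, `fp`, `fn`, `precision`,
#'   `sensitivity`, `f1`. By convention `f1 = 0` when `tp = 0` and
#'   `precision = 1` when no positive call is made.
#' @export
confusion_at_threshold <- function(theta, stats, reference, opposite,
                                   side = c("depleted", "unaffected")) {
  side <- match.arg(side)
  check_disjoint_refs(reference, opposite)
  pool <- scan_pool(stats)
  ref_means <- pool$mean_log2[pool$protein_id %in% reference]
  opp_means <- pool$mean_log2[pool$protein_id %in% opposite]
  if (side == "depleted") {
    tp <- sum(ref_means <= theta + GRID_EPS)
    fp <- sum(opp_means <= theta + GRID_EPS)
    fn <- length(ref_means) - tp
  } else {
    tp <- sum(ref_means > theta + GRID_EPS)
    fp <- sum(opp_means > theta + GRID_EPS)
    fn <- length(ref_means) - tp
  }
  m <- f1_from_counts(tp, fp, fn)
  tibble(threshold = theta, tp = tp, fp = fp, fn = fn,
         precision = m$precision, sensitivity = m$sensitivity, f1 = m$f1)
}

# Evaluate one F1 curve over a vector of grid thresholds (vectorised via
# sorted counting; equivalent to confusion_at_threshold at each point).
f1_curve <- function(grid, ref_means, opp_means, side) {
  sr <- sort(ref_means)
  so <- sort(opp_means)
  n_ref <- length(sr)
  tp_le <- findInterval(grid + GRID_EPS, sr)
  fp_le <- findInterval(grid + GRID_EPS, so)
  if (side == "depleted") {
    tp <- tp_le; fp <- fp_le; fn <- n_ref - tp_le
  } else {
    tp <- n_ref - tp_le; fp <- length(so) - fp_le; fn <- tp_le
  }
  m <- f1_from_counts(tp, fp, fn)
  tibble(threshold = grid, tp = tp, fp = fp, fn = fn,
         precision = m$precision, sensitivity = m$sensitivity, f1 = m$f1)
}

#' Dual-reference F1-score threshold scan
#'
#' Derives the significance threshold separating knockdown-depleted
#' (organellar) from unaffected proteins by scanning candidate thresholds
#' on the mean log2 ratio and scoring each against two curated reference
#' proteomes. For the positive (organellar) reference the positive call is
#' depletion (`mean_log2 <= theta`); for the negative reference the mirror
#' call (`mean_log2 > theta`) is scored. The F1 score — harmonic mean of
#' precision TP/(TP+FP) and sensitivity TP/(TP+FN) — is maximised on each
#' curve, giving thresholds `t2` (positive reference) and `t1` (negative
#' reference); the more stringent (more negative) of the two is adopted.
#'
#' Under the default `start_rule = "literal"` each curve starts at the
#' lowest ratio at which it has at least one TP and one FP, rounded down to
#' the grid, and proceeds in `grid_step` increments to the maximum observed
#' mean ratio. `start_rule = "full"` spans all observed means, defining
#' precision as 1 where no FP is called (this admits perfectly separating
#' thresholds that the literal rule skips). `candidates = "observed"`
#' evaluates the observed mean ratios themselves instead of the grid.
#'
#' @param stats Per-protein statistics from [apply_identification_filter()].
#' @param positive_ref,negative_ref Disjoint accession vectors (e.g. from
#'   [read_reference_set()]); both must intersect the quantified,
#'   filter-passing proteins.
#' @param grid_step Scan increment on the log2 scale (default 0.01).
#' @param start_rule `"literal"` or `"full"` (see Details).
#' @param candidates `"grid"` (default) or `"observed"`.
#' @return An object of class `f1_scan`: a list with `curves` (a tibble of
#'   both F1 curves, column `reference` in `{"positive", "negative"}`),
#'   `t1`, `t2`, `chosen_threshold`, `grid_step`, `start_rule`,
#'   `candidates`. Ties in the maximum F1 break toward the more negative
#'   (more stringent) threshold.
#' @seealso [choose_threshold()], [call_importome()]
#' @export
scan_f1 <- function(stats, positive_ref, negative_ref, grid_step = 0.01,
                    start_rule = c("literal", "full"),
                    candidates = c("grid", "observed")) {
  start_rule <- match.arg(start_rule)
  candidates <- match.arg(candidates)
  if (grid_step <= 0) abort("grid_step must be positive")
  check_disjoint_refs(positive_ref, negative_ref)

  pool <- scan_pool(stats)
  pos_means <- pool$mean_log2[pool$protein_id %in% positive_ref]
  neg_means <- pool$mean_log2[pool$protein_id %in% negative_ref]
  if (length(pos_means) == 0L || length(neg_means) == 0L) {
    abort("a reference set has no quantified, filter-passing members")
  }

  digits <- grid_digits(grid_step)
  all_means <- c(pos_means, neg_means, pool$mean_log2)
  grid_max <- ceiling(max(all_means) / grid_step) * grid_step
  make_grid <- function(start) {
    round(seq(floor(start / grid_step) * grid_step, grid_max, by = grid_step),
          digits)
  }

  curve_for <- function(ref_means, opp_means, side) {
    if (candidates == "observed") {
      cand <- sort(unique(pool$mean_log2))
    } else if (start_rule == "full") {
      cand <- make_grid(min(all_means))
    } else if (side == "depleted") {
      # >=1 TP needs theta >= min(ref); >=1 FP needs theta >= min(opp)
      cand <- make_grid(max(min(ref_means), min(opp_means)))
      cand <- cand[findInterval(cand + GRID_EPS, sort(ref_means)) >= 1L &
                     findInterval(cand + GRID_EPS, sort(opp_means)) >= 1L]
    } else {
      # mirror: >=1 TP needs theta < max(ref); >=1 FP needs theta < max(opp)
      cand <- make_grid(min(all_means))
      cand <- cand[cand + GRID_EPS < max(ref_means) &
                     cand + GRID_EPS < max(opp_means)]
    }
    f1_curve(cand, ref_means, opp_means, side)
  }

  curve_pos <- curve_for(pos_means, neg_means, "depleted")
  curve_neg <- curve_for(neg_means, pos_means, "unaffected")
  # which.max takes the first maximum; grids ascend, so ties break toward
  # the more negative (more stringent) threshold
  t2 <- curve_pos$threshold[which.max(curve_pos$f1)]
  t1 <- curve_neg$threshold[which.max(curve_neg$f1)]

  structure(
    list(
      curves = dplyr::bind_rows(
        dplyr::mutate(curve_pos, reference = "positive", .before = 1L),
        dplyr::mutate(curve_neg, reference = "negative", .before = 1L)
      ),
      t1 = t1,
      t2 = t2,
      chosen_threshold = choose_threshold(t1, t2),
      grid_step = grid_step,
      start_rule = start_rule,
      candidates = candidates
    ),
    class = "f1_scan"
  )
}

#' Adopt the more stringent of two candidate thresholds
#'
#' Depletion is called below the threshold, so the more negative of `t1`
#' (negative-reference optimum) and `t2` (positive-reference optimum)
#' imposes the more stringent filter and is adopted.
#'
#' @param t1,t2 Candidate thresholds on the log2 ratio scale.
#' @return `min(t1, t2)`.
#' @examples
#' choose_threshold(-0.33, -0.59)  # -0.59
#' @export
choose_threshold <- function(t1, t2) {
  if (is.na(t1) || is.na(t2)) abort("both thresholds must be defined")
  min(t1, t2)
}

#' @export
print.f1_scan <- function(x, ...) {
  cat("<f1_scan>  grid step", x$grid_step,
      paste0("(", x$start_rule, " start, ", x$candidates, " candidates)\n"))
  cat("  t2 (positive ref):", format(x$t2), "  t1 (negative ref):",
      format(x$t1), "\n")
  cat("  chosen threshold :", format(x$chosen_threshold), "\n")
  invisible(x)
}

#' @rdname scan_f1
#' @param x An `f1_scan` object.
#' @param ... Unused.
#' @method tidy f1_scan
#' @export
tidy.f1_scan <- function(x, ...) {
  x$curves
}

#' @rdname scan_f1
#' @method glance f1_scan
#' @export
glance.f1_scan <- function(x, ...) {
  by_ref <- split(x$curves$f1, x$curves$reference)
  tibble(
    t1 = x$t1,
    t2 = x$t2,
    chosen_threshold = x$chosen_threshold,
    max_f1_positive = max(by_ref$positive),
    max_f1_negative = max(by_ref$negative),
    grid_step = x$grid_step,
    n_thresholds = nrow(x$curves)
  )
}

#' @rdname scan_f1
#' @param object An `f1_scan` object.
#' @method autoplot f1_scan
#' @export
autoplot.f1_scan <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(.data$threshold, .data$f1,
                               colour = .data$reference)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$chosen_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "mean log2 ratio threshold", y = "F1 score",
                  colour = "reference set",
                  title = sprintf("Threshold scan: t1 = %.2f, t2 = %.2f, chosen = %.2f",
                                  object$t1, object$t2,
                                  object$chosen_threshold)) +
    ggplot2::theme_minimal()
}
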