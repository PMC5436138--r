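#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value is the total probability, under the hypergeometric
#' null with fixed margins, of all tables at least as extreme as (with
#' point probability no larger than) the observed one.
#'
#' @param a,b,c,d Non-negative counts: rows are in/out of the hit set,
#'   columns have/lack the property.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(3, 1, 1, 3)  # 34/70
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("table entries must be non-negative integers")
  }
  if (sum(counts) < 1) abort("table must contain at least one observation")
  fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; output order matches input
#' order, values are monotone-enforced and capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

sample_odds_ratio <- function(a, b, c, d) {
  if (b == 0 || c == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
}

#' Test a hit set for overrepresentation of predicted substrates
#'
#' Builds the 2x2 table (hit vs non-hit, predicted vs not) over the
#' quantified background of the experiment and applies the two-sided
#' Fisher's exact test. The background is always the set of proteins
#' quantified in the same experiment, never the whole genome.
#'
#' @param hit_set Accessions significantly affected by the knockdown;
#'   must be a subset of `background`.
#' @param predicted_set Accessions predicted as substrates (intersected
#'   with the background before counting).
#' @param background All quantified accessions of the experiment.
#' @param term_id Label for the tested property.
#' @return A one-row tibble: `term_id`, `hits_with_term`, `hits_total`,
#'   `background_with_term`, `background_total`, `odds_ratio`, `p_raw`,
#'   `p_adjusted` (equal to `p_raw` for this single test).
#' @export
test_substrate_enrichment <- function(hit_set, predicted_set, background,
                                      term_id = "predicted_substrate") {
  hit_set <- unique(hit_set)
  background <- unique(background)
  outside <- setdiff(hit_set, background)
  if (length(outside) > 0L) {
    abort(paste0("hit set not contained in background: ",
                 paste(head(outside, 5L), collapse = ", ")))
  }
  predicted <- intersect(unique(predicted_set), background)
  a <- length(intersect(hit_set, predicted))
  b <- length(hit_set) - a
  c <- length(predicted) - a
  d <- length(background) - length(hit_set) - c
  p <- fisher_exact_two_sided(a, b, c, d)
  tibble(
    term_id = term_id,
    hits_with_term = a,
    hits_total = length(hit_set),
    background_with_term = length(predicted),
    background_total = length(background),
    odds_ratio = sample_odds_ratio(a, b, c, d),
    p_raw = p,
    p_adjusted = p
  )
}

# Transitive closure of a parent map given as a tibble (term_id, ancestor_id);
# returns a named list term -> all ancestors (excluding the term itself).
close_ancestors <- function(ancestor_map) {
  parents <- split(ancestor_map$ancestor_id, ancestor_map$term_id)
  closed <- new.env(parent = emptyenv())
  expand <- function(term, seen = character()) {
    if (!is.null(closed[[term]])) return(closed[[term]])
    direct <- setdiff(unique(parents[[term]]), c(term, seen))
    anc <- direct
    for (p in direct) {
      if (!is.null(parents[[p]])) {
        anc <- union(anc, expand(p, seen = c(seen, term)))
      }
    }
    closed[[term]] <- anc
    anc
  }
  for (term in names(parents)) expand(term)
  as.list(closed)
}

#' Reduce term annotations to a slim vocabulary
#'
#' Replaces each protein's terms by the union of the terms and all their
#' ancestors, intersected with the slim set, removing redundancy. The
#' ancestor map (term to parent pairs) is transitively closed internally.
#' Terms absent from the ancestor map trigger a warning and pass through
#' only if they are themselves slim terms; proteins with no slim hit have
#' no rows in the output (the empty set).
#'
#' @param term_assignments Tibble with columns `protein_id`, `term_id`.
#' @param ancestor_map Tibble with columns `term_id`, `ancestor_id`
#'   (direct parents suffice).
#' @param slim_terms Character vector of slim term IDs.
#' @return Tibble with columns `protein_id`, `term_id` (slim terms only),
#'   deduplicated.
#' @export
reduce_to_slim <- function(term_assignments, ancestor_map, slim_terms) {
  stopifnot(is.data.frame(term_assignments), is.data.frame(ancestor_map))
  closure <- close_ancestors(ancestor_map)
  unknown <- setdiff(unique(term_assignments$term_id), names(closure))
  if (length(unknown) > 0L) {
    warn(paste0("term(s) absent from the ancestor map: ",
                paste(head(unknown, 10L), collapse = ", ")))
  }
  out <- term_assignments |>
    dplyr::mutate(
      slim = purrr::map(.data$term_id, function(t) {
        intersect(union(t, closure[[t]]), slim_terms)
      })
    ) |>
    dplyr::select("protein_id", "slim") |>
    tidyr::unnest("slim") |>
    dplyr::rename(term_id = "slim") |>
    dplyr::distinct()
  out
}

#' Per-term enrichment of a hit set over a quantified background
#'
#' One two-sided Fisher's exact test per term with at least one hit-set
#' member, Benjamini-Hochberg correction across the tested terms, records
#' sorted by adjusted p-value. Terms with no hit-set member are not tested
#' (shrinking the correction family); their number is recorded in the
#' `n_terms_skipped` attribute.
#'
#' @param hit_set Accessions of interest; subset of `background`.
#' @param slim_assignments Tibble with columns `protein_id`, `term_id`
#'   (e.g. from [reduce_to_slim()]).
#' @param background All quantified accessions of the experiment.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return A tibble of enrichment records (`term_id`, `hits_with_term`,
#'   `hits_total`, `background_with_term`, `background_total`,
#'   `odds_ratio`, `p_raw`, `p_adjusted`, `enriched`), sorted by
#'   `p_adjusted` then `term_id`.
#' @export
term_enrichment <- function(hit_set, slim_assignments, background,
                            alpha = 0.05) {
  hit_set <- unique(hit_set)
  background <- unique(background)
  if (length(background) == 0L) abort("background is empty")
  outside <- setdiff(hit_set, background)
  if (length(outside) > 0L) {
    abort(paste0("hit set not contained in background: ",
                 paste(head(outside, 5L), collapse = ", ")))
  }
  ann <- slim_assignments |>
    dplyr::filter(.data$protein_id %in% background) |>
    dplyr::distinct(.data$protein_id, .data$term_id)
  per_term <- split(ann$protein_id, ann$term_id)
  with_hit <- names(per_term)[vapply(per_term, function(ids)
    any(ids %in% hit_set), logical(1))]
  n_skipped <- length(per_term) - length(with_hit)
  if (length(with_hit) == 0L) {
    out <- tibble(term_id = character(), hits_with_term = integer(),
                  hits_total = integer(), background_with_term = integer(),
                  background_total = integer(), odds_ratio = double(),
                  p_raw = double(), p_adjusted = double(),
                  enriched = logical())
    attr(out, "n_terms_skipped") <- n_skipped
    return(out)
  }
  rows <- purrr::map(with_hit, function(term) {
    members <- per_term[[term]]
    a <- length(intersect(members, hit_set))
    b <- length(hit_set) - a
    c <- length(members) - a
    d <- length(background) - length(hit_set) - c
    tibble(
      term_id = term,
      hits_with_term = a,
      hits_total = length(hit_set),
      background_with_term = length(members),
      background_total = length(background),
      odds_ratio = sample_odds_ratio(a, b, c, d),
      p_raw = fisher_exact_two_sided(a, b, c, d)
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(p_adjusted = bh_adjust(.data$p_raw),
                  enriched = .data$p_adjusted < alpha) |>
    dplyr::arrange(.data$p_adjusted, .data$term_id)
  attr(out, "n_terms_skipped") <- n_skipped
  out
}
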