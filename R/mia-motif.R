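# Average (isotope-abundance-weighted) residue masses in Daltons for the
# 20 standard amino acids; X (unknown) contributes their unweighted mean.
residue_masses <- function() {
  m <- c(
    G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
    T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
    D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
    H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
  )
  c(m, X = mean(m))
}

WATER_MASS <- 18.0153

#' Average molecular mass of a protein sequence
#'
#' Sum of average residue masses plus one water (18.0153 Da). `X` counts
#' as the mean of the 20 standard residue masses; any other non-standard
#' letter is an error.
#'
#' @param sequence Character vector of amino-acid sequences (upper case).
#' @return Numeric vector of masses in Daltons.
#' @examples
#' average_mass("G")   # 75.0672
#' average_mass("GG")  # 132.1191
#' @export
average_mass <- function(sequence) {
  masses <- residue_masses()
  vapply(sequence, function(s) {
    if (is.na(s) || !nzchar(s)) abort("sequence must be non-empty")
    res <- strsplit(toupper(s), "")[[1]]
    bad <- setdiff(unique(res), names(masses))
    if (length(bad) > 0L) {
      abort(paste0("unknown residue letter(s): ", paste(bad, collapse = ", ")))
    }
    sum(masses[res]) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' Find twin CxnC motifs by a greedy non-overlapping scan
#'
#' A CxnC motif is a cysteine, exactly `spacing` non-cysteine residues,
#' and a closing cysteine (spacing 3 for Cx3C, 9 for Cx9C — the hallmark
#' of soluble intermembrane-space proteins imported via the disulfide
#' relay). The scan is greedy left-to-right and non-overlapping: a
#' cysteine cannot serve two motifs, and scanning resumes after each
#' closing cysteine.
#'
#' @param sequence A single amino-acid string.
#' @param spacing Number of non-cysteine residues between the cysteine
#'   pair: 3 or 9.
#' @return A tibble with columns `motif_type`, `start`, `end` (1-based,
#'   inclusive positions of the opening and closing cysteine).
#' @examples
#' find_twin_cx_motifs("CAAAC", spacing = 3)
#' @export
find_twin_cx_motifs <- function(sequence, spacing = c(3L, 9L)) {
  spacing <- as.integer(spacing[1])
  if (!spacing %in% c(3L, 9L)) abort("spacing must be 3 or 9")
  stopifnot(is.character(sequence), length(sequence) == 1L)
  pattern <- sprintf("C[^C]{%d}C", spacing)
  m <- gregexpr(pattern, sequence)[[1]]
  if (m[1] == -1L) {
    return(tibble(motif_type = character(), start = integer(),
                  end = integer()))
  }
  tibble(
    motif_type = sprintf("Cx%dC", spacing),
    start = as.integer(m),
    end = as.integer(m) + spacing + 1L
  )
}

#' Predict MIA-pathway substrates by motif content and mass
#'
#' Classical substrates of the mitochondrial intermembrane-space import
#' (MIA) pathway are small cysteine-rich proteins carrying twin Cx3C or
#' twin Cx9C motifs. A protein is predicted a substrate when its average
#' mass is strictly below `mass_cutoff_da` and it carries at least
#' `min_motifs` motifs — of the same type under the default
#' `count_mode = "same_type"` (the classical twin arrangement), or summed
#' across both types under `"total"`.
#'
#' Sequences with more than 10% unknown residues (`X`) are flagged in the
#' output, as their motif and mass calls are unreliable.
#'
#' @param sequences Tibble from [read_fasta()] (`protein_id`, `sequence`).
#' @param mass_cutoff_da Mass gate in Daltons, strict (default 50000).
#' @param min_motifs Minimum motif count (default 2).
#' @param count_mode `"same_type"` (default) or `"total"`.
#' @return A tibble with one row per input protein: `protein_id`,
#'   `average_mass_da`, `n_cx3c`, `n_cx9c`, `hits` (list-column of motif
#'   tibbles), `high_x_content`, `is_predicted_substrate`. All inputs are
#'   returned, not only the positives.
#' @export
predict_mia_substrates <- function(sequences, mass_cutoff_da = 50000,
                                   min_motifs = 2L,
                                   count_mode = c("same_type", "total")) {
  count_mode <- match.arg(count_mode)
  stopifnot(is.data.frame(sequences))
  hits <- purrr::map(sequences$sequence, function(s) {
    dplyr::bind_rows(find_twin_cx_motifs(s, 3L), find_twin_cx_motifs(s, 9L))
  })
  n_cx3c <- vapply(hits, function(h) sum(h$motif_type == "Cx3C"), integer(1))
  n_cx9c <- vapply(hits, function(h) sum(h$motif_type == "Cx9C"), integer(1))
  mass <- average_mass(sequences$sequence)
  x_frac <- stringr::str_count(sequences$sequence, "X") /
    nchar(sequences$sequence)
  motif_count <- if (count_mode == "same_type") pmax(n_cx3c, n_cx9c) else
    n_cx3c + n_cx9c
  tibble(
    protein_id = sequences$protein_id,
    average_mass_da = mass,
    n_cx3c = n_cx3c,
    n_cx9c = n_cx9c,
    hits = hits,
    high_x_content = x_frac > 0.1,
    is_predicted_substrate = mass < mass_cutoff_da & motif_count >= min_motifs
  )
}
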