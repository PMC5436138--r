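mk_stats <- function(mean_log2, p_value, passed = TRUE,
                     ids = sprintf("P%03d", seq_along(mean_log2))) {
  tibble::tibble(
    protein_id = ids, n_peptides = 3L, n_unique_peptides = 2L,
    n_quantified = 4L, n_msms = 4L, mean_log2 = mean_log2,
    p_value = p_value, passed_filter = rep_len(passed, length(mean_log2))
  )
}

test_that("importome calls gate on ratio (inclusive) and p (strict)", {
  st <- mk_stats(c(-0.62, -5.0, -0.62, -0.61, -1.0),
                 c(0.049, 0.2, 0.05, 0.001, NA))
  calls <- call_importome(st, threshold = -0.62)
  expect_equal(as.character(calls$call),
               c("imported",        # boundary mean, p < alpha
                 "unaffected",      # p gate fails despite huge depletion
                 "unaffected",      # p = alpha is not < alpha
                 "unaffected",      # mean above threshold
                 "unquantifiable")) # missing p
  expect_equal(attr(calls, "threshold"), -0.62)
  g <- glance(calls)
  expect_equal(g$n_imported, 1L)
  expect_equal(g$n_imported + g$n_unaffected + g$n_unquantifiable, nrow(st))
})

test_that("filter-failing proteins are unquantifiable regardless of values", {
  st <- mk_stats(c(-3, -3), c(1e-5, 1e-5), passed = c(TRUE, FALSE))
  calls <- call_importome(st, -0.62)
  expect_equal(as.character(calls$call), c("imported", "unquantifiable"))
})

test_that("every quantifiable protein is exactly one of imported/unaffected", {
  set.seed(21)
  st <- mk_stats(rnorm(300, -0.5, 1), runif(300),
                 passed = runif(300) > 0.1)
  calls <- call_importome(st, -0.62)
  quantifiable <- sum(st$passed_filter)
  expect_equal(sum(calls$call == "imported") +
                 sum(calls$call == "unaffected"), quantifiable)
  # monotonicity: stricter gates never grow the imported set
  imp <- function(thr, alpha) {
    calls <- call_importome(st, thr, alpha)
    calls$protein_id[calls$call == "imported"]
  }
  base <- imp(-0.62, 0.05)
  expect_true(all(imp(-1.0, 0.05) %in% base))
  expect_true(all(imp(-0.62, 0.01) %in% base))
})

test_that("fixed fold-change calls split by direction", {
  st <- mk_stats(c(-0.58, -0.59, 0.7, -1.2, 2.0),
                 c(0.01, 0.01, 0.01, 0.30, 0.01))
  calls <- call_fixed_fold(st, fold = 1.5)
  # log2(1.5) = 0.585: -0.58 is just inside, -0.59 just beyond
  expect_equal(as.character(calls$direction),
               c("none", "down", "up", "none", "up"))
  expect_error(call_fixed_fold(st, fold = 1), "greater than 1")
})

test_that("new candidates are the imported set minus the known reference", {
  st <- mk_stats(c(-2, -2, -2, 0), rep(0.001, 4),
                 ids = c("A", "B", "C", "D"))
  calls <- call_importome(st, -0.62)
  expect_setequal(identify_new_candidates(calls, c("B")), c("A", "C"))
  expect_equal(identify_new_candidates(calls, c("A", "B", "C")),
               character(0))
  flagged <- flag_new_candidates(calls, c("B"))
  expect_equal(flagged$is_new_candidate, c(TRUE, FALSE, TRUE, NA))
  # disjoint union: new candidates plus known imported equal the importome
  imported <- calls$protein_id[calls$call == "imported"]
  new <- identify_new_candidates(calls, c("B"))
  known_imported <- intersect(imported, c("B"))
  expect_setequal(c(new, known_imported), imported)
  expect_length(intersect(new, known_imported), 0)
})

test_that("reference overlap summary counts quantified members and percentages", {
  ids <- sprintf("P%02d", 1:14)
  st <- mk_stats(c(rep(-2, 8), rep(0, 6)),
                 c(rep(0.001, 8), rep(0.5, 6)), ids = ids)
  st$passed_filter[14] <- FALSE
  calls <- call_importome(st, -0.62)
  pos <- ids[1:10]   # 8 imported of 10 quantified
  neg <- ids[11:14]  # 3 quantified (one filtered out), 0 imported
  ov <- reference_overlap_summary(calls, pos, neg)
  expect_equal(ov$n_quantified, c(10L, 3L))
  expect_equal(ov$n_imported, c(8L, 0L))
  expect_equal(ov$pct_imported, c(80.0, 0.0))
  expect_error(reference_overlap_summary(calls, pos, c(pos[1], neg)),
               "overlap")
})

test_that("volcano table covers exactly the filter-passing proteins", {
  st <- mk_stats(c(-1, 0, 1), c(0.01, 0.5, NA), passed = c(TRUE, TRUE, FALSE))
  calls <- call_importome(st, -0.62)
  v <- volcano_table(st, calls, positive_ref = "P001",
                     negative_ref = "P002")
  expect_equal(nrow(v), 2L)
  expect_equal(v$neg_log10_p[v$protein_id == "P001"], 2)
  expect_equal(v$reference, c("positive", "negative"))
  expect_error(volcano_table(st[1:2, ], calls), "different protein IDs")
})
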