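toy_stats <- stats_from_means(c(-2.0, -1.5, -0.3, -0.4, 0.0, 0.5),
                              ids = c("R1", "R2", "R3", "O1", "O2", "O3"))
toy_ref <- c("R1", "R2", "R3")
toy_opp <- c("O1", "O2", "O3")

test_that("confusion counts at a threshold match direct enumeration", {
  pt_ <- confusion_at_threshold(-0.30, toy_stats, toy_ref, toy_opp,
                                side = "depleted")
  expect_equal(pt_$tp, 3L)
  expect_equal(pt_$fp, 1L)
  expect_equal(pt_$fn, 0L)
  expect_equal(pt_$f1, 6 / 7, tolerance = 1e-12)

  # theta below every ratio: no call, F1 = 0 by convention
  low <- confusion_at_threshold(-5, toy_stats, toy_ref, toy_opp,
                                side = "depleted")
  expect_equal(low$tp, 0L)
  expect_equal(low$f1, 0)

  # perfect separation
  sep <- confusion_at_threshold(-0.45, stats_from_means(
    c(-2, -1, -0.5, 0, 0.2, 0.4), ids = c(toy_ref, toy_opp)),
    toy_ref, toy_opp, side = "depleted")
  expect_equal(sep$precision, 1)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$f1, 1)
})

test_that("overlapping reference sets are rejected with the shared IDs", {
  expect_error(
    confusion_at_threshold(0, toy_stats, toy_ref, c("R2", "O1")), "R2")
  expect_error(scan_f1(toy_stats, toy_ref, c("R2", "O1")), "R2")
})

test_that("the toy scan finds max F1 at -0.30 with the stringent tie-break", {
  scan <- scan_f1(toy_stats, toy_ref, toy_opp)
  pos <- dplyr::filter(tidy(scan), reference == "positive")
  expect_equal(max(pos$f1), 6 / 7, tolerance = 1e-12)
  expect_equal(scan$t2, -0.30)
  expect_equal(scan$chosen_threshold, choose_threshold(scan$t1, scan$t2))
  g <- glance(scan)
  expect_equal(g$t2, -0.30)
  expect_equal(g$max_f1_positive, 6 / 7, tolerance = 1e-12)
})

test_that("choose_threshold adopts the more stringent cut", {
  expect_equal(choose_threshold(-0.33, -0.59), -0.59)
  expect_equal(choose_threshold(-0.5, -0.5), -0.5)
  expect_equal(choose_threshold(-0.62, -0.10), -0.62)
  expect_error(choose_threshold(NA, -0.5), "defined")
})

test_that("scan output equals brute-force recomputation at every grid point", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 60
    means <- c(rnorm(n / 2, -1.2, 0.6), rnorm(n / 2, 0, 0.4))
    ids <- sprintf("P%03d", 1:n)
    st <- stats_from_means(means, ids)
    ref <- ids[1:(n / 2)]
    opp <- ids[(n / 2 + 1):n]
    scan <- scan_f1(st, ref, opp)
    curves <- tidy(scan)
    for (side_ref in c("positive", "negative")) {
      curve <- dplyr::filter(curves, reference == side_ref)
      sub <- curve[sample(nrow(curve), 25), ]
      for (i in seq_len(nrow(sub))) {
        bf <- bf_confusion(sub$threshold[i],
                           if (side_ref == "positive") means[1:(n / 2)] else
                             means[(n / 2 + 1):n],
                           if (side_ref == "positive")
                             means[(n / 2 + 1):n] else means[1:(n / 2)],
                           if (side_ref == "positive") "depleted" else
                             "unaffected")
        expect_equal(sub$tp[i], bf$tp)
        expect_equal(sub$fp[i], bf$fp)
        expect_equal(sub$f1[i], bf$f1, tolerance = 1e-12)
      }
    }
  }
})

test_that("halving the grid step never lowers the best F1 and moves the argmax at most one coarse step", {
  set.seed(55)
  means <- c(rnorm(80, -1.5, 0.5), rnorm(80, 0, 0.4))
  ids <- sprintf("P%03d", seq_along(means))
  st <- stats_from_means(means, ids)
  ref <- ids[1:80]
  opp <- ids[81:160]
  coarse <- scan_f1(st, ref, opp, grid_step = 0.02)
  fine <- scan_f1(st, ref, opp, grid_step = 0.01)
  f1max <- function(scan, which) {
    max(scan$curves$f1[scan$curves$reference == which])
  }
  expect_gte(f1max(fine, "positive") + 1e-12, f1max(coarse, "positive"))
  expect_gte(f1max(fine, "negative") + 1e-12, f1max(coarse, "negative"))
  expect_lte(abs(fine$t2 - coarse$t2), 0.02 + 1e-9)
  expect_lte(abs(fine$t1 - coarse$t1), 0.02 + 1e-9)
})

test_that("the full-grid rule admits perfectly separating thresholds", {
  means <- c(-2, -1.8, -1.6, 0.5, 0.6, 0.7)
  ids <- c("A", "B", "C", "X", "Y", "Z")
  st <- stats_from_means(means, ids)
  full <- scan_f1(st, c("A", "B", "C"), c("X", "Y", "Z"),
                  start_rule = "full")
  expect_equal(max(full$curves$f1), 1)
  # the literal rule starts only where a false positive exists, so its
  # best depleted-side F1 stays below 1
  lit <- scan_f1(st, c("A", "B", "C"), c("X", "Y", "Z"))
  pos_lit <- lit$curves$f1[lit$curves$reference == "positive"]
  expect_lt(max(pos_lit), 1)
})

test_that("observed-ratio candidates reproduce the grid optimum on dense data", {
  set.seed(77)
  means <- c(rnorm(100, -1.5, 0.5), rnorm(100, 0, 0.4))
  ids <- sprintf("P%03d", seq_along(means))
  st <- stats_from_means(means, ids)
  obs <- scan_f1(st, ids[1:100], ids[101:200], candidates = "observed")
  grid <- scan_f1(st, ids[1:100], ids[101:200])
  expect_lte(abs(obs$chosen_threshold - grid$chosen_threshold), 0.05)
  expect_equal(max(obs$curves$f1), max(grid$curves$f1), tolerance = 0.02)
})
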