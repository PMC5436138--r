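design2 <- replicate_design(c("r1", "r2"), c("heavy", "light"))
cols2 <- c(r1 = "ratio_r1", r2 = "ratio_r2")

write_quant_fixture <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(df, path, na = "")
  path
}

test_that("ratios are oriented by the induced channel at read time", {
  path <- write_quant_fixture(tibble::tibble(
    protein_id = c("A", "B"), n_peptides = c(3L, 2L),
    n_unique_peptides = c(2L, 1L),
    ratio_r1 = c(0.5, 2), ratio_r2 = c(2, 0.5)
  ))
  rec <- read_quant_table(path, design2, cols2)
  # induced heavy: log2(raw); induced light (label switch): -log2(raw)
  expect_equal(rec$oriented_log2_ratio[rec$protein_id == "A"], c(-1, -1))
  expect_equal(rec$oriented_log2_ratio[rec$protein_id == "B"], c(1, 1))
  expect_equal(rec$evidence, rep("msms", 4))
})

test_that("orientation is an involution: flipping every channel negates ratios", {
  set.seed(42)
  raw <- tibble::tibble(
    protein_id = sprintf("P%02d", 1:20),
    n_peptides = 3L, n_unique_peptides = 2L,
    ratio_r1 = 2^rnorm(20), ratio_r2 = 2^rnorm(20)
  )
  raw$ratio_r2[3] <- NA
  path <- write_quant_fixture(raw)
  all_heavy <- replicate_design(c("r1", "r2"), c("heavy", "heavy"))
  all_light <- replicate_design(c("r1", "r2"), c("light", "light"))
  rec_h <- read_quant_table(path, all_heavy, cols2)
  rec_l <- read_quant_table(path, all_light, cols2)
  expect_equal(rec_h$oriented_log2_ratio, -rec_l$oriented_log2_ratio)
})

test_that("empty tables, missing cells and row conservation behave", {
  path <- write_quant_fixture(tibble::tibble(
    protein_id = character(), n_peptides = integer(),
    n_unique_peptides = integer(), ratio_r1 = double(), ratio_r2 = double()
  ))
  expect_equal(nrow(read_quant_table(path, design2, cols2)), 0L)

  path2 <- write_quant_fixture(tibble::tibble(
    protein_id = c("A", "B", "C"), n_peptides = 2L, n_unique_peptides = 1L,
    ratio_r1 = c(1, NA, NA), ratio_r2 = c(NA, NA, 0.5)
  ))
  rec <- read_quant_table(path2, design2, cols2)
  # one row per protein and replicate, independent of missingness
  expect_equal(nrow(rec), 6L)
  expect_equal(sum(is.na(rec$oriented_log2_ratio)), 4L)
  expect_equal(rec$evidence[is.na(rec$oriented_log2_ratio)],
               rep("absent", 4))
})

test_that("format and value errors name the offending column or row", {
  path <- write_quant_fixture(tibble::tibble(
    protein_id = "A", n_peptides = 2L, n_unique_peptides = 1L,
    ratio_r1 = 1
  ))
  expect_error(read_quant_table(path, design2, cols2), "ratio_r2")

  path2 <- write_quant_fixture(tibble::tibble(
    protein_id = c("A", "B"), n_peptides = 2L, n_unique_peptides = 1L,
    ratio_r1 = c(1, -2), ratio_r2 = c(1, 1)
  ))
  expect_error(read_quant_table(path2, design2, cols2),
               "non-positive.*row.*2")
})

test_that("reference sets deduplicate, skip comments and refuse emptiness", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "A", "A", "B", "", "C  "), path)
  expect_warning(ref <- read_reference_set(path, "toy"), "duplicate")
  expect_setequal(as.character(ref), c("A", "B", "C"))
  expect_equal(attr(ref, "name"), "toy")

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines("# only a comment", empty)
  expect_error(read_reference_set(empty, "toy"), "empty")
})

test_that("FASTA reading normalises case, joins wrapped lines, rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "caa", "ac", ">P2", "GGG"), path)
  seqs <- read_fasta(path)
  expect_equal(seqs$protein_id, c("P1", "P2"))
  expect_equal(seqs$sequence, c("CAAAC", "GGG"))

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "AAA", ">P1", "CCC"), dup)
  expect_error(read_fasta(dup), "duplicate")
})

test_that("write/read round trip preserves ratios and schema", {
  set.seed(7)
  raw <- tibble::tibble(
    protein_id = sprintf("P%02d", 1:10),
    n_peptides = 3L, n_unique_peptides = 2L,
    ratio_r1 = round(2^rnorm(10), 6), ratio_r2 = round(2^rnorm(10), 6)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(raw, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back), names(raw))
  expect_equal(back$ratio_r1, raw$ratio_r1, tolerance = 1e-6)

  # header-only output for an empty collection
  empty_path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(raw[0, ], empty_path)
  expect_equal(readLines(empty_path), paste(names(raw), collapse = "\t"))
})
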