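test_that("read_methylation_matrix parses shape, ages and missing cells", {
  ds <- read_methylation_matrix(write_tiny_matrix_file())
  expect_s3_class(ds, "methyl_dataset")
  expect_equal(dim(ds$beta), c(3L, 2L))
  expect_equal(ds$age, c(1, 5, 9))
  expect_equal(site_ids(ds), c("cgA", "cgB"))
  expect_false(anyNA(ds$beta))

  ds2 <- read_methylation_matrix(write_tiny_matrix_file(missing_cell = TRUE))
  expect_true(is.na(ds2$beta["s2", "cgA"]))
  expect_equal(sum(is.na(ds2$beta)), 1L)  # missing stays missing, not 0
})

test_that("read_methylation_matrix rejects malformed inputs", {
  expect_error(read_methylation_matrix(write_tiny_matrix_file(dup_site = TRUE)),
               "cgA")
  expect_error(read_methylation_matrix(tempfile()), "not found")

  bad_age <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,age,cgA", "s1,young,0.2"), bad_age)
  expect_error(read_methylation_matrix(bad_age), "age")

  dup_sample <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,age,cgA", "s1,1,0.2", "s1,2,0.3"), dup_sample)
  expect_error(read_methylation_matrix(dup_sample), "sample id")
})

test_that("GEO series-matrix reader transposes and extracts ages", {
  ds <- read_geo_series_matrix(geo_fixture_path())
  expect_equal(dim(ds$beta), c(2L, 3L))
  expect_equal(sample_ids(ds), c("GSM000001", "GSM000002"))
  expect_equal(site_ids(ds), paste0("cg0000000", 1:3))
  expect_equal(ds$age, c(34, 67))
  expect_equal(unname(ds$beta["GSM000002", "cg00000001"]), 0.34)
})

test_that("GEO reader errors without table delimiters, warns without ages", {
  lines <- readLines(geo_fixture_path())
  truncated <- tempfile(fileext = ".txt")
  writeLines(lines[!grepl("table_end", lines)], truncated)
  expect_error(read_geo_series_matrix(truncated), "delimiters")

  no_age <- tempfile(fileext = ".txt")
  writeLines(lines[!grepl("age:", lines)], no_age)
  expect_warning(ds <- read_geo_series_matrix(no_age), "age")
  expect_null(ds$age)
})

test_that("merge_datasets intersects sites and concatenates samples", {
  mk <- function(ids, sites, prefix) {
    beta <- matrix(runif(length(ids) * length(sites)), length(ids),
                   dimnames = list(ids, sites))
    methyl_dataset(beta, age = seq_along(ids),
                   source = rep(prefix, length(ids)))
  }
  a <- mk(c("a1", "a2"), c("s1", "s2", "s3"), "A")
  b <- mk(c("b1", "b2", "b3"), c("s2", "s3", "s4"), "B")
  m <- merge_datasets(list(a, b))
  expect_equal(site_ids(m), c("s2", "s3"))  # first dataset's order
  expect_equal(n_samples(m), 5L)
  expect_equal(m$source, c("A", "A", "B", "B", "B"))

  expect_identical(merge_datasets(list(a)), a)
  c_ds <- mk(c("c1", "c2"), c("zz1", "zz2"), "C")
  expect_error(merge_datasets(list(a, c_ds)), "intersection")
})

test_that("merge_datasets deduplicates clashing sample ids with a warning", {
  mk <- function(ids) methyl_dataset(
    matrix(runif(2 * length(ids)), length(ids),
           dimnames = list(ids, c("s1", "s2"))), age = seq_along(ids))
  expect_warning(m <- merge_datasets(list(mk(c("x", "y")), mk(c("y", "z")))),
                 "duplicate")
  expect_equal(anyDuplicated(sample_ids(m)), 0L)
  expect_equal(n_samples(m), 4L)
})

test_that("merge_datasets is associative up to sample order", {
  set.seed(11)
  mk <- function(ids, sites) methyl_dataset(
    matrix(runif(length(ids) * length(sites)), length(ids),
           dimnames = list(ids, sites)), age = seq_along(ids))
  a <- mk(paste0("a", 1:3), c("s1", "s2", "s3", "s4"))
  b <- mk(paste0("b", 1:2), c("s2", "s3", "s4"))
  c_ds <- mk(paste0("c", 1:4), c("s2", "s4", "s5"))
  left <- merge_datasets(list(merge_datasets(list(a, b)), c_ds))
  right <- merge_datasets(list(a, merge_datasets(list(b, c_ds))))
  expect_equal(site_ids(left), site_ids(right))
  expect_equal(left$beta[sample_ids(right), ], right$beta)
})

test_that("selection reports round-trip through disk", {
  rep3 <- selection_report("2", c("cgX", "cgY", "cgZ"), c(5.2, 4.1, 3.9))
  path <- tempfile(fileext = ".tsv")
  write_selection_report(rep3, path)
  lines <- readLines(path)
  expect_length(lines, 5L)  # comment + header + 3 rows
  back <- read_selection_report(path)
  expect_equal(back$ranked_sites, rep3$ranked_sites)
  expect_equal(back$per_site_cv_mad, rep3$per_site_cv_mad)
  expect_equal(back$group_label, "2")

  empty <- selection_report("1", character(0), numeric(0))
  write_selection_report(empty, path)
  back0 <- read_selection_report(path)
  expect_length(back0$ranked_sites, 0L)
})

test_that("dataset invariants are enforced", {
  expect_error(methyl_dataset(matrix(c(0.1, 1.5), 1), age = 3), "\\[0,1\\]")
  expect_error(methyl_dataset(matrix(0.5, 2, 1), age = c(-1, 2)), "negative")
  expect_error(methyl_dataset(matrix(0.5, 2, 2,
                                     dimnames = list(c("a", "a"), c("x", "y"))),
                              age = c(1, 2)), "duplicate sample")
  expect_error(methyl_dataset(matrix(0.5, 1, 2), age = c(1, 2)), "length")
})
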