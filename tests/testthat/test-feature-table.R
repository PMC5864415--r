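test_that("construction enforces count and id invariants", {
  m <- toy_counts()
  expect_s3_class(feature_table(m), "feature_table")

  neg <- m; neg[1, 1] <- -1L
  expect_error(feature_table(neg), class = "katharoseq_error_negative_counts")

  frac <- matrix(c(1.5, 2), nrow = 1,
                 dimnames = list("f1", c("a", "b")))
  expect_error(feature_table(frac), class = "katharoseq_error_fractional_counts")

  dup <- m; rownames(dup) <- c("f", "f", "g")
  expect_error(feature_table(dup), class = "katharoseq_error_duplicate_ids")

  expect_error(feature_table(m, taxonomy = c(nope = "k__Bacteria")),
               class = "katharoseq_error_invalid_taxonomy")
})

test_that("TSV reading matches hand-computed sums and flags malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2\ttaxonomy",
               "f1\t906\t0\tk__Bacteria; g__Bacillus",
               "f2\t94\t50\tk__Bacteria; g__Vibrio",
               "f3\t0\t50\t"), path)
  tab <- read_feature_table(path)
  expect_equal(unname(sample_depth(tab)), c(906 + 94, 100))
  expect_equal(tab$taxonomy[["f1"]], "k__Bacteria; g__Bacillus")
  expect_false("f3" %in% names(tab$taxonomy))

  hdr_only <- withr::local_tempfile(fileext = ".tsv")
  writeLines("feature_id\ts1\ts2", hdr_only)
  empty <- read_feature_table(hdr_only)
  expect_equal(dim(empty), c(0L, 2L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1", "f1\tabc"), bad)
  expect_error(read_feature_table(bad), class = "katharoseq_error_nonnumeric_counts")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1", "f1\t-3"), neg)
  expect_error(read_feature_table(neg), class = "katharoseq_error_negative_counts")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1", "f1\t3", "f1\t4"), dup)
  expect_error(read_feature_table(dup), class = "katharoseq_error_duplicate_ids")
})

test_that("write/read round trips preserve tables in both formats", {
  set.seed(101)
  for (i in 1:5) {
    tab <- random_table(n_feat = sample(1:8, 1), n_samp = sample(1:5, 1),
                        with_tax = i %% 2 == 0)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_feature_table(tab, path)
    back <- read_feature_table(path)
    expect_identical(back$counts, tab$counts)
    expect_identical(back$taxonomy, tab$taxonomy)
    expect_identical(colSums(back$counts), colSums(tab$counts))
  }

  tab <- toy_table()
  biom_path <- withr::local_tempfile(fileext = ".biom")
  write_feature_table(tab, biom_path, format = "biom")
  back <- read_feature_table(biom_path, format = "biom")
  expect_identical(back$counts[feature_ids(tab), sample_ids(tab)], tab$counts)
  expect_identical(back$taxonomy[names(tab$taxonomy)], tab$taxonomy)
})

test_that("TSV writing is byte-stable and keeps taxonomy verbatim", {
  tab <- toy_table()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, p1)
  write_feature_table(tab, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_true(any(grepl("k__Bacteria; g__Bacillus; s__subtilis",
                        readLines(p1), fixed = TRUE)))

  empty <- feature_table(matrix(integer(), nrow = 0, ncol = 2,
                                dimnames = list(NULL, c("s1", "s2"))))
  pe <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(empty, pe)
  expect_length(readLines(pe), 1L)  # header only
})

test_that("metadata reading derives titration levels and validates classes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#SampleID\tcontrol_class\tinput_cells\ttarget_spec",
               "p1\textraction_positive\t5\tg__Bacillus",
               "p2\textraction_positive\t5000\tg__Bacillus",
               "p3\textraction_positive\t50\tg__Bacillus",
               "p4\textraction_positive\t500\tg__Bacillus",
               "n1\textraction_negative\t\t",
               "s1\tsample\t\t"), path)
  design <- read_metadata(path)
  expect_s3_class(design, "katharo_design")
  expect_equal(titration_levels(design), c(5, 50, 500, 5000))

  only_samples <- study_design(tibble::tibble(
    sample_id = c("a", "b"), control_class = "sample"))
  expect_length(titration_levels(only_samples), 0)

  expect_error(
    study_design(tibble::tibble(sample_id = "p", control_class = "extraction_positive")),
    class = "katharoseq_error_missing_input_cells")
  expect_error(
    study_design(tibble::tibble(sample_id = "p", control_class = "positive")),
    class = "katharoseq_error_unknown_class")
  expect_error(
    study_design(tibble::tibble(sample_id = c("a", "a"), control_class = "sample")),
    class = "katharoseq_error_duplicate_ids")
})
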