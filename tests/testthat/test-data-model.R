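test_that("age datasets round-trip through the table format", {
  d1 <- age_dataset("d1", "Orcinus orca", "female", "popA",
                    ages = c(12, 15), counts = c(3, 1),
                    growth_prior = c(0.02, 0.01), bias_window = c(5, 10),
                    age_bias_offset = 2, source_type = "bycatch")
  d2 <- age_dataset("d2", "Orcinus orca", "female", "popB",
                    ages = c(11, 20, 30), counts = c(2, 2, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_age_datasets(list(d1, d2), path)
  back <- read_age_datasets(path)
  expect_length(back, 2)
  expect_equal(back$d1$records, d1$records, ignore_attr = TRUE)
  expect_equal(back$d1$growth_prior, c(0.02, 0.01))
  expect_equal(back$d1$bias_window, c(5, 10))
  expect_equal(back$d1$age_bias_offset, 2)
  expect_equal(back$d1$source_type, "bycatch")
  expect_equal(back$d2$max_observed_age, 30)
  expect_null(back$d2$bias_window)
})

test_that("invalid age data are rejected with informative errors", {
  expect_error(age_dataset("x", "sp", "female", "p", ages = c(1, -2),
                           counts = c(1, 1)), "negative observed age")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("dataset_id\tspecies\tsex\tpopulation_id\tage\tcount",
               "a\tsp\tfemale\tp\t5\t-1"), path)
  expect_error(read_age_datasets(path), "negative count")
  writeLines(c("dataset_id\tspecies\tsex\tage\tcount",
               "a\tsp\tfemale\t5\t1"), path)
  expect_error(read_age_datasets(path), "population_id")
  expect_error(age_dataset("x", "sp", "female", "p", ages = 10, counts = 2,
                           bias_window = c(5, 40)), "bias_window")
})

test_that("corpora and trait tables read back with defaults and warnings", {
  cd <- corpora_dataset("c1", "Globicephala melas", ages = c(12, 14, 20),
                        corpora = c(1, 3, 9), age_at_maturity = 8,
                        max_lifespan_age = 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpora_datasets(list(cd), path)
  back <- read_corpora_datasets(path)
  expect_equal(back$c1$records, cd$records, ignore_attr = TRUE)
  expect_equal(back$c1$sampling_rate, 3 / 50)

  tpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tsex\tlength_mean\tmaturity_mean\tmenopause",
               "sp1\tfemale\t400\t9\t0"), tpath)
  w <- capture_warnings(tr <- read_traits(tpath))
  expect_match(w, "sd set to 0", all = TRUE)
  expect_length(w, 2)
  expect_equal(tr[[1]]$length_sd, 0)
  expect_equal(tr[[1]]$maturity_sd, 0)
})

test_that("Newick chronograms give hand-checked patristic distances", {
  path <- withr::local_tempfile(fileext = ".nwk")
  three_taxon_tree(path)
  ch <- read_trees(path)
  expect_length(ch, 1)
  D <- ch[[1]]$D
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(diag(D), c(A = 0, B = 0, C = 0))
  expect_true(ch[[1]]$ultrametric)

  empty <- withr::local_tempfile(fileext = ".nwk")
  file.create(empty)
  expect_error(suppressWarnings(read_trees(empty)))
  expect_error(read_trees(path, required_taxa = c("A", "D")), "D")
  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:3):1,C:2);", bad)
  expect_warning(read_trees(bad), "ultrametric")
})

test_that("inclusion filters apply the published thresholds exactly", {
  mk <- function(id, adult_ages, adult_counts) {
    age_dataset(id, "sp", "female", "p", ages = adult_ages,
                counts = adult_counts)
  }
  ## 11 adults, max age 20 -> rate 0.55 -> included
  in1 <- mk("in1", c(11, 20), c(10, 1))
  ## 12 adults, max age 30 -> rate 0.40 -> excluded
  ex1 <- mk("ex1", c(11, 30), c(11, 1))
  res <- apply_inclusion_filters(list(in1, ex1), "lifespan", maturity = 10)
  expect_length(res$included, 1)
  expect_equal(res$included[[1]]$dataset_id, "in1")
  expect_equal(res$log$rule, "sampling_rate")
  expect_equal(res$log$value, 12 / 30)
  ## partition is exhaustive
  expect_equal(length(res$included) + length(res$excluded), 2)
  ## idempotent on the included set
  res2 <- apply_inclusion_filters(res$included, "lifespan", maturity = 10)
  expect_length(res2$excluded, 0)

  c19 <- corpora_dataset("c19", "sp", ages = seq(2, 38, 2),
                         corpora = rep(1, 19), age_at_maturity = 8,
                         max_lifespan_age = 20)
  cres <- apply_inclusion_filters(list(c19), "corpora")
  expect_length(cres$excluded, 1)
  expect_true("sample_size" %in% cres$log$rule)

  juv <- mk("juv", c(1, 2, 15), c(60, 50, 20))
  jres <- apply_inclusion_filters(list(juv), "juvenile", maturity = 10)
  expect_length(jres$included, 1)
  expect_error(apply_inclusion_filters(list(in1), "adult"), "arg")
})
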