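test_that("the generator is deterministic and rejects invalid configs", {
  cfg <- toy_config(n_cases = 500, duplicate_rate = 0.2)
  expect_identical(generate_cases(cfg), generate_cases(cfg))

  expect_error(synthetic_config(0, c(drug_x = 0.1)), "n_cases")
  expect_error(synthetic_config(10, c(drug_x = 1.5)), "drug_exposure_probs")
  expect_error(synthetic_config(10, c(drug_x = 0.1), female_fraction = -0.1),
               "female_fraction")
  expect_error(synthetic_config(10, c(drug_x = 0.1, drug_x = 0.2)), "duplicated")
  expect_error(association_spec("x", "y", -2, 0.1), "true_odds_ratio")
  expect_error(association_spec("x", "y", 2, 0), "baseline_event_prob")
  expect_error(synthetic_config(10, c(drug_x = 0.1),
                                associations = list(association_spec("ghost", "y", 2, 0.1))),
               "ghost")
})

test_that("a null association yields an empirical odds ratio near 1", {
  cfg <- toy_config(n_cases = 200000, or_z = 1, seed = 7)
  cases <- as_report_cases(generate_cases(cfg))
  tab <- build_table(cases, "drug_z", toy_set("event_z", 2))
  r <- compute_ror(tab)
  expect_true(r$defined)
  expect_gt(r$ror, 0.8)
  expect_lt(r$ror, 1.25)
})

test_that("exact-margin construction recounts to the requested cells", {
  set <- toy_set("event_y")
  cases <- generate_from_counts(2, 3, 1, 4, "drug_x", set)
  expect_equal(nrow(cases$demo), 10)
  expect_true(all(cases$demo$sex == "female"))
  expect_equal(cells_of(build_table(cases, "drug_x", set)), c(2, 3, 1, 4))

  degenerate <- generate_from_counts(0, 0, 0, 5, "drug_x", set)
  expect_equal(nrow(degenerate$demo), 5)
  expect_equal(nrow(degenerate$drugs), 0)
  expect_equal(nrow(degenerate$events), 0)
  expect_equal(cells_of(build_table(degenerate, "drug_x", set)), c(0, 0, 0, 5))
})

test_that("duplicate injection is undone exactly by deduplication", {
  db <- generate_cases(toy_config(n_cases = 300))
  expect_identical(inject_duplicates(db, 0), db)

  small <- db
  small$demo <- small$demo[1:10, ]
  dup_all <- inject_duplicates(small, 1, seed = 3)
  expect_equal(nrow(dup_all$demo), 20)
  expect_equal(length(unique(dup_all$demo$case_id)), 10)
  expect_equal(sort(unique(dup_all$demo$report_sequence)), c(1L, 2L))

  set <- toy_set("event_y", 3)
  base_counts <- cells_of(build_table(as_report_cases(db), "drug_x", set))
  for (rate in c(0.1, 0.5, 0.9)) {
    noisy <- inject_duplicates(db, rate, seed = 11)
    expect_equal(cells_of(build_table(as_report_cases(noisy), "drug_x", set)),
                 base_counts, info = sprintf("rate = %g", rate))
  }
})

test_that("written tables round-trip through the reader", {
  db <- generate_cases(toy_config(n_cases = 100, duplicate_rate = 0.25))
  dir <- withr::local_tempdir()
  paths <- write_jader_tables(db, dir)
  expect_true(all(file.exists(paths)))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))

  back <- read_jader(paths[["DEMO"]], paths[["DRUG"]], paths[["REAC"]],
                     paths[["HIST"]])
  expect_equal(unclass(back)[c("demo", "drugs", "events")],
               unclass(as_report_cases(db))[c("demo", "drugs", "events")],
               ignore_attr = TRUE)
})

test_that("a renamed-header dialect still round-trips", {
  map <- jader_column_map(
    demo = c(case_id = "ID", report_sequence = "SEQ", sex = "SEX", quarter = "Q"),
    drug = c(case_id = "ID", drug_name = "DRUG", participation = "ROLE"),
    reac = c(case_id = "ID", pt_name = "PT", pt_code = "PTCODE"),
    sex_levels = c(female = "F", male = "M", unknown = "U"),
    participation_levels = c(suspected = "S", concomitant = "C", interacting = "I"))
  db <- generate_cases(toy_config(n_cases = 60))
  dir <- withr::local_tempdir()
  paths <- write_jader_tables(db, dir, column_map = map)
  back <- read_jader(paths[["DEMO"]], paths[["DRUG"]], paths[["REAC"]],
                     column_map = map)
  expect_equal(unclass(back)[c("demo", "drugs", "events")],
               unclass(as_report_cases(db))[c("demo", "drugs", "events")],
               ignore_attr = TRUE)
})
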