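mixed_cases <- function() {
  demo <- data.frame(
    case_id = sprintf("M%02d", 1:5),
    report_sequence = 1L,
    sex = c("female", "female", "female", "male", "male"),
    quarter = c("2005Q1", "2010Q3", "2018Q4", "2010Q1", "2012Q2"),
    stringsAsFactors = FALSE)
  drugs <- data.frame(
    case_id = c("M01", "M02", "M02", "M04"),
    drug_name = c("drug_x", "drug_x", "drug_z", "drug_x"),
    participation = c("concomitant", "suspected", "suspected", "suspected"),
    stringsAsFactors = FALSE)
  events <- data.frame(case_id = c("M01", "M03"),
                       pt_name = c("event_y pt 1", "event_y pt 1"),
                       pt_code = "90000101", stringsAsFactors = FALSE)
  assemble_cases(demo, drugs, events)
}

test_that("sex, participation and window filters behave as specified", {
  cases <- mixed_cases()
  fem <- filter_cases(cases, cohort_filter(sex = "female"))
  expect_equal(nrow(fem$demo), 3)

  # a concomitant-only mention is removed, but the case stays in the cohort
  expect_false("M01" %in% fem$drugs$case_id)
  expect_true("M01" %in% fem$demo$case_id)
  tab <- build_table(fem, "drug_x", term_set("event_y", "event_y pt 1", "90000101"))
  expect_equal(cells_of(tab), c(0, 1, 2, 0))

  none <- filter_cases(cases, cohort_filter(quarter_range = c("2020Q1", "2021Q4")))
  expect_equal(nrow(none$demo), 0)

  windowed <- filter_cases(cases, cohort_filter(sex = "all",
                                                quarter_range = c("2010Q1", "2012Q4")))
  expect_equal(sort(windowed$demo$case_id), c("M02", "M04", "M05"))

  # monotone: adding a filter never grows the cohort
  specs <- list(cohort_filter(sex = "all"),
                cohort_filter(sex = "female"),
                cohort_filter(sex = "female", quarter_range = c("2010Q1", "2018Q4")),
                cohort_filter(sex = "female", quarter_range = c("2010Q1", "2010Q4")))
  sizes <- vapply(specs, function(s) nrow(filter_cases(cases, s)$demo), 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("packaged term sets load with the documented contents", {
  breast <- load_term_set("benign_and_malignant_breast_neoplasms")
  expect_equal(nrow(breast$pt), 60)
  expect_true("10006187" %in% breast$pt$pt_code)
  expect_equal(breast$pt$pt_name[breast$pt$pt_code == "10006187"], "Breast cancer")
  expect_false(anyDuplicated(breast$pt$pt_code) > 0)

  hp <- load_term_set("hyperprolactinaemia")
  expect_equal(nrow(hp$pt), 1)

  expect_error(load_term_set("no_such_set"), "no_such_set")
})

test_that("user term-set files are parsed and duplicates collapsed", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "custom.tsv")
  writeLines(c("pt_name\tpt_code", "Alpha\t10000001", "Beta\t10000002",
               "Alpha dup\t10000001"), path)
  expect_warning(ts <- load_term_set(path), "duplicated")
  expect_equal(nrow(ts$pt), 2)

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("pt_name\tpt_code", ""), bad)
  expect_error(load_term_set(bad), "line 2")
})

test_that("the composite-event indicator counts a case once", {
  demo <- data.frame(case_id = c("A", "B", "C"), report_sequence = 1L,
                     sex = "female", quarter = "2010Q1", stringsAsFactors = FALSE)
  events <- data.frame(
    case_id = c("A", "A", "C"),
    pt_name = c("Breast cancer", "Fibroadenoma of breast", "Alopecia"),
    pt_code = c("10006187", "10016613", "10001760"), stringsAsFactors = FALSE)
  cases <- assemble_cases(demo, data.frame(case_id = character(0),
                                           drug_name = character(0),
                                           participation = character(0)),
                          events)
  breast <- load_term_set("benign_and_malignant_breast_neoplasms")
  ind <- case_has_event(cases, breast)
  expect_identical(unname(ind), c(TRUE, FALSE, FALSE))
  # two member PTs in case A still one TRUE -> contributes one count
  expect_equal(sum(ind), 1)

  # name-based matching when the report carries no code
  uncoded <- cases
  uncoded$events$pt_code <- NA_character_
  expect_identical(unname(case_has_event(uncoded, breast)), c(TRUE, FALSE, FALSE))
})
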