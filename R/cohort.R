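# Cohort construction: the screen analyses female cases only, counts a drug
# as an exposure only when it is reported as a suspected drug, and restricts
# to the study reporting window.

#' Specify the cohort filters
#'
#' @param sex `"female"`, `"male"` or `"all"`.
#' @param participation Participation roles that count as exposure; subset of
#'   `c("suspected", "concomitant", "interacting")`, nonempty.
#' @param quarter_range Optional closed interval of year-quarter labels,
#'   e.g. `c("2004Q2", "2019Q1")`; `NULL` keeps all quarters.
#' @return A `cohort_filter` specification.
#' @export
cohort_filter <- function(sex = c("female", "male", "all"),
                          participation = "suspected",
                          quarter_range = NULL) {
  sex <- match.arg(sex)
  participation <- match.arg(participation,
                             c("suspected", "concomitant", "interacting"),
                             several.ok = TRUE)
  if (!is.null(quarter_range)) {
    stopifnot(is.character(quarter_range), length(quarter_range) == 2L,
              quarter_range[1] <= quarter_range[2])
  }
  structure(list(sex = sex, participation = participation,
                 quarter_range = quarter_range),
            class = "cohort_filter")
}

#' Apply cohort filters to assembled cases
#'
#' Keeps the cases satisfying the sex and quarter predicates, then removes
#' drug mentions whose participation role is outside the filter. A case whose
#' mentions are all removed stays in the cohort (it still contributes to the
#' report denominator); only the sex/quarter predicates drop cases.
#'
#' @param cases A `report_cases` object.
#' @param filter A [cohort_filter()].
#' @return The filtered `report_cases`.
#' @export
filter_cases <- function(cases, filter = cohort_filter()) {
  stopifnot(inherits(cases, "report_cases"), inherits(filter, "cohort_filter"))
  keep <- rep(TRUE, nrow(cases$demo))
  if (filter$sex != "all") keep <- keep & cases$demo$sex == filter$sex
  if (!is.null(filter$quarter_range)) {
    keep <- keep & cases$demo$quarter >= filter$quarter_range[1] &
      cases$demo$quarter <= filter$quarter_range[2]
  }
  demo <- cases$demo[keep, , drop = FALSE]
  drugs <- cases$drugs[cases$drugs$case_id %in% demo$case_id &
                         cases$drugs$participation %in% filter$participation, ,
                       drop = FALSE]
  events <- cases$events[cases$events$case_id %in% demo$case_id, , drop = FALSE]
  rownames(demo) <- rownames(drugs) <- rownames(events) <- NULL
  structure(list(demo = demo, drugs = drugs, events = events),
            class = "report_cases")
}
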