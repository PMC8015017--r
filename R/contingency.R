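# 2x2 contingency tables for (drug, event set) pairs.
#
# Counting unit: the case. Each case contributes to exactly one cell of each
# drug's table -- so one case reporting two suspected drugs appears in both
# drugs' rows (the screen counts drug mentions, not unique cases, across
# rows), but never twice within a row. Exposure means any suspected (or
# other role kept by the cohort filter) mention of the drug; the composite
# event indicator is case-level (a case with several member PTs counts once).

#' Build one drug-event 2x2 contingency table
#'
#' Cells: `a` cases with the drug and the event, `b` drug without event, `c`
#' event without drug, `d` neither; `a+b+c+d` equals the cohort size.
#'
#' @param cases Cohort-filtered `report_cases` (see [filter_cases()]).
#' @param drug_name Drug label; matched after trimming, width folding and
#'   case folding (see the package's name normalization), optionally through
#'   `synonyms`.
#' @param event_set A [term_set()].
#' @param synonyms Optional named character vector mapping alternative drug
#'   spellings to canonical labels, applied to both sides before matching.
#' @return A `contingency_table`: list with `a`, `b`, `c`, `d`, `n_total`,
#'   `drug_name`, `event_set_name`.
#' @export
build_table <- function(cases, drug_name, event_set, synonyms = NULL) {
  stopifnot(inherits(cases, "report_cases"), inherits(event_set, "term_set"))
  exposed <- .exposure_indicator(cases, drug_name, synonyms)
  event <- case_has_event(cases, event_set)
  a <- sum(exposed & event)
  b <- sum(exposed & !event)
  c_ <- sum(!exposed & event)
  d <- sum(!exposed & !event)
  structure(list(a = a, b = b, c = c_, d = d, n_total = a + b + c_ + d,
                 drug_name = drug_name, event_set_name = event_set$name),
            class = "contingency_table")
}

.exposure_indicator <- function(cases, drug_name, synonyms = NULL) {
  canon <- function(x) {
    x <- normalize_label(x)
    if (!is.null(synonyms)) {
      syn <- stats::setNames(normalize_label(unname(synonyms)),
                             normalize_label(names(synonyms)))
      hit <- match(x, names(syn))
      x[!is.na(hit)] <- syn[hit[!is.na(hit)]]
    }
    x
  }
  mention <- cases$drugs[canon(cases$drugs$drug_name) == canon(drug_name), ,
                         drop = FALSE]
  cases$demo$case_id %in% mention$case_id
}

#' Build the full screen of 2x2 tables
#'
#' One table per (drug, event set) pair on a shared cohort; every table sums
#' to the same cohort size.
#'
#' @inheritParams build_table
#' @param drug_names Character vector of drug labels.
#' @param event_sets A [term_set()] or list of them.
#' @return A data frame of class `contingency_set` with columns `drug_name`,
#'   `event_set_name`, `a`, `b`, `c`, `d`, `n_total`, one row per pair,
#'   ordered by drug then event set.
#' @export
build_all <- function(cases, drug_names, event_sets, synonyms = NULL) {
  stopifnot(inherits(cases, "report_cases"))
  if (inherits(event_sets, "term_set")) event_sets <- list(event_sets)
  stopifnot(length(drug_names) >= 1, length(event_sets) >= 1,
            all(vapply(event_sets, inherits, TRUE, "term_set")))
  drug_names <- sort(unique(drug_names))
  event_ind <- lapply(event_sets, function(ts) case_has_event(cases, ts))
  names(event_ind) <- vapply(event_sets, `[[`, "", "name")
  rows <- list()
  for (dn in drug_names) {
    exposed <- .exposure_indicator(cases, dn, synonyms)
    for (es in names(event_ind)) {
      ev <- event_ind[[es]]
      rows[[length(rows) + 1L]] <- data.frame(
        drug_name = dn, event_set_name = es,
        a = sum(exposed & ev), b = sum(exposed & !ev),
        c = sum(!exposed & ev), d = sum(!exposed & !ev),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$n_total <- out$a + out$b + out$c + out$d
  out <- out[order(out$drug_name, out$event_set_name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contingency_set", "data.frame")
  out
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s x %s (N = %d)\n", x$drug_name,
              x$event_set_name, x$n_total))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("drug", "no drug"), c("event", "no event")))
  print(m)
  invisible(x)
}

#' @export
as.data.frame.contingency_table <- function(x, ...) {
  data.frame(drug_name = x$drug_name, event_set_name = x$event_set_name,
             a = x$a, b = x$b, c = x$c, d = x$d, n_total = x$n_total,
             stringsAsFactors = FALSE)
}
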