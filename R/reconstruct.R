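# Reconstruction harness for published screen tables.
#
# Published disproportionality tables typically print, per drug: the drug's
# report total (a+b), the event count n (= a), the statistics, and a single
# grand total N -- but not the event marginal a+c. With one printed ROR the
# marginal can be back-solved in closed form:
#   ROR = (a d)/(b c), b = total - n, c + d = N - total
#   =>  c = (N - total) / (1 + ROR * b / n),  marginal = c + n.
# With the marginal recovered, every cell and hence every statistic of every
# row is recomputable, and rows whose own implied marginal disagrees with
# the consensus are flagged as internally inconsistent.

#' Load a packaged published screen table
#'
#' Packaged transcriptions of published per-drug screen rows:
#' `"table2_breast_neoplasms"` (29 antipsychotics vs the composite breast
#' neoplasm event) and `"table3_hyperprolactinaemia"` (the same drugs vs
#' hyperprolactinaemia). Columns: `drug_name`, `drug_class`, `drug_total`
#' (= a+b), `n` (= a), printed `ror`, `ror_ci_low`, `ror_ci_high`, `prr`,
#' `chi2`, `ic`, `ic_ci_low`, `ic_ci_high`, printed signal flags, and
#' `grand_total` (N). Rows with `n = 0` carry `NA` statistics.
#'
#' @param name Packaged table name or path to a tab-separated file with the
#'   same columns.
#' @return A data frame of published rows.
#' @export
published_table <- function(name) {
  packaged <- system.file("extdata", paste0(name, ".tsv"), package = "pvscreen")
  path <- if (nzchar(packaged)) packaged else name
  if (!file.exists(path)) {
    stop(sprintf("published table '%s' is neither packaged nor an existing file", name))
  }
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug_name", "drug_total", "n", "ror", "grand_total")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    stop(sprintf("published table '%s' is missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  bad <- with(out, n > drug_total | drug_total > grand_total)
  if (any(bad)) {
    stop(sprintf("published table '%s': row %d violates n <= drug_total <= grand_total",
                 path, which(bad)[1]))
  }
  out
}

#' Back-solve the event marginal from one published row
#'
#' Inverts the ROR formula (see the module notes above) to recover the
#' unprinted event marginal a+c implied by one row's `n`, drug total and
#' printed ROR. Real-valued: the printed ROR is rounded, so the implied
#' marginal is not an integer.
#'
#' @param n Event count of the row (= a); must be >= 1.
#' @param drug_total The drug's report total (= a+b).
#' @param printed_ror The ROR as printed.
#' @param grand_total The cohort size N.
#' @return The implied event marginal (vectorized); `NA` with a warning for
#'   unsolvable rows (`n = 0` or nonpositive ROR).
#' @export
solve_event_marginal <- function(n, drug_total, printed_ror, grand_total) {
  b <- drug_total - n
  ok <- !is.na(printed_ror) & printed_ror > 0 & n >= 1 & b >= 0 &
    grand_total > drug_total
  if (any(!ok)) {
    warning(sprintf("%d row(s) unsolvable (need printed ROR > 0, n >= 1, drug_total <= N)",
                    sum(!ok)))
  }
  c_ <- ifelse(ok, (grand_total - drug_total) / (1 + printed_ror * b / n),
               NA_real_)
  c_ + n
}

#' Recompute a full statistic row from margins
#'
#' Builds the 2x2 table `(a, b, c, d) = (n, drug_total - n,
#' event_marginal - n, remainder)` and screens it.
#'
#' @param n Event count for the drug (= a).
#' @param drug_total Drug report total (= a+b).
#' @param event_marginal Event marginal (= a+c), integer.
#' @param grand_total Cohort size N.
#' @inheritParams screen_signals
#' @param drug_name,event_set_name Labels carried into the output row.
#' @return A one-row `signal_screen` data frame.
#' @export
recompute_row <- function(n, drug_total, event_marginal, grand_total,
                          priors = bcpnn_priors(), criteria = signal_criteria(),
                          ci_method = "delta", drug_name = "drug",
                          event_set_name = "event") {
  a <- n; b <- drug_total - n; c_ <- event_marginal - n
  d <- grand_total - drug_total - c_
  if (c_ < 0 || d < 0 || b < 0) {
    stop(sprintf("infeasible row: (a,b,c,d) = (%s, %s, %s, %s)", a, b, c_, d))
  }
  screen_signals(data.frame(drug_name = drug_name,
                            event_set_name = event_set_name,
                            a = a, b = b, c = c_, d = d,
                            stringsAsFactors = FALSE),
                 priors = priors, criteria = criteria, ci_method = ci_method)
}

#' Consistency report over a published table
#'
#' Back-solves the implied event marginal of every row with a printed ROR,
#' forms a robust consensus (the median over all solvable rows, rounded to
#' the nearest integer), and reports each row's relative deviation from it.
#' Rows deviating by more than `tolerance` are flagged as internally
#' inconsistent with the rest of the table; the flag is diagnostic -- the
#' consensus is the plain median, robust to a minority of anomalous rows.
#'
#' @param rows A published-rows data frame ([published_table()]).
#' @param tolerance Relative deviation above which a row is flagged (0.05).
#' @return A `marginal_estimate`: list with `event_marginal` (integer
#'   consensus), `per_row` (drug, implied marginal, deviation, flag) and
#'   `tolerance`.
#' @export
consistency_report <- function(rows, tolerance = 0.05) {
  usable <- !is.na(rows$ror) & rows$n >= 1
  if (sum(usable) < 2) {
    stop("consistency_report needs at least 2 rows with printed statistics")
  }
  implied <- rep(NA_real_, nrow(rows))
  implied[usable] <- solve_event_marginal(rows$n[usable],
                                          rows$drug_total[usable],
                                          rows$ror[usable],
                                          rows$grand_total[usable])
  consensus_real <- stats::median(implied, na.rm = TRUE)
  consensus <- round(consensus_real)
  deviation <- implied / consensus_real - 1
  per_row <- data.frame(drug_name = rows$drug_name,
                        n = rows$n, drug_total = rows$drug_total,
                        implied_marginal = implied,
                        deviation = deviation,
                        flagged = !is.na(deviation) & abs(deviation) > tolerance,
                        stringsAsFactors = FALSE)
  structure(list(event_marginal = consensus,
                 per_row = per_row[usable, , drop = FALSE],
                 tolerance = tolerance),
            class = "marginal_estimate")
}

#' @export
print.marginal_estimate <- function(x, ...) {
  cat(sprintf("<marginal_estimate> consensus event marginal = %d (median of %d rows)\n",
              x$event_marginal, nrow(x$per_row)))
  flagged <- x$per_row$drug_name[x$per_row$flagged]
  if (length(flagged)) {
    cat(sprintf("  flagged (>%g%% deviation): %s\n", 100 * x$tolerance,
                paste(flagged, collapse = ", ")))
  }
  y <- x$per_row
  y$implied_marginal <- round(y$implied_marginal, 1)
  y$deviation <- round(y$deviation, 4)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Recompute every row of a published table
#'
#' Runs [consistency_report()] (unless an explicit `event_marginal` is
#' given), then [recompute_row()] for every row with `n >= 1`.
#'
#' @inheritParams consistency_report
#' @inheritParams screen_signals
#' @param event_marginal Optional integer marginal overriding the consensus.
#' @return A `signal_screen` data frame with the consistency report attached
#'   as attribute `consistency` (when computed).
#' @export
reconstruct_table <- function(rows, priors = bcpnn_priors(),
                              criteria = signal_criteria(),
                              ci_method = "delta", event_marginal = NULL,
                              tolerance = 0.05) {
  consistency <- NULL
  if (is.null(event_marginal)) {
    consistency <- consistency_report(rows, tolerance)
    event_marginal <- consistency$event_marginal
  }
  keep <- rows$n >= 1
  cc <- event_marginal - rows$n[keep]
  dd <- rows$grand_total[keep] - rows$drug_total[keep] - cc
  if (any(cc < 0 | dd < 0)) {
    stop(sprintf("infeasible row for marginal %d: %s", event_marginal,
                 rows$drug_name[keep][which(cc < 0 | dd < 0)[1]]))
  }
  out <- screen_signals(data.frame(
    drug_name = rows$drug_name[keep],
    event_set_name = if (!is.null(rows$event_set_name)) rows$event_set_name[keep] else "event",
    a = rows$n[keep], b = rows$drug_total[keep] - rows$n[keep],
    c = event_marginal - rows$n[keep],
    d = rows$grand_total[keep] - rows$drug_total[keep] -
      (event_marginal - rows$n[keep]),
    stringsAsFactors = FALSE),
    priors = priors, criteria = criteria, ci_method = ci_method)
  attr(out, "event_marginal") <- event_marginal
  attr(out, "consistency") <- consistency
  out
}
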