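# Disproportionality statistics for 2x2 report tables and their signal
# criteria.
#
# Conventions for a table (a, b, c, d), N = a+b+c+d:
#   ROR = (a d)/(b c), Woolf 95% CI on the log scale:
#         exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d));
#         signal when the CI lower bound exceeds 1. Undefined (no signal)
#         when any cell is zero; an optional Haldane-Anscombe 0.5 continuity
#         add is available but off by default.
#   PRR = [a/(a+b)] / [c/(c+d)], with the continuity-corrected chi-square
#         sum_cells (|O - E| - 0.5)^2 / E at margin-fixed expectations
#         E = row * column / N, each cell's |O - E| - 0.5 floored at 0;
#         signal when PRR >= 2, chi-square >= 4 and n = a >= 3.
#   IC  = BCPNN information component, the shrinkage posterior expectation of
#         log2 of observed-over-expected reporting, with C = N, c_x = a+b,
#         c_y = a+c, c_xy = a and priors (alpha, beta, alpha1, beta1,
#         gamma11); gamma is derived as
#           gamma = gamma11 (C+alpha)(C+beta) / ((c_x+alpha1)(c_y+beta1)).
#         E(IC) = log2[ (c_xy+gamma11)(C+alpha)(C+beta) /
#                       ((C+gamma)(c_x+alpha1)(c_y+beta1)) ]
#         V(IC) = (ln 2)^-2 [ (C-c_xy+gamma-gamma11)/((c_xy+gamma11)(1+C+gamma))
#                           + (C-c_x+alpha-alpha1)/((c_x+alpha1)(1+C+alpha))
#                           + (C-c_y+beta-beta1)/((c_y+beta1)(1+C+beta)) ]
#         Defined for all nonnegative tables, zero cells included. The 95%
#         interval is E(IC) +/- z sqrt(V(IC)) (delta method) or a percentile
#         interval from posterior sampling; signal when the lower bound
#         exceeds 0.

#' Signal criteria thresholds
#'
#' Defaults are the standard criteria: ROR signal when the Woolf 95% CI
#' lower bound exceeds 1; PRR signal when PRR >= 2, Yates chi-square >= 4 and
#' n >= 3; IC signal when the 95% interval lower bound exceeds 0.
#'
#' @param z Normal quantile for the 95% intervals (1.96).
#' @param prr_threshold,chi2_threshold,n_threshold The three-part PRR
#'   criterion thresholds.
#' @param ror_lower_bound,ic_lower_bound Interval lower-bound cutoffs for the
#'   ROR and IC signals.
#' @return A `signal_criteria` list.
#' @export
signal_criteria <- function(z = 1.96, prr_threshold = 2, chi2_threshold = 4,
                            n_threshold = 3, ror_lower_bound = 1,
                            ic_lower_bound = 0) {
  stopifnot(z > 0)
  structure(list(z = z, prr_threshold = prr_threshold,
                 chi2_threshold = chi2_threshold, n_threshold = n_threshold,
                 ror_lower_bound = ror_lower_bound,
                 ic_lower_bound = ic_lower_bound),
            class = "signal_criteria")
}

#' BCPNN priors
#'
#' The standard priors: `alpha = beta = 2`, `alpha1 = beta1 = 1`,
#' `gamma11 = 1`, under which a table with all margins at half the total
#' shrinks the IC toward 0. `gamma` is derived from the margins, not stored.
#'
#' @param alpha,beta Priors on the margin totals.
#' @param alpha1,beta1 Priors on the drug and event margins.
#' @param gamma11 Prior on the joint cell.
#' @return A `bcpnn_priors` list.
#' @export
bcpnn_priors <- function(alpha = 2, beta = 2, alpha1 = 1, beta1 = 1,
                         gamma11 = 1) {
  vals <- c(alpha = alpha, beta = beta, alpha1 = alpha1, beta1 = beta1,
            gamma11 = gamma11)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all BCPNN priors must be positive reals")
  }
  structure(as.list(vals), class = "bcpnn_priors")
}

.cells <- function(table) {
  if (inherits(table, "contingency_table") || is.list(table)) {
    c(a = table$a, b = table$b, c = table$c, d = table$d)
  } else if (is.numeric(table) && length(table) == 4) {
    c(a = table[[1]], b = table[[2]], c = table[[3]], d = table[[4]])
  } else {
    stop("'table' must be a contingency_table or a numeric vector (a, b, c, d)")
  }
}

# Vectorized cores shared by the scalar compute_* wrappers and the screen.

.ror_stats <- function(a, b, c, d, z = 1.96, haldane = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  if (haldane) {
    adj <- (a == 0 | b == 0 | c == 0 | d == 0) * 0.5
    a <- a + adj; b <- b + adj; c <- c + adj; d <- d + adj
  }
  defined <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ifelse(defined, (a * d) / (b * c), NA_real_)
  se <- ifelse(defined, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  list(ror = ror, ci_low = exp(log(ror) - z * se),
       ci_high = exp(log(ror) + z * se), defined = defined)
}

.prr_stats <- function(a, b, c, d) {
  # doubles throughout: margin products overflow 32-bit integers
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n_tot <- a + b + c + d
  defined <- (a + b) > 0 & c > 0
  prr <- ifelse(defined, (a / (a + b)) / (c / (c + d)), NA_real_)
  # margin-fixed expectations; each cell's Yates term floored at 0
  yates_term <- function(o, e) ifelse(e > 0, pmax(abs(o - e) - 0.5, 0)^2 / e, 0)
  e_a <- (a + b) * (a + c) / n_tot
  e_b <- (a + b) * (b + d) / n_tot
  e_c <- (c + d) * (a + c) / n_tot
  e_d <- (c + d) * (b + d) / n_tot
  chi2 <- yates_term(a, e_a) + yates_term(b, e_b) +
    yates_term(c, e_c) + yates_term(d, e_d)
  chi2[n_tot == 0] <- NA_real_
  list(prr = prr, chi2 = ifelse(defined, chi2, NA_real_), n = a,
       defined = defined)
}

.ic_stats <- function(a, b, c, d, priors = bcpnn_priors()) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  C <- a + b + c + d
  cx <- a + b; cy <- a + c; cxy <- a
  al <- priors$alpha; be <- priors$beta
  al1 <- priors$alpha1; be1 <- priors$beta1; g11 <- priors$gamma11
  g <- g11 * (C + al) * (C + be) / ((cx + al1) * (cy + be1))
  ic <- log2((cxy + g11) * (C + al) * (C + be) /
               ((C + g) * (cx + al1) * (cy + be1)))
  v <- (1 / log(2)^2) * (
    (C - cxy + g - g11) / ((cxy + g11) * (1 + C + g)) +
      (C - cx + al - al1) / ((cx + al1) * (1 + C + al)) +
      (C - cy + be - be1) / ((cy + be1) * (1 + C + be)))
  list(ic = ic, variance = v, gamma = g)
}

#' Reporting odds ratio with Woolf interval
#'
#' @param table A `contingency_table` or numeric `c(a, b, c, d)`.
#' @param criteria A [signal_criteria()].
#' @param haldane Apply the Haldane-Anscombe 0.5 continuity add to all cells
#'   of tables with a zero cell instead of declaring them undefined. Off by
#'   default: the screen flags zero-cell tables as undefined.
#' @return A `ror_result`: `ror`, `ci_low`, `ci_high`, `defined`, `signal`
#'   (`TRUE` iff defined and `ci_low` exceeds the criterion bound).
#' @examples
#' compute_ror(c(12, 1383, 1503, 700948))
#' @export
compute_ror <- function(table, criteria = signal_criteria(), haldane = FALSE) {
  x <- .cells(table)
  s <- .ror_stats(x["a"], x["b"], x["c"], x["d"], z = criteria$z,
                  haldane = haldane)
  structure(list(ror = unname(s$ror), ci_low = unname(s$ci_low),
                 ci_high = unname(s$ci_high), defined = unname(s$defined),
                 signal = isTRUE(unname(s$defined) &
                                   s$ci_low > criteria$ror_lower_bound)),
            class = "ror_result")
}

#' Proportional reporting ratio with Yates chi-square
#'
#' @inheritParams compute_ror
#' @return A `prr_result`: `prr`, `chi2`, `n` (= a), `defined`, `signal`
#'   (`TRUE` iff defined and the three-part criterion holds).
#' @examples
#' compute_prr(c(12, 1383, 1503, 700948))
#' @export
compute_prr <- function(table, criteria = signal_criteria()) {
  x <- .cells(table)
  s <- .prr_stats(x["a"], x["b"], x["c"], x["d"])
  sig <- isTRUE(unname(s$defined) &
                  s$prr >= criteria$prr_threshold &
                  s$chi2 >= criteria$chi2_threshold &
                  s$n >= criteria$n_threshold)
  structure(list(prr = unname(s$prr), chi2 = unname(s$chi2),
                 n = unname(s$n), defined = unname(s$defined), signal = sig),
            class = "prr_result")
}

#' BCPNN information component
#'
#' The Bayesian shrinkage estimate of the base-2 log observed-over-expected
#' reporting ratio. Defined for every nonnegative table, zero cells included.
#' The 95% interval is either the delta-method interval from the posterior
#' variance (default) or a percentile interval from posterior sampling of the
#' three cell probabilities (independent Beta posteriors for the joint and
#' the two margin probabilities). The Monte Carlo method draws from the
#' session RNG; seed it for reproducibility.
#'
#' @inheritParams compute_ror
#' @param priors A [bcpnn_priors()].
#' @param ci_method `"delta"` or `"monte_carlo"`.
#' @param n_mc Posterior draws for the Monte Carlo interval.
#' @return An `ic_result`: `ic`, `variance`, `ci_low`, `ci_high`,
#'   `ci_method`, `signal` (`TRUE` iff `ci_low` exceeds the criterion bound).
#' @examples
#' compute_ic(c(12, 1383, 1503, 700948))
#' @export
compute_ic <- function(table, priors = bcpnn_priors(),
                       criteria = signal_criteria(),
                       ci_method = c("delta", "monte_carlo"), n_mc = 10000) {
  ci_method <- match.arg(ci_method)
  x <- .cells(table)
  s <- .ic_stats(x["a"], x["b"], x["c"], x["d"], priors)
  ic <- unname(s$ic); v <- unname(s$variance)
  if (ci_method == "delta") {
    lo <- ic - criteria$z * sqrt(v)
    hi <- ic + criteria$z * sqrt(v)
  } else {
    C <- sum(x); cxy <- x[["a"]]; cx <- x[["a"]] + x[["b"]]
    cy <- x[["a"]] + x[["c"]]; g <- unname(s$gamma)
    p_xy <- stats::rbeta(n_mc, cxy + priors$gamma11, C - cxy + g - priors$gamma11)
    p_x <- stats::rbeta(n_mc, cx + priors$alpha1, C - cx + priors$alpha - priors$alpha1)
    p_y <- stats::rbeta(n_mc, cy + priors$beta1, C - cy + priors$beta - priors$beta1)
    draws <- log2(p_xy / (p_x * p_y))
    qs <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  structure(list(ic = ic, variance = v, ci_low = lo, ci_high = hi,
                 ci_method = ci_method,
                 signal = isTRUE(lo > criteria$ic_lower_bound)),
            class = "ic_result")
}

#' Evaluate the three signal flags together
#'
#' @param ror A `ror_result` (or `NULL`).
#' @param prr A `prr_result` (or `NULL`).
#' @param ic An `ic_result` (or `NULL`).
#' @return Named logical vector `c(ror_signal, prr_signal, ic_signal)`;
#'   undefined or absent statistics yield `FALSE`.
#' @export
evaluate_signals <- function(ror = NULL, prr = NULL, ic = NULL) {
  flag <- function(x) isTRUE(x$signal)
  c(ror_signal = flag(ror), prr_signal = flag(prr), ic_signal = flag(ic))
}

#' Screen a set of contingency tables
#'
#' Computes all three statistics and signal flags for each table. Full
#' precision is retained in the returned data frame; the print method rounds
#' to two decimals for display.
#'
#' @param tables A `contingency_set` data frame ([build_all()]), a list of
#'   `contingency_table` objects, or a data frame with columns `a`, `b`, `c`,
#'   `d` (and optionally `drug_name`, `event_set_name`).
#' @inheritParams compute_ic
#' @return A data frame of class `signal_screen`, one row per table ordered
#'   by drug then event set: `drug_name`, `event_set_name`, `total` (= a+b),
#'   `n` (= a), `ror`, `ror_ci_low`, `ror_ci_high`, `prr`, `chi2`, `ic`,
#'   `ic_ci_low`, `ic_ci_high`, `ror_signal`, `prr_signal`, `ic_signal`.
#' @export
screen_signals <- function(tables, priors = bcpnn_priors(),
                           criteria = signal_criteria(),
                           ci_method = c("delta", "monte_carlo"),
                           n_mc = 10000) {
  ci_method <- match.arg(ci_method)
  empty <- data.frame(drug_name = character(0), event_set_name = character(0),
                      total = integer(0), n = integer(0), ror = numeric(0),
                      ror_ci_low = numeric(0), ror_ci_high = numeric(0),
                      prr = numeric(0), chi2 = numeric(0), ic = numeric(0),
                      ic_ci_low = numeric(0), ic_ci_high = numeric(0),
                      ror_signal = logical(0), prr_signal = logical(0),
                      ic_signal = logical(0), stringsAsFactors = FALSE)
  if (is.list(tables) && !is.data.frame(tables)) {
    tables <- do.call(rbind, lapply(tables, as.data.frame))
  }
  if (is.null(tables) || nrow(tables) == 0) {
    class(empty) <- c("signal_screen", "data.frame")
    return(empty)
  }
  stopifnot(is.data.frame(tables), all(c("a", "b", "c", "d") %in% names(tables)))
  if (is.null(tables$drug_name)) tables$drug_name <- sprintf("drug_%03d", seq_len(nrow(tables)))
  if (is.null(tables$event_set_name)) tables$event_set_name <- "event"
  a <- tables$a; b <- tables$b; c_ <- tables$c; d <- tables$d
  r <- .ror_stats(a, b, c_, d, z = criteria$z)
  p <- .prr_stats(a, b, c_, d)
  i <- .ic_stats(a, b, c_, d, priors)
  if (ci_method == "delta") {
    ic_lo <- i$ic - criteria$z * sqrt(i$variance)
    ic_hi <- i$ic + criteria$z * sqrt(i$variance)
  } else {
    mc <- vapply(seq_len(nrow(tables)), function(k) {
      res <- compute_ic(c(a[k], b[k], c_[k], d[k]), priors, criteria,
                        ci_method = "monte_carlo", n_mc = n_mc)
      c(res$ci_low, res$ci_high)
    }, numeric(2))
    ic_lo <- mc[1, ]; ic_hi <- mc[2, ]
  }
  out <- data.frame(
    drug_name = tables$drug_name, event_set_name = tables$event_set_name,
    total = a + b, n = a,
    ror = r$ror, ror_ci_low = r$ci_low, ror_ci_high = r$ci_high,
    prr = p$prr, chi2 = p$chi2,
    ic = i$ic, ic_ci_low = ic_lo, ic_ci_high = ic_hi,
    ror_signal = !is.na(r$ror) & r$defined & r$ci_low > criteria$ror_lower_bound,
    prr_signal = p$defined & !is.na(p$prr) & !is.na(p$chi2) &
      p$prr >= criteria$prr_threshold & p$chi2 >= criteria$chi2_threshold &
      p$n >= criteria$n_threshold,
    ic_signal = ic_lo > criteria$ic_lower_bound,
    stringsAsFactors = FALSE)
  out <- out[order(out$drug_name, out$event_set_name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signal_screen", "data.frame")
  out
}

#' @export
print.signal_screen <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE) & !(names(y) %in% c("total", "n"))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, ...)
  invisible(x)
}

#' Write a screen as tab-separated text
#'
#' @param x A `signal_screen` data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_screen <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
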