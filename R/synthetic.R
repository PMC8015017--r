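# Synthetic JADER-dialect report generator. Every downstream stage (reading,
# deduplication, cohort filtering, 2x2 counting, signal statistics) is
# testable against this generator's known ground truth without the real
# database.
#
# Generative model: sex ~ Bernoulli(female_fraction); drug exposures are
# independent Bernoulli draws per drug; each composite event is linked to one
# drug through a two-point model -- event probability p0 among unexposed
# cases and p1 among exposed, with p1 chosen so the population odds ratio
# equals the configured value:
#   p1 = OR * p0 / (1 - p0 + OR * p0).
# Exposed drugs are recorded with participation role "suspected"; unexposed
# filler cases carry no drug mention at all, so a drug's report total equals
# its exposure count.

#' Specify one drug-event association with a known true odds ratio
#'
#' @param drug_name Drug label; must appear in the config's
#'   `drug_exposure_probs`.
#' @param event_set_name Name of one of the config's event term sets.
#' @param true_odds_ratio Positive real: the reporting odds ratio the
#'   generator induces in the population.
#' @param baseline_event_prob Event probability among unexposed cases,
#'   in (0,1).
#' @return An `association_spec` with the implied exposed-case event
#'   probability `p1` attached.
#' @export
association_spec <- function(drug_name, event_set_name, true_odds_ratio,
                             baseline_event_prob) {
  stopifnot(is.character(drug_name), length(drug_name) == 1L,
            is.character(event_set_name), length(event_set_name) == 1L)
  if (!is.numeric(true_odds_ratio) || length(true_odds_ratio) != 1L ||
      !is.finite(true_odds_ratio) || true_odds_ratio <= 0) {
    stop("'true_odds_ratio' must be a positive real")
  }
  check_prob(baseline_event_prob, "baseline_event_prob",
             allow_zero = FALSE, allow_one = FALSE)
  p0 <- baseline_event_prob
  p1 <- true_odds_ratio * p0 / (1 - p0 + true_odds_ratio * p0)
  if (!(p1 > 0 && p1 < 1)) {
    stop("implied exposed-case event probability 'p1' falls outside (0,1)")
  }
  structure(list(drug_name = drug_name, event_set_name = event_set_name,
                 true_odds_ratio = true_odds_ratio,
                 baseline_event_prob = p0, p1 = p1),
            class = "association_spec")
}

#' Configure the synthetic report generator
#'
#' @param n_cases Number of base cases (before duplicate injection).
#' @param drug_exposure_probs Named numeric vector: per-drug exposure
#'   probability; names must be unique.
#' @param female_fraction Probability that a case is female. Default 0.55, a
#'   typical spontaneous-report sex balance.
#' @param event_term_sets List of [term_set()] objects the associations may
#'   reference.
#' @param associations List of [association_spec()] objects.
#' @param duplicate_rate Fraction of cases re-reported once with an
#'   incremented report sequence (see [inject_duplicates()]).
#' @param seed Integer seed; the whole generator is deterministic given the
#'   config.
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(n_cases, drug_exposure_probs,
                             female_fraction = 0.55,
                             event_term_sets = list(),
                             associations = list(),
                             duplicate_rate = 0, seed = 1L) {
  n_cases <- check_count(n_cases, "n_cases", positive = TRUE)
  check_prob(female_fraction, "female_fraction")
  check_prob(duplicate_rate, "duplicate_rate")
  if (length(drug_exposure_probs) == 0 || is.null(names(drug_exposure_probs)) ||
      any(!nzchar(names(drug_exposure_probs)))) {
    stop("'drug_exposure_probs' must be a named numeric vector")
  }
  if (anyDuplicated(names(drug_exposure_probs))) {
    stop("'drug_exposure_probs' has duplicated drug labels")
  }
  check_prob(drug_exposure_probs, "drug_exposure_probs")
  if (!is.list(event_term_sets) ||
      !all(vapply(event_term_sets, inherits, TRUE, "term_set"))) {
    stop("'event_term_sets' must be a list of term_set objects")
  }
  set_names <- vapply(event_term_sets, `[[`, "", "name")
  if (!is.list(associations) ||
      !all(vapply(associations, inherits, TRUE, "association_spec"))) {
    stop("'associations' must be a list of association_spec objects")
  }
  for (assoc in associations) {
    if (!(assoc$drug_name %in% names(drug_exposure_probs))) {
      stop(sprintf("association drug '%s' is not in 'drug_exposure_probs'", assoc$drug_name))
    }
    if (!(assoc$event_set_name %in% set_names)) {
      stop(sprintf("association event set '%s' is not in 'event_term_sets'", assoc$event_set_name))
    }
  }
  structure(list(n_cases = n_cases, female_fraction = female_fraction,
                 drug_exposure_probs = drug_exposure_probs,
                 event_term_sets = event_term_sets,
                 associations = associations,
                 duplicate_rate = duplicate_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic report database
#'
#' Draws `n_cases` base cases under the configured generative model, then
#' injects duplicate re-reports at `duplicate_rate`. Reproducible: the same
#' config (including seed) yields byte-identical output.
#'
#' @param config A [synthetic_config()].
#' @return A `jader_db` object: list of raw `demo`, `drugs`, `events` data
#'   frames (demo may contain repeated case ids when duplicates were
#'   injected), with the ground truth attached as attribute `ground_truth`.
#' @seealso [as_report_cases()] to deduplicate and assemble the result,
#'   [write_jader_tables()] to serialize it.
#' @export
generate_cases <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_cases
    ids <- sprintf("C%08d", seq_len(n))
    demo <- data.frame(
      case_id = ids,
      report_sequence = 1L,
      sex = ifelse(stats::rbinom(n, 1L, config$female_fraction) == 1L,
                   "female", "male"),
      quarter = sample(quarter_labels(), n, replace = TRUE),
      stringsAsFactors = FALSE)

    drug_names <- names(config$drug_exposure_probs)
    exposed <- matrix(FALSE, n, length(drug_names),
                      dimnames = list(NULL, drug_names))
    for (dn in drug_names) {
      exposed[, dn] <- stats::rbinom(n, 1L, config$drug_exposure_probs[[dn]]) == 1L
    }
    drugs <- data.frame(case_id = character(0), drug_name = character(0),
                        participation = character(0), stringsAsFactors = FALSE)
    for (dn in drug_names) {
      idx <- which(exposed[, dn])
      if (length(idx)) {
        drugs <- rbind(drugs, data.frame(case_id = ids[idx], drug_name = dn,
                                         participation = "suspected",
                                         stringsAsFactors = FALSE))
      }
    }

    set_by_name <- stats::setNames(config$event_term_sets,
                                   vapply(config$event_term_sets, `[[`, "", "name"))
    events <- data.frame(case_id = character(0), pt_name = character(0),
                         pt_code = character(0), stringsAsFactors = FALSE)
    truth <- list()
    for (assoc in config$associations) {
      p <- ifelse(exposed[, assoc$drug_name], assoc$p1, assoc$baseline_event_prob)
      hit <- which(stats::rbinom(n, 1L, p) == 1L)
      if (length(hit)) {
        pt <- set_by_name[[assoc$event_set_name]]$pt
        pick <- sample.int(nrow(pt), length(hit), replace = TRUE)
        events <- rbind(events, data.frame(case_id = ids[hit],
                                           pt_name = pt$pt_name[pick],
                                           pt_code = pt$pt_code[pick],
                                           stringsAsFactors = FALSE))
      }
      truth[[length(truth) + 1L]] <- list(
        drug_name = assoc$drug_name, event_set_name = assoc$event_set_name,
        true_odds_ratio = assoc$true_odds_ratio,
        baseline_event_prob = assoc$baseline_event_prob, p1 = assoc$p1,
        n_exposed = sum(exposed[, assoc$drug_name]), n_event = length(hit))
    }

    db <- structure(list(demo = demo, drugs = drugs, events = events),
                    class = "jader_db",
                    ground_truth = list(
                      n_cases = n,
                      female_fraction = config$female_fraction,
                      drug_exposure_probs = as.list(config$drug_exposure_probs),
                      duplicate_rate = config$duplicate_rate,
                      seed = config$seed,
                      associations = truth))
    if (config$duplicate_rate > 0) {
      db <- inject_duplicates(db, config$duplicate_rate, config$seed + 1L)
    }
    db
  })
}

#' Inject duplicate case re-reports
#'
#' Marks a `rate` fraction of cases (exact count, `round(rate * n)`) as
#' re-reported: their DEMO row appears a second time with `report_sequence`
#' incremented and otherwise identical content. DRUG/REAC rows are keyed by
#' case id and shared between the reports, mirroring how a re-report carries
#' the same mentions. [deduplicate()] must undo this exactly.
#'
#' @param db A `jader_db` (or any list with a `demo` data frame).
#' @param rate Fraction of cases to duplicate, in \[0,1\].
#' @param seed Integer seed for the sampling of which cases re-report.
#' @return The `jader_db` with duplicated DEMO rows appended.
#' @export
inject_duplicates <- function(db, rate, seed = 1L) {
  check_prob(rate, "rate")
  demo <- db$demo
  if (rate == 0 || nrow(demo) == 0) return(db)
  n_dup <- round(rate * nrow(demo))
  if (n_dup == 0) return(db)
  idx <- with_seed(seed, sort(sample.int(nrow(demo), n_dup)))
  dup <- demo[idx, , drop = FALSE]
  dup$report_sequence <- dup$report_sequence + 1L
  demo <- rbind(demo, dup)
  rownames(demo) <- NULL
  db$demo <- demo
  db
}

#' Deduplicate and assemble a raw synthetic database
#'
#' @param db A `jader_db` from [generate_cases()].
#' @return A `report_cases` object (see [assemble_cases()]).
#' @export
as_report_cases <- function(db) {
  assemble_cases(deduplicate(db$demo), db$drugs, db$events)
}

#' Construct female cases that recount to an exact 2x2 table
#'
#' Builds `a+b+c+d` deduplicated female cases so that
#' [build_table()] on them returns exactly `(a, b, c, d)`: `a` cases with a
#' suspected mention of the drug and a member PT of the event set, `b` with
#' the drug only, `c` with the event only, `d` with neither. This is the
#' exact-margin path for reproducing published screen rows.
#'
#' @param a,b,c,d Nonnegative cell counts (drug&event, drug only, event only,
#'   neither).
#' @param drug_name Drug label for the exposed cases.
#' @param event_set A [term_set()]; event cases report its first PT.
#' @return A `report_cases` object of `a+b+c+d` cases.
#' @export
generate_from_counts <- function(a, b, c, d, drug_name = "drug_x",
                                 event_set = term_set("event_y", "Event Y")) {
  a <- check_count(a, "a"); b <- check_count(b, "b")
  c <- check_count(c, "c"); d <- check_count(d, "d")
  stopifnot(inherits(event_set, "term_set"))
  n <- a + b + c + d
  ids <- sprintf("Q%08d", seq_len(max(n, 1L)))[seq_len(n)]
  demo <- data.frame(case_id = ids, report_sequence = 1L, sex = "female",
                     quarter = "2010Q1", stringsAsFactors = FALSE)
  drug_ids <- ids[seq_len(a + b)]                      # first a+b exposed
  event_ids <- ids[c(seq_len(a), a + b + seq_len(c))]  # a exposed + c unexposed
  drugs <- data.frame(case_id = drug_ids,
                      drug_name = rep(drug_name, length(drug_ids)),
                      participation = rep("suspected", length(drug_ids)),
                      stringsAsFactors = FALSE)
  events <- data.frame(case_id = event_ids,
                       pt_name = rep(event_set$pt$pt_name[1], length(event_ids)),
                       pt_code = rep(event_set$pt$pt_code[1], length(event_ids)),
                       stringsAsFactors = FALSE)
  assemble_cases(demo, drugs, events)
}

#' Write a database as four JADER-dialect csv tables
#'
#' Writes `DEMO.csv`, `DRUG.csv`, `REAC.csv` and an empty-bodied `HIST.csv`
#' under `dir`, using the headers and vocabularies of `column_map`, so that
#' [read_jader()] with the same map reproduces the cases exactly. When the
#' database carries generator ground truth it is recorded in a sidecar
#' `ground_truth.json`.
#'
#' @param db A `jader_db` or `report_cases` object.
#' @param dir Output directory (created if needed).
#' @inheritParams read_jader_table
#' @return Invisibly, the named vector of file paths written.
#' @export
write_jader_tables <- function(db, dir, column_map = jader_column_map(),
                               encoding = "UTF-8") {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    stop(sprintf("cannot create output directory '%s'", dir))
  }
  unmap <- function(x, levels) unname(levels[x])
  demo <- db$demo; drugs <- db$drugs; events <- db$events
  demo$sex <- unmap(demo$sex, column_map$sex_levels)
  drugs$participation <- unmap(drugs$participation, column_map$participation_levels)
  rename <- function(df, map) { names(df) <- unname(map[names(df)]); df }
  paths <- c(DEMO = file.path(dir, "DEMO.csv"), DRUG = file.path(dir, "DRUG.csv"),
             REAC = file.path(dir, "REAC.csv"), HIST = file.path(dir, "HIST.csv"))
  utils::write.csv(rename(demo, column_map$demo), paths[["DEMO"]],
                   row.names = FALSE, fileEncoding = encoding, na = "")
  utils::write.csv(rename(drugs, column_map$drug), paths[["DRUG"]],
                   row.names = FALSE, fileEncoding = encoding, na = "")
  utils::write.csv(rename(events, column_map$reac), paths[["REAC"]],
                   row.names = FALSE, fileEncoding = encoding, na = "")
  hist <- data.frame(case_id = character(0), disease = character(0))
  names(hist)[1] <- unname(column_map$demo[["case_id"]])
  utils::write.csv(hist, paths[["HIST"]], row.names = FALSE, fileEncoding = encoding)
  gt <- attr(db, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(paths)
}

#' @export
print.jader_db <- function(x, ...) {
  cat(sprintf("<jader_db> %d DEMO row(s) (%d distinct case(s)), %d DRUG, %d REAC\n",
              nrow(x$demo), length(unique(x$demo$case_id)),
              nrow(x$drugs), nrow(x$events)))
  invisible(x)
}
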