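# End-to-end orchestration: simulate or read a database, filter the cohort,
# tabulate every (drug, event set) pair, score, and write the screen plus a
# run log. The inst/cli/pvscreen script is a thin shell wrapper over this.

#' Run a full disproportionality screen
#'
#' `config` is a list (or path to a YAML/JSON file holding one) with exactly
#' one of:
#' \describe{
#'   \item{`input`}{list of file paths `demo`, `drug`, `reac` (optional
#'     `hist`, `encoding`, `pmda_columns = TRUE` to use the public-release
#'     headers) -- read mode;}
#'   \item{`simulate`}{list of [synthetic_config()] arguments, with
#'     `event_term_sets` given as packaged set names or files and
#'     `associations` as lists of [association_spec()] arguments -- simulate
#'     mode;}
#'   \item{`reconstruct`}{list with `rows` (packaged published-table name or
#'     file) and optional `event_marginal`, `tolerance` -- reconstruction
#'     mode.}
#' }
#' Optional entries: `cohort` (arguments of [cohort_filter()]), `drugs`
#' (character vector or one-column file of drug labels; default: the drugs
#' mentioned in the data), `event_sets` (packaged names or files; default
#' `"benign_and_malignant_breast_neoplasms"` and `"hyperprolactinaemia"`),
#' `priors`, `criteria`, `ci_method`, `seed`, `out` (output directory).
#'
#' Writes `screen.tsv` and `run_log.json` (per-stage row counts, dedup
#' summary, cohort size, timings) under `out` when given. Deterministic for
#' a fixed config and seed.
#'
#' @param config List or path to a YAML/JSON run configuration.
#' @return The `signal_screen` data frame, invisibly when `out` is set.
#' @export
run_screen <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file '%s' does not exist", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  modes <- c("input", "simulate", "reconstruct")
  present <- modes[modes %in% names(config)]
  if (length(present) != 1L) {
    stop("config must contain exactly one of 'input', 'simulate', 'reconstruct'")
  }
  log <- list(mode = present, started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  t0 <- proc.time()[["elapsed"]]
  seed <- as.integer(config$seed %||% 1L)

  criteria <- do.call(signal_criteria, as.list(config$criteria %||% list()))
  priors <- do.call(bcpnn_priors, as.list(config$priors %||% list()))
  ci_method <- config$ci_method %||% "delta"

  if (present == "reconstruct") {
    rows <- published_table(config$reconstruct$rows)
    screen <- reconstruct_table(rows, priors = priors, criteria = criteria,
                                ci_method = ci_method,
                                event_marginal = config$reconstruct$event_marginal,
                                tolerance = config$reconstruct$tolerance %||% 0.05)
    log$n_published_rows <- nrow(rows)
    log$n_scored_rows <- nrow(screen)
    log$event_marginal <- attr(screen, "event_marginal")
  } else {
    if (present == "simulate") {
      sim <- config$simulate
      sets <- lapply(sim$event_term_sets %||% list(), function(s) {
        if (inherits(s, "term_set")) s else load_term_set(s)
      })
      assoc <- lapply(sim$associations %||% list(), function(a) {
        if (inherits(a, "association_spec")) a else do.call(association_spec, a)
      })
      probs <- unlist(sim$drug_exposure_probs)
      cfg <- synthetic_config(
        n_cases = sim$n_cases,
        drug_exposure_probs = probs,
        female_fraction = sim$female_fraction %||% 0.55,
        event_term_sets = sets, associations = assoc,
        duplicate_rate = sim$duplicate_rate %||% 0,
        seed = sim$seed %||% seed)
      db <- generate_cases(cfg)
      log$n_demo_rows <- nrow(db$demo)
    } else {
      inp <- config$input
      for (f in c("demo", "drug", "reac")) {
        if (is.null(inp[[f]])) stop(sprintf("input mode requires path '%s'", f))
        if (!file.exists(inp[[f]])) stop(sprintf("input file '%s' does not exist", inp[[f]]))
      }
      cmap <- if (isTRUE(inp$pmda_columns)) jader_pmda_column_map() else jader_column_map()
      db <- list(
        demo = read_jader_table(inp$demo, "DEMO", cmap, inp$encoding %||% "UTF-8"),
        drugs = read_jader_table(inp$drug, "DRUG", cmap, inp$encoding %||% "UTF-8"),
        events = read_jader_table(inp$reac, "REAC", cmap, inp$encoding %||% "UTF-8"))
      log$n_demo_rows <- nrow(db$demo)
    }
    demo_dedup <- deduplicate(db$demo)
    log$n_cases_after_dedup <- nrow(demo_dedup)
    log$n_duplicate_rows_removed <- log$n_demo_rows - nrow(demo_dedup)
    cases <- assemble_cases(demo_dedup, db$drugs, db$events)
    log$n_orphan_rows_dropped <- as.list(attr(cases, "dropped"))

    cohort_args <- as.list(config$cohort %||% list())
    cohort <- filter_cases(cases, do.call(cohort_filter, cohort_args))
    log$cohort_size <- nrow(cohort$demo)

    drugs <- config$drugs %||% sort(unique(cohort$drugs$drug_name))
    if (is.character(drugs) && length(drugs) == 1L && file.exists(drugs)) {
      drugs <- utils::read.delim(drugs, stringsAsFactors = FALSE)[[1]]
    }
    set_names <- config$event_sets %||%
      c("benign_and_malignant_breast_neoplasms", "hyperprolactinaemia")
    sets <- lapply(set_names, function(s) if (inherits(s, "term_set")) s else load_term_set(s))
    if (length(drugs) == 0) stop("no drugs to screen: the cohort has no drug mentions")
    tables <- build_all(cohort, drugs, sets)
    log$n_tables <- nrow(tables)
    screen <- with_seed(seed, screen_signals(tables, priors = priors,
                                             criteria = criteria,
                                             ci_method = ci_method))
  }
  log$elapsed_seconds <- round(proc.time()[["elapsed"]] - t0, 3)
  log$n_signals <- list(ror = sum(screen$ror_signal), prr = sum(screen$prr_signal),
                        ic = sum(screen$ic_signal))

  out_dir <- config$out
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
      stop(sprintf("cannot create output directory '%s'", out_dir))
    }
    write_screen(screen, file.path(out_dir, "screen.tsv"))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(screen))
  }
  screen
}
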