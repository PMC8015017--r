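# Shared builders and the independent counting oracle.

toy_set <- function(name = "event_y", n_pt = 1) {
  term_set(name, sprintf("%s pt %d", name, seq_len(n_pt)),
           sprintf("9%07d", seq_len(n_pt) + match(name, c("event_y", "event_z"), nomatch = 3) * 100))
}

toy_config <- function(n_cases = 1000, duplicate_rate = 0, seed = 42,
                       or_x = 4, or_z = 1, p0 = 0.05, exposure = 0.05) {
  synthetic_config(
    n_cases = n_cases,
    drug_exposure_probs = c(drug_x = exposure, drug_z = exposure),
    female_fraction = 0.55,
    event_term_sets = list(toy_set("event_y", 3), toy_set("event_z", 2)),
    associations = list(
      association_spec("drug_x", "event_y", or_x, p0),
      association_spec("drug_z", "event_z", or_z, p0)),
    duplicate_rate = duplicate_rate, seed = seed)
}

# Brute-force recount: loops over cases and uses per-case set algebra only,
# independent of the vectorized counting path it cross-checks.
oracle_table <- function(cases, drug_name, event_set) {
  norm <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))
  set_codes <- event_set$pt$pt_code[!is.na(event_set$pt$pt_code)]
  set_names <- norm(event_set$pt$pt_name)
  counts <- c(a = 0L, b = 0L, c = 0L, d = 0L)
  for (id in cases$demo$case_id) {
    dr <- cases$drugs[cases$drugs$case_id == id, , drop = FALSE]
    ev <- cases$events[cases$events$case_id == id, , drop = FALSE]
    exposed <- any(norm(dr$drug_name) == norm(drug_name))
    coded <- !is.na(ev$pt_code) & nzchar(ev$pt_code)
    event <- any(ev$pt_code[coded] %in% set_codes) ||
      any(norm(ev$pt_name[!coded]) %in% set_names)
    cell <- if (exposed && event) "a" else if (exposed) "b" else if (event) "c" else "d"
    counts[cell] <- counts[cell] + 1L
  }
  counts
}

cells_of <- function(tab) c(tab$a, tab$b, tab$c, tab$d)

# absolute-tolerance comparison (expect_equal's tolerance is relative)
expect_within <- function(actual, expected, tol, what) {
  testthat::expect_true(
    is.finite(actual) && abs(actual - expected) < tol,
    info = sprintf("%s: got %.4f, published %.4f (tol %.3f)",
                   what, actual, expected, tol))
}
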