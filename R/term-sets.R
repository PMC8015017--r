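# Composite adverse-event definitions: named sets of MedDRA preferred terms.

#' Create a composite event term set
#'
#' A term set names a composite adverse event as a set of MedDRA preferred
#' terms (PTs). A case is counted as reporting the composite event when any
#' of its reported PTs belongs to the set; it counts once no matter how many
#' member PTs it reports.
#'
#' @param name Label for the composite event (used in screen output).
#' @param pt_name Character vector of preferred-term names.
#' @param pt_code Optional vector of 8-digit MedDRA PT codes, parallel to
#'   `pt_name`. Matching prefers codes when both sides carry one.
#' @return An object of class `term_set` with elements `name` and `pt`
#'   (a data frame with columns `pt_name`, `pt_code`).
#' @examples
#' hp <- term_set("hyperprolactinaemia", "Hyperprolactinaemia", "10020870")
#' @export
term_set <- function(name, pt_name, pt_code = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  pt_name <- as.character(pt_name)
  if (length(pt_name) == 0) stop("a term set must contain at least one preferred term")
  if (is.null(pt_code)) pt_code <- rep(NA_character_, length(pt_name))
  pt_code <- as.character(pt_code)
  pt_code[!is.na(pt_code) & !nzchar(trimws(pt_code))] <- NA_character_
  if (length(pt_code) != length(pt_name)) {
    stop("'pt_code' must be parallel to 'pt_name'")
  }
  keep <- !duplicated(ifelse(is.na(pt_code), paste0("name:", normalize_label(pt_name)),
                             paste0("code:", trimws(pt_code))))
  if (any(!keep)) {
    warning(sprintf("term set '%s': %d duplicated entr%s collapsed", name,
                    sum(!keep), if (sum(!keep) == 1) "y" else "ies"))
  }
  structure(
    list(name = name,
         pt = data.frame(pt_name = pt_name[keep], pt_code = trimws(pt_code)[keep],
                         stringsAsFactors = FALSE)),
    class = "term_set")
}

#' Load a packaged or user-supplied event term set
#'
#' Packaged sets: `"benign_and_malignant_breast_neoplasms"` (the 60 PTs of
#' the MedDRA high level term grouping breast neoplasms, benign and
#' malignant) and `"hyperprolactinaemia"` (a single PT). Any other `source`
#' is taken as a path to a two-column delimited text file with a header row
#' `pt_name<TAB>pt_code` (`pt_code` may be empty).
#'
#' @param source Packaged set name or path to a term-set file.
#' @return A [term_set()].
#' @examples
#' breast <- load_term_set("benign_and_malignant_breast_neoplasms")
#' nrow(breast$pt)  # 60
#' @export
load_term_set <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  packaged <- system.file("extdata", paste0(source, ".tsv"), package = "pvscreen")
  path <- if (nzchar(packaged)) packaged else source
  if (!file.exists(path)) {
    stop(sprintf("term set '%s' is neither a packaged set nor an existing file", source))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 2) stop(sprintf("term-set file '%s' has no entries", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1]])
  if (!all(c("pt_name", "pt_code") %in% header)) {
    stop(sprintf("term-set file '%s': header must contain pt_name and pt_code", path))
  }
  i_name <- match("pt_name", header); i_code <- match("pt_code", header)
  bad <- which(lengths(fields[-1]) < i_name) + 1L
  if (length(bad)) {
    stop(sprintf("term-set file '%s': malformed line %d", path, bad[1]))
  }
  nm <- vapply(fields[-1], `[`, "", i_name)
  cd <- vapply(fields[-1], function(f) if (length(f) >= i_code) f[i_code] else "", "")
  cd[!nzchar(trimws(cd))] <- NA_character_
  set_name <- if (nzchar(packaged)) source else sub("\\.[^.]*$", "", basename(path))
  term_set(set_name, nm, cd)
}

#' @export
print.term_set <- function(x, ...) {
  cat(sprintf("<term_set> %s: %d preferred term%s\n", x$name, nrow(x$pt),
              if (nrow(x$pt) == 1) "" else "s"))
  invisible(x)
}

# Logical: does each case report at least one PT of the set?  Matching uses
# the PT code when both the report and the set entry carry one, otherwise the
# width/case-normalized PT name. Returns a vector aligned with cases$demo.
#' Composite-event indicator per case
#'
#' @param cases A `report_cases` object (see [assemble_cases()]).
#' @param set A [term_set()].
#' @return Named logical vector (names are case ids, order of `cases$demo`);
#'   `TRUE` when the case reports any member PT. Multiple matching PTs in one
#'   case still count once.
#' @export
case_has_event <- function(cases, set) {
  stopifnot(inherits(cases, "report_cases"), inherits(set, "term_set"))
  ev <- cases$events
  has_code <- !is.na(set$pt$pt_code)
  set_codes <- set$pt$pt_code[has_code]
  set_names_all <- normalize_label(set$pt$pt_name)
  set_names_codeless <- set_names_all[!has_code]
  ev_coded <- !is.na(ev$pt_code) & nzchar(ev$pt_code)
  by_code <- ev_coded & ev$pt_code %in% set_codes
  # name matching applies where the code-vs-code rule cannot: uncoded report
  # PTs match any entry name; coded report PTs match only uncoded entries
  ev_names <- normalize_label(ev$pt_name)
  by_name <- (!ev_coded & ev_names %in% set_names_all) |
    (ev_coded & !by_code & ev_names %in% set_names_codeless)
  hit_ids <- unique(ev$case_id[by_code | by_name])
  out <- cases$demo$case_id %in% hit_ids
  names(out) <- cases$demo$case_id
  out
}
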