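# Reading JADER-dialect extracts: four delimited-text tables keyed by case id
# (DEMO demographics, DRUG mentions, REAC adverse events, HIST history --
# HIST is accepted and ignored), followed by case deduplication and assembly
# into one joined record per case.

#' Column and vocabulary map for JADER-dialect tables
#'
#' Maps the canonical field names used throughout the package to the column
#' headers found in the files, and enumerated file values to the canonical
#' vocabularies (`sex`: female/male/unknown; `participation`:
#' suspected/concomitant/interacting). The default matches the headers the
#' packaged writer emits; [jader_pmda_column_map()] matches the Japanese
#' headers of the public PMDA distribution.
#'
#' @param demo,drug,reac Named character vectors mapping canonical names
#'   (`case_id`, `report_sequence`, `sex`, `quarter`; `drug_name`,
#'   `participation`; `pt_name`, `pt_code`) to file column headers.
#' @param sex_levels,participation_levels Named character vectors mapping
#'   canonical vocabulary values to the strings used in the files.
#' @return A list of class `jader_column_map`.
#' @export
jader_column_map <- function(demo = c(case_id = "case_id",
                                      report_sequence = "report_sequence",
                                      sex = "sex", quarter = "quarter"),
                             drug = c(case_id = "case_id",
                                      drug_name = "drug_name",
                                      participation = "participation"),
                             reac = c(case_id = "case_id",
                                      pt_name = "pt_name", pt_code = "pt_code"),
                             sex_levels = c(female = "female", male = "male",
                                            unknown = "unknown"),
                             participation_levels = c(suspected = "suspected",
                                                      concomitant = "concomitant",
                                                      interacting = "interacting")) {
  structure(list(demo = demo, drug = drug, reac = reac,
                 sex_levels = sex_levels,
                 participation_levels = participation_levels),
            class = "jader_column_map")
}

#' @rdname jader_column_map
#' @export
jader_pmda_column_map <- function() {
  # Headers and vocabularies of the quarterly PMDA csv release.
  jader_column_map(
    demo = c(case_id = "識別番号",          # identification number
             report_sequence = "報告回数",  # report count
             sex = "性別",                          # sex
             quarter = "報告年度・四半期"),
    drug = c(case_id = "識別番号",
             drug_name = "医薬品（一般名）",
             participation = "医薬品の関与"),
    reac = c(case_id = "識別番号",
             pt_name = "有害事象",
             pt_code = "MedDRA PTコード"),
    sex_levels = c(female = "女性", male = "男性",
                   unknown = "不明"),
    participation_levels = c(suspected = "被疑薬",
                             concomitant = "併用薬",
                             interacting = "相互作用"))
}

.map_vocab <- function(x, levels, field, table) {
  idx <- match(x, levels)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf(
      "%s: value '%s' in column '%s' (row %d) is outside the configured vocabulary {%s}",
      table, x[bad], field, bad, paste(levels, collapse = ", ")), call. = FALSE)
  }
  names(levels)[idx]
}

#' Read one JADER-dialect table
#'
#' Parses a delimited-text table (comma-separated, header row) into canonical
#' records. Enumerated columns (`sex`, `participation`) are validated against
#' the map's vocabulary; a value outside it is an error naming the value and
#' row. `HIST` is read and returned as-is (the screen does not use it).
#'
#' @param path File path.
#' @param kind One of `"DEMO"`, `"DRUG"`, `"REAC"`, `"HIST"`.
#' @param column_map A [jader_column_map()].
#' @param encoding File encoding (the public files are not UTF-8; pass e.g.
#'   `"CP932"` for them).
#' @return A data frame of canonical records for the table kind.
#' @export
read_jader_table <- function(path, kind = c("DEMO", "DRUG", "REAC", "HIST"),
                             column_map = jader_column_map(),
                             encoding = "UTF-8") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("input file '%s' does not exist", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = encoding)
  if (kind == "HIST") return(raw)
  wanted <- column_map[[tolower(kind)]]
  required <- wanted[setdiff(names(wanted), "pt_code")]
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop(sprintf("%s file '%s' is missing required column(s): %s",
                 kind, path, paste(missing, collapse = ", ")))
  }
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    lapply(wanted, function(col) {
                      if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
                    }))
  names(out) <- names(wanted)
  if (kind == "DEMO") {
    out$report_sequence <- suppressWarnings(as.integer(out$report_sequence))
    if (anyNA(out$report_sequence) && nrow(out)) {
      stop(sprintf("DEMO file '%s': non-integer report_sequence at row %d",
                   path, which(is.na(out$report_sequence))[1]))
    }
    if (nrow(out)) out$sex <- .map_vocab(out$sex, column_map$sex_levels, "sex", "DEMO")
    if (any(!nzchar(out$case_id))) {
      stop(sprintf("DEMO file '%s': empty case_id at row %d",
                   path, which(!nzchar(out$case_id))[1]))
    }
  } else if (kind == "DRUG") {
    if (nrow(out)) {
      out$participation <- .map_vocab(out$participation,
                                      column_map$participation_levels,
                                      "participation", "DRUG")
    }
    if (any(!nzchar(trimws(out$drug_name)))) {
      stop(sprintf("DRUG file '%s': empty drug_name at row %d",
                   path, which(!nzchar(trimws(out$drug_name)))[1]))
    }
  } else if (kind == "REAC") {
    out$pt_code[!is.na(out$pt_code) & !nzchar(trimws(out$pt_code))] <- NA_character_
    blank <- !nzchar(trimws(out$pt_name)) & is.na(out$pt_code)
    if (any(blank)) {
      stop(sprintf("REAC file '%s': row %d has neither pt_name nor pt_code",
                   path, which(blank)[1]))
    }
  }
  out
}

#' Deduplicate case reports
#'
#' Spontaneous-report databases carry re-reports of the same case under the
#' same case id with an incremented report sequence. For each case id exactly
#' the record with the highest `report_sequence` is retained (the latest
#' report supersedes earlier ones); ties keep the last occurrence.
#'
#' @param demo A DEMO data frame (see [read_jader_table()]).
#' @return The deduplicated DEMO data frame, one row per case id, input order
#'   of first appearance preserved. Idempotent.
#' @export
deduplicate <- function(demo) {
  stopifnot(is.data.frame(demo), all(c("case_id", "report_sequence") %in% names(demo)))
  if (nrow(demo) == 0) return(demo)
  ord <- order(match(demo$case_id, unique(demo$case_id)),
               demo$report_sequence, seq_len(nrow(demo)))
  demo <- demo[ord, , drop = FALSE]
  keep <- !duplicated(demo$case_id, fromLast = TRUE)
  out <- demo[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble joined per-case records
#'
#' Joins the three tables on case id into one `report_cases` object: the
#' deduplicated demographics plus each case's drug mentions and event PTs as
#' sets (repeated identical mentions collapse). DRUG/REAC rows whose case id
#' is absent from the deduplicated DEMO are dropped and counted in a message.
#'
#' @param demo Deduplicated DEMO data frame ([deduplicate()]).
#' @param drug DRUG data frame.
#' @param reac REAC data frame.
#' @return An object of class `report_cases`: a list with data frames `demo`
#'   (one row per case), `drugs` (`case_id`, `drug_name`, `participation`)
#'   and `events` (`case_id`, `pt_name`, `pt_code`), plus a `dropped`
#'   attribute with the orphan-row counts.
#' @export
assemble_cases <- function(demo, drug, reac) {
  if (anyDuplicated(demo$case_id)) {
    stop("'demo' contains duplicated case ids; run deduplicate() first")
  }
  drug <- unique(drug[, c("case_id", "drug_name", "participation")])
  reac <- unique(reac[, c("case_id", "pt_name", "pt_code")])
  orphan_drug <- !(drug$case_id %in% demo$case_id)
  orphan_reac <- !(reac$case_id %in% demo$case_id)
  if (any(orphan_drug) || any(orphan_reac)) {
    message(sprintf("assemble_cases: dropped %d DRUG and %d REAC row(s) with case ids absent from DEMO",
                    sum(orphan_drug), sum(orphan_reac)))
  }
  drug <- drug[!orphan_drug, , drop = FALSE]
  reac <- reac[!orphan_reac, , drop = FALSE]
  # canonical row order makes assembly independent of input row order
  demo <- demo[order(demo$case_id), , drop = FALSE]
  drug <- drug[order(drug$case_id, drug$drug_name, drug$participation), , drop = FALSE]
  reac <- reac[order(reac$case_id, reac$pt_name, reac$pt_code,
                     na.last = TRUE, method = "radix"), , drop = FALSE]
  rownames(demo) <- rownames(drug) <- rownames(reac) <- NULL
  structure(list(demo = demo, drugs = drug, events = reac),
            dropped = c(drug = sum(orphan_drug), reac = sum(orphan_reac)),
            class = "report_cases")
}

#' Read, deduplicate and assemble a JADER-dialect extract
#'
#' Convenience wrapper: [read_jader_table()] on the three (or four) files,
#' [deduplicate()] on DEMO, then [assemble_cases()].
#'
#' @param demo,drug,reac,hist File paths (`hist` optional, read and ignored).
#' @inheritParams read_jader_table
#' @return A `report_cases` object.
#' @export
read_jader <- function(demo, drug, reac, hist = NULL,
                       column_map = jader_column_map(), encoding = "UTF-8") {
  d <- read_jader_table(demo, "DEMO", column_map, encoding)
  g <- read_jader_table(drug, "DRUG", column_map, encoding)
  r <- read_jader_table(reac, "REAC", column_map, encoding)
  if (!is.null(hist)) read_jader_table(hist, "HIST", column_map, encoding)
  assemble_cases(deduplicate(d), g, r)
}

#' @export
print.report_cases <- function(x, ...) {
  cat(sprintf("<report_cases> %d case(s), %d drug mention(s), %d event PT(s)\n",
              nrow(x$demo), nrow(x$drugs), nrow(x$events)))
  tab <- table(x$demo$sex)
  cat("  sex:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
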