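# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream. Used by every generator so fixed-seed runs are byte-identical no
# matter what the session did before.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Trim, collapse internal runs of whitespace, fold full-width ASCII
# (U+FF01..U+FF5E) and ideographic space to their half-width forms, and
# lowercase. JADER drug and term strings mix widths; matching is exact after
# this normalization.
normalize_label <- function(x) {
  fw <- intToUtf8(c(0x3000L, 0xFF01:0xFF5E), multiple = FALSE)
  hw <- intToUtf8(c(0x20L, 0x21:0x7E), multiple = FALSE)
  x <- chartr(fw, hw, as.character(x))
  x <- gsub("[[:space:]]+", " ", trimws(x))
  tolower(x)
}

check_prob <- function(x, field, allow_zero = TRUE, allow_one = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (length(x) == 0 || anyNA(x) || !all(is.finite(x) & lo_ok & hi_ok)) {
    stop(sprintf("'%s' must be a probability in %s0,1%s",
                 field, if (allow_zero) "[" else "(",
                 if (allow_one) "]" else ")"), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, field, positive = FALSE) {
  ok <- length(x) >= 1 && !anyNA(x) && all(is.finite(x)) &&
    all(x == trunc(x)) && all(x >= if (positive) 1 else 0)
  if (!ok) {
    stop(sprintf("'%s' must be %s integer count%s", field,
                 if (positive) "a positive" else "a nonnegative",
                 if (length(x) > 1) "s" else ""), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Quarter labels of the form "2004Q2"; lexicographic order equals
# chronological order for four-digit years, which range checks rely on.
quarter_labels <- function(from = "2004Q2", to = "2019Q1") {
  grid <- as.vector(t(outer(2004:2030, 1:4, function(y, q) sprintf("%04dQ%d", y, q))))
  grid[grid >= from & grid <= to]
}
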