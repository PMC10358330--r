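# Small internal helpers.

# Classed error so callers/tests can distinguish failure modes.
abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "dietimpact_error")))
}

# Assert that `df` carries the named columns; schema error otherwise.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          "dietimpact_schema_error")
  }
  invisible(df)
}

# Assert that values lie in a closed vocabulary.
check_vocab <- function(x, vocab, what) {
  bad <- setdiff(unique(x[!is.na(x)]), vocab)
  if (length(bad) > 0L) {
    abort(sprintf("%s contains value(s) outside the allowed vocabulary: %s",
                  what, paste(bad, collapse = ", ")),
          "dietimpact_vocabulary_error")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tucker's coefficient of congruence between two loading/signature vectors.
#' Tucker congruence between two vectors
#'
#' \eqn{\phi(x, y) = \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}}; a scale-free
#' measure of shape agreement used to match fitted pattern loadings to
#' planted generator signatures.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A scalar in \[-1, 1\].
#' @export
tucker_congruence <- function(x, y) {
  stopifnot(length(x) == length(y))
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}
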