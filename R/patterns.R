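# Dietary-pattern derivation: PCA on the correlation matrix of the 18
# food-group intakes. Correlation (not covariance) input because group
# intakes differ by orders of magnitude (rice ~365 g/day vs oils ~5
# g/day); covariance PCA would be dominated by the staple. Loadings are
# variable-component correlations (eigenvector x sqrt(eigenvalue)); the
# sign of each component is fixed so its largest-|loading| entry is
# positive, which makes output deterministic across linear-algebra
# backends.

#' Fit dietary patterns by principal component analysis
#'
#' @param group_intakes n x 18 numeric matrix (or data.frame) of g/day per
#'   AFE by food group; rownames (if present) are household ids. Requires
#'   n >= 180 (ten observations per input variable) and no constant
#'   column.
#' @param K Number of components to retain (default: eigenvalue > 1 rule).
#' @param rotation `"none"` (default) or `"varimax"`.
#' @return An object of class `pattern_model` with elements `loadings`
#'   (18 x K, variable-component correlations), `eigenvalues` (all 18),
#'   `explained_variance` (length K), `scores` (n x K, mean 0, unit
#'   variance), `quintile` (n x K data.frame of `Q1`..`Q5` labels),
#'   `retained_K`, `n`, `rotation`.
#' @export
fit_patterns <- function(group_intakes, K = NULL, rotation = c("none",
                                                               "varimax")) {
  rotation <- match.arg(rotation)
  X <- as.matrix(group_intakes)
  if (ncol(X) != 18L) {
    abort("group_intakes must have 18 columns (one per food group)",
          "dietimpact_parameter_error")
  }
  n <- nrow(X)
  if (n < 10L * 18L) {
    abort(sprintf(
      "need at least %d households (10 per input variable), got %d",
      180L, n), "dietimpact_parameter_error")
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    grp <- colnames(X) %||% as.character(which(sds == 0))
    abort(sprintf("constant food-group column(s): %s",
                  paste(grp[sds == 0], collapse = ", ")),
          "dietimpact_degenerate_input_error")
  }
  C <- stats::cor(X)
  eig <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  if (is.null(K)) K <- max(1L, sum(lambda > 1))
  if (K > 18L || K < 1L) {
    abort("K must lie in 1..18", "dietimpact_parameter_error")
  }
  V <- eig$vectors[, seq_len(K), drop = FALSE]
  loadings <- sweep(V, 2, sqrt(lambda[seq_len(K)]), `*`)
  Z <- scale(X)
  scores <- Z %*% sweep(V, 2, sqrt(lambda[seq_len(K)]), `/`)

  if (rotation == "varimax") {
    rot <- stats::varimax(loadings, normalize = FALSE)
    loadings <- loadings %*% rot$rotmat
    # rotated scores: re-standardise each rotated component
    scores <- scores %*% rot$rotmat
    scores <- sweep(scores, 2, apply(scores, 2, stats::sd), `/`)
  }

  # deterministic sign: largest-|loading| entry of each component positive
  for (k in seq_len(K)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(K)))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(K)))

  quint <- as.data.frame(apply(scores, 2, assign_quintiles),
                         stringsAsFactors = FALSE)
  structure(list(loadings = loadings,
                 eigenvalues = lambda,
                 # sum of squared loadings per component; equals the
                 # eigenvalue for unrotated components
                 explained_variance = colSums(loadings^2) / 18,
                 scores = scores,
                 quintile = quint,
                 retained_K = K,
                 n = n,
                 rotation = rotation),
            class = "pattern_model")
}

#' @export
print.pattern_model <- function(x, ...) {
  cat("Dietary pattern model:", x$retained_K, "components on", x$n,
      "households;", "explained variance",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' Scree / retention diagnostics
#'
#' Eigenvalue table with cumulative explained variance and first
#' differences (the elbow statistic). Retention is ultimately a user
#' decision; the suggested K counts eigenvalues above 1, and
#' `noise_margin` gives the approximate upper edge of the pure-noise
#' spectrum, \eqn{(1 + \sqrt{p/n})^2}, against which to judge whether a
#' component exceeds sampling noise.
#'
#' @param model A fitted `pattern_model`.
#' @return A list with `table` (component, eigenvalue, prop_var, cum_var,
#'   diff), `suggested_k`, `noise_margin`.
#' @export
scree_report <- function(model) {
  stopifnot(inherits(model, "pattern_model"))
  lambda <- model$eigenvalues
  tab <- data.frame(component = seq_along(lambda),
                    eigenvalue = lambda,
                    prop_var = lambda / 18,
                    cum_var = cumsum(lambda) / 18,
                    diff = c(NA, -diff(lambda)))
  list(table = tab,
       suggested_k = sum(lambda > 1),
       noise_margin = (1 + sqrt(18 / model$n))^2)
}

#' Assign adherence quintiles from component scores
#'
#' Households are ranked by score (ties broken by stable input order) and
#' cut at n/5 boundaries; `Q5` is highest adherence. Every quintile holds
#' between floor(n/5) and ceiling(n/5) households, so n = 8,225 gives
#' exactly 1,645 per quintile.
#'
#' @param scores Numeric vector of scores for one pattern.
#' @return Character vector of labels `Q1`..`Q5`.
#' @export
assign_quintiles <- function(scores) {
  n <- length(scores)
  if (n < 5L) {
    abort("need at least 5 observations to form quintiles",
          "dietimpact_parameter_error")
  }
  rnk <- integer(n)
  rnk[order(scores, seq_len(n))] <- seq_len(n)
  paste0("Q", ceiling(rnk * 5 / n))
}

#' Printable loading table
#'
#' Loadings multiplied by 100 and rounded to integers, with entries below
#' the display threshold left blank -- the conventional presentation of a
#' pattern-loading table.
#'
#' @param model A fitted `pattern_model`.
#' @param display_threshold Minimum |loading| to display (default 0.20).
#' @return Character matrix (18 x K) with display-name rownames.
#' @export
format_loading_table <- function(model, display_threshold = 0.20) {
  stopifnot(inherits(model, "pattern_model"))
  L <- model$loadings
  out <- matrix("", nrow(L), ncol(L), dimnames =
                  list(unname(pattern_group_labels()[rownames(L)]),
                       colnames(L)))
  show <- abs(L) >= display_threshold
  out[show] <- sprintf("%d", round(100 * L[show]))
  out
}

#' Match fitted components to planted signatures
#'
#' For each planted signature, finds the fitted component with the
#' largest |Tucker congruence| and reports the signed congruence after
#' sign alignment.
#'
#' @param model A fitted `pattern_model`.
#' @param signatures 18 x K matrix of planted signatures (g/day shifts).
#' @return Data.frame with `signature`, `component`, `congruence`.
#' @export
match_signatures <- function(model, signatures) {
  sig_names <- colnames(signatures) %||%
    paste0("S", seq_len(ncol(signatures)))
  rows <- lapply(seq_len(ncol(signatures)), function(k) {
    cong <- apply(model$loadings, 2, tucker_congruence, y = signatures[, k])
    j <- which.max(abs(cong))
    data.frame(signature = sig_names[k], component = colnames(model$loadings)[j],
               congruence = abs(cong[j]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
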