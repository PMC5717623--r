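# Quadratic assignment procedure (QAP) machinery: joint row/column node
# permutation, MRQAP regression with double semi-partialling, and node-level
# permutation regression.
#
# Dyadic observations are not independent: every actor appears in many
# dyads, so ordinary regression p-values are invalid on network data. QAP
# respects the dependence structure by permuting node labels (rows and
# columns jointly), which preserves each permuted matrix's internal
# structure while breaking its alignment with the outcome. The double
# semi-partialling variant residualizes each predictor matrix on the
# remaining predictors and permutes the residual matrix, which keeps the
# other predictors' association with the outcome intact under the null and
# is robust to network autocorrelation and skewness.

#' Jointly permute the rows and columns of a dyadic matrix
#'
#' Applies one node-label permutation: cell `(i, j)` of the result holds the
#' value of cell `(perm[i], perm[j])` of the input. The off-diagonal value
#' multiset is preserved and the node labels keep their original order.
#'
#' @param m a [dyad_matrix()] or plain square matrix with dimnames.
#' @param perm a permutation: either an integer vector (a rearrangement of
#'   `1:n`) or a character vector (a rearrangement of the node ids).
#' @return the permuted matrix, same class and labels as the input.
#' @export
qap_permute <- function(m, perm) {
  ids <- rownames(m)
  n <- nrow(m)
  if (is.character(perm)) {
    if (!setequal(perm, ids) || length(perm) != n) {
      stop("perm must be a bijection on the node ids", call. = FALSE)
    }
    perm <- match(perm, ids)
  }
  if (!identical(sort(as.integer(perm)), seq_len(n))) {
    stop("perm must be a bijection on the node ids", call. = FALSE)
  }
  out <- m
  out[] <- unclass(m)[perm, perm]
  out
}

# Off-diagonal cell index pairs (row, col) in a fixed order.
.offdiag_cells <- function(n) {
  idx <- which(row(diag(n)) != col(diag(n)))
  cbind(((idx - 1) %% n) + 1, ((idx - 1) %/% n) + 1)
}

.zscore <- function(v, what) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    stop(sprintf("%s is constant across the dyads used", what), call. = FALSE)
  }
  (v - mean(v)) / s
}

.new_perm_result <- function(coefficients, r_squared, p_values, n_permutations,
                             seed, n_used, method) {
  structure(list(coefficients = coefficients, r_squared = r_squared,
                 p_values = p_values, n_permutations = n_permutations,
                 seed = seed, n_dyads_used = n_used, method = method),
            class = "perm_regression")
}

#' @export
print.perm_regression <- function(x, ...) {
  cat(sprintf("<perm_regression> method: %s | n used: %d | permutations: %d | seed: %s\n",
              x$method, x$n_dyads_used, x$n_permutations, format(x$seed)))
  tab <- data.frame(beta = round(x$coefficients, 4), p = round(x$p_values, 4))
  print(tab)
  cat(sprintf("r-squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' MRQAP regression with double semi-partialling
#'
#' Regresses a dyadic outcome matrix on one or more dyadic predictor
#' matrices. Point estimates are ordinary least squares on the vectorized
#' off-diagonal dyads of the z-scored variables (so coefficients are
#' standardized betas); dyads missing in the outcome or any predictor are
#' dropped listwise. Significance is assessed per predictor by double
#' semi-partialling: predictor `k` is residualized on the remaining
#' predictors, the residuals are arranged back into a dyadic matrix, and
#' `n_perm` joint row/column node permutations of that residual matrix are
#' each refitted alongside the remaining predictors. The two-tailed p-value
#' uses the add-one convention, `p = (#{|beta*| >= |beta|} + 1) / (n_perm + 1)`,
#' so it is always positive. With a single predictor no residualization is
#' needed and the procedure reduces to QAP regression.
#'
#' @param y outcome [dyad_matrix()].
#' @param xs named list of predictor dyadic matrices over the same node set.
#' @param n_perm number of node permutations (default 2000).
#' @param seed integer seed controlling the permutation stream; recorded in
#'   the result, and results are bit-reproducible given the seed.
#' @return a `perm_regression` object: standardized `coefficients`,
#'   `r_squared`, permutation `p_values`, `n_permutations`, `seed`,
#'   `n_dyads_used`.
#' @export
mrqap_dsp <- function(y, xs, n_perm = 2000, seed = 1L) {
  if (inherits(xs, "dyad_matrix") || (is.matrix(xs) && !is.list(xs))) xs <- list(xs)
  if (is.null(names(xs)) || any(!nzchar(names(xs)))) {
    names(xs) <- paste0("x", seq_along(xs))
  }
  ids <- rownames(y)
  n <- nrow(y)
  for (nm in names(xs)) {
    if (!setequal(rownames(xs[[nm]]), ids)) {
      stop(sprintf("predictor '%s' has a different node set than the outcome", nm),
           call. = FALSE)
    }
    xs[[nm]] <- unclass(xs[[nm]])[ids, ids]
  }
  cells <- .offdiag_cells(n)
  yv_all <- unclass(y)[cells]
  xv_all <- vapply(xs, function(x) x[cells], numeric(nrow(cells)))
  complete <- !is.na(yv_all) & rowSums(is.na(xv_all)) == 0
  k <- length(xs)
  n_used <- sum(complete)
  if (n_used < k + 2) {
    stop(sprintf("only %d complete dyads for %d predictors; need at least %d",
                 n_used, k, k + 2), call. = FALSE)
  }
  yv <- .zscore(yv_all[complete], "outcome")
  X <- vapply(seq_len(k),
              function(j) .zscore(xv_all[complete, j], sprintf("predictor '%s'", names(xs)[j])),
              numeric(n_used))
  colnames(X) <- names(xs)
  if (k > 1) {
    cc <- stats::cor(X)
    for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
      if (abs(cc[a, b]) > 0.9999) {
        stop(sprintf("predictors '%s' and '%s' are collinear",
                     names(xs)[a], names(xs)[b]), call. = FALSE)
      }
    }
  }
  if (qr(X)$rank < k) stop("predictor matrix is rank deficient", call. = FALSE)
  fit <- stats::lm.fit(X, yv)
  beta <- coef(fit)
  r2 <- 1 - sum(fit$residuals^2) / sum(yv^2)
  cells_c <- cells[complete, , drop = FALSE]
  set.seed(seed)
  p_values <- numeric(k)
  for (j in seq_len(k)) {
    others <- X[, -j, drop = FALSE]
    ek <- if (ncol(others) == 0) X[, j] else stats::lm.fit(others, X[, j])$residuals
    Ek <- matrix(NA_real_, n, n)
    Ek[cells_c] <- ek
    exceed <- 0L
    valid <- 0L
    ref <- abs(beta[j]) - 1e-12
    for (p in seq_len(n_perm)) {
      pp <- sample.int(n)
      ev <- Ek[pp, pp][cells_c]
      use <- !is.na(ev)
      if (sum(use) < k + 2 || stats::sd(ev[use]) == 0) next
      D <- cbind(others[use, , drop = FALSE], ev[use])
      bstar <- stats::lm.fit(D, yv[use])$coefficients[k]
      if (is.na(bstar)) next
      valid <- valid + 1L
      if (abs(bstar) >= ref) exceed <- exceed + 1L
    }
    p_values[j] <- (exceed + 1) / (valid + 1)
  }
  names(p_values) <- names(xs)
  .new_perm_result(beta, r2, p_values, n_perm, seed, n_used, "mrqap_dsp")
}

#' Node-level permutation regression
#'
#' Regresses a per-node outcome (e.g. proximity indegree) on per-node
#' attributes (e.g. repertoire-homogeneity centrality, sex). Point estimates
#' are ordinary least squares on z-scored complete cases (standardized
#' betas); significance comes from permuting the outcome vector across nodes
#' `n_perm` times and refitting, with the same two-tailed add-one p-value
#' convention as [mrqap_dsp()].
#'
#' @param y numeric outcome vector, one value per node.
#' @param xs `data.frame` (or named list) of numeric per-node predictors.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed; recorded in the result.
#' @return a `perm_regression` object.
#' @export
node_level_regression <- function(y, xs, n_perm = 10000, seed = 1L) {
  xs <- as.data.frame(xs)
  if (is.null(names(xs)) || any(!nzchar(names(xs)))) {
    names(xs) <- paste0("x", seq_along(xs))
  }
  if (length(y) != nrow(xs)) {
    stop("outcome and predictors must cover the same nodes", call. = FALSE)
  }
  complete <- !is.na(y) & stats::complete.cases(xs)
  k <- ncol(xs)
  n_used <- sum(complete)
  if (n_used < k + 2) {
    stop(sprintf("only %d complete cases for %d predictors; need at least %d",
                 n_used, k, k + 2), call. = FALSE)
  }
  yc <- y[complete]
  if (stats::sd(yc) == 0) stop("outcome is constant", call. = FALSE)
  yv <- .zscore(yc, "outcome")
  X <- vapply(seq_len(k),
              function(j) .zscore(xs[complete, j], sprintf("predictor '%s'", names(xs)[j])),
              numeric(n_used))
  colnames(X) <- names(xs)
  if (qr(X)$rank < k) stop("predictor matrix is rank deficient", call. = FALSE)
  fit <- stats::lm.fit(X, yv)
  beta <- coef(fit)
  r2 <- 1 - sum(fit$residuals^2) / sum(yv^2)
  XtXinv_Xt <- solve(crossprod(X), t(X))
  set.seed(seed)
  exceed <- integer(k)
  ref <- abs(beta) - 1e-12
  for (p in seq_len(n_perm)) {
    bstar <- XtXinv_Xt %*% yv[sample.int(n_used)]
    exceed <- exceed + (abs(bstar[, 1]) >= ref)
  }
  p_values <- (exceed + 1) / (n_perm + 1)
  names(p_values) <- names(xs)
  .new_perm_result(beta, r2, p_values, n_perm, seed, n_used, "node_permutation")
}
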