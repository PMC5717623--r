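# Dyadic matrices and normalized degree centrality.

#' Construct a dyadic matrix from per-dyad values
#'
#' Builds a labelled square matrix with an undefined diagonal from values
#' keyed by ordered pairs of node ids. For an undirected network, values may
#' be supplied once per unordered pair and are mirrored; if both orderings
#' of a pair are supplied with different values the call errors. Dyads
#' without a supplied value stay missing.
#'
#' @param values `data.frame` with columns `id_a`, `id_b`, `value`.
#' @param directed logical flag.
#' @param ids node set; defaults to the ids occurring in `values`.
#' @return a `dyad_matrix`: a numeric matrix with a `directed` attribute and
#'   `NA` diagonal.
#' @export
build_matrix <- function(values, directed, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(values$id_a, values$id_b)))
  unknown <- setdiff(c(values$id_a, values$id_b), ids)
  if (length(unknown)) {
    stop(sprintf("unknown node id(s): %s", paste(unique(unknown), collapse = ", ")),
         call. = FALSE)
  }
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(values))) {
    i <- values$id_a[k]; j <- values$id_b[k]; v <- values$value[k]
    if (i == j) stop("dyadic values must have id_a != id_b", call. = FALSE)
    if (directed) {
      m[i, j] <- v
    } else {
      if (!is.na(m[i, j]) && !isTRUE(all.equal(m[i, j], v))) {
        stop(sprintf("asymmetric values for undirected dyad %s-%s", i, j),
             call. = FALSE)
      }
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  as_dyad_matrix(m, directed = directed)
}

#' Mark a square matrix as a dyadic network matrix
#'
#' @param m square numeric matrix with row/column dimnames; the diagonal is
#'   set to `NA` (it is never read).
#' @param directed logical flag; undirected matrices are checked for
#'   symmetry on construction.
#' @return the matrix with class `dyad_matrix` and a `directed` attribute.
#' @export
as_dyad_matrix <- function(m, directed) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m))) {
    stop("dyadic matrices need node ids as dimnames", call. = FALSE)
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column ids must agree", call. = FALSE)
  }
  storage.mode(m) <- "double"
  diag(m) <- NA_real_
  if (!directed) {
    off <- m[upper.tri(m)]
    off_t <- t(m)[upper.tri(m)]
    same <- (is.na(off) & is.na(off_t)) |
      (!is.na(off) & !is.na(off_t) & abs(off - off_t) < 1e-9)
    if (!all(same)) {
      stop("undirected dyadic matrix must be symmetric", call. = FALSE)
    }
  }
  attr(m, "directed") <- directed
  class(m) <- c("dyad_matrix", class(m))
  m
}

#' @export
print.dyad_matrix <- function(x, ...) {
  cat(sprintf("<dyad_matrix> %d nodes, %s\n", nrow(x),
              if (attr(x, "directed")) "directed" else "undirected"))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Normalized degree centrality
#'
#' The normalized degree of a node is the average tie value of its row
#' (outdegree: behaviour directed by the node to others) or column
#' (indegree: behaviour received), over the off-diagonal entries. For an
#' undirected network the single `n_degree` (row mean) is reported. Missing
#' ties are excluded from the mean by default; `zero_fill = TRUE` instead
#' counts them as zero-valued ties (dividing by `n - 1`), mimicking tools
#' that zero-fill incomplete matrices.
#'
#' @param m a [dyad_matrix()].
#' @param mode `"n_degree"` (undirected), `"outdegree"` or `"indegree"`.
#' @param zero_fill treat missing off-diagonal ties as zeros.
#' @return `data.frame` with columns `id` and `centrality`; nodes with all
#'   ties missing get `NA` (logged).
#' @export
normalized_degree <- function(m, mode = c("n_degree", "outdegree", "indegree"),
                              zero_fill = FALSE) {
  mode <- match.arg(mode)
  mm <- unclass(m)
  attr(mm, "directed") <- NULL
  diag(mm) <- NA_real_
  if (zero_fill) {
    off <- row(mm) != col(mm)
    mm[off & is.na(mm)] <- 0
  }
  vals <- if (mode == "indegree") colMeans(mm, na.rm = TRUE) else rowMeans(mm, na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  if (anyNA(vals)) {
    message(sprintf("centrality undefined for node(s) with all ties missing: %s",
                    paste(names(vals)[is.na(vals)], collapse = ", ")))
  }
  data.frame(id = rownames(mm), centrality = unname(vals), stringsAsFactors = FALSE)
}

#' Centrality table for a network
#'
#' Convenience wrapper: `n_degree` for undirected matrices, indegree and
#' outdegree side by side for directed ones.
#'
#' @param m a [dyad_matrix()].
#' @param zero_fill see [normalized_degree()].
#' @return a `data.frame` keyed by `id`.
#' @export
centrality_table <- function(m, zero_fill = FALSE) {
  if (attr(m, "directed")) {
    out_d <- normalized_degree(m, "outdegree", zero_fill)
    in_d <- normalized_degree(m, "indegree", zero_fill)
    data.frame(id = out_d$id, outdegree = out_d$centrality,
               indegree = in_d$centrality, stringsAsFactors = FALSE)
  } else {
    d <- normalized_degree(m, "n_degree", zero_fill)
    names(d)[2] <- "n_degree"
    d
  }
}
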