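#' Biweight midcorrelation
#'
#' Robust correlation using Tukey biweights. For a vector `x`,
#' `u_i = (x_i - med(x)) / (9 * MAD(x))` with unscaled MAD,
#' `w_i = (1 - u_i^2)^2 * 1[|u_i| < 1]`, `x~_i = (x_i - med(x)) * w_i`, and
#' `bicor(x, y) = sum(x~ y~) / (sqrt(sum(x~^2)) * sqrt(sum(y~^2)))`.
#' Pairs where either vector has `MAD == 0` (constant in the robust sense)
#' fall back to Pearson correlation; missing values are handled
#' pairwise-complete, with median/MAD recomputed on the shared observed
#' positions.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in `[-1, 1]`.
#' @export
bicor <- function(x, y) {
  res <- cpp_bicor(matrix(as.numeric(x), nrow = 1),
                   matrix(as.numeric(y), nrow = 1))
  if (length(res$bad_i))
    stop("fewer than 4 pairwise-complete observations")
  res$r[1, 1]
}

.bicor_rows <- function(X, Y = NULL, context = "bicor",
                        on_deficient = "error") {
  res <- cpp_bicor(X, if (is.null(Y)) NULL else Y)
  if (length(res$bad_i) && on_deficient == "error") {
    labs <- sprintf("(%s, %s)",
                    rownames(X)[res$bad_i],
                    if (is.null(Y)) rownames(X)[res$bad_j] else rownames(Y)[res$bad_j])
    stop(context, ": gene pairs with fewer than 4 pairwise-complete observations: ",
         paste(head(labs, 10), collapse = ", "))
  }
  r <- res$r
  rownames(r) <- rownames(X)
  colnames(r) <- if (is.null(Y)) rownames(X) else rownames(Y)
  attr(r, "pearson_fallback_rows") <- rownames(X)[res$pearson_rows_x]
  r
}

#' All-pairs biweight midcorrelation matrix
#'
#' @param expr `expr_matrix` or matrix (genes x conditions); every gene pair
#'   needs >= 4 pairwise-complete observations.
#' @param warn_fallback warn when rows with `MAD == 0` fall back to Pearson.
#' @return symmetric correlation matrix with unit diagonal, `"method"`
#'   attribute `"bicor"`, and the Pearson-fallback rows recorded in the
#'   `"pearson_fallback_rows"` attribute.
#' @export
bicor_matrix <- function(expr, warn_fallback = TRUE) {
  v <- .values(expr)
  if (ncol(v) < 4) stop("need at least 4 conditions")
  r <- .bicor_rows(v)
  fb <- attr(r, "pearson_fallback_rows")
  if (warn_fallback && length(fb))
    warning(sprintf("%d gene(s) with MAD == 0 use Pearson for all their pairs: %s",
                    length(fb), paste(head(fb, 10), collapse = ", ")))
  attr(r, "method") <- "bicor"
  r
}

#' Signed soft-threshold adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta`, mapping correlation into `[0, 1]` so
#' that strongly negative correlation gives near-zero connection strength;
#' the diagonal is set to 1.
#'
#' @param cor symmetric correlation matrix.
#' @param beta soft-threshold power (default 18).
#' @return adjacency matrix in `[0, 1]`.
#' @export
signed_adjacency <- function(cor, beta = 18) {
  if (beta < 1) stop("beta must be >= 1")
  a <- ((1 + cor) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_{u != i} a_iu`; diagonal 1.
#'
#' @param adj symmetric adjacency in `[0, 1]`.
#' @return TOM similarity matrix in `[0, 1]`.
#' @export
tom_similarity <- function(adj) {
  a <- adj
  diag(a) <- 0
  num <- a %*% a + a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}
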