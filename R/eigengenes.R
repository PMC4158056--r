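#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene-by-condition submatrix (genes standardized to mean 0, sd 1 first),
#' expressed as a unit-norm profile over conditions and sign-oriented so
#' that its correlation with the module's mean standardized profile is
#' non-negative. Missing entries are imputed by the gene's row mean for the
#' decomposition only.
#'
#' @param expr `expr_matrix` or matrix (genes x conditions).
#' @param labels named integer vector, gene -> module label (0 = unassigned).
#' @return list with `eigengenes` (conditions x modules matrix, columns
#'   named `ME<label>`), `prop_var_explained` (named numeric), and
#'   `labels` (the module labels, as integers).
#' @export
module_eigengenes <- function(expr, labels) {
  v <- .values(expr)
  labels <- labels[rownames(v)]
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) stop("no modules (all genes unassigned)")
  me <- matrix(NA_real_, ncol(v), length(mods),
               dimnames = list(colnames(v), paste0("ME", mods)))
  pve <- setNames(numeric(length(mods)), as.character(mods))
  for (k in seq_along(mods)) {
    m <- mods[k]
    sub <- v[labels == m, , drop = FALSE]
    # impute missing by row mean, confined to this decomposition
    if (anyNA(sub)) {
      rm <- rowMeans(sub, na.rm = TRUE)
      idx <- which(is.na(sub), arr.ind = TRUE)
      sub[idx] <- rm[idx[, 1]]
    }
    sds <- apply(sub, 1, sd)
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) < 2)
      stop("module ", m, " has fewer than 2 usable genes")
    z <- t(scale(t(sub)))
    sv <- svd(z, nu = 0, nv = 1)
    prof <- sv$v[, 1]
    if (isTRUE(cor(prof, colMeans(z)) < 0)) prof <- -prof
    me[, k] <- prof
    pve[k] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, prop_var_explained = pve, labels = mods)
}

#' Module membership (kME)
#'
#' Correlation of every gene's expression profile with every module
#' eigengene, members and non-members alike, using biweight midcorrelation
#' (with the usual Pearson fallback for constant rows).
#'
#' @param expr `expr_matrix` or matrix.
#' @param megs result of [module_eigengenes()] (or a conditions x modules
#'   eigengene matrix).
#' @return gene x module matrix of correlations.
#' @export
kme <- function(expr, megs) {
  v <- .values(expr)
  me <- if (is.list(megs)) megs$eigengenes else megs
  if (nrow(me) != ncol(v)) stop("eigengenes and expression must share the condition axis")
  k <- .bicor_rows(v, t(me), context = "kme")
  attr(k, "pearson_fallback_rows") <- NULL
  k
}
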