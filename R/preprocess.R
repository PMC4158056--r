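#' Collapse probe-level signals to gene level
#'
#' Probes mapping to more than one gene are discarded; genes hit by several
#' remaining probes get the per-sample arithmetic mean of their probes'
#' signals.
#'
#' @param values numeric probe-by-sample matrix with probe rownames.
#' @param probe_map data.frame with columns `probe_id`, `gene_id`; a probe
#'   may appear on several rows (multi-gene probes are dropped).
#' @return `expr_matrix` (genes x samples, standardization `"raw"`).
#' @export
aggregate_probes <- function(values, probe_map) {
  values <- .values(values)
  if (!all(c("probe_id", "gene_id") %in% names(probe_map)))
    stop("probe_map needs columns probe_id, gene_id")
  pm <- unique(probe_map[, c("probe_id", "gene_id")])
  n_genes <- tapply(pm$gene_id, pm$probe_id, function(g) length(unique(g)))
  multi <- names(n_genes)[n_genes > 1]
  pm <- pm[!(pm$probe_id %in% multi) & pm$probe_id %in% rownames(values), ]
  if (nrow(pm) == 0)
    stop("no probes left after discarding multi-gene probes")
  genes <- sort(unique(pm$gene_id))
  out <- matrix(NA_real_, length(genes), ncol(values),
                dimnames = list(genes, colnames(values)))
  for (g in genes) {
    pr <- pm$probe_id[pm$gene_id == g]
    sub <- values[pr, , drop = FALSE]
    out[g, ] <- colMeans(sub)
  }
  expr_matrix(out, "raw")
}

#' Log2-transform and average replicates per condition
#'
#' Applies `log2` (skipped when the input is already tagged `"log2"`), then
#' averages replicate samples belonging to the same condition.
#'
#' @param expr `expr_matrix` or matrix (genes x samples).
#' @param sheet data.frame with columns `sample_id`, `condition_id` (and
#'   optionally `replicate`); every sample maps to exactly one condition.
#' @return `expr_matrix` (genes x conditions, standardization `"averaged"`).
#' @export
log2_and_average <- function(expr, sheet) {
  v <- .values(expr)
  tag <- .standardization(expr)
  if (!all(c("sample_id", "condition_id") %in% names(sheet)))
    stop("sample sheet needs columns sample_id, condition_id")
  if (anyDuplicated(sheet$sample_id))
    stop("a sample maps to more than one condition: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  sheet <- sheet[sheet$sample_id %in% colnames(v), , drop = FALSE]
  if (nrow(sheet) == 0) stop("no sheet samples found in the matrix")
  v <- v[, sheet$sample_id, drop = FALSE]
  if (tag == "raw") {
    bad <- which(v <= 0, arr.ind = TRUE)
    if (length(bad))
      stop(sprintf("non-positive value for gene %s, sample %s",
                   rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
    v <- log2(v)
  } else if (tag != "log2") {
    stop("log2_and_average expects raw or log2 input, got ", tag)
  }
  conds <- unique(sheet$condition_id)
  out <- matrix(NA_real_, nrow(v), length(conds),
                dimnames = list(rownames(v), conds))
  for (cc in conds) {
    s <- sheet$sample_id[sheet$condition_id == cc]
    out[, cc] <- rowMeans(v[, s, drop = FALSE], na.rm = TRUE)
  }
  expr_matrix(out, "averaged")
}

# shared row-standardizer; center/scale are functions of the observed values
.standardize_rows <- function(expr, center_fun, scale_fun, tag, what) {
  v <- .values(expr)
  n_obs <- rowSums(!is.na(v))
  if (any(n_obs < 3))
    stop("rows with fewer than 3 observed values: ",
         paste(head(rownames(v)[n_obs < 3], 10), collapse = ", "))
  out <- v
  flat <- character(0)
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    obs <- !is.na(x)
    ctr <- center_fun(x[obs])
    sc <- scale_fun(x[obs], ctr)
    if (sc == 0) {
      out[i, obs] <- 0
      flat <- c(flat, rownames(v)[i])
    } else {
      out[i, obs] <- (x[obs] - ctr) / sc
    }
  }
  if (length(flat))
    warning(sprintf("%d row(s) with zero %s set to all-zero: %s",
                    length(flat), what,
                    paste(head(flat, 10), collapse = ", ")))
  res <- expr_matrix(out, tag)
  attr(res, "zero_scale_genes") <- flat
  res
}

#' Robust z-scores (MAD units from the median)
#'
#' Per gene: `(x - median(x)) / MAD(x)` with the unscaled
#' `MAD = median(|x - median(x)|)` (no 1.4826 consistency factor), computed
#' over observed entries; missing entries are propagated. Rows with
#' `MAD == 0` are set to all-zero and reported in a warning (and in the
#' `"zero_scale_genes"` attribute) rather than dropped, so gene universes
#' stay aligned across datasets.
#'
#' @param expr `expr_matrix` or matrix; every row needs >= 3 observed values.
#' @return `expr_matrix` tagged `"robust_z"`.
#' @export
robust_z <- function(expr) {
  .standardize_rows(expr,
                    center_fun = function(x) median(x),
                    scale_fun = function(x, m) median(abs(x - m)),
                    tag = "robust_z", what = "MAD")
}

#' Ordinary z-scores (standard deviations from the mean)
#'
#' Per gene: `(x - mean(x)) / sd(x)` over observed entries, sample sd with
#' divisor n-1. Zero-sd rows are zeroed with a warning.
#'
#' @inheritParams robust_z
#' @return `expr_matrix` tagged `"z"`.
#' @export
zscore <- function(expr) {
  .standardize_rows(expr,
                    center_fun = function(x) mean(x),
                    scale_fun = function(x, m) sd(x),
                    tag = "z", what = "standard deviation")
}

#' Central-tendency normalization of abundance columns
#'
#' Subtracts each condition column's median (over observed entries) so all
#' column medians become 0. Intended for log-scale protein abundances.
#'
#' @param expr `expr_matrix` or matrix.
#' @return `expr_matrix` with the input standardization tag preserved.
#' @export
central_tendency_normalize <- function(expr) {
  v <- .values(expr)
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    if (all(is.na(x))) stop("column ", colnames(v)[j], " is entirely missing")
    v[, j] <- x - median(x, na.rm = TRUE)
  }
  tag <- .standardization(expr)
  expr_matrix(v, if (tag == "raw") "log2" else tag)
}

#' Drop rows with too many missing values
#'
#' Rows with strictly more than `max_missing` missing entries are removed
#' (the published filter keeps rows with up to two missing values).
#' Retained values are never altered.
#'
#' @param expr `expr_matrix` or matrix.
#' @param max_missing maximum number of missing entries a row may keep
#'   (default 2).
#' @return `expr_matrix`; removed gene ids are in the `"removed_genes"`
#'   attribute.
#' @export
filter_missing <- function(expr, max_missing = 2) {
  v <- .values(expr)
  n_miss <- rowSums(is.na(v))
  drop <- n_miss > max_missing
  if (all(drop)) warning("all rows removed by the missing-value filter")
  out <- expr_matrix(v[!drop, , drop = FALSE], .standardization(expr))
  attr(out, "removed_genes") <- rownames(v)[drop]
  out
}
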