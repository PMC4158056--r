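#' Resampling analysis of module stability
#'
#' Conditions are drawn with replacement (same count as the original),
#' modules are re-detected on each resampled matrix, and each reference
#' module is scored by its best-match overlap: the largest fraction of its
#' genes co-clustered in a single resampled module. Resamples on which
#' detection fails (e.g. a degenerate draw producing constant genes) are
#' skipped and counted.
#'
#' @param expr `expr_matrix` or matrix.
#' @param params [network_params()]; `params$seed` seeds the resampling.
#' @param n_resamples number of bootstrap resamples (>= 2).
#' @param reference optional precomputed [detect_modules()] result.
#' @return data.frame with columns `module`, `size`, `median_overlap`,
#'   `iqr_overlap`; the number of skipped resamples is in the
#'   `"n_skipped"` attribute.
#' @export
module_stability <- function(expr, params = network_params(), n_resamples = 20,
                             reference = NULL) {
  if (n_resamples < 2) stop("n_resamples must be >= 2")
  v <- .values(expr)
  if (is.null(reference)) reference <- detect_modules(v, params)
  ref <- reference$labels
  mods <- sort(unique(ref[ref > 0]))
  if (!length(mods)) stop("reference partition has no modules")
  set.seed(params$seed)
  overlaps <- matrix(NA_real_, length(mods), n_resamples,
                     dimnames = list(as.character(mods), NULL))
  n_skipped <- 0
  for (b in seq_len(n_resamples)) {
    idx <- sample(ncol(v), ncol(v), replace = TRUE)
    vb <- v[, idx, drop = FALSE]
    colnames(vb) <- sprintf("bs%03d", seq_len(ncol(vb)))
    part_b <- tryCatch(detect_modules(vb, params), error = function(e) NULL)
    if (is.null(part_b)) { n_skipped <- n_skipped + 1; next }
    lb <- part_b$labels[names(ref)]
    for (m in mods) {
      genes <- names(ref)[ref == m]
      tab <- table(lb[genes])
      tab <- tab[names(tab) != "0"]
      overlaps[as.character(m), b] <-
        if (length(tab)) max(tab) / length(genes) else 0
    }
  }
  out <- data.frame(module = mods,
                    size = sapply(mods, function(m) sum(ref == m)),
                    median_overlap = apply(overlaps, 1, median, na.rm = TRUE),
                    iqr_overlap = apply(overlaps, 1, IQR, na.rm = TRUE),
                    row.names = NULL)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "overlaps") <- overlaps
  out
}

# leaf sets of all internal nodes of an hclust, as sorted label vectors
.clades <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pair <- hc$merge[i, ]
    s <- c()
    for (x in pair) {
      s <- c(s, if (x < 0) hc$labels[-x] else sets[[x]])
    }
    sets[[i]] <- sort(s)
  }
  sets
}

#' Bootstrap support for condition clustering
#'
#' Average-linkage hierarchical clustering of conditions with distance
#' `1 - Pearson(condition profiles)`. Support (BP) for each internal node
#' is the fraction of gene-bootstrap replicates in which the exact same
#' leaf set reappears as a cluster.
#'
#' @param expr `expr_matrix` or matrix (genes x conditions, >= 3 conditions).
#' @param n_boot number of gene bootstrap replicates; fewer than 100 yields
#'   a warning about unstable support values.
#' @param seed RNG seed.
#' @return list with `hclust` (the reference tree), `support` (BP per
#'   internal node, ordered as `hclust$merge` rows), `clades` (leaf sets).
#' @export
cluster_conditions_bootstrap <- function(expr, n_boot = 1000, seed = 1L) {
  v <- .values(expr)
  if (ncol(v) < 3) stop("need at least 3 conditions")
  if (n_boot < 100) warning("n_boot < 100 gives unstable support values")
  cond_dist <- function(m) as.dist(1 - cor(m, use = "pairwise.complete.obs"))
  hc <- hclust(cond_dist(v), method = "average")
  ref_clades <- .clades(hc)
  keys <- vapply(ref_clades, paste, "", collapse = "\r")
  counts <- setNames(numeric(length(keys)), keys)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- sample(nrow(v), nrow(v), replace = TRUE)
    hb <- tryCatch(hclust(cond_dist(v[idx, , drop = FALSE]), method = "average"),
                   error = function(e) NULL)
    if (is.null(hb)) next
    kb <- vapply(.clades(hb), paste, "", collapse = "\r")
    hit <- keys %in% kb
    counts[hit] <- counts[hit] + 1
  }
  list(hclust = hc, support = unname(counts) / n_boot, clades = ref_clades)
}
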