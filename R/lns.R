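#' Fisher (atanh) transform of a correlation matrix
#'
#' Entries are clipped to `|r| <= 1 - clip` before `atanh` so the result is
#' finite (the unit diagonal would otherwise transform to infinity). The
#' diagonal carries the clipped `atanh(1)` value but is excluded from the
#' LNS vectors by [lns_all()].
#'
#' @param cor symmetric correlation matrix.
#' @param clip clipping margin (default `1e-12`).
#' @return matrix of atanh-transformed correlations with a `"clip"`
#'   attribute.
#' @export
atanh_corr <- function(cor, clip = 1e-12) {
  w <- atanh(pmin(pmax(cor, -1 + clip), 1 - clip))
  attr(w, "clip") <- clip
  attr(w, "method") <- NULL
  w
}

#' Local Network Similarity for all ortholog pairs
#'
#' Both matrices must be indexed by the same ortholog order (reference gene
#' ids; see [restrict_to_common()] and [lns_from_expr()]). For ortholog
#' pair `i`, LNS is the Pearson correlation between row `i` of `WA` and row
#' `i` of `WB` after deleting the self position `i` from both vectors.
#'
#' @param WA,WB atanh-transformed correlation matrices over the n orthologs.
#' @param map optional data.frame (`ref_gene`, `test_gene`) naming the
#'   pairs; defaults to the matrix rownames on both sides.
#' @return data.frame with columns `ref_gene`, `test_gene`, `lns`.
#' @export
lns_all <- function(WA, WB, map = NULL) {
  n <- nrow(WA)
  if (!all(dim(WA) == dim(WB)) || n != ncol(WA))
    stop("WA and WB must be square matrices of equal size")
  if (n < 5) stop("need at least 5 orthologs (4 matched components)")
  if (is.null(map)) {
    map <- data.frame(ref_gene = rownames(WA) %||% sprintf("g%04d", 1:n),
                      test_gene = rownames(WB) %||% sprintf("g%04d", 1:n))
  }
  vals <- vapply(seq_len(n), function(i) cor(WA[i, -i], WB[i, -i]), 0.0)
  data.frame(ref_gene = map$ref_gene, test_gene = map$test_gene, lns = vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' LNS randomization null and empirical p-values
#'
#' Each permutation shuffles the test-gene column of the ortholog mapping
#' table (full shuffles; fixed points allowed) while leaving both
#' correlation matrices, and thus both network topologies, untouched, and
#' recomputes LNS for all shuffled pairs. The pooled null is summarized and
#' each observed pair gets `empirical_p = (1 + #null >= observed) /
#' (1 + #null)` against the pooled null (`per_pair = TRUE` restricts the
#' comparison to that pair's own null values instead).
#'
#' With `null_method = "node"` the alternative randomization is used: ref
#' gene `i` is paired with test gene `sigma(i)` but vector components stay
#' matched by the original ortholog index. This preserves neither the
#' pairing nor the component matching jointly and yields a different null;
#' the map randomization is the default.
#'
#' @inheritParams lns_all
#' @param n_perm number of permutations (default 100).
#' @param seed RNG seed.
#' @param per_pair compute empirical p per pair instead of pooled.
#' @param null_method `"map"` (default) or `"node"`.
#' @return list with `table` (the [lns_all()] table plus `null_mean`,
#'   `null_sd`, `null_min`, `null_max`, `empirical_p`), `null_values`
#'   (n x n_perm matrix), `n_perm`, `seed`.
#' @export
lns_null <- function(WA, WB, map = NULL, n_perm = 100, seed = 1L,
                     per_pair = FALSE, null_method = c("map", "node")) {
  null_method <- match.arg(null_method)
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- lns_all(WA, WB, map)
  n <- nrow(WA)
  null_values <- matrix(NA_real_, n, n_perm)
  set.seed(seed)
  for (p in seq_len(n_perm)) {
    sig <- sample(n)
    if (null_method == "map") {
      WBp <- WB[sig, sig, drop = FALSE]
      null_values[, p] <- vapply(seq_len(n), function(i)
        cor(WA[i, -i], WBp[i, -i]), 0.0)
    } else {
      null_values[, p] <- vapply(seq_len(n), function(i) {
        drop_idx <- unique(c(i, sig[i]))
        cor(WA[i, -drop_idx], WB[sig[i], -drop_idx])
      }, 0.0)
    }
  }
  pooled <- as.vector(null_values)
  tab <- obs
  tab$null_mean <- mean(pooled)
  tab$null_sd <- sd(pooled)
  tab$null_min <- min(pooled)
  tab$null_max <- max(pooled)
  if (per_pair) {
    tab$empirical_p <- vapply(seq_len(n), function(i)
      (1 + sum(null_values[i, ] >= obs$lns[i])) / (1 + n_perm), 0.0)
  } else {
    tab$empirical_p <- vapply(obs$lns, function(x)
      (1 + sum(pooled >= x)) / (1 + length(pooled)), 0.0)
  }
  list(table = tab, null_values = null_values, n_perm = n_perm, seed = seed)
}

#' LNS between two expression datasets
#'
#' Convenience wrapper: restricts both datasets to the mapped genes,
#' computes biweight midcorrelation matrices, atanh-transforms them and
#' returns LNS plus the randomization null.
#'
#' @param ref,test `expr_matrix` or matrix.
#' @param map ortholog map data.frame (`ref_gene`, `test_gene`).
#' @inheritParams lns_null
#' @return as [lns_null()].
#' @export
lns_from_expr <- function(ref, test, map, n_perm = 100, seed = 1L,
                          per_pair = FALSE) {
  rc <- restrict_to_common(ref, test, map,
                           setNames(integer(0), character(0)))
  WA <- atanh_corr(bicor_matrix(rc$ref, warn_fallback = FALSE))
  WB <- atanh_corr(bicor_matrix(rc$test, warn_fallback = FALSE))
  map2 <- map[map$ref_gene %in% rownames(.values(rc$ref)), , drop = FALSE]
  map2 <- map2[match(rownames(.values(rc$ref)), map2$ref_gene), ]
  lns_null(WA, WB, map2, n_perm = n_perm, seed = seed, per_pair = per_pair)
}

#' Within-species split-half LNS
#'
#' Conditions are randomly and evenly divided into two disjoint halves
#' (sizes floor(C/2) and ceiling(C/2)); a biweight midcorrelation matrix is
#' computed per half, and the per-gene LNS between the two halves (identity
#' mapping) measures how reproducible each gene's co-expression
#' neighborhood is within the dataset. The split is repeated `n_rep` times.
#'
#' @param expr `expr_matrix` or matrix with >= 8 conditions.
#' @param n_rep number of random splits (default 100).
#' @param seed RNG seed.
#' @return list with `mean_lns` (named per-gene mean over repeats) and
#'   `per_repeat` (gene x repeat matrix).
#' @export
within_species_lns <- function(expr, n_rep = 100, seed = 1L) {
  v <- .values(expr)
  C <- ncol(v)
  if (C < 8) stop("need at least 8 conditions (4 per half)")
  if (n_rep < 1) stop("n_rep must be >= 1")
  per <- matrix(NA_real_, nrow(v), n_rep, dimnames = list(rownames(v), NULL))
  set.seed(seed)
  for (r in seq_len(n_rep)) {
    idx <- sample(C)
    h1 <- idx[seq_len(floor(C / 2))]
    h2 <- idx[(floor(C / 2) + 1):C]
    W1 <- atanh_corr(.bicor_rows(v[, h1, drop = FALSE]))
    W2 <- atanh_corr(.bicor_rows(v[, h2, drop = FALSE]))
    per[, r] <- vapply(seq_len(nrow(v)), function(i)
      suppressWarnings(cor(W1[i, -i], W2[i, -i])), 0.0)
  }
  list(mean_lns = rowMeans(per, na.rm = TRUE), per_repeat = per)
}

#' Median LNS per module
#'
#' @param table LNS table with columns `ref_gene`, `lns` (from [lns_all()]
#'   or [lns_null()]`$table`).
#' @param part partition or named label vector on the reference genes;
#'   unassigned genes (label 0) form their own reported group.
#' @return named numeric vector, module label -> median LNS; modules with
#'   no scored pairs are omitted with a warning.
#' @export
median_lns_per_module <- function(table, part) {
  labels <- .labels_of(part)
  if (!all(table$ref_gene %in% names(labels)))
    stop("every reference gene in the LNS table must be labeled")
  lab <- labels[table$ref_gene]
  mods <- sort(unique(labels))
  med <- vapply(mods, function(m) {
    x <- table$lns[lab == m]
    if (!length(x)) NA_real_ else median(x, na.rm = TRUE)
  }, 0.0)
  names(med) <- as.character(mods)
  empty <- names(med)[is.na(med)]
  if (length(empty)) {
    warning("modules with no LNS pairs omitted: ", paste(empty, collapse = ", "))
    med <- med[!is.na(med)]
  }
  med
}

#' Correlate median-LNS with cor.kMEall across modules
#'
#' @param medians named vector from [median_lns_per_module()].
#' @param report `preservation_report` (its `preservation$cor_kME_all`
#'   column is used) or a named vector of cor.kMEall values.
#' @return list with `estimate` (Pearson r), `p_value` (two-sided, from the
#'   t transform), and `table` (paired module-level values).
#' @export
lns_vs_kmeall <- function(medians, report) {
  if (inherits(report, "preservation_report")) {
    kall <- setNames(report$preservation$cor_kME_all,
                     as.character(report$preservation$module))
  } else kall <- report
  common <- intersect(names(medians), names(kall))
  common <- common[common != "0"]
  tab <- data.frame(module = common,
                    median_lns = unname(medians[common]),
                    cor_kME_all = unname(kall[common]))
  tab <- tab[is.finite(tab$median_lns) & is.finite(tab$cor_kME_all), ]
  if (nrow(tab) < 3) stop("need at least 3 modules with both statistics")
  if (sd(tab$median_lns) == 0 || sd(tab$cor_kME_all) == 0) {
    warning("zero variance in one of the vectors; correlation undefined")
    return(list(estimate = NA_real_, p_value = NA_real_, table = tab))
  }
  ct <- cor.test(tab$median_lns, tab$cor_kME_all, method = "pearson")
  list(estimate = unname(ct$estimate), p_value = ct$p.value, table = tab)
}
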