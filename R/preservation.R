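#' Restrict a reference/test dataset pair to their common (ortholog) genes
#'
#' Both matrices are cut down to the one-to-one mapped genes present in
#' both, the test genes are relabeled by their reference ortholog ids (so
#' downstream statistics are pure matrix operations on a shared index), and
#' the module partition is restricted accordingly. Modules reduced below 2
#' genes are dropped (set to unassigned) with a warning.
#'
#' @param ref,test `expr_matrix` or matrix.
#' @param map data.frame with columns `ref_gene`, `test_gene`, one-to-one.
#' @param part [detect_modules()] result or named integer label vector for
#'   the reference genes.
#' @return list with `ref`, `test` (both reference-indexed `expr_matrix`),
#'   `labels`, and `dropped_modules`.
#' @export
restrict_to_common <- function(ref, test, map, part) {
  rv <- .values(ref); tv <- .values(test)
  map <- .validate_ortholog_map(map)
  keep <- map$ref_gene %in% rownames(rv) & map$test_gene %in% rownames(tv)
  map <- map[keep, , drop = FALSE]
  if (nrow(map) == 0) stop("empty intersection between map and matrices")
  labels <- .labels_of(part)
  r2 <- rv[map$ref_gene, , drop = FALSE]
  t2 <- tv[map$test_gene, , drop = FALSE]
  rownames(t2) <- map$ref_gene
  lab <- setNames(rep(0L, nrow(map)), map$ref_gene)
  known <- intersect(map$ref_gene, names(labels))
  lab[known] <- labels[known]
  sizes <- table(lab[lab > 0])
  dropped <- as.integer(names(sizes)[sizes < 2])
  if (length(dropped)) {
    warning("modules reduced below 2 genes dropped: ",
            paste(dropped, collapse = ", "))
    lab[lab %in% dropped] <- 0L
  }
  list(ref = expr_matrix(r2, .standardization(ref)),
       test = expr_matrix(t2, .standardization(test)),
       labels = lab, dropped_modules = dropped)
}

# first-PC profile of one module submatrix (rows standardized, row-mean
# imputation for missing values confined to the decomposition)
.single_me <- function(v) {
  if (anyNA(v)) {
    rm <- rowMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- rm[idx[, 1]]
  }
  sds <- apply(v, 1, sd)
  v <- v[sds > 0, , drop = FALSE]
  if (nrow(v) < 2) return(NULL)
  z <- t(scale(t(v)))
  sv <- svd(z, nu = 0, nv = 1)
  prof <- sv$v[, 1]
  if (isTRUE(cor(prof, colMeans(z)) < 0)) prof <- -prof
  list(profile = prof, pve = sv$d[1]^2 / sum(sv$d^2))
}

.cor_safe <- function(x, y, method = "pearson") {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  if (method == "bicor") bicor(x[ok], y[ok]) else cor(x[ok], y[ok])
}

.density_stats <- c("meanCor", "meanAdj", "propVarExplained", "meanKME")
.connectivity_stats <- c("cor.kIM", "cor.kME", "cor.cor")
.preservation_stats <- c(.density_stats, .connectivity_stats)

#' Raw per-module preservation statistics
#'
#' Computes, for every module of the (reference-indexed) partition, the
#' density statistics in the test data (mean off-diagonal bicor, mean
#' signed adjacency, eigengene variance explained, mean kME of members to
#' the module's test eigengene) and the ref-vs-test connectivity statistics
#' (correlation across module genes of intramodular connectivity, of kME,
#' and of the vectorized within-module correlation matrices), plus
#' `cor_kME_all`: the correlation over all common genes of kME to the
#' module eigengene, reference vs test.
#'
#' @param ref,test reference-indexed matrices from [restrict_to_common()].
#' @param part partition or named label vector on the shared gene ids.
#' @param params [network_params()] (only `beta` is used here).
#' @param stat_cor correlation used for `cor_kME_all` (`"bicor"` or
#'   `"pearson"`).
#' @param kme_all compute the (relatively expensive) `cor_kME_all` column.
#' @return data.frame, one row per module (modules with fewer than 3 genes
#'   get `NA` statistics).
#' @export
observed_stats <- function(ref, test, part, params = network_params(),
                           stat_cor = c("bicor", "pearson"), kme_all = TRUE) {
  stat_cor <- match.arg(stat_cor)
  rv <- .values(ref); tv <- .values(test)
  if (!identical(rownames(rv), rownames(tv)))
    stop("ref and test must be reference-indexed on the same genes; see restrict_to_common()")
  labels <- .labels_of(part)[rownames(rv)]
  mods <- sort(unique(labels[labels > 0]))
  cols <- c(.preservation_stats, "cor_kME_all")
  out <- as.data.frame(matrix(NA_real_, length(mods), length(cols),
                              dimnames = list(NULL, cols)))
  out <- cbind(data.frame(module = mods,
                          size = sapply(mods, function(m) sum(labels == m))),
               out)
  for (i in seq_along(mods)) {
    m <- mods[i]
    idx <- which(labels == m)
    if (length(idx) < 3) next
    r_sub <- rv[idx, , drop = FALSE]
    t_sub <- tv[idx, , drop = FALSE]
    Cr <- .bicor_rows(r_sub, on_deficient = "na")
    Ct <- .bicor_rows(t_sub, on_deficient = "na")
    off <- upper.tri(Ct)
    out$meanCor[i] <- mean(Ct[off], na.rm = TRUE)
    At <- signed_adjacency(Ct, params$beta)
    Ar <- signed_adjacency(Cr, params$beta)
    out$meanAdj[i] <- mean(At[off], na.rm = TRUE)
    me_t <- .single_me(t_sub)
    me_r <- .single_me(r_sub)
    if (is.null(me_t) || is.null(me_r)) next
    out$propVarExplained[i] <- me_t$pve
    kme_t <- .bicor_rows(t_sub, matrix(me_t$profile, nrow = 1),
                         on_deficient = "na")[, 1]
    kme_r <- .bicor_rows(r_sub, matrix(me_r$profile, nrow = 1),
                         on_deficient = "na")[, 1]
    out$meanKME[i] <- mean(kme_t, na.rm = TRUE)
    kim_r <- rowSums(Ar, na.rm = TRUE) - 1
    kim_t <- rowSums(At, na.rm = TRUE) - 1
    out[["cor.kIM"]][i] <- .cor_safe(kim_r, kim_t)
    out[["cor.kME"]][i] <- .cor_safe(kme_r, kme_t)
    out[["cor.cor"]][i] <- .cor_safe(Cr[off], Ct[off])
    if (kme_all) {
      kall_r <- .bicor_rows(rv, matrix(me_r$profile, nrow = 1),
                            on_deficient = "na")[, 1]
      kall_t <- .bicor_rows(tv, matrix(me_t$profile, nrow = 1),
                            on_deficient = "na")[, 1]
      out$cor_kME_all[i] <- .cor_safe(kall_r, kall_t, method = stat_cor)
    }
  }
  out
}

# medianRank: rank each observed component across modules, 1 = most
# preserved (largest value); per-module median over components.
.median_rank <- function(obs) {
  ranks <- sapply(.preservation_stats, function(s)
    rank(-obs[[s]], ties.method = "average", na.last = "keep"))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = nrow(obs))
  apply(ranks, 1, function(r) median(r, na.rm = TRUE))
}

.z_from_null <- function(obs, null_arr) {
  # null_arr: n_perm x n_modules x n_stats
  z <- matrix(NA_real_, dim(null_arr)[2], dim(null_arr)[3],
              dimnames = list(NULL, dimnames(null_arr)[[3]]))
  warn_sd0 <- FALSE
  for (j in seq_len(dim(null_arr)[2])) {
    for (s in seq_len(dim(null_arr)[3])) {
      nv <- null_arr[, j, s]
      nv <- nv[is.finite(nv)]
      o <- obs[j, s]
      if (length(nv) < 2 || !is.finite(o)) next
      sdn <- sd(nv)
      # a null that is constant up to floating-point noise (e.g. exact
      # self-comparison, where every correlation statistic is 1) carries no
      # information; its Z is undefined rather than noise-amplified
      if (sdn <= 1e-8 * max(1, abs(mean(nv)))) { warn_sd0 <- TRUE; next }
      z[j, s] <- (o - mean(nv)) / sdn
    }
  }
  if (warn_sd0)
    warning("zero null standard deviation for some statistics; Z left undefined")
  z
}

.summarize_pass <- function(obs, z) {
  zden <- apply(z[, .density_stats, drop = FALSE], 1, median, na.rm = TRUE)
  zcon <- apply(z[, .connectivity_stats, drop = FALSE], 1, median, na.rm = TRUE)
  zsum <- rowMeans(cbind(zden, zcon), na.rm = TRUE)
  df <- obs
  colnames(z) <- paste0("Z.", colnames(z))
  df <- cbind(df, as.data.frame(z))
  df$Zdensity <- zden
  df$Zconnectivity <- zcon
  df$Zsummary <- zsum
  df$medianRank <- .median_rank(obs)
  df
}

#' Permutation-based module quality and preservation statistics
#'
#' For each module, a null distribution of every component statistic is
#' built by permuting module membership labels among the common genes
#' (module sizes preserved, expression untouched) and recomputing the
#' observed statistics; `Z = (observed - null mean) / null sd`.
#' `Zdensity` / `Zconnectivity` are the medians of the density /
#' connectivity component Z's and `Zsummary` their mean. The quality pass
#' runs the same machinery with `test := ref`. `medianRank` is the
#' per-module median of the across-module ranks of the observed component
#' statistics (rank 1 = most preserved). Zsummary > 2 is conventionally
#' read as weak-to-moderate and > 10 as strong evidence of preservation.
#'
#' @inheritParams observed_stats
#' @param n_perm number of label permutations (>= 2; 1000 in the original
#'   analyses, a few hundred is adequate at desk scale).
#' @param seed RNG seed for the permutations.
#' @return list of class `preservation_report` with data.frames
#'   `preservation` and `quality` (observed statistics, per-component Z,
#'   `Zdensity`, `Zconnectivity`, `Zsummary`, `medianRank`), `n_perm`,
#'   `seed`.
#' @export
module_preservation <- function(ref, test, part, params = network_params(),
                                n_perm = 200, seed = params$seed,
                                stat_cor = c("bicor", "pearson")) {
  stat_cor <- match.arg(stat_cor)
  if (n_perm < 2) stop("n_perm must be >= 2")
  rv <- .values(ref); tv <- .values(test)
  labels <- .labels_of(part)[rownames(rv)]
  names(labels) <- rownames(rv)
  obs_pres <- observed_stats(rv, tv, labels, params, stat_cor, kme_all = TRUE)
  obs_qual <- observed_stats(rv, rv, labels, params, stat_cor, kme_all = TRUE)
  mods <- obs_pres$module
  nstat <- length(.preservation_stats)
  null_pres <- array(NA_real_, c(n_perm, length(mods), nstat),
                     dimnames = list(NULL, NULL, .preservation_stats))
  null_qual <- null_pres
  set.seed(seed)
  for (p in seq_len(n_perm)) {
    perm <- setNames(sample(unname(labels)), names(labels))
    sp <- observed_stats(rv, tv, perm, params, stat_cor, kme_all = FALSE)
    sq <- observed_stats(rv, rv, perm, params, stat_cor, kme_all = FALSE)
    null_pres[p, , ] <- as.matrix(sp[match(mods, sp$module), .preservation_stats])
    null_qual[p, , ] <- as.matrix(sq[match(mods, sq$module), .preservation_stats])
  }
  om_pres <- as.matrix(obs_pres[, .preservation_stats])
  om_qual <- as.matrix(obs_qual[, .preservation_stats])
  res <- list(preservation = .summarize_pass(obs_pres, .z_from_null(om_pres, null_pres)),
              quality = .summarize_pass(obs_qual, .z_from_null(om_qual, null_qual)),
              n_perm = n_perm, seed = seed)
  class(res) <- "preservation_report"
  res
}

#' @export
print.preservation_report <- function(x, ...) {
  cat(sprintf("preservation_report: %d modules, %d permutations (seed %d)\n",
              nrow(x$preservation), x$n_perm, x$seed))
  print(x$preservation[, c("module", "size", "Zdensity", "Zconnectivity",
                           "Zsummary", "medianRank", "cor_kME_all")])
  invisible(x)
}

#' Module reproducibility after removing conditions
#'
#' Runs [module_preservation()] with the test dataset equal to the
#' reference minus the excluded condition columns, and flags which modules
#' clear the conventional Zsummary thresholds 2, 5 and 10.
#'
#' @param ref `expr_matrix` or matrix.
#' @param excluded_conditions condition ids to drop (>= 4 must remain).
#' @param part partition on the reference genes.
#' @inheritParams module_preservation
#' @return `preservation_report` whose `preservation` data.frame gains
#'   logical columns `th2`, `th5`, `th10`.
#' @export
reproducibility_in_subset <- function(ref, excluded_conditions, part,
                                      params = network_params(), n_perm = 200,
                                      seed = params$seed) {
  rv <- .values(ref)
  missing_conds <- setdiff(excluded_conditions, colnames(rv))
  if (length(missing_conds))
    stop("unknown conditions: ", paste(missing_conds, collapse = ", "))
  keep <- setdiff(colnames(rv), excluded_conditions)
  if (length(keep) == 0) stop("cannot exclude all conditions")
  if (length(keep) < 4) stop("fewer than 4 conditions would remain")
  tv <- rv[, keep, drop = FALSE]
  rep <- module_preservation(rv, tv, part, params, n_perm, seed)
  rep$preservation$th2 <- rep$preservation$Zsummary > 2
  rep$preservation$th5 <- rep$preservation$Zsummary > 5
  rep$preservation$th10 <- rep$preservation$Zsummary > 10
  rep
}
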