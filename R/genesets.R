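#' Hypergeometric over-representation p-value
#'
#' Upper tail `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of
#' drawing at least `k` genes of a set of size `K` when sampling a module
#' of size `n` from a universe of size `N`.
#'
#' @param k observed overlap; `n` module size; `K` set size; `N` universe
#'   size. Requires `0 <= k <= min(n, K) <= N`.
#' @param n,K,N see `k`.
#' @return p-value in `(0, 1]`.
#' @export
hypergeom_test <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N)
    stop("inconsistent counts: need 0 <= k <= min(n, K) <= N")
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  # extreme overlaps underflow the tail to 0; keep p in (0, 1]
  max(p, .Machine$double.xmin)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values with monotonicity enforcement, capped at 1;
#' input order preserved.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return adjusted values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of gene sets in modules
#'
#' One hypergeometric test per (module, set) pair after intersecting every
#' set with the universe; FDR correction is applied jointly across all
#' tests (`pool = "joint"`) or within each set category
#' (`pool = "category"`).
#'
#' @param part partition or named label vector.
#' @param sets named list of gene-id vectors (see [read_gmt()]); an
#'   optional `"category"` attribute (named character) tags each set.
#' @param universe character vector of gene ids; must contain all module
#'   genes.
#' @param min_set_size sets smaller than this after intersection are
#'   dropped (default 3; the count is reported in the result attribute
#'   `"n_dropped_sets"`).
#' @param fdr_threshold significance flag threshold (default 0.05).
#' @param pool FDR pooling scope.
#' @return data.frame with columns `module`, `set`, `category`, `overlap`,
#'   `module_size`, `set_size`, `universe_size`, `p_value`, `fdr`,
#'   `significant`.
#' @export
ora <- function(part, sets, universe, min_set_size = 3, fdr_threshold = 0.05,
                pool = c("joint", "category")) {
  pool <- match.arg(pool)
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  labels <- .labels_of(part)
  labels <- labels[names(labels) %in% universe]
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no modules in the universe")
  cats <- attr(sets, "category") %||% setNames(rep(NA_character_, length(sets)),
                                               names(sets))
  sets2 <- lapply(sets, intersect, universe)
  small <- lengths(sets2) < min_set_size
  sets2 <- sets2[!small]
  N <- length(universe)
  rows <- list()
  for (m in mods) {
    mg <- names(labels)[labels == m]
    for (s in names(sets2)) {
      k <- length(intersect(mg, sets2[[s]]))
      rows[[length(rows) + 1]] <- data.frame(
        module = m, set = s, category = unname(cats[s]),
        overlap = k, module_size = length(mg),
        set_size = length(sets2[[s]]), universe_size = N,
        p_value = hypergeom_test(k, length(mg), length(sets2[[s]]), N))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable (module, set) pairs")
  if (pool == "joint" || all(is.na(out$category))) {
    out$fdr <- bh_fdr(out$p_value)
  } else {
    out$fdr <- NA_real_
    for (cc in unique(out$category)) {
      idx <- which(out$category %in% cc)
      out$fdr[idx] <- bh_fdr(out$p_value[idx])
    }
  }
  out$significant <- out$fdr < fdr_threshold
  attr(out, "n_dropped_sets") <- sum(small)
  out
}

# Vectorized one-sided Mann-Whitney tests (normal approximation with tie
# correction and continuity correction) of `x` against each column of `M`.
.rank_sum_p <- function(x, M) {
  nx <- length(x); ny <- nrow(M); N <- nx + ny
  p_greater <- p_less <- numeric(ncol(M))
  for (j in seq_len(ncol(M))) {
    comb <- c(x, M[, j])
    r <- rank(comb)
    U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    ties <- table(comb)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(nx * ny / 12 * ((N + 1) - tie_term))
    mu <- nx * ny / 2
    p_greater[j] <- pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE)
    p_less[j] <- pnorm((U - mu + 0.5) / sigma)
  }
  list(p_greater = p_greater, p_less = p_less)
}

#' Rank-based permutation test for differential DNA packaging of modules
#'
#' All genes are ranked by the robust z-score of their packaging signal.
#' Each module's ranks are compared against `n_random` randomly selected
#' gene sets of the same size (drawn without replacement from the full
#' scored universe, independently per draw) with one-sided
#' Wilcoxon-Mann-Whitney tests in both directions at level `alpha`. A
#' module is called `"packaged"` when it is significantly greater (higher
#' signal) than at least `frac` of the random sets and no random set is
#' significantly greater than it; `"excluded"` by the mirrored criterion;
#' otherwise `"neutral"`.
#'
#' @param scores named numeric vector, gene -> packaging signal; must cover
#'   all partitioned genes.
#' @param part partition or named label vector.
#' @param n_random number of random gene sets (default 1000).
#' @param alpha per-test significance level (default 0.01).
#' @param frac fraction of random sets that must be beaten (default 0.85).
#' @param seed RNG seed.
#' @return data.frame with columns `module`, `size`, `median_rank`,
#'   `count_greater`, `count_less`, `n_random`, `verdict`.
#' @export
packaging_test <- function(scores, part, n_random = 1000, alpha = 0.01,
                           frac = 0.85, seed = 1L) {
  labels <- .labels_of(part)
  if (!all(names(labels) %in% names(scores)))
    stop("scores must cover all partitioned genes")
  scores <- scores[names(scores) %in% names(labels)]
  madv <- median(abs(scores - median(scores)))
  # ranking is invariant to the (monotone) robust-z transform; guard MAD = 0
  rz <- if (madv > 0) (scores - median(scores)) / madv else scores
  ranks <- rank(rz)
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no modules to test")
  set.seed(seed)
  out <- data.frame(module = mods, size = NA_integer_, median_rank = NA_real_,
                    count_greater = NA_integer_, count_less = NA_integer_,
                    n_random = n_random, verdict = NA_character_)
  for (i in seq_along(mods)) {
    m <- mods[i]
    mg <- names(labels)[labels == m]
    s <- length(mg)
    if (s > length(ranks) / 2)
      warning("module ", m, " covers more than half the universe; test power degenerates")
    mranks <- ranks[mg]
    draws <- matrix(NA_real_, s, n_random)
    for (b in seq_len(n_random))
      draws[, b] <- ranks[sample(names(ranks), s)]
    ps <- .rank_sum_p(mranks, draws)
    cg <- sum(ps$p_greater < alpha)  # module significantly greater
    cl <- sum(ps$p_less < alpha)     # random set significantly greater
    verdict <- "neutral"
    if (cg >= frac * n_random && cl == 0) verdict <- "packaged"
    if (cl >= frac * n_random && cg == 0) verdict <- "excluded"
    out$size[i] <- s
    out$median_rank[i] <- median(mranks)
    out$count_greater[i] <- cg
    out$count_less[i] <- cl
    out$verdict[i] <- verdict
  }
  out
}
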