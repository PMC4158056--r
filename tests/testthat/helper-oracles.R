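# Independent brute-force oracles, written directly from the definitions
# and kept free of any package internals.

# biweight midcorrelation by direct evaluation of the formula,
# pairwise-complete, with Pearson fallback when either MAD is 0
oracle_bicor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 4)
  tf <- function(v) {
    med <- median(v)
    mad0 <- median(abs(v - med))
    if (mad0 == 0) return(NULL)
    u <- (v - med) / (9 * mad0)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - med) * w
  }
  tx <- tf(x); ty <- tf(y)
  if (is.null(tx) || is.null(ty)) {
    tx <- x - mean(x); ty <- y - mean(y)
  }
  sum(tx * ty) / sqrt(sum(tx^2) * sum(ty^2))
}

# topological overlap by explicit triple loop
oracle_tom <- function(adj) {
  n <- nrow(adj)
  a <- adj; diag(a) <- 0
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- sum(a[i, ] * a[, j]) + a[i, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    tom[i, j] <- num / (min(ki, kj) + 1 - a[i, j])
  }
  tom
}

# LNS by explicit loops over vector components
oracle_lns <- function(WA, WB) {
  n <- nrow(WA)
  sapply(seq_len(n), function(i) {
    xa <- numeric(0); xb <- numeric(0)
    for (k in seq_len(n)) {
      if (k == i) next
      xa <- c(xa, WA[i, k]); xb <- c(xb, WB[i, k])
    }
    cor(xa, xb)
  })
}

# hypergeometric upper tail by exhaustive enumeration of all draws
oracle_hyper <- function(k, n, K, N) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are "the set"
  mean(hits >= k)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small planted-module expression matrix (genes x conditions)
planted_expr <- function(n_modules, module_size, rho, n_conditions,
                         n_background = 0, seed = 1) {
  set.seed(seed)
  n <- n_modules * module_size + n_background
  m <- matrix(rnorm(n * n_conditions), n, n_conditions)
  labels <- rep(0L, n)
  for (k in seq_len(n_modules)) {
    idx <- ((k - 1) * module_size + 1):(k * module_size)
    latent <- rnorm(n_conditions)
    m[idx, ] <- rho * matrix(latent, module_size, n_conditions, byrow = TRUE) +
      sqrt(1 - rho^2) * m[idx, ]
    labels[idx] <- k
  }
  rownames(m) <- sprintf("g%04d", seq_len(n))
  colnames(m) <- sprintf("c%03d", seq_len(n_conditions))
  list(values = m, labels = setNames(labels, rownames(m)))
}
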