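test_that("bicor matches the brute-force definition and its limit cases", {
  set.seed(7)
  x <- rnorm(200); y <- 0.4 * x + rnorm(200)
  expect_equal(bicor(x, y), oracle_bicor(x, y), tolerance = 1e-12)
  expect_equal(bicor(x, x), 1, tolerance = 1e-12)
  expect_equal(bicor(x, -x), -1, tolerance = 1e-12)

  # matrix path, with missing values and an outlier-heavy pair
  m <- matrix(rnorm(10 * 20), 10, 20,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("c%02d", 1:20)))
  m[1, 3] <- 50
  m[2, c(2, 9)] <- NA
  m[3, 15] <- NA
  r <- bicor_matrix(m)
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(r[i, j], oracle_bicor(m[i, ], m[j, ]), tolerance = 1e-12)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 10))

  # constant row: Pearson fallback for all its pairs
  m2 <- m
  m2[4, ] <- 3
  expect_warning(r2 <- bicor_matrix(m2), "Pearson")
  expect_true(all(is.na(r2[4, -4])))  # constant also under Pearson -> undefined

  # too few complete observations
  bad <- matrix(rnorm(8), 2, 4, dimnames = list(c("a", "b"), paste0("c", 1:4)))
  bad[1, 1:2] <- NA; bad[2, 3] <- NA
  expect_error(bicor_matrix(bad), "4 conditions|pairwise-complete")
})

test_that("signed adjacency is the soft-threshold power transform", {
  cm <- matrix(c(1, 0, -1, 0, 1, 0.5, -1, 0.5, 1), 3, 3)
  a <- signed_adjacency(cm, beta = 18)
  expect_equal(a[1, 3], 0)
  expect_equal(a[1, 2], 0.5^18)
  expect_equal(a[2, 3], 0.75^18)
  expect_equal(unname(diag(a)), rep(1, 3))
  # strictly increasing in correlation
  r <- seq(-1, 1, by = 0.05)
  expect_true(all(diff(((1 + r) / 2)^18) > 0))
})

test_that("topological overlap matches hand values and the triple-loop oracle", {
  chain <- matrix(c(1, 0.5, 0, 0.5, 1, 0.5, 0, 0.5, 1), 3, 3)
  tom <- tom_similarity(chain)
  expect_equal(tom[1, 3], 1 / 6)

  clique <- matrix(1, 3, 3)
  expect_equal(tom_similarity(clique), matrix(1, 3, 3))

  empty <- diag(3)
  expect_equal(tom_similarity(empty), diag(3))

  set.seed(11)
  r <- cor(matrix(rnorm(25 * 30), 30, 25))
  a <- signed_adjacency(r, 6)
  t1 <- tom_similarity(a)
  expect_equal(unname(t1), oracle_tom(a), tolerance = 1e-12)
  expect_true(all(t1 >= -1e-12 & t1 <= 1 + 1e-12))
})

test_that("module eigengenes: rank-1 modules, orthogonal blocks, sign contract", {
  prof <- rnorm(12)
  m <- matrix(rep(prof, each = 4), 4, 12,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:12)))
  labels <- setNames(rep(1L, 4), rownames(m))
  me <- module_eigengenes(m, labels)
  expect_equal(unname(me$prop_var_explained), 1)
  expect_equal(abs(cor(me$eigengenes[, 1], prof)), 1, tolerance = 1e-10)
  expect_true(cor(me$eigengenes[, 1], colMeans(t(scale(t(m))))) >= 0)
  expect_equal(sum(me$eigengenes[, 1]^2), 1)  # unit norm

  # two orthogonal profiles in equal counts -> half the variance each
  p1 <- rep(c(1, -1), 6); p2 <- rep(c(1, 1, -1, -1), 3)
  m2 <- rbind(p1, p1, p2, p2)
  dimnames(m2) <- list(paste0("g", 1:4), paste0("c", 1:12))
  me2 <- module_eigengenes(m2, setNames(rep(1L, 4), rownames(m2)))
  expect_equal(unname(me2$prop_var_explained), 0.5, tolerance = 1e-10)
})

test_that("kME is 1 for the eigengene itself and 0 for an orthogonal gene", {
  # +-1 profiles give every point the same biweight, so bicor == Pearson
  p1 <- rep(c(1, -1), 6)
  orth <- rep(c(1, 1, -1, -1), 3)  # orthogonal to p1
  m <- rbind(g1 = p1, g2 = p1, g3 = orth)
  colnames(m) <- paste0("c", 1:12)
  me <- module_eigengenes(m, setNames(c(1L, 1L, 0L), rownames(m)))
  k <- kme(m, me)
  expect_equal(abs(k["g1", "ME1"]), 1, tolerance = 1e-10)
  expect_lt(abs(k["g3", "ME1"]), 1e-10)
})

test_that("planted modules are recovered and members have top kME", {
  pe <- planted_expr(4, 30, 0.9, 30, n_background = 60, seed = 3)
  part <- detect_modules(pe$values, network_params())
  got <- part$labels[part$labels > 0]
  expect_gte(ari(got, pe$labels[names(got)]), 0.9)
  # members' kME for their own module beats their kME elsewhere
  mem <- names(pe$labels)[pe$labels == 1 & part$labels > 0]
  own <- part$labels[mem[1]]
  kown <- part$kme[mem, paste0("ME", own)]
  kother <- apply(part$kme[mem, setdiff(colnames(part$kme),
                                        paste0("ME", own)), drop = FALSE], 1, max)
  expect_true(all(kown > kother))
})

test_that("partition is invariant to gene-row permutation", {
  pe <- planted_expr(3, 20, 0.9, 25, n_background = 40, seed = 5)
  p1 <- detect_modules(pe$values, network_params())
  set.seed(9)
  shuffled <- pe$values[sample(nrow(pe$values)), ]
  p2 <- detect_modules(shuffled, network_params())
  common <- names(p1$labels)
  expect_equal(ari(p1$labels[common], p2$labels[common]), 1)
})

test_that("modules with highly correlated eigenprofiles are merged", {
  set.seed(21)
  n_cond <- 30
  e1 <- rnorm(n_cond)
  e2 <- 0.98 * e1 + sqrt(1 - 0.98^2) * rnorm(n_cond)  # ME cor ~ 0.95+
  e3 <- rnorm(n_cond)
  m <- rbind(
    t(replicate(25, 0.95 * e1 + sqrt(1 - 0.95^2) * rnorm(n_cond))),
    t(replicate(25, 0.95 * e2 + sqrt(1 - 0.95^2) * rnorm(n_cond))),
    t(replicate(25, 0.95 * e3 + sqrt(1 - 0.95^2) * rnorm(n_cond))))
  dimnames(m) <- list(sprintf("g%03d", 1:75), sprintf("c%02d", seq_len(n_cond)))
  part <- detect_modules(m, network_params(merge_cut_height = 0.15))
  lab <- part$labels
  expect_equal(length(unique(lab[lab > 0])), 2)
  expect_equal(length(unique(lab[1:50])), 1)  # the twin blocks fused
})

test_that("mostly-noise data stays mostly unassigned", {
  frac <- sapply(1:3, function(s) {
    set.seed(100 + s)
    m <- matrix(rnorm(500 * 30), 500, 30,
                dimnames = list(sprintf("g%03d", 1:500), sprintf("c%02d", 1:30)))
    p <- detect_modules(m, network_params())
    mean(p$labels > 0)
  })
  expect_true(all(frac <= 0.2))
})

test_that("module stability: planted modules are stable, boundary enforced", {
  pe <- planted_expr(3, 20, 0.95, 20, n_background = 40, seed = 13)
  expect_error(module_stability(pe$values, n_resamples = 1), ">= 2")
  st <- module_stability(pe$values, network_params(seed = 4), n_resamples = 8)
  expect_true(all(st$median_overlap >= 0.8))
})

test_that("condition bootstrap: planted groups supported, duplicates exact", {
  set.seed(17)
  # two condition groups with block-distinct profiles
  n_genes <- 200
  grp <- c(rep(1, 5), rep(2, 5))
  base <- matrix(rnorm(n_genes * 2), n_genes, 2)
  m <- base[, grp] * 2 + matrix(rnorm(n_genes * 10), n_genes, 10)
  dimnames(m) <- list(sprintf("g%03d", 1:n_genes), sprintf("c%02d", 1:10))
  cb <- cluster_conditions_bootstrap(m, n_boot = 300, seed = 2)
  leafsets <- lapply(cb$clades, sort)
  g1 <- sort(sprintf("c%02d", 1:5)); g2 <- sort(sprintf("c%02d", 6:10))
  i1 <- which(vapply(leafsets, identical, TRUE, g1))
  i2 <- which(vapply(leafsets, identical, TRUE, g2))
  expect_length(i1, 1); expect_length(i2, 1)
  expect_gte(cb$support[i1], 0.9)
  expect_gte(cb$support[i2], 0.9)

  # duplicated condition columns join at height 0 with certain support
  md <- m
  md[, 2] <- md[, 1]
  colnames(md) <- colnames(m)
  cbd <- suppressWarnings(cluster_conditions_bootstrap(md, n_boot = 100, seed = 3))
  pair <- which(vapply(cbd$clades, identical, TRUE, c("c01", "c02")))
  expect_length(pair, 1)
  expect_equal(cbd$hclust$height[pair], 0, tolerance = 1e-12)
  expect_equal(cbd$support[pair], 1)
})
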