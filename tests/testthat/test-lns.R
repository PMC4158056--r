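random_atanh_matrix <- function(n, n_cond, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * n_cond), n, n_cond,
              dimnames = list(sprintf("g%03d", 1:n), sprintf("c%02d", 1:n_cond)))
  atanh_corr(cor(t(m)))
}

test_that("atanh transform: closed forms and clipping", {
  expect_equal(atanh_corr(matrix(0, 1, 1))[1, 1], 0)
  expect_equal(atanh_corr(matrix(0.5, 1, 1))[1, 1], log(3) / 2, tolerance = 1e-12)
  w1 <- atanh_corr(matrix(1, 1, 1))[1, 1]
  expect_true(is.finite(w1) && w1 > 13)
  wm1 <- atanh_corr(matrix(-1, 1, 1))[1, 1]
  expect_true(is.finite(wm1) && wm1 < -13)
})

test_that("LNS limit cases and brute-force equivalence", {
  WA <- random_atanh_matrix(20, 30, seed = 1)
  expect_equal(lns_all(WA, WA)$lns, rep(1, 20), tolerance = 1e-12)
  expect_equal(lns_all(WA, -WA)$lns, rep(-1, 20), tolerance = 1e-12)

  # hand-written 4x4-free fixture (5 genes so deletions leave 4 components)
  WB <- random_atanh_matrix(20, 25, seed = 2)
  expect_equal(lns_all(WA, WB)$lns, oracle_lns(WA, WB), tolerance = 1e-12)

  small <- random_atanh_matrix(4, 10, seed = 3)
  expect_error(lns_all(small, small), "at least 5")
})

test_that("LNS is symmetric in dataset order and stable under joint reordering", {
  WA <- random_atanh_matrix(15, 20, seed = 4)
  WB <- random_atanh_matrix(15, 22, seed = 5)
  expect_equal(lns_all(WA, WB)$lns, lns_all(WB, WA)$lns, tolerance = 1e-12)
  set.seed(6)
  ord <- sample(15)
  expect_equal(sort(lns_all(WA[ord, ord], WB[ord, ord])$lns),
               sort(lns_all(WA, WB)$lns), tolerance = 1e-12)
})

test_that("randomization null is centered, deterministic, and maximal for self", {
  WA <- random_atanh_matrix(150, 30, seed = 7)
  WB <- random_atanh_matrix(150, 30, seed = 8)
  nl <- lns_null(WA, WB, n_perm = 40, seed = 9)
  pooled <- as.vector(nl$null_values)
  se <- sd(pooled) / sqrt(length(pooled))
  expect_lt(abs(mean(pooled)), 3 * se)

  nl2 <- lns_null(WA, WB, n_perm = 40, seed = 9)
  expect_identical(nl$null_values, nl2$null_values)

  # identical networks with identity map: every observed LNS beats the null
  self <- lns_null(WA, WA, n_perm = 20, seed = 10)
  n_null <- length(self$null_values)
  expect_equal(self$table$empirical_p, rep(1 / (1 + n_null), 150),
               tolerance = 1e-12)
  expect_true(all(self$table$lns > max(self$table$null_max)))
})

test_that("within-species split-half LNS separates module genes from noise", {
  pe <- planted_expr(3, 25, 0.9, 40, n_background = 75, seed = 12)
  w <- within_species_lns(pe$values, n_rep = 10, seed = 3)
  mod_genes <- names(pe$labels)[pe$labels > 0]
  bg_genes <- names(pe$labels)[pe$labels == 0]
  expect_gt(median(w$mean_lns[mod_genes]), 0.5)
  expect_gt(median(w$mean_lns[mod_genes]), median(w$mean_lns[bg_genes]))

  w1 <- within_species_lns(pe$values, n_rep = 1, seed = 8)
  w2 <- within_species_lns(pe$values, n_rep = 1, seed = 8)
  expect_identical(w1$per_repeat, w2$per_repeat)
  expect_error(within_species_lns(pe$values[, 1:6], n_rep = 2), "8 conditions")
})

test_that("median LNS per module aggregates and warns as specified", {
  tab <- data.frame(ref_gene = c("a", "b", "c", "d"),
                    test_gene = c("a", "b", "c", "d"),
                    lns = c(0.2, 0.4, 0.9, 0.7))
  labels <- setNames(c(1L, 1L, 1L, 2L), c("a", "b", "c", "d"))
  med <- median_lns_per_module(tab, labels)
  expect_equal(med[["1"]], 0.4)
  expect_equal(med[["2"]], 0.7)  # single-pair module

  labels2 <- setNames(c(1L, 1L, 1L, 1L), c("a", "b", "c", "d"))
  labels2 <- c(labels2, e = 2L)  # module 2 has no scored pairs
  expect_warning(med2 <- median_lns_per_module(tab, labels2), "omitted")
  expect_false("2" %in% names(med2))

  expect_error(median_lns_per_module(tab, setNames(1L, "a")), "labeled")
})

test_that("median-LNS tracks cor.kMEall across modules on planted data", {
  sp <- synth_spec(n_genes_A = 260, n_conditions_A = 30, n_conditions_B = 30,
                   module_sizes = rep(40, 5),
                   preserved_flags = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                   within_module_cor = 0.9, ortholog_fraction = 1, seed = 33)
  d <- gen_two_species(sp)
  zA <- robust_z(d$exprA); zB <- robust_z(d$exprB)
  labels <- d$truth$module_of_gene
  rc <- restrict_to_common(zA, zB, d$map, labels)
  # planted modules are internally exchangeable, so the informative member
  # genes look like outliers to a robust correlation of the kME vectors;
  # the Pearson variant of cor.kMEall is the appropriate one here
  rep <- suppressWarnings(module_preservation(rc$ref, rc$test, rc$labels,
                                              n_perm = 30, seed = 2,
                                              stat_cor = "pearson"))
  ln <- lns_from_expr(zA, zB, d$map, n_perm = 10, seed = 4)
  med <- suppressWarnings(median_lns_per_module(ln$table, labels))
  out <- lns_vs_kmeall(med, rep)
  expect_gt(out$estimate, 0.5)
  expect_equal(nrow(out$table), 5)

  # identical vectors give r = 1; constant vectors are flagged
  fake <- setNames(out$table$median_lns, out$table$module)
  expect_equal(lns_vs_kmeall(fake, fake)$estimate, 1)
  const <- setNames(rep(0.5, 5), out$table$module)
  expect_warning(res <- lns_vs_kmeall(const, fake), "zero variance")
  expect_true(is.na(res$estimate))
})
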