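two_species_fixture <- function(seed = 11, preserved = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                                rho = 0.9, n_bg = 100) {
  sp <- synth_spec(n_genes_A = length(preserved) * 40 + n_bg,
                   n_conditions_A = 30, n_conditions_B = 30,
                   module_sizes = rep(40, length(preserved)),
                   preserved_flags = preserved, within_module_cor = rho,
                   ortholog_fraction = 1, seed = seed)
  d <- gen_two_species(sp)
  list(zA = robust_z(d$exprA), zB = robust_z(d$exprB), d = d)
}

test_that("restriction to common genes relabels, counts and drops correctly", {
  pe <- planted_expr(2, 10, 0.9, 12, n_background = 5, seed = 2)
  ids <- rownames(pe$values)

  # identity map, identical gene sets: matrices unchanged
  idmap <- data.frame(ref_gene = ids, test_gene = ids)
  rc <- restrict_to_common(pe$values, pe$values, idmap, pe$labels)
  expect_equal(as.matrix(rc$ref), pe$values)
  expect_equal(as.matrix(rc$test), pe$values)

  # half map: output row count equals mapped-and-present count
  half <- idmap[seq(1, nrow(idmap), by = 2), ]
  rc2 <- restrict_to_common(pe$values, pe$values, half, pe$labels)
  expect_equal(nrow(as.matrix(rc2$ref)), nrow(half))

  # a module reduced to one surviving gene is dropped and reported
  one <- idmap[c(1, 11:25), ]  # one gene of module 1, all of module 2, bg
  expect_warning(rc3 <- restrict_to_common(pe$values, pe$values, one, pe$labels),
                 "dropped")
  expect_identical(rc3$dropped_modules, 1L)
  expect_true(all(rc3$labels[rc3$labels > 0] == 2))

  # test genes are relabeled by their reference ortholog ids
  renamed <- pe$values
  rownames(renamed) <- paste0("x_", ids)
  m2 <- data.frame(ref_gene = ids, test_gene = paste0("x_", ids))
  rc4 <- restrict_to_common(pe$values, renamed, m2, pe$labels)
  expect_identical(rownames(as.matrix(rc4$test)), ids)

  expect_error(restrict_to_common(pe$values, pe$values,
                                  data.frame(ref_gene = "zz", test_gene = "zz"),
                                  pe$labels), "empty intersection")
})

test_that("self-comparison gives exactly unit connectivity statistics", {
  pe <- planted_expr(3, 15, 0.85, 20, n_background = 20, seed = 6)
  obs <- observed_stats(pe$values, pe$values, pe$labels)
  expect_equal(obs[["cor.kIM"]], rep(1, 3), tolerance = 1e-12)
  expect_equal(obs[["cor.kME"]], rep(1, 3), tolerance = 1e-12)
  expect_equal(obs[["cor.cor"]], rep(1, 3), tolerance = 1e-12)
  expect_equal(obs$cor_kME_all, rep(1, 3), tolerance = 1e-12)
})

test_that("permuting gene rows of the test matrix destroys connectivity pairing", {
  pe <- planted_expr(4, 25, 0.8, 24, n_background = 0, seed = 8)
  set.seed(3)
  permuted <- pe$values[sample(nrow(pe$values)), ]
  rownames(permuted) <- rownames(pe$values)  # same ids, scrambled content
  obs <- observed_stats(pe$values, permuted, pe$labels)
  expect_lt(abs(mean(obs[["cor.cor"]])), 0.1)
})

test_that("a preserved module is denser in the test data than a random gene set", {
  fx <- two_species_fixture(seed = 21, preserved = c(TRUE, FALSE), n_bg = 120)
  rc <- restrict_to_common(fx$zA, fx$zB, fx$d$map, fx$d$truth$module_of_gene)
  obs <- observed_stats(rc$ref, rc$test, rc$labels)
  set.seed(5)
  rand_lab <- setNames(sample(rc$labels), names(rc$labels))
  rand_obs <- observed_stats(rc$ref, rc$test, rand_lab)
  expect_gt(obs$meanCor[obs$module == 1], rand_obs$meanCor[rand_obs$module == 1])
})

test_that("self-preservation yields strong Zsummary for genuine modules", {
  pe <- planted_expr(3, 25, 0.9, 25, n_background = 100, seed = 4)
  rep <- suppressWarnings(module_preservation(pe$values, pe$values, pe$labels,
                                              n_perm = 100, seed = 2))
  expect_true(all(rep$preservation$Zsummary > 10))
  expect_true(all(rep$quality$Zsummary > 10))
  # exact self-comparison: the connectivity null is degenerate (everything
  # is 1), so Zsummary is carried by the density side
  expect_true(all(is.na(rep$preservation$Zconnectivity)))
  expect_error(module_preservation(pe$values, pe$values, pe$labels, n_perm = 1),
               "n_perm")
})

test_that("preservation Zsummary increases with the planted module correlation", {
  zs <- sapply(c(0.3, 0.6, 0.9), function(rho) {
    sp <- synth_spec(n_genes_A = 300, n_conditions_A = 30, n_conditions_B = 30,
                     module_sizes = c(30, 30), preserved_flags = c(TRUE, TRUE),
                     within_module_cor = rho, ortholog_fraction = 1, seed = 31)
    d <- gen_two_species(sp)
    rc <- restrict_to_common(robust_z(d$exprA), robust_z(d$exprB), d$map,
                             d$truth$module_of_gene)
    rep <- suppressWarnings(module_preservation(rc$ref, rc$test, rc$labels,
                                                n_perm = 60, seed = 7))
    mean(rep$preservation$Zsummary)
  })
  expect_true(all(diff(zs) > 0))
})

test_that("permutation determinism: same seed, same report", {
  pe <- planted_expr(2, 12, 0.8, 15, n_background = 10, seed = 9)
  r1 <- suppressWarnings(module_preservation(pe$values, pe$values, pe$labels,
                                             n_perm = 30, seed = 5))
  r2 <- suppressWarnings(module_preservation(pe$values, pe$values, pe$labels,
                                             n_perm = 30, seed = 5))
  expect_identical(r1$preservation, r2$preservation)
})

test_that("reproducibility after condition exclusion tracks where the signal lives", {
  # Heterogeneous modules (members with varying loading) and weakly
  # structured background, mimicking real co-expression data where
  # connectivity patterns have a continuum of membership strengths. All
  # module signal lives in conditions 1:12; 13:24 are noise-only.
  set.seed(15)
  n_cond <- 24; sig <- 1:12
  m <- matrix(rnorm(300 * n_cond), 300, n_cond)
  lat <- replicate(5, { l <- rep(0, n_cond); l[sig] <- rnorm(12); l })
  labels <- rep(0L, 300)
  for (k in 1:5) {
    idx <- ((k - 1) * 30 + 1):(k * 30)
    rho_i <- seq(0.55, 0.95, length.out = 30)
    m[idx, ] <- rho_i * matrix(lat[, k], 30, n_cond, byrow = TRUE) +
      sqrt(1 - rho_i^2) * m[idx, ]
    labels[idx] <- k
  }
  extras <- replicate(8, { l <- rep(0, n_cond); l[sig] <- rnorm(12); l })
  for (g in 151:300) {
    f <- sample(8, 1); r <- runif(1, 0, 0.35)
    m[g, ] <- r * extras[, f] + sqrt(1 - r^2) * m[g, ]
  }
  dimnames(m) <- list(sprintf("g%03d", 1:300), sprintf("c%03d", 1:n_cond))
  labels <- setNames(labels, rownames(m))

  # excluding the noise-only conditions keeps every module reproducible
  rep1 <- suppressWarnings(reproducibility_in_subset(
    m, sprintf("c%03d", 13:24), labels, n_perm = 60, seed = 3))
  expect_true(all(rep1$preservation$th5))

  # excluding the only conditions where the modules vary abolishes them
  rep2 <- suppressWarnings(reproducibility_in_subset(
    m, sprintf("c%03d", sig), labels, n_perm = 60, seed = 3))
  expect_true(all(rep2$preservation$Zsummary < 2))

  expect_error(reproducibility_in_subset(m, colnames(m), labels), "all conditions")
})
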