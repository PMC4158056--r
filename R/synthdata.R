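#' Specification for the two-species synthetic generator
#'
#' The defaults emulate the data regime of the study system this package
#' was designed around: a reference bacterium with a few thousand genes
#' measured over ~23 conditions, a second species with more conditions, a
#' one-to-one ortholog subset covering roughly 60% of the genes, planted
#' co-expression modules spanning sizes ~15-400 of which about a third are
#' preserved in the second species, a small proteomics-like layer (6
#' conditions, missing values), and a packaging signal with one module
#' shifted by 3 MAD units.
#'
#' `background_fraction` is derived from `n_genes_A` and `module_sizes`
#' (genes not in a planted module are background). Passing
#' `background_fraction = 1` is the degenerate switch meaning "no planted
#' modules"; any other explicit value must match the derived fraction.
#'
#' @param n_genes_A total genes in species A.
#' @param n_conditions_A,n_conditions_B condition counts per species.
#' @param module_sizes planted module sizes (each >= 2, sum <= n_genes_A).
#' @param preserved_flags logical, one per module: is the module's
#'   co-expression structure preserved in species B?
#' @param within_module_cor target gene-eigenprofile correlation rho in
#'   (0, 1).
#' @param background_fraction see Details; usually left `NULL`.
#' @param ortholog_fraction fraction of A genes with a one-to-one B
#'   ortholog, in (0, 1].
#' @param proteome_n_conditions conditions in the proteomics-like layer
#'   (<= `n_conditions_A`).
#' @param proteome_noise_sd Gaussian noise sd added to the proteome layer.
#' @param proteome_missing_rate missing-at-random cell rate in `[0, 1)`.
#' @param packaging_shift shift (in MAD-like units) applied to the packaged
#'   module's packaging scores; 0 plants no effect.
#' @param seed integer seed; all generators are pure functions of
#'   (spec, seed).
#' @return validated list of class `synth_spec`.
#' @export
synth_spec <- function(n_genes_A = 2000, n_conditions_A = 23,
                       n_conditions_B = 40,
                       module_sizes = c(400, 250, 150, 100, 80, 60, 40, 25, 15),
                       preserved_flags = c(TRUE, FALSE, TRUE, FALSE, FALSE,
                                           TRUE, FALSE, FALSE, TRUE),
                       within_module_cor = 0.8, background_fraction = NULL,
                       ortholog_fraction = 0.6, proteome_n_conditions = 6,
                       proteome_noise_sd = 0.5, proteome_missing_rate = 0.1,
                       packaging_shift = 3, seed = 1L) {
  if (!is.null(background_fraction) && background_fraction == 1) {
    module_sizes <- integer(0)
    preserved_flags <- logical(0)
  }
  if (length(module_sizes) != length(preserved_flags))
    stop("invariant violated: len(preserved_flags) == len(module_sizes)")
  if (length(module_sizes) && any(module_sizes < 2))
    stop("invariant violated: all module_sizes >= 2")
  if (sum(module_sizes) > n_genes_A)
    stop("invariant violated: sum(module_sizes) <= n_genes_A")
  derived_bf <- 1 - sum(module_sizes) / n_genes_A
  if (!is.null(background_fraction) && background_fraction != 1 &&
      abs(background_fraction - derived_bf) > 0.5 / n_genes_A)
    stop("background_fraction inconsistent with n_genes_A and module_sizes ",
         sprintf("(derived %.4f)", derived_bf))
  if (within_module_cor <= 0 || within_module_cor >= 1)
    stop("within_module_cor must be in (0, 1)")
  if (ortholog_fraction <= 0 || ortholog_fraction > 1)
    stop("ortholog_fraction must be in (0, 1]")
  if (proteome_n_conditions > n_conditions_A)
    stop("proteome_n_conditions must be <= n_conditions_A")
  if (proteome_missing_rate < 0 || proteome_missing_rate >= 1)
    stop("proteome_missing_rate must be in [0, 1)")
  if (proteome_noise_sd < 0) stop("proteome_noise_sd must be >= 0")
  structure(list(n_genes_A = as.integer(n_genes_A),
                 n_conditions_A = as.integer(n_conditions_A),
                 n_conditions_B = as.integer(n_conditions_B),
                 module_sizes = as.integer(module_sizes),
                 preserved_flags = preserved_flags,
                 within_module_cor = within_module_cor,
                 background_fraction = derived_bf,
                 ortholog_fraction = ortholog_fraction,
                 proteome_n_conditions = as.integer(proteome_n_conditions),
                 proteome_noise_sd = proteome_noise_sd,
                 proteome_missing_rate = proteome_missing_rate,
                 packaging_shift = packaging_shift,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

.as_spec <- function(spec) {
  if (inherits(spec, "synth_spec")) spec else do.call(synth_spec, spec)
}

# rho * latent + sqrt(1 - rho^2) * noise, one row per member gene
.module_block <- function(latent, n_members, rho) {
  C <- length(latent)
  noise <- matrix(rnorm(n_members * C), n_members, C)
  rho * matrix(latent, n_members, C, byrow = TRUE) + sqrt(1 - rho^2) * noise
}

#' Generate a two-species expression dataset with planted module structure
#'
#' Species A: each planted module is driven by a latent standard-normal
#' profile over A's conditions; member genes are
#' `rho * latent + sqrt(1 - rho^2) * noise`; background genes are pure
#' noise. Species B holds one ortholog per sampled A gene plus extra
#' B-only noise genes. Preserved modules re-draw their latent profile over
#' B's own conditions with the same membership (ortholog-consistent);
#' non-preserved modules' B members are randomly re-partitioned into
#' equally sized groups driven by fresh, independent latent profiles, so
#' module size is held constant while the cross-species connectivity
#' pattern is destroyed. Deterministic given `spec$seed` (each layer uses a
#' fixed seed offset).
#'
#' @param spec [synth_spec()].
#' @return list with `exprA`, `exprB` (both `expr_matrix`, tag
#'   `"averaged"`), `map` (data.frame `ref_gene`, `test_gene`), and `truth`
#'   (list: `module_of_gene`, `preserved`, `ortholog_pairs`,
#'   `packaged_module`, `b_partition`).
#' @export
gen_two_species <- function(spec) {
  spec <- .as_spec(spec)
  nA <- spec$n_genes_A
  CA <- spec$n_conditions_A
  CB <- spec$n_conditions_B
  sizes <- spec$module_sizes
  M <- length(sizes)
  rho <- spec$within_module_cor
  genesA <- sprintf("ga%04d", seq_len(nA))
  condsA <- sprintf("ca%03d", seq_len(CA))
  condsB <- sprintf("cb%03d", seq_len(CB))

  labels <- rep(0L, nA)
  if (M) labels[seq_len(sum(sizes))] <- rep(seq_len(M), sizes)
  names(labels) <- genesA

  set.seed(spec$seed + 1L)  # species A layer
  A <- matrix(rnorm(nA * CA), nA, CA, dimnames = list(genesA, condsA))
  for (m in seq_len(M)) {
    latent <- rnorm(CA)
    A[labels == m, ] <- .module_block(latent, sizes[m], rho)
  }

  set.seed(spec$seed + 2L)  # ortholog sampling
  n_orth <- round(spec$ortholog_fraction * nA)
  orthA <- sort(sample(genesA, n_orth))
  map <- data.frame(ref_gene = orthA,
                    test_gene = sprintf("gb%04d", seq_len(n_orth)),
                    stringsAsFactors = FALSE)

  set.seed(spec$seed + 3L)  # species B layer
  n_extra <- ceiling(0.1 * nA)  # B-only noise genes
  genesB <- c(map$test_gene, sprintf("gx%04d", seq_len(n_extra)))
  B <- matrix(rnorm(length(genesB) * CB), length(genesB), CB,
              dimnames = list(genesB, condsB))
  lab_orth <- labels[map$ref_gene]
  b_labels <- setNames(rep(0L, length(genesB)), genesB)
  for (m in seq_len(M)) {
    members <- map$test_gene[lab_orth == m]
    if (length(members) < 2) next
    if (spec$preserved_flags[m]) {
      latentB <- rnorm(CB)
      B[members, ] <- .module_block(latentB, length(members), rho)
      b_labels[members] <- m
    }
  }
  # Non-preserved modules: B modules of the same sizes exist, but their
  # membership is re-drawn from the pool of non-preserved-module and
  # background orthologs. Sizes are held constant (no size confound) while
  # a reference module's genes become exchangeable with a random draw, so
  # its cross-species density and connectivity signal is destroyed.
  np_idx <- which(lab_orth > 0 & !spec$preserved_flags[pmax(lab_orth, 1)])
  if (length(np_idx) >= 2) {
    pool_genes <- map$test_gene[lab_orth == 0 | (lab_orth > 0 &
                                !spec$preserved_flags[pmax(lab_orth, 1)])]
    pool <- sample(pool_genes)
    group_sizes <- as.vector(table(lab_orth[np_idx]))
    start <- 1L
    for (g in seq_along(group_sizes)) {
      sz <- min(group_sizes[g], length(pool) - start + 1L)
      if (sz < 2) break
      members <- pool[start:(start + sz - 1L)]
      start <- start + sz
      latentB <- rnorm(CB)
      B[members, ] <- .module_block(latentB, length(members), rho)
      b_labels[members] <- M + g
    }
  }

  packaged <- if (spec$packaging_shift != 0 && M >= 1) 1L else NA_integer_
  truth <- list(module_of_gene = labels,
                preserved = if (M) setNames(spec$preserved_flags, seq_len(M))
                            else setNames(logical(0), integer(0)),
                ortholog_pairs = map,
                packaged_module = packaged,
                b_partition = b_labels)
  list(exprA = expr_matrix(A, "averaged"),
       exprB = expr_matrix(B, "averaged"),
       map = map, truth = truth)
}

#' Generate a proteomics-like layer from species A
#'
#' Selects a random half of A's genes and a random subset of its
#' conditions, adds Gaussian noise, and masks cells missing-at-random.
#'
#' @param exprA species A `expr_matrix` (from [gen_two_species()]).
#' @param spec [synth_spec()].
#' @return `expr_matrix` (tag preserved from the input) with `has_missing`
#'   set when cells were masked.
#' @export
gen_proteomics <- function(exprA, spec) {
  spec <- .as_spec(spec)
  v <- .values(exprA)
  if (spec$proteome_n_conditions > ncol(v))
    stop("proteome_n_conditions exceeds the available conditions")
  set.seed(spec$seed + 101L)
  genes <- sort(sample(rownames(v), ceiling(nrow(v) / 2)))
  conds <- sort(sample(ncol(v), spec$proteome_n_conditions))
  p <- v[genes, conds, drop = FALSE]
  if (spec$proteome_noise_sd > 0)
    p <- p + matrix(rnorm(length(p), sd = spec$proteome_noise_sd),
                    nrow(p), ncol(p))
  if (spec$proteome_missing_rate > 0) {
    mask <- matrix(runif(length(p)) < spec$proteome_missing_rate,
                   nrow(p), ncol(p))
    p[mask] <- NA_real_
  }
  expr_matrix(p, .standardization(exprA))
}

#' Generate a per-gene DNA packaging signal
#'
#' Background genes get standard-normal scores; genes of the packaged
#' module (recorded in the truth) are shifted by `packaging_shift`.
#'
#' @param truth `truth` element of [gen_two_species()].
#' @param spec [synth_spec()].
#' @return named numeric vector over the species A genes.
#' @export
gen_packaging_signal <- function(truth, spec) {
  spec <- .as_spec(spec)
  labels <- truth$module_of_gene
  set.seed(spec$seed + 202L)
  scores <- rnorm(length(labels))
  names(scores) <- names(labels)
  pm <- truth$packaged_module
  if (!is.na(pm)) {
    if (!pm %in% labels)
      stop("unknown packaged module label: ", pm)
    scores[labels == pm] <- scores[labels == pm] + spec$packaging_shift
  }
  scores
}
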