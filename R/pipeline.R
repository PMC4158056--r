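#' Pipeline configuration
#'
#' Collects every stage's parameters plus a single global seed from which
#' all stage seeds are derived by fixed offsets. In simulation mode
#' (`simulate = TRUE`, the default) the inputs are generated by
#' [gen_two_species()]; otherwise `paths` must name existing `expr_a`,
#' `expr_b` and `orthologs` files (validated before any computation).
#'
#' @param seed global integer seed.
#' @param simulate generate inputs with the bundled synthetic generator.
#' @param synth [synth_spec()] used when simulating (its seed is overridden
#'   by `seed`).
#' @param network [network_params()].
#' @param n_perm_preservation label permutations for module preservation.
#' @param lns_n_perm ortholog-map randomizations for the LNS null.
#' @param within_n_rep split-half repeats for within-species LNS (0 skips).
#' @param stability_n_resamples module-stability resamples (0 skips).
#' @param condition_n_boot gene bootstraps for condition clustering
#'   (0 skips).
#' @param ora_fdr ORA significance threshold.
#' @param packaging_n_random,packaging_alpha,packaging_frac packaging-test
#'   parameters.
#' @param paths named list of input file paths (non-simulation mode).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, simulate = TRUE, synth = synth_spec(),
                       network = network_params(),
                       n_perm_preservation = 200, lns_n_perm = 100,
                       within_n_rep = 50, stability_n_resamples = 0,
                       condition_n_boot = 1000, ora_fdr = 0.05,
                       packaging_n_random = 1000, packaging_alpha = 0.01,
                       packaging_frac = 0.85, paths = list()) {
  cfg <- list(seed = as.integer(seed), simulate = simulate, synth = synth,
              network = network, n_perm_preservation = n_perm_preservation,
              lns_n_perm = lns_n_perm, within_n_rep = within_n_rep,
              stability_n_resamples = stability_n_resamples,
              condition_n_boot = condition_n_boot, ora_fdr = ora_fdr,
              packaging_n_random = packaging_n_random,
              packaging_alpha = packaging_alpha,
              packaging_frac = packaging_frac, paths = paths)
  class(cfg) <- "run_config"
  cfg
}

.write_df <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rhodonet %s", .rhodonet_version()),
               paste0("# ", comments)), con)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) gsub(" ", "", formatC(x, format = "g", digits = 15)))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full comparative co-expression pipeline
#'
#' Stages, mirroring the analysis order the package implements: data
#' generation (or loading), robust z-standardization, signed network and
#' module detection in the reference species, condition-cluster bootstrap,
#' module preservation against the second species and against the
#' proteomics layer, LNS with randomization nulls (cross-species,
#' mRNA-protein, and within-species split-half), median-LNS per module and
#' its correlation with cor.kMEall, over-representation analysis, and the
#' packaging permutation test. All artifacts are written as
#' comment-headered TSVs plus a JSON manifest with md5 digests; a rerun
#' with the same config reproduces every output bit-identically.
#'
#' @param config [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  # validation-first: all referenced inputs must exist before any compute
  if (!config$simulate) {
    need <- c("expr_a", "expr_b", "orthologs")
    missing_paths <- need[!vapply(need, function(p)
      !is.null(config$paths[[p]]) && file.exists(config$paths[[p]]), TRUE)]
    if (length(missing_paths))
      stop("missing input file(s): ", paste(missing_paths, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  res <- list(config = config)

  message("[data] ", if (config$simulate) "simulating inputs" else "loading inputs")
  if (config$simulate) {
    spec <- config$synth
    spec$seed <- seed
    sim <- gen_two_species(spec)
    exprA <- sim$exprA; exprB <- sim$exprB; map <- sim$map
    truth <- sim$truth
    proteome <- gen_proteomics(exprA, spec)
    packaging <- gen_packaging_signal(truth, spec)
    write_expr_tsv(exprA, file.path(out_dir, "exprA.tsv"),
                   sprintf("seed: %d", seed))
    write_expr_tsv(exprB, file.path(out_dir, "exprB.tsv"),
                   sprintf("seed: %d", seed))
    write_expr_tsv(proteome, file.path(out_dir, "proteome.tsv"),
                   sprintf("seed: %d", seed))
    .write_df(map, file.path(out_dir, "orthologs.tsv"))
    .write_df(data.frame(gene = names(packaging), score = unname(packaging)),
              file.path(out_dir, "packaging.tsv"))
    jsonlite::write_json(
      list(module_of_gene = as.list(truth$module_of_gene),
           preserved = as.list(truth$preserved),
           packaged_module = truth$packaged_module),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE)
    res$truth <- truth
  } else {
    exprA <- read_expr_tsv(config$paths$expr_a, "averaged")
    exprB <- read_expr_tsv(config$paths$expr_b, "averaged")
    map <- read_orthologs_tsv(config$paths$orthologs)
    proteome <- if (!is.null(config$paths$proteome))
      read_expr_tsv(config$paths$proteome, "averaged") else NULL
    packaging <- if (!is.null(config$paths$packaging)) {
      df <- read.delim(config$paths$packaging, comment.char = "#")
      setNames(df[[2]], df[[1]])
    } else NULL
    truth <- NULL
  }

  message("[preprocess] robust z-scores")
  zA <- robust_z(exprA)
  zB <- robust_z(exprB)

  message("[network] module detection in the reference species")
  params <- config$network
  params$seed <- seed + 11L
  part <- detect_modules(zA, params)
  res$partition <- part
  write_partition_tsv(part, file.path(out_dir, "partition.tsv"),
                      sprintf("seed: %d", seed))
  if (!is.null(part$eigengenes)) {
    eg <- data.frame(condition = rownames(part$eigengenes), part$eigengenes)
    .write_df(eg, file.path(out_dir, "eigengenes.tsv"))
    km <- data.frame(gene = rownames(part$kme), part$kme, check.names = FALSE)
    .write_df(km, file.path(out_dir, "kme.tsv"))
  }

  if (config$condition_n_boot > 0) {
    message("[network] condition dendrogram bootstrap")
    cb <- cluster_conditions_bootstrap(zA, config$condition_n_boot,
                                       seed = seed + 12L)
    .write_df(data.frame(node = seq_along(cb$support),
                         height = cb$hclust$height, bp = cb$support),
              file.path(out_dir, "condition_bootstrap.tsv"))
    res$condition_bootstrap <- cb
  }
  if (config$stability_n_resamples > 0) {
    message("[network] module stability resampling")
    st <- module_stability(zA, params, config$stability_n_resamples,
                           reference = part)
    .write_df(st, file.path(out_dir, "stability.tsv"))
    res$stability <- st
  }

  message("[preservation] reference vs second species")
  rc <- restrict_to_common(zA, zB, map, part)
  pres_b <- module_preservation(rc$ref, rc$test, rc$labels, params,
                                n_perm = config$n_perm_preservation,
                                seed = seed + 21L)
  res$preservation_b <- pres_b
  .write_df(pres_b$preservation, file.path(out_dir, "preservation_b.tsv"),
            sprintf("n_perm: %d seed: %d", pres_b$n_perm, pres_b$seed))
  .write_df(pres_b$quality, file.path(out_dir, "quality_b.tsv"))

  pres_p <- NULL
  if (!is.null(proteome)) {
    message("[preservation] mRNA vs protein")
    pv <- .values(proteome)
    pv <- pv[rowSums(!is.na(pv)) >= 3, , drop = FALSE]  # z-scoreable rows
    zP <- filter_missing(zscore(central_tendency_normalize(pv)), 2)
    pmap <- data.frame(ref_gene = intersect(gene_ids(zA), rownames(.values(zP))),
                       stringsAsFactors = FALSE)
    pmap$test_gene <- pmap$ref_gene
    rcp <- restrict_to_common(zA, zP, pmap, part)
    pres_p <- module_preservation(rcp$ref, rcp$test, rcp$labels, params,
                                  n_perm = config$n_perm_preservation,
                                  seed = seed + 22L)
    res$preservation_prot <- pres_p
    .write_df(pres_p$preservation, file.path(out_dir, "preservation_prot.tsv"))
  }

  message("[lns] cross-species LNS with randomization null")
  lns_b <- lns_from_expr(zA, zB, map, n_perm = config$lns_n_perm,
                         seed = seed + 31L)
  med <- median_lns_per_module(lns_b$table, part$labels)
  lns_b$table$module <- .labels_of(part)[lns_b$table$ref_gene]
  lns_b$table$median_lns_of_module <-
    unname(med[as.character(lns_b$table$module)])
  .write_df(lns_b$table, file.path(out_dir, "lns.tsv"),
            sprintf("n_perm: %d seed: %d", lns_b$n_perm, lns_b$seed))
  .write_df(data.frame(module = names(med), median_lns = unname(med)),
            file.path(out_dir, "median_lns.tsv"))
  res$lns_b <- lns_b
  res$median_lns <- med
  res$lns_kmeall <- tryCatch(lns_vs_kmeall(med, pres_b), error = function(e) NULL)

  if (config$within_n_rep > 0) {
    message("[lns] within-species split-half LNS")
    wl <- within_species_lns(zA, n_rep = config$within_n_rep,
                             seed = seed + 32L)
    .write_df(data.frame(gene = names(wl$mean_lns),
                         mean_lns = unname(wl$mean_lns)),
              file.path(out_dir, "within_lns.tsv"))
    res$within_lns <- wl
  }

  message("[genesets] over-representation analysis")
  universe <- gene_ids(zA)
  sets <- if (!is.null(config$paths$gmt)) {
    read_gmt(config$paths$gmt)
  } else if (config$simulate && any(part$labels > 0) && !is.null(truth)) {
    # planted modules as sets plus size-matched random decoys
    tl <- truth$module_of_gene
    s <- lapply(sort(unique(tl[tl > 0])), function(m) names(tl)[tl == m])
    names(s) <- paste0("planted_", sort(unique(tl[tl > 0])))
    set.seed(seed + 41L)
    decoys <- lapply(seq_len(10), function(i) sample(universe, 30))
    names(decoys) <- paste0("decoy_", seq_len(10))
    c(s, decoys)
  } else NULL
  if (!is.null(sets)) {
    enr <- ora(part, sets, universe, fdr_threshold = config$ora_fdr)
    .write_df(enr, file.path(out_dir, "enrichment.tsv"))
    res$enrichment <- enr
  }

  if (!is.null(packaging)) {
    message("[genesets] packaging permutation test")
    pk <- packaging_test(packaging, part,
                         n_random = config$packaging_n_random,
                         alpha = config$packaging_alpha,
                         frac = config$packaging_frac, seed = seed + 42L)
    .write_df(pk, file.path(out_dir, "packaging_verdicts.tsv"),
              c(sprintf("criterion: one-sided rank-sum tests per random set at alpha=%g;",
                        config$packaging_alpha),
                sprintf("packaged when > %g of %d random sets beaten and none beat the module",
                        config$packaging_frac, config$packaging_n_random)))
    res$packaging <- pk
  }

  files <- sort(list.files(out_dir, pattern = "\\.(tsv|json)$"))
  files <- setdiff(files, "manifest.json")
  digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(digests) <- files
  manifest <- list(tool = "rhodonet", version = .rhodonet_version(),
                   seed = seed,
                   parameters = list(
                     beta = params$beta,
                     min_module_size = params$min_module_size,
                     merge_cut_height = params$merge_cut_height,
                     n_perm_preservation = config$n_perm_preservation,
                     lns_n_perm = config$lns_n_perm,
                     within_n_rep = config$within_n_rep,
                     packaging_n_random = config$packaging_n_random),
                   digests = digests)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
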