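#' Network construction and module-detection parameters
#'
#' Defaults follow the published construction: biweight midcorrelation
#' raised to soft-threshold power `beta = 18` in a signed network, minimum
#' module size 15, gene reassignment threshold 0, PAM stage not respecting
#' the dendrogram, and topological overlap as the clustering similarity.
#'
#' @param beta soft-threshold power (>= 1).
#' @param min_module_size smallest allowed module (>= 2).
#' @param merge_cut_height modules whose eigengene dissimilarity
#'   `1 - cor(ME)` falls below this are merged.
#' @param deep_split integer 0-4; larger values prefer deeper (finer) branch
#'   cuts when several cut heights yield the same number of modules.
#' @param use_tom cluster on 1 - TOM (otherwise 1 - adjacency).
#' @param reassign_threshold with the default 0, a gene moves to another
#'   module only when its kME there strictly exceeds kME in its own module.
#' @param pam_respects_dendro when `TRUE`, unassigned genes may only join
#'   the module nearest to them in the dendrogram dissimilarity.
#' @param min_kme module-membership (kME) gate of the PAM-like stage: an
#'   unassigned gene joins a module only when its kME there reaches this
#'   value, and an assigned gene whose own-module kME falls below it is
#'   released. The default `NULL` resolves at run time to
#'   `3 / sqrt(n_conditions)`, three standard errors of a null correlation,
#'   so spurious clusters of uncorrelated genes dissolve regardless of the
#'   condition count.
#' @param seed RNG seed used by resampling utilities.
#' @return list of class `network_params`.
#' @export
network_params <- function(beta = 18, min_module_size = 15,
                           merge_cut_height = 0.15, deep_split = 2,
                           use_tom = TRUE, reassign_threshold = 0,
                           pam_respects_dendro = FALSE, min_kme = NULL,
                           seed = 1L) {
  if (beta < 1) stop("beta must be >= 1")
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  if (merge_cut_height < 0 || merge_cut_height > 1)
    stop("merge_cut_height must be in [0, 1]")
  if (!deep_split %in% 0:4) stop("deep_split must be an integer in 0..4")
  structure(list(beta = beta, min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height, deep_split = deep_split,
                 use_tom = use_tom, reassign_threshold = reassign_threshold,
                 pam_respects_dendro = pam_respects_dendro, min_kme = min_kme,
                 seed = as.integer(seed)),
            class = "network_params")
}

# conventional size-ordered module color palette (label 0 = "grey")
.module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta", "sienna3", "yellowgreen", "skyblue3",
  "plum1", "orangered4", "mediumpurple3")

#' Map integer module labels to conventional color names
#'
#' Label 0 is `"grey"`; labels 1, 2, 3, ... (size-ordered) map to the
#' conventional palette starting turquoise, blue, brown, ...
#'
#' @param labels integer module labels.
#' @return character vector of color names.
#' @export
module_colors <- function(labels) {
  out <- ifelse(labels == 0, "grey",
                ifelse(labels <= length(.module_colors),
                       .module_colors[pmax(labels, 1)],
                       paste0("module", labels)))
  names(out) <- names(labels)
  out
}

# relabel nonzero modules 1..m by decreasing size (ties: smaller old label first)
.relabel_by_size <- function(labels) {
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) return(labels)
  sizes <- sapply(mods, function(m) sum(labels == m))
  ord <- mods[order(-sizes, mods)]
  new <- labels
  for (k in seq_along(ord)) new[labels == ord[k]] <- k
  new
}

# Static-cut scan: choose the cut height maximizing the number of clusters
# of size >= min_size; among maximizing heights deep_split picks the
# quantile (4 = lowest / finest, 0 = highest / coarsest).
.adaptive_cut <- function(hc, min_size, deep_split) {
  hts <- sort(unique(hc$height))
  if (length(hts) > 1) {
    cand <- (hts[-length(hts)] + hts[-1]) / 2
  } else {
    cand <- hts / 2
  }
  cand <- c(hts[1] / 2, cand)
  cuts <- cutree(hc, h = cand)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1)
  counts <- apply(cuts, 2, function(cl) sum(table(cl) >= min_size))
  best <- max(counts)
  if (best == 0) return(setNames(rep(0L, length(hc$labels)), hc$labels))
  at <- which(counts == best)
  pick <- at[round((1 - deep_split / 4) * (length(at) - 1)) + 1]
  cl <- cuts[, pick]
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  out <- ifelse(cl %in% keep, match(cl, keep), 0L)
  setNames(as.integer(out), hc$labels)
}

#' Detect co-expression modules
#'
#' Single-block pipeline: biweight midcorrelation, signed soft-threshold
#' adjacency, topological overlap (optional), average-linkage clustering of
#' the dissimilarity, an adaptive branch cut honoring the minimum module
#' size, a PAM-like stage that rescues unassigned genes by module
#' membership (kME) and reassigns genes whose kME is strictly higher in
#' another module, eigengene-correlation merging, and a final relabeling of
#' modules by decreasing size. Deterministic given the input (genes are
#' ordered lexicographically internally so gene-row permutations do not
#' change the partition).
#'
#' @param expr `expr_matrix` or matrix (genes x conditions).
#' @param params [network_params()].
#' @return list of class `module_partition` with elements `labels` (named
#'   integer vector, 0 = unassigned), `colors`, `eigengenes`,
#'   `prop_var_explained`, `kme`, `dendro` (the gene `hclust`), `params`.
#' @export
detect_modules <- function(expr, params = network_params()) {
  v <- .values(expr)
  if (nrow(v) < 2 * params$min_module_size)
    stop("need at least 2 * min_module_size genes")
  if (ncol(v) < 4) stop("need at least 4 conditions")
  v <- v[order(rownames(v)), , drop = FALSE]  # lexicographic tie-break

  cr <- bicor_matrix(v, warn_fallback = FALSE)
  if (anyNA(cr)) stop("undefined correlations (constant genes?); filter the input")
  adj <- signed_adjacency(cr, params$beta)
  sim <- if (params$use_tom) tom_similarity(adj) else adj
  diss <- 1 - sim
  hc <- hclust(as.dist(diss), method = "average")

  labels <- .adaptive_cut(hc, params$min_module_size, params$deep_split)
  labels <- labels[rownames(v)]

  min_kme <- params$min_kme %||% (3 / sqrt(ncol(v)))
  if (any(labels > 0)) {
    # PAM-like stage on kME to the core-cluster eigengenes: release weak
    # members, rescue well-fitting unassigned genes, reassign genes whose
    # membership is strictly higher elsewhere
    me <- module_eigengenes(v, labels)
    km <- kme(v, me)
    mods <- me$labels
    for (g in rownames(v)) {
      cand <- mods
      if (params$pam_respects_dendro && labels[g] == 0) {
        # nearest module in dendrogram dissimilarity only
        dmean <- sapply(mods, function(m) mean(diss[g, names(labels)[labels == m]]))
        cand <- mods[which.min(dmean)]
      }
      best <- cand[which.max(km[g, paste0("ME", cand)])]
      bk <- km[g, paste0("ME", best)]
      own <- labels[g]
      own_k <- if (own > 0) km[g, paste0("ME", own)] else -Inf
      if (bk >= min_kme &&
          (own == 0 || own_k < min_kme ||
           (best != own && bk > own_k + params$reassign_threshold))) {
        labels[g] <- best
      } else if (own > 0 && own_k < min_kme) {
        labels[g] <- 0L
      }
    }
    # drop modules pushed below min size by reassignment
    sizes <- table(labels[labels > 0])
    small <- as.integer(names(sizes)[sizes < params$min_module_size])
    labels[labels %in% small] <- 0L

    # merge modules with correlated eigengenes
    repeat {
      mods <- sort(unique(labels[labels > 0]))
      if (length(mods) < 2) break
      me <- module_eigengenes(v, labels)
      cm <- cor(me$eigengenes)
      mh <- hclust(as.dist(1 - cm), method = "average")
      grp <- cutree(mh, h = params$merge_cut_height)
      if (max(grp) == length(mods)) break
      newlab <- labels
      for (gi in unique(grp)) {
        members <- mods[grp == gi]
        newlab[labels %in% members] <- min(members)
      }
      labels <- newlab
    }
  }

  labels <- .relabel_by_size(labels)
  if (any(labels > 0)) {
    me <- module_eigengenes(v, labels)
    km <- kme(v, me)
  } else {
    me <- list(eigengenes = NULL, prop_var_explained = numeric(0))
    km <- NULL
  }
  structure(list(labels = labels, colors = module_colors(labels),
                 eigengenes = me$eigengenes,
                 prop_var_explained = me$prop_var_explained,
                 kme = km, dendro = hc, params = params),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  n <- length(x$labels)
  m <- sum(unique(x$labels) > 0)
  cat(sprintf("module_partition: %d genes, %d modules, %d unassigned\n",
              n, m, sum(x$labels == 0)))
  invisible(x)
}

# extract a plain label vector from a partition or named vector
.labels_of <- function(part) {
  if (inherits(part, "module_partition")) return(part$labels)
  if (is.numeric(part) && !is.null(names(part))) {
    storage.mode(part) <- "integer"
    return(part)
  }
  stop("expected a module_partition or a named integer label vector")
}
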