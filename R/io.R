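#' Read a gene-by-condition TSV matrix
#'
#' First column gene id, header row of condition/sample ids; empty cells or
#' `"NA"` are missing. Lines starting with `#` are comments (the package's
#' writers use them for version/seed headers). Duplicate gene ids, ragged
#' rows and non-numeric cells are rejected with the offending line.
#'
#' @param path TSV file path.
#' @param standardization tag to attach; a `#! standardization:` comment in
#'   the file takes precedence.
#' @return `expr_matrix`.
#' @export
read_expr_tsv <- function(path, standardization = "raw") {
  lines <- readLines(path)
  is_comment <- grepl("^#", lines)
  tagline <- grep("^#! standardization:", lines, value = TRUE)
  if (length(tagline))
    standardization <- trimws(sub("^#! standardization:", "", tagline[1]))
  body_idx <- which(!is_comment & nzchar(lines))
  if (length(body_idx) < 2) stop("no data rows in ", path)
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != ncols[1]))
    stop("ragged row at line ", body_idx[which(ncols != ncols[1])[1]])
  header <- fields[[1]]
  conds <- header[-1]
  ids <- vapply(fields[-1], `[[`, "", 1)
  dup <- duplicated(ids)
  if (any(dup))
    stop("duplicate gene id '", ids[dup][1], "' at line ",
         body_idx[-1][which(dup)[1]])
  cells <- lapply(fields[-1], function(f) f[-1])
  vals <- suppressWarnings(
    vapply(cells, function(x) as.numeric(ifelse(x == "" | x == "NA", NA, x)),
           numeric(length(conds))))
  raw_nonnum <- vapply(seq_along(cells), function(i)
    any(!is.na(cells[[i]]) & cells[[i]] != "" & cells[[i]] != "NA" &
        is.na(suppressWarnings(as.numeric(cells[[i]])))), TRUE)
  if (any(raw_nonnum))
    stop("non-numeric cell at line ", body_idx[-1][which(raw_nonnum)[1]])
  m <- t(matrix(vals, nrow = length(conds), dimnames = list(conds, ids)))
  expr_matrix(m, standardization)
}

#' Write a gene-by-condition TSV matrix
#'
#' Emits a comment header with the package version and the standardization
#' tag (plus any extra comment lines), then the matrix with `NA` for
#' missing cells. `read_expr_tsv(write_expr_tsv(x))` round-trips exactly.
#'
#' @param expr `expr_matrix` or matrix.
#' @param path output path.
#' @param comments optional extra header lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_expr_tsv <- function(expr, path, comments = character(0)) {
  v <- .values(expr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rhodonet %s", .rhodonet_version()),
               paste0("# ", comments),
               sprintf("#! standardization: %s", .standardization(expr))), con)
  writeLines(paste(c("gene", colnames(v)), collapse = "\t"), con)
  body <- apply(v, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "\t"))
  body <- gsub(" ", "", body, fixed = TRUE)
  writeLines(paste(rownames(v), body, sep = "\t"), con)
  invisible(path)
}

.validate_ortholog_map <- function(map) {
  if (!all(c("ref_gene", "test_gene") %in% names(map))) {
    if (ncol(map) < 2) stop("ortholog map needs two columns")
    names(map)[1:2] <- c("ref_gene", "test_gene")
  }
  map$ref_gene <- as.character(map$ref_gene)
  map$test_gene <- as.character(map$test_gene)
  if (anyDuplicated(map$ref_gene))
    stop("ortholog map not one-to-one: duplicate reference gene ",
         map$ref_gene[duplicated(map$ref_gene)][1])
  if (anyDuplicated(map$test_gene))
    stop("ortholog map not one-to-one: duplicate test gene ",
         map$test_gene[duplicated(map$test_gene)][1])
  map
}

#' Read a one-to-one ortholog map (two-column TSV)
#'
#' @param path TSV with columns reference gene, test gene; optional header
#'   and `#` comments. Duplicates in either column are rejected.
#' @return data.frame with columns `ref_gene`, `test_gene`.
#' @export
read_orthologs_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("ortholog map needs two columns")
  .validate_ortholog_map(df[, 1:2])
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. Gene ids are deduplicated within a set; a line without
#' any gene is rejected with its line number.
#'
#' @param path GMT file path.
#' @param category optional category tag applied to all sets in the file
#'   (pathway, protein domain, protein complex, transcription unit, ...).
#' @return named list of gene-id vectors with a `"category"` attribute.
#' @export
read_gmt <- function(path, category = NA_character_) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !grepl("^#", lines))
  sets <- list()
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has no genes (need name, description, >= 1 gene)")
    nm <- f[1]
    if (nm %in% names(sets)) stop("duplicate set name '", nm, "' at line ", i)
    sets[[nm]] <- unique(f[-(1:2)])
  }
  if (!length(sets)) stop("no gene sets in ", path)
  attr(sets, "category") <- setNames(rep(category, length(sets)), names(sets))
  sets
}

#' Write a module partition TSV (gene, module, color)
#'
#' @param part [detect_modules()] result or named label vector.
#' @param path output path.
#' @param comments optional extra header comment lines.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(part, path, comments = character(0)) {
  labels <- .labels_of(part)
  df <- data.frame(gene = names(labels), module = unname(labels),
                   color = unname(module_colors(labels)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rhodonet %s", .rhodonet_version()),
               paste0("# ", comments)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a module partition TSV
#'
#' @param path file written by [write_partition_tsv()].
#' @return named integer label vector.
#' @export
read_partition_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  setNames(as.integer(df$module), df$gene)
}
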