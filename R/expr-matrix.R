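#' Expression matrix container
#'
#' A light container for a gene-by-condition numeric matrix with unique row
#' (gene) and column (condition) labels, a standardization tag recording
#' where the matrix sits in the preprocessing chain, and a missing-value
#' flag. All analysis functions in the package accept either an
#' `expr_matrix` or a plain labelled numeric matrix.
#'
#' @param values numeric matrix, genes in rows, conditions in columns, with
#'   unique `rownames` and `colnames`. `NA` marks missing measurements.
#' @param standardization one of `"raw"`, `"log2"`, `"averaged"`,
#'   `"robust_z"`, `"z"`.
#' @return An object of class `expr_matrix` with fields `values`,
#'   `standardization`, `has_missing`.
#' @export
expr_matrix <- function(values, standardization = "raw") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and condition colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate condition ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  standardization <- match.arg(standardization,
                               c("raw", "log2", "averaged", "robust_z", "z"))
  structure(list(values = values,
                 standardization = standardization,
                 has_missing = anyNA(values)),
            class = "expr_matrix")
}

#' @export
as.matrix.expr_matrix <- function(x, ...) x$values

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d conditions [%s]%s\n",
              nrow(x$values), ncol(x$values), x$standardization,
              if (x$has_missing) ", has missing values" else ""))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
gene_ids <- function(x) rownames(.values(x))

#' @rdname expr_matrix
#' @export
condition_ids <- function(x) colnames(.values(x))

# Accept expr_matrix or plain labelled matrix everywhere.
.values <- function(x) {
  if (inherits(x, "expr_matrix")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) {
    if (is.null(rownames(x))) rownames(x) <- sprintf("g%04d", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- sprintf("c%03d", seq_len(ncol(x)))
    return(x)
  }
  stop("expected an expr_matrix or a numeric matrix")
}

.standardization <- function(x) {
  if (inherits(x, "expr_matrix")) x$standardization else "raw"
}
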