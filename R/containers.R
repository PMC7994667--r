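#' Expression-matrix container
#'
#' Light list-based container (in the style of limma's `EList`) holding a
#' features x samples grid of log2 abundances or log2 ratios together with
#' the per-column sample design and a layer tag.
#'
#' @param values numeric matrix, features x samples; rownames are feature
#'   ids, colnames are sample ids.
#' @param design sample design data.frame (one row per column of `values`).
#' @param layer one of `"protein"`, `"phospho"`, `"metabolite"`, `"mrna"`.
#' @param row_flags optional data.frame of per-feature flags (e.g. MaxQuant
#'   reverse / contaminant markers), carried as an attribute.
#' @return object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, design, layer = c("protein", "phospho",
                                                        "metabolite", "mrna"),
                              row_flags = NULL) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (ncol(values) != nrow(design)) {
    stop("design has ", nrow(design), " rows but the matrix has ",
         ncol(values), " columns")
  }
  if (is.null(rownames(values))) {
    stop("values must have rownames (feature ids)")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated feature id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  validate_design(design, require_reference = FALSE)
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), as.character(design$sample_id))) {
    stop("column names of values do not match design$sample_id")
  }
  colnames(values) <- design$sample_id
  obj <- list(values = values, design = design, layer = layer)
  if (!is.null(row_flags)) attr(obj, "row_flags") <- row_flags
  class(obj) <- "ExpressionMatrix"
  obj
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix [", x$layer, "]: ", nrow(x$values), " features x ",
      ncol(x$values), " samples\n", sep = "")
  cat("treatments:", paste(unique(x$design$treatment), collapse = ", "), "\n")
  cat("plexes:", paste(unique(x$design$plex), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

n_features <- function(m) nrow(m$values)

#' Subset an ExpressionMatrix by features and/or samples
#'
#' @param m ExpressionMatrix.
#' @param features character or logical/integer selector of rows.
#' @param samples character or logical/integer selector of columns.
#' @return subsetted ExpressionMatrix.
#' @export
subset_matrix <- function(m, features = NULL, samples = NULL) {
  v <- m$values
  d <- m$design
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, d$sample_id)
    v <- v[, samples, drop = FALSE]
    d <- d[samples, , drop = FALSE]
  }
  expression_matrix(v, d, m$layer, row_flags = attr(m, "row_flags"))
}
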