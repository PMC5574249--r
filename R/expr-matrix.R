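#' Expression matrix container
#'
#' A light container for a genes-by-samples expression matrix with an
#' explicit missingness mask and optional per-sample batch labels. The mask
#' is kept separate from the values so that a stage can flag an entry as
#' missing (e.g. low-signal probes) without destroying the measured number.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique rownames (gene or probe identifiers) and unique colnames
#'   (sample identifiers).
#' @param mask Logical matrix of the same dimension; `TRUE` marks a missing
#'   entry. Defaults to `is.na(values)`.
#' @param batch Optional per-sample batch labels (character or factor),
#'   either named by sample or in column order.
#'
#' @return An object of class `expr_matrix` with fields `values`, `mask`
#'   and `batch`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expr_matrix(m)
#' dim(em)
expr_matrix <- function(values, mask = NULL, batch = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "brcaness_input_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have rownames (genes) and colnames (samples).",
          class = "brcaness_input_error")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    abort(paste0("Duplicated gene identifier: ", dup),
          class = "brcaness_input_error")
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    abort(paste0("Duplicated sample identifier: ", dup),
          class = "brcaness_input_error")
  }
  if (is.null(mask)) mask <- is.na(values)
  if (!is.logical(mask) || !identical(dim(mask), dim(values))) {
    abort("`mask` must be a logical matrix with the dimensions of `values`.",
          class = "brcaness_input_error")
  }
  dimnames(mask) <- dimnames(values)
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (!is.null(names(batch))) {
      if (!setequal(names(batch), colnames(values))) {
        abort("`batch` names must match the sample identifiers.",
              class = "brcaness_input_error")
      }
      batch <- batch[colnames(values)]
    } else if (length(batch) != ncol(values)) {
      abort("`batch` must have one label per sample.",
            class = "brcaness_input_error")
    }
    batch <- setNames(as.character(batch), colnames(values))
  }
  structure(list(values = values, mask = mask, batch = batch),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Values with masked entries set to NA
#'
#' @param x An `expr_matrix`.
#' @return A numeric matrix where every masked entry is `NA`.
#' @export
masked_values <- function(x) {
  v <- x$values
  v[x$mask] <- NA_real_
  v
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples", nrow(x$values),
              ncol(x$values)))
  nmiss <- sum(x$mask)
  if (nmiss > 0) cat(sprintf(", %d missing entries", nmiss))
  if (!is.null(x$batch)) {
    cat(sprintf(", %d batches", length(unique(x$batch))))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.matrix.expr_matrix <- function(x, ...) masked_values(x)

#' Convert an expression matrix to a long tibble
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `value`,
#'   `missing`, and `batch` when batch labels are present.
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  out <- tibble(
    gene_id = rep(gene_ids(x), times = ncol(x$values)),
    sample_id = rep(sample_ids(x), each = nrow(x$values)),
    value = as.vector(x$values),
    missing = as.vector(x$mask)
  )
  if (!is.null(x$batch)) out$batch <- unname(x$batch[out$sample_id])
  out
}

# internal: rebuild with new values/mask, preserving batch
update_expr <- function(x, values = x$values, mask = x$mask) {
  expr_matrix(values, mask = mask, batch = x$batch)
}

as_expr_matrix <- function(x, batch = NULL) {
  if (inherits(x, "expr_matrix")) {
    if (!is.null(batch)) return(expr_matrix(x$values, x$mask, batch))
    return(x)
  }
  expr_matrix(as.matrix(x), batch = batch)
}
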