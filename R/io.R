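# write a data frame as TSV with doubles at %.17g (exact round-trip; the
# default shortest-representation formatting stops at 16 significant digits)
write_tsv_full <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      col <- sprintf("%.17g", df[[j]])
      col[is.na(df[[j]])] <- NA_character_
      df[[j]] <- col
    }
  }
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read and write expression matrices as TSV
#'
#' Tab-separated, genes in rows: the first column holds the gene (or probe)
#' identifier and the header row the sample identifiers. Values are written
#' at full double precision; masked entries are written as `NA`.
#'
#' @param m An [expr_matrix].
#' @param path File path.
#' @return `write_expression_tsv()` returns `path` invisibly;
#'   `read_expression_tsv()` returns an [expr_matrix].
#' @export
write_expression_tsv <- function(m, path) {
  m <- as_expr_matrix(m)
  df <- as.data.frame(masked_values(m))
  df <- cbind(gene_id = rownames(df), df)
  write_tsv_full(df, path)
}

#' @rdname write_expression_tsv
#' @param batch Optional per-sample batch labels to attach on read.
#' @export
read_expression_tsv <- function(path, batch = NULL) {
  # parse numbers via as.numeric (correctly-rounded strtod) rather than the
  # fast approximate parser, so written values are recovered bit-exactly
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          .default = readr::col_character()))
  if (ncol(df) < 2) {
    abort("Expression TSV needs a gene column and at least one sample.",
          class = "brcaness_io_error")
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicated gene identifier: ",
                 ids[duplicated(ids)][1]),
          class = "brcaness_io_error")
  }
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) {
    abort(paste0("Duplicated sample identifier: ",
                 samples[duplicated(samples)][1]),
          class = "brcaness_io_error")
  }
  v <- matrix(NA_real_, length(ids), length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    raw <- df[[j + 1]]
    col <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(col) & !is.na(raw) & raw != "NA")
    if (length(bad) > 0) {
      abort(paste0("Malformed value in column ", samples[j],
                   " at data row ", bad[1]),
            class = "brcaness_io_error")
    }
    v[, j] <- col
  }
  expr_matrix(v, batch = batch)
}

#' Read and write sample annotation as TSV
#'
#' Columns `sample_id`, `label` (logical) and optionally `batch`.
#'
#' @param samples A tibble with at least `sample_id` and `label`.
#' @param path File path.
#' @return The annotation tibble (readers) or `path` invisibly (writers).
#' @export
write_annotation_tsv <- function(samples, path) {
  if (!all(c("sample_id", "label") %in% names(samples))) {
    abort("Annotation needs columns `sample_id` and `label`.",
          class = "brcaness_io_error")
  }
  write_tsv_full(samples, path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    abort("Annotation needs columns `sample_id` and `label`.",
          class = "brcaness_io_error")
  }
  if (anyDuplicated(df$sample_id)) {
    abort(paste0("Duplicated sample identifier: ",
                 df$sample_id[duplicated(df$sample_id)][1]),
          class = "brcaness_io_error")
  }
  df$label <- as.logical(df$label)
  if (anyNA(df$label)) {
    bad <- which(is.na(df$label))[1]
    abort(paste0("Unparseable label at data row ", bad),
          class = "brcaness_io_error")
  }
  df
}

#' Read and write per-patient trial tables as TSV
#'
#' Columns `patient_id`, `arm`, `biomarker`, `hr_status`,
#' `tumor_size_cat` (may be empty) and `pcr`.
#'
#' @param table A trial table.
#' @param path File path.
#' @return The validated trial tibble (reader) or `path` invisibly
#'   (writer).
#' @export
write_trial_tsv <- function(table, path) {
  write_tsv_full(table, path)
}

#' @rdname write_trial_tsv
#' @export
read_trial_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          .default = readr::col_character()))
  if ("patient_id" %in% names(df) && anyDuplicated(df$patient_id)) {
    abort(paste0("Duplicated patient identifier: ",
                 df$patient_id[duplicated(df$patient_id)][1]),
          class = "brcaness_io_error")
  }
  if (!"pcr" %in% names(df)) {
    abort("Trial table is missing column: pcr",
          class = "brcaness_io_error")
  }
  pcr <- suppressWarnings(as.numeric(df$pcr))
  bad_pcr <- which(is.na(pcr) | !pcr %in% c(0, 1))
  if (length(bad_pcr) > 0) {
    abort(paste0("Malformed pcr value at data row ", bad_pcr[1]),
          class = "brcaness_io_error")
  }
  df$pcr <- as.integer(pcr)
  out <- check_trial(df)
  class(out) <- c("trial_table", class(out))
  out
}

#' Read and write the portable signature model as JSON
#'
#' The JSON object has fields `genes`, `centroid_pos`, `centroid_neg` and
#' `threshold`, written at full double precision.
#'
#' @param model A `signature_model` from [fit_centroids()].
#' @param path File path.
#' @return The model (reader) or `path` invisibly (writer).
#' @export
write_signature_model <- function(model, path) {
  if (!inherits(model, "signature_model")) {
    abort("`model` must be a signature_model.",
          class = "brcaness_io_error")
  }
  jsonlite::write_json(
    list(genes = model$genes,
         centroid_pos = as.numeric(model$centroid_pos),
         centroid_neg = as.numeric(model$centroid_neg),
         threshold = model$threshold),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("genes", "centroid_pos", "centroid_neg", "threshold")
  miss <- setdiff(need, names(obj))
  if (length(miss) > 0) {
    abort(paste0("Signature model JSON is missing field: ", miss[1]),
          class = "brcaness_schema_error")
  }
  if (length(obj$genes) != length(obj$centroid_pos) ||
      length(obj$genes) != length(obj$centroid_neg)) {
    abort("Centroid lengths must match the gene list.",
          class = "brcaness_schema_error")
  }
  structure(list(genes = as.character(obj$genes),
                 centroid_pos = setNames(as.numeric(obj$centroid_pos),
                                         obj$genes),
                 centroid_neg = setNames(as.numeric(obj$centroid_neg),
                                         obj$genes),
                 threshold = as.numeric(obj$threshold)),
            class = "signature_model")
}
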