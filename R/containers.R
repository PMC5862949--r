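#' Construct a validated expression matrix
#'
#' The central data container of the package: a dense matrix of log2
#' intensities (genes in rows, samples in columns) together with the
#' condition label and replicate index of every sample. All downstream
#' contrasts and set-activity profiles consume this container.
#'
#' @param values numeric matrix, genes x samples, with row and column names.
#'   Values are log2 intensities and must be finite; missing entries are
#'   rejected rather than silently imputed.
#' @param condition character vector of condition labels, either named by
#'   sample id or given in column order.
#' @param replicate optional integer vector of replicate indices, same
#'   conventions as `condition`. Defaults to 1..k within each condition.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values`, `condition` (named), and `replicate` (named).
#' @export
expression_matrix <- function(values, condition, replicate = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("non-finite expression values; impute or remove them explicitly ",
         "before constructing the matrix")
  samples <- colnames(values)
  condition <- .align_sample_vector(condition, samples, "condition")
  if (anyNA(condition) || any(!nzchar(condition))) {
    missing <- samples[is.na(condition) | !nzchar(condition)]
    stop("no condition for sample(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(samples), condition, FUN = seq_along)
    names(replicate) <- samples
  } else {
    replicate <- .align_sample_vector(replicate, samples, "replicate")
    replicate <- as.integer(replicate)
    names(replicate) <- samples
  }
  structure(list(values = values,
                 condition = condition,
                 replicate = replicate),
            class = "ExpressionMatrix")
}

.align_sample_vector <- function(x, samples, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(samples, names(x))
    if (length(missing) > 0)
      stop("annotation missing for sample(s): ",
           paste(missing, collapse = ", "))
    x <- x[samples]
  } else if (length(x) != length(samples)) {
    stop("'", what, "' must be named by sample or have one entry per sample")
  } else {
    names(x) <- samples
  }
  x
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  tab <- table(x$condition)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Condition labels of an expression matrix
#' @param x an `ExpressionMatrix`
#' @return named character vector, one condition per sample
#' @export
conditions <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  x$condition
}

#' Construct a gene-set collection
#'
#' A named list of gene sets in the style of an MSigDB collection (MIR,
#' TFT, Biocarta, ...). Member symbols are case-normalized to upper case
#' and deduplicated; set names must be unique and sets non-empty.
#'
#' @param sets named list of character vectors of gene symbols
#' @param name collection label, e.g. `"MIR"`
#' @return object of class `GeneSetCollection`
#' @export
gene_set_collection <- function(sets, name = "collection") {
  if (!is.list(sets)) stop("'sets' must be a list of character vectors")
  if (length(sets) > 0) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
      stop("every set must be named")
    if (anyDuplicated(names(sets)))
      stop("duplicate set name(s): ",
           paste(unique(names(sets)[duplicated(names(sets))]),
                 collapse = ", "))
    sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
    empty <- vapply(sets, length, 1L) == 0L
    if (any(empty))
      stop("empty set(s): ", paste(names(sets)[empty], collapse = ", "))
  }
  structure(list(name = name, sets = sets), class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  sizes <- vapply(x$sets, length, 1L)
  cat("GeneSetCollection '", x$name, "': ", length(x$sets), " sets",
      if (length(sizes)) paste0(" (", min(sizes), "-", max(sizes),
                                " genes each)"), "\n", sep = "")
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Construct a validated clinical table
#'
#' Per-patient survival and treatment-response annotation: overall and
#' recurrence-free survival (months, with 0/1 event indicators) and chemo
#' response. Unknown responses are preserved, never coerced.
#'
#' @param df data frame with columns `patient_id`, `os_time`, `os_event`,
#'   `rfs_time`, `rfs_event`, `chemo_response`; additional columns are kept
#'   as covariates.
#' @return the validated data frame with class `ClinicalTable`
#' @export
clinical_table <- function(df) {
  required <- c("patient_id", "os_time", "os_event",
                "rfs_time", "rfs_event", "chemo_response")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("clinical table missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient identifiers")
  for (col in c("os_time", "rfs_time"))
    if (any(!is.finite(df[[col]])) || any(df[[col]] < 0))
      stop("'", col, "' must be non-negative and finite")
  for (col in c("os_event", "rfs_event"))
    if (!all(df[[col]] %in% c(0, 1)))
      stop("'", col, "' must be 0/1")
  ok <- c("sensitive", "resistant", "unknown")
  if (!all(df$chemo_response %in% ok))
    stop("'chemo_response' must be one of: ", paste(ok, collapse = ", "))
  class(df) <- c("ClinicalTable", "data.frame")
  df
}
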