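#' Read a tab-separated expression matrix with sample annotation
#'
#' The matrix file has a header row of sample identifiers and a first
#' column of gene symbols; the annotation file is tab-separated with
#' columns `sample`, `condition` and optionally `replicate`. Duplicate
#' gene rows (multiple probes per symbol) are collapsed to the probe with
#' the highest mean intensity, standard practice for symbol-level set
#' matching.
#'
#' @param path path to the TSV expression file
#' @param annotation_path path to the TSV sample annotation file
#' @param collapse rule for duplicate gene rows; only `"max-mean"` (keep
#'   the row with the largest mean) is implemented
#' @return an [expression_matrix()]
#' @export
read_expression <- function(path, annotation_path, collapse = "max-mean") {
  collapse <- match.arg(collapse, "max-mean")
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", sep = "\t")
  if (ncol(raw) < 2) stop("expression file needs gene ids plus >=1 sample")
  genes <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat),
                                dimnames = dimnames(mat)))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric value '%s' at row %d (gene %s), column '%s'",
                 mat[bad[1, 1], bad[1, 2]], bad[1, 1], genes[bad[1, 1]],
                 colnames(mat)[bad[1, 2]]))
  if (anyNA(num))
    stop("missing expression values; impute or remove them before loading")
  rownames(num) <- genes
  if (anyDuplicated(genes)) {
    n_in <- nrow(num)
    means <- rowMeans(num)
    keep <- unlist(lapply(split(seq_len(n_in), genes),
                          function(i) i[which.max(means[i])]),
                   use.names = FALSE)
    num <- num[sort(keep), , drop = FALSE]
    message(sprintf(
      "collapsed duplicate gene rows by rule '%s': %d rows in, %d out",
      collapse, n_in, nrow(num)))
  }
  ann <- utils::read.delim(annotation_path, header = TRUE,
                           check.names = FALSE, sep = "\t",
                           colClasses = "character")
  if (!all(c("sample", "condition") %in% names(ann)))
    stop("annotation must have columns 'sample' and 'condition'")
  cond <- stats::setNames(ann$condition, ann$sample)
  repl <- if ("replicate" %in% names(ann))
    stats::setNames(as.integer(ann$replicate), ann$sample) else NULL
  expression_matrix(num, cond, repl)
}

#' Write an expression matrix and its annotation
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces them exactly.
#'
#' @param x an `ExpressionMatrix`
#' @param path output TSV for the matrix
#' @param annotation_path output TSV for the sample annotation
#' @export
write_expression <- function(x, path, annotation_path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  fmt <- array(sprintf("%.17g", v), dim = dim(v), dimnames = dimnames(v))
  df <- data.frame(gene = rownames(v), fmt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(sample = colnames(v),
                    condition = unname(x$condition),
                    replicate = unname(x$replicate),
                    stringsAsFactors = FALSE)
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, annotation_path))
}

#' Read a GMT gene-set file
#'
#' One set per line: set name, description, then member symbols, all
#' tab-separated. The description field is discarded, members are
#' case-normalized and deduplicated per set.
#'
#' @param path path to the GMT file
#' @param name collection label; defaults to the file name without extension
#' @return a [gene_set_collection()]
#' @export
read_gmt <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(gene_set_collection(stats::setNames(list(), character(0)), name))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0)
    stop("GMT line ", short[1], " has fewer than 3 fields")
  set_names <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(set_names))
    stop("duplicate set name(s) in GMT: ",
         paste(unique(set_names[duplicated(set_names)]), collapse = ", "))
  sets <- lapply(fields, function(f) f[-c(1, 2)])
  names(sets) <- set_names
  gene_set_collection(sets, name)
}

#' Write a gene-set collection in GMT format
#' @param collection a `GeneSetCollection`
#' @param path output path
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table from CSV
#' @param path CSV path with a header row
#' @return a [clinical_table()]
#' @export
read_clinical <- function(path) {
  clinical_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a clinical table to CSV
#' @param x a `ClinicalTable`
#' @param path output path
#' @export
write_clinical <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
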