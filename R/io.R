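#' Read and write pipeline artifacts
#'
#' Plain-text formats used throughout: beta and detection-p matrices as TSV
#' with probes as rows and samples as columns; sample sheets as CSV;
#' pyrosequencing tables as long CSV (`locus_id`, `sample_id`, `percent`);
#' models and reports as JSON.
#'
#' @param beta,detp Numeric matrix, probes x samples.
#' @param path File path.
#' @name meth_io
NULL

#' @rdname meth_io
#' @export
write_beta_tsv <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname meth_io
#' @export
read_beta_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname meth_io
#' @param samples Sample sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname meth_io
#' @export
read_sample_sheet <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname meth_io
#' @param pyro Loci x samples percent-methylation matrix with `NA`.
#' @export
write_pyro_csv <- function(pyro, path) {
  long <- data.frame(
    locus_id = rep(rownames(pyro), times = ncol(pyro)),
    sample_id = rep(colnames(pyro), each = nrow(pyro)),
    percent = as.vector(pyro),
    stringsAsFactors = FALSE
  )
  long <- long[!is.na(long$percent), , drop = FALSE]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname meth_io
#' @param sample_ids Full sample universe (columns of the returned matrix);
#'   defaults to the samples present in the file.
#' @export
read_pyro_csv <- function(path, sample_ids = NULL) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  loci <- unique(long$locus_id)
  if (is.null(sample_ids)) sample_ids <- unique(long$sample_id)
  m <- matrix(NA_real_, length(loci), length(sample_ids),
              dimnames = list(loci, sample_ids))
  m[cbind(long$locus_id, long$sample_id)] <- long$percent
  m
}

#' @rdname meth_io
#' @param model A `meth_logistic_model`.
#' @export
write_model_json <- function(model, path) {
  x <- unclass(model)
  for (nm in c("ref_means", "ref_sds", "coefficients"))
    x[[nm]] <- as.list(x[[nm]])       # keep marker names in the JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname meth_io
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$ref_means <- unlist(x$ref_means)
  x$ref_sds <- unlist(x$ref_sds)
  x$coefficients <- unlist(x$coefficients)
  x$marker_ids <- as.character(x$marker_ids)
  x$dropped_markers <- as.character(x$dropped_markers)
  structure(x, class = "meth_logistic_model")
}
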