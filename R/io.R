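#' Read a compatibility matrix from MatrixMarket files
#'
#' Reads an MTX file (coordinate, real, general; 1-based indices per the
#' MatrixMarket standard) of conditional read probabilities, optionally a
#' two-column row-weights TSV (`row`, `weight`), and optionally a
#' transcript-metadata TSV with columns `transcript_id`, `gene_id`,
#' `effective_length`.
#'
#' @param mtx_path path to the `.mtx` file.
#' @param weights_path optional path to the row-weights TSV.
#' @param meta_path optional path to the transcript metadata TSV.
#' @param collapse collapse identical rows (default TRUE).
#' @return a [read_compat]; when metadata is given, with `transcript_ids`
#'   set and attributes `gene_id` and `effective_length`.
#' @export
read_compat_mtx <- function(mtx_path, weights_path = NULL,
                            meta_path = NULL, collapse = TRUE) {
  p <- tryCatch(Matrix::readMM(mtx_path), error = function(e) {
    stop(sprintf("malformed MatrixMarket file '%s': %s",
                 mtx_path, conditionMessage(e)))
  })
  weights <- NULL
  if (!is.null(weights_path)) {
    wtab <- utils::read.delim(weights_path, header = TRUE)
    if (ncol(wtab) < 2L) stop("row-weights TSV needs columns row, weight")
    weights <- integer(nrow(p))
    weights[wtab[[1L]]] <- as.integer(wtab[[2L]])
    if (any(weights < 1L)) stop("row-weights TSV must cover every row")
  }
  ids <- NULL
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- read_transcript_meta(meta_path)
    if (nrow(meta) != ncol(p)) {
      stop("transcript metadata rows must match transcript count")
    }
    ids <- meta$transcript_id
  }
  compat <- read_compat(p, weights = weights, collapse = collapse,
                        transcript_ids = ids)
  if (!is.null(meta)) {
    attr(compat, "gene_id") <- meta$gene_id
    attr(compat, "effective_length") <- meta$effective_length
  }
  compat
}

#' Write a compatibility matrix to MatrixMarket files
#'
#' @param compat a [read_compat].
#' @param mtx_path output `.mtx` path.
#' @param weights_path optional output path for the row-weights TSV.
#' @return `mtx_path`, invisibly.
#' @export
write_compat_mtx <- function(compat, mtx_path, weights_path = NULL) {
  Matrix::writeMM(compat$p, mtx_path)
  if (!is.null(weights_path)) {
    utils::write.table(
      data.frame(row = seq_along(compat$weights), weight = compat$weights),
      weights_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(mtx_path)
}

#' Read a transcript metadata table
#'
#' @param path TSV with columns `transcript_id`, `gene_id`,
#'   `effective_length`.
#' @return a data.frame.
#' @export
read_transcript_meta <- function(path) {
  meta <- utils::read.delim(path, header = TRUE,
                            colClasses = c(transcript_id = "character",
                                           gene_id = "character"))
  need <- c("transcript_id", "gene_id", "effective_length")
  if (!all(need %in% names(meta))) {
    stop(sprintf("transcript metadata must have columns: %s",
                 paste(need, collapse = ", ")))
  }
  if (any(meta$effective_length <= 0)) {
    stop("effective_length must be positive")
  }
  meta
}

#' Write a transcript metadata table
#'
#' @param transcript_ids,gene_ids character vectors.
#' @param effective_lengths positive numeric vector.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_transcript_meta <- function(transcript_ids, gene_ids,
                                  effective_lengths, path) {
  utils::write.table(
    data.frame(transcript_id = transcript_ids, gene_id = gene_ids,
               effective_length = effective_lengths),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
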