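# Omics block container and I/O: reading/writing delimited matrices,
# subject alignment across modalities, variance filtering, z-scoring.

MODALITIES <- c("protein", "mirna", "torna")

#' Construct an omics block
#'
#' An omics block is one modality's subjects x features numeric matrix plus
#' identifier and provenance metadata. Identifiers must be unique and all
#' values finite: the pipeline is complete-case by design, so non-finite
#' cells are a construction error, not something to impute downstream.
#'
#' @param values numeric matrix, subjects in rows, features in columns;
#'   dimnames are used as identifiers when `subject_ids`/`feature_ids` are
#'   not given.
#' @param modality one of `"protein"`, `"mirna"`, `"torna"`.
#' @param subject_ids,feature_ids optional character identifiers.
#' @param scale free-text provenance tag describing the value scale.
#' @return An object of class `omics_block`.
#' @export
omics_block <- function(values, modality,
                        subject_ids = rownames(values),
                        feature_ids = colnames(values),
                        scale = "unknown") {
  modality <- match.arg(modality, MODALITIES)
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("omics block values must be numeric")
  if (is.null(subject_ids) || is.null(feature_ids))
    stop("subject and feature identifiers are required")
  subject_ids <- as.character(subject_ids)
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(subject_ids))
    stop("duplicate subject identifier(s): ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature identifier(s): ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (nrow(values) != length(subject_ids) || ncol(values) != length(feature_ids))
    stop("matrix dimensions do not match identifier lengths")
  if (!all(is.finite(values)))
    stop("non-finite value(s) in ", modality,
         " block; complete, finite matrices are required")
  dimnames(values) <- list(subject_ids, feature_ids)
  structure(
    list(modality = modality, subject_ids = subject_ids,
         feature_ids = feature_ids, values = values, scale = scale),
    class = "omics_block")
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("<omics_block> modality=%s  %d subjects x %d features  scale=%s\n",
              x$modality, length(x$subject_ids), length(x$feature_ids), x$scale))
  invisible(x)
}

#' @export
dim.omics_block <- function(x) dim(x$values)

#' Read an omics matrix from delimited text
#'
#' Expects a header row of feature identifiers and a first column of subject
#' identifiers. Any non-numeric cell, ragged row, or duplicated identifier
#' is an error.
#'
#' @param path file path.
#' @param modality modality name.
#' @param delim field delimiter, `"\t"` (default) or `","`.
#' @param scale provenance tag stored on the block.
#' @return An [omics_block()].
#' @export
read_omics_matrix <- function(path, modality, delim = "\t", scale = "file") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (ncol(df) < 2) stop("expected a subject-ID column plus >=1 feature column")
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = dimnames(mat)))
  bad <- which(is.na(num) & !(mat %in% c("NA", "NaN")))
  if (length(bad))
    stop("non-numeric cell(s) in ", path, ", e.g. '", mat[bad[1]], "'")
  rownames(num) <- ids
  block <- omics_block(num, modality, scale = scale)
  snf_log(sprintf("read %s: %d subjects x %d features", path,
                  nrow(num), ncol(num)))
  block
}

#' Write an omics block as tab-delimited text
#'
#' Inverse of [read_omics_matrix()] (round-trips to ~1e-12).
#'
#' @param block an [omics_block()].
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(block, path, delim = "\t") {
  df <- data.frame(subject = block$subject_ids, block$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align omics blocks to their common subjects
#'
#' Restricts every block to the intersection of subject identifiers, in one
#' canonical (sorted) order, and reports how many subjects each block
#' dropped. The result is the multi-omics dataset all fusion and
#' characterization stages consume.
#'
#' @param blocks list of [omics_block()] objects (>= 2).
#' @return An object of class `multi_omics_dataset`: list with `blocks`
#'   (named by modality) and `subject_ids`.
#' @export
align_subjects <- function(blocks) {
  if (length(blocks) < 2) stop("need at least two blocks to align")
  common <- Reduce(intersect, lapply(blocks, `[[`, "subject_ids"))
  if (length(common) == 0)
    stop("empty subject intersection across blocks")
  common <- sort(common)
  out <- lapply(blocks, function(b) {
    dropped <- setdiff(b$subject_ids, common)
    if (length(dropped))
      snf_log(sprintf("align: dropping %d subject(s) from %s block",
                      length(dropped), b$modality))
    omics_block(b$values[common, , drop = FALSE], b$modality, scale = b$scale)
  })
  names(out) <- vapply(out, `[[`, "", "modality")
  if (anyDuplicated(names(out))) stop("duplicate modality among blocks")
  structure(list(blocks = out, subject_ids = common),
            class = "multi_omics_dataset")
}

#' @export
print.multi_omics_dataset <- function(x, ...) {
  cat(sprintf("<multi_omics_dataset> %d subjects, modalities: %s\n",
              length(x$subject_ids), paste(names(x$blocks), collapse = ", ")))
  invisible(x)
}

#' Keep the most variable features of a block
#'
#' Retains the `ceiling(top_fraction * F)` features with largest sample
#' variance. Ties are broken by feature-identifier lexicographic order so
#' the selection is fully deterministic; survivors keep their original
#' column order.
#'
#' @param block an [omics_block()].
#' @param top_fraction fraction of features to keep, in (0, 1].
#' @return Filtered [omics_block()].
#' @export
variance_filter <- function(block, top_fraction) {
  if (!is.numeric(top_fraction) || length(top_fraction) != 1 ||
      top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  nf <- length(block$feature_ids)
  if (nf == 0) stop("empty block")
  keep_n <- ceiling(top_fraction * nf)
  v <- apply(block$values, 2, stats::var)
  ord <- order(-v, block$feature_ids)
  keep <- sort(ord[seq_len(keep_n)])   # original order among survivors
  omics_block(block$values[, keep, drop = FALSE], block$modality,
              scale = block$scale)
}

#' Z-score each feature of a block
#'
#' Centres and scales every feature column to mean 0, SD 1, so Euclidean
#' distances weight features comparably before network construction.
#' Constant features carry no distance information and are dropped with a
#' warning.
#'
#' @param block an [omics_block()].
#' @return Standardized [omics_block()] (idempotent).
#' @export
standardize_features <- function(block) {
  v <- apply(block$values, 2, stats::sd)
  keep <- v > 0
  if (!any(keep)) stop("no feature with nonzero variance in ",
                       block$modality, " block")
  if (any(!keep))
    warning(sum(!keep), " constant feature(s) dropped from ",
            block$modality, " block during standardization")
  vals <- scale(block$values[, keep, drop = FALSE])
  attr(vals, "scaled:center") <- NULL
  attr(vals, "scaled:scale") <- NULL
  omics_block(vals, block$modality, scale = "z-score")
}
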