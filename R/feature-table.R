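# The feature table: a samples-by-features intensity matrix plus sample and
# feature metadata. Every pipeline stage consumes and returns this object.

.META_COLS <- c("sample_id", "class", "bio_rep", "tech_rep", "qc",
                "injection_order")

#' Construct a feature table
#'
#' @param intensities Non-negative samples-by-features numeric matrix.
#' @param samples Data frame with one row per sample; must contain
#'   `sample_id` (unique), `class`, `bio_rep`, `tech_rep`, `qc` (logical),
#'   `injection_order`.
#' @param features Optional data frame with one row per feature
#'   (`feature_id` unique; typically also `mz`, `rt_min`, `hmdb_id`).
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(intensities, samples, features = NULL) {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) == 0L) stop("feature table has zero samples", call. = FALSE)
  if (any(intensities < 0)) {
    bad <- which(intensities < 0, arr.ind = TRUE)[1, ]
    stop("negative intensity at sample ", bad[1], ", feature ", bad[2],
         call. = FALSE)
  }
  stopifnot(is.data.frame(samples), nrow(samples) == nrow(intensities),
            all(.META_COLS %in% names(samples)))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids", call. = FALSE)
  if (!is.null(features)) {
    stopifnot(is.data.frame(features), nrow(features) == ncol(intensities),
              "feature_id" %in% names(features))
    if (anyDuplicated(features$feature_id)) stop("duplicate feature ids", call. = FALSE)
    colnames(intensities) <- features$feature_id
  } else {
    if (is.null(colnames(intensities))) {
      colnames(intensities) <- paste0("F", seq_len(ncol(intensities)))
    }
    features <- data.frame(feature_id = colnames(intensities),
                           stringsAsFactors = FALSE)
  }
  rownames(intensities) <- samples$sample_id
  structure(list(intensities = intensities, samples = samples,
                 features = features),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$intensities), "samples x",
      ncol(x$intensities), "features\n")
  cat("  classes:", paste(names(table(x$samples$class)), "=",
                          table(x$samples$class), collapse = ", "), "\n")
  cat("  QC samples:", sum(x$samples$qc), "\n")
  invisible(x)
}

#' Write a feature table to CSV
#'
#' Samples as rows; the metadata columns (`sample_id`, `class`, `bio_rep`,
#' `tech_rep`, `qc`, `injection_order`) come first, followed by one column
#' per feature. Feature metadata, when present beyond bare ids, goes to a
#' companion CSV.
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @param features_path Optional path for the feature-metadata CSV.
#' @export
write_feature_table <- function(table, path, features_path = NULL) {
  stopifnot(inherits(table, "feature_table"))
  df <- cbind(table$samples[, .META_COLS],
              as.data.frame(table$intensities, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(features_path)) {
    utils::write.csv(table$features, features_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Inverse of [write_feature_table()]. Validation errors name the offending
#' sample/feature.
#'
#' @param path CSV path (metadata prefix columns then feature columns).
#' @param features_path Optional feature-metadata CSV.
#' @param classes Optional declared class-label set; labels outside it are
#'   an error (QC rows are exempt).
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, features_path = NULL, classes = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_meta <- setdiff(.META_COLS, names(df))
  if (length(missing_meta)) {
    stop("missing metadata column(s): ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  samples <- df[, .META_COLS]
  samples$qc <- as.logical(samples$qc)
  X <- as.matrix(df[, setdiff(names(df), .META_COLS), drop = FALSE])
  if (any(X < 0)) {
    bad <- which(X < 0, arr.ind = TRUE)[1, ]
    stop("negative intensity at sample '", samples$sample_id[bad[1]],
         "', feature '", colnames(X)[bad[2]], "'", call. = FALSE)
  }
  if (!is.null(classes)) {
    unknown <- setdiff(unique(samples$class[!samples$qc]), classes)
    if (length(unknown)) {
      stop("unknown class label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  features <- if (!is.null(features_path)) {
    utils::read.csv(features_path, stringsAsFactors = FALSE)
  } else NULL
  feature_table(X, samples, features)
}

#' Subset a feature table by sample
#'
#' @param table A `feature_table`.
#' @param keep Logical or integer index over samples.
#' @return A `feature_table` with the selected samples.
#' @export
subset_samples <- function(table, keep) {
  stopifnot(inherits(table, "feature_table"))
  feature_table(table$intensities[keep, , drop = FALSE],
                table$samples[keep, , drop = FALSE],
                table$features)
}
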