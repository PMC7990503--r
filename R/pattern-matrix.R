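#' Subject-by-voxel pattern matrices
#'
#' A pattern matrix holds one condition contrast's voxel values per
#' subject, as extracted from a region of interest. The container is a
#' plain numeric matrix (subjects in rows) carrying subject ids and ROI /
#' contrast labels as attributes.
#'
#' @param x Numeric matrix (subjects x voxels) or a data frame whose first
#'   column is `subject_id`.
#' @param subject_ids Subject identifiers; defaults to row numbers (or the
#'   `subject_id` column of a data frame).
#' @param roi_label,contrast_label Free-text labels.
#' @return An `mc_patterns` matrix.
#' @export
as_pattern_matrix <- function(x, subject_ids = NULL, roi_label = "",
                              contrast_label = "") {
  if (is.data.frame(x)) {
    if (names(x)[1] == "subject_id") {
      subject_ids <- subject_ids %||% x$subject_id
      x <- as.matrix(x[, -1, drop = FALSE])
    } else {
      x <- as.matrix(x)
    }
  }
  storage.mode(x) <- "double"
  if (anyNA(x)) abort("pattern matrices may not contain missing values")
  if (ncol(x) < 2) abort("pattern matrices need at least 2 voxels")
  subject_ids <- subject_ids %||% seq_len(nrow(x))
  stopifnot(length(subject_ids) == nrow(x))
  structure(x, subject_ids = subject_ids, roi_label = roi_label,
            contrast_label = contrast_label,
            class = c("mc_patterns", "matrix", "array"))
}

#' @export
print.mc_patterns <- function(x, ...) {
  cat("<mc_patterns: ", nrow(x), " subjects x ", ncol(x), " voxels",
      if (nzchar(attr(x, "roi_label"))) paste0("; ROI ", attr(x, "roi_label")),
      if (nzchar(attr(x, "contrast_label")))
        paste0("; contrast ", attr(x, "contrast_label")),
      ">\n", sep = "")
  invisible(x)
}

#' Read / write pattern matrices as delimited text
#'
#' The interchange format is a CSV with a `subject_id` first column and
#' one column per voxel.
#'
#' @param path File path.
#' @param roi_label,contrast_label Labels attached on read.
#' @return `read_pattern_matrix()` returns an `mc_patterns` matrix;
#'   `write_pattern_matrix()` returns `path` invisibly.
#' @export
read_pattern_matrix <- function(path, roi_label = "", contrast_label = "") {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "subject_id") {
    abort("pattern files must have `subject_id` as their first column")
  }
  as_pattern_matrix(df, roi_label = roi_label,
                    contrast_label = contrast_label)
}

#' @rdname read_pattern_matrix
#' @param patterns An `mc_patterns` matrix.
#' @export
write_pattern_matrix <- function(patterns, path) {
  df <- data.frame(subject_id = attr(patterns, "subject_ids"),
                   unclass(patterns), check.names = FALSE)
  names(df)[-1] <- paste0("v", seq_len(ncol(patterns)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @exportS3Method generics::tidy
tidy.mc_patterns <- function(x, ...) {
  tibble(subject_id = rep(attr(x, "subject_ids"), ncol(x)),
         voxel = rep(seq_len(ncol(x)), each = nrow(x)),
         value = as.vector(unclass(x)))
}
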