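#' Long-format longitudinal view of one dataset
#'
#' A `longitudinal_view` stores one dataset in long format: one row per
#' individual visit, with an individual identifier, an observation time and a
#' numeric feature vector. Individuals may have any number of visits
#' (including none), visit times are arbitrary real numbers, and duplicate
#' `(id, time)` pairs are kept as distinct visits. Missingness is encoded as
#' absent rows; a stored row never contains `NA`.
#'
#' @param ids character (or coercible) vector of individual identifiers, one
#'   per row.
#' @param times numeric vector of observation times, one per row. Units are
#'   study time and are used as-is by the trajectory models.
#' @param features numeric matrix with one row per visit and one column per
#'   feature.
#' @param feature_names optional character vector of feature names; defaults
#'   to the column names of `features` or `V1..Vp`.
#'
#' @return An object of class `longitudinal_view` with elements `ids`,
#'   `times` and `features`.
#' @examples
#' v <- longitudinal_view(c("a", "a", "b"), c(1, 2, 1),
#'                        matrix(rnorm(6), 3, 2))
#' block(v, "a")
#' @export
longitudinal_view <- function(ids, times, features, feature_names = NULL) {
  ids <- as.character(ids)
  times <- as.numeric(times)
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features)) features <- matrix(features, ncol = 1L)
  storage.mode(features) <- "double"
  n <- length(ids)
  if (length(times) != n || nrow(features) != n)
    stop("ids, times and features must have one entry/row per visit")
  if (any(!is.finite(times)))
    stop("observation times must be finite")
  if (anyNA(features))
    stop("stored rows may not contain missing values; encode missingness as absent rows")
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names))
      feature_names <- paste0("V", seq_len(ncol(features)))
  }
  if (length(feature_names) != ncol(features))
    stop("feature_names length must match the number of feature columns")
  colnames(features) <- feature_names
  rownames(features) <- NULL
  structure(list(ids = ids, times = times, features = features),
            class = "longitudinal_view")
}

#' @export
print.longitudinal_view <- function(x, ...) {
  cat("Longitudinal view:", length(unique(x$ids)), "individuals,",
      length(x$ids), "visits,", ncol(x$features), "features\n")
  invisible(x)
}

#' @export
dim.longitudinal_view <- function(x) dim(x$features)

#' Coerce a long-format data frame to a longitudinal view
#'
#' @param df data frame with an id column, a time column and numeric feature
#'   columns.
#' @param id_col,time_col names of the id and time columns.
#' @return A [longitudinal_view()].
#' @export
as_longitudinal_view <- function(df, id_col = "id", time_col = "time") {
  if (inherits(df, "longitudinal_view")) return(df)
  if (!id_col %in% names(df)) stop("id column '", id_col, "' not found")
  if (!time_col %in% names(df)) stop("time column '", time_col, "' not found")
  feat_cols <- setdiff(names(df), c(id_col, time_col))
  feats <- df[feat_cols]
  for (j in seq_along(feats)) {
    col <- feats[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(as.character(col)))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric value in feature column '%s', row %d",
                     feat_cols[j], bad[1L]))
      feats[[j]] <- num
    }
  }
  longitudinal_view(df[[id_col]], df[[time_col]],
                    as.matrix(as.data.frame(feats)),
                    feature_names = feat_cols)
}

infer_delim <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a long-format longitudinal CSV/TSV file
#'
#' The file must have a header row with an id column, a time column and then
#' numeric feature columns. The delimiter is inferred from the extension
#' (`.tsv`/`.txt` are tab-separated, anything else comma-separated).
#' Duplicate `(id, time)` rows are kept as distinct visits. Rows are returned
#' in file order.
#'
#' @param path file path.
#' @param id_col,time_col column names for the individual identifier and the
#'   observation time.
#' @return A [longitudinal_view()].
#' @export
read_long_csv <- function(path, id_col = "id", time_col = "time") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = infer_delim(path),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (!id_col %in% names(df)) stop("id column '", id_col, "' not found in ", path)
  if (!time_col %in% names(df)) stop("time column '", time_col, "' not found in ", path)
  df[[time_col]] <- as.numeric(df[[time_col]])
  as_longitudinal_view(df, id_col = id_col, time_col = time_col)
}

#' Write a longitudinal view to CSV/TSV
#'
#' Floats are written with 17 significant digits so that a
#' read-write-read cycle reproduces the view exactly.
#'
#' @param view a [longitudinal_view()].
#' @param path output path; delimiter inferred from the extension.
#' @param id_col,time_col header names to use for the id and time columns.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(view, path, id_col = "id", time_col = "time") {
  stopifnot(inherits(view, "longitudinal_view"))
  sep <- infer_delim(path)
  fmt <- function(x) sprintf("%.17g", x)
  out <- cbind(view$ids, fmt(view$times),
               apply(view$features, 2L, fmt))
  colnames(out) <- c(id_col, time_col, colnames(view$features))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Standardize the feature columns of a view
#'
#' Centers every column to mean zero and scales to unit sample variance over
#' all rows. Zero-variance columns are centered only and their scale is
#' recorded as 1. Standard preprocessing before canonical correlation
#' analysis, where features must be on comparable scales.
#'
#' @param view a [longitudinal_view()] with at least two rows.
#' @param scale if `FALSE`, only center.
#' @return A list with elements `view` (the standardized view), `centers` and
#'   `scales` (named numeric vectors).
#' @export
standardize_columns <- function(view, scale = TRUE) {
  stopifnot(inherits(view, "longitudinal_view"))
  if (nrow(view$features) < 2L)
    stop("standardization needs at least 2 rows (sample variance undefined)")
  centers <- colMeans(view$features)
  x <- sweep(view$features, 2L, centers, "-")
  if (scale) {
    scales <- apply(x, 2L, stats::sd)
    scales[scales == 0] <- 1
    x <- sweep(x, 2L, scales, "/")
  } else {
    scales <- rep(1, ncol(x))
  }
  names(scales) <- names(centers) <- colnames(view$features)
  list(view = longitudinal_view(view$ids, view$times, x),
       centers = centers, scales = scales)
}

#' Extract one individual's block
#'
#' Returns the `mi x p` feature block and the `mi` observation times for one
#' individual. An unknown id yields a valid `0 x p` block (an individual may
#' be entirely absent from a view).
#'
#' @param view a [longitudinal_view()].
#' @param id individual identifier.
#' @return A list with `times` and `features` (matrix).
#' @export
block <- function(view, id) {
  stopifnot(inherits(view, "longitudinal_view"))
  sel <- view$ids == as.character(id)
  list(times = view$times[sel],
       features = view$features[sel, , drop = FALSE])
}

#' Pair two longitudinal views
#'
#' Bundles an X view (p features) and a Y view (q features) over an
#' overlapping set of individuals. The views may have different visit counts
#' per individual and non-matching time grids; an id present in only one view
#' is retained with a warning (its latent values on the other view are later
#' predicted from fixed effects only).
#'
#' @param x_view,y_view [longitudinal_view()] objects.
#' @return An object of class `paired_longitudinal` with elements `x`, `y`
#'   and `individuals` (sorted union of ids).
#' @export
paired_longitudinal <- function(x_view, y_view) {
  stopifnot(inherits(x_view, "longitudinal_view"),
            inherits(y_view, "longitudinal_view"))
  idx <- unique(x_view$ids)
  idy <- unique(y_view$ids)
  only <- c(setdiff(idx, idy), setdiff(idy, idx))
  if (length(only))
    warning("ids present in only one view (retained): ",
            paste(utils::head(only, 5L), collapse = ", "),
            if (length(only) > 5L) ", ..." else "")
  if (!length(intersect(idx, idy)))
    stop("the two views share no individuals")
  structure(list(x = x_view, y = y_view,
                 individuals = sort(unique(c(idx, idy)))),
            class = "paired_longitudinal")
}

#' @export
print.paired_longitudinal <- function(x, ...) {
  cat("Paired longitudinal data:", length(x$individuals), "individuals\n")
  cat("  X:", length(x$x$ids), "visits x", ncol(x$x$features), "features\n")
  cat("  Y:", length(x$y$ids), "visits x", ncol(x$y$features), "features\n")
  invisible(x)
}

#' Union time grid of a paired dataset
#'
#' @param data a [paired_longitudinal()].
#' @return Sorted unique vector of all observation times in either view.
#' @export
union_times <- function(data) {
  stopifnot(inherits(data, "paired_longitudinal"))
  sort(unique(c(data$x$times, data$y$times)))
}
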