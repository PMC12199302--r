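#' Feature matrix container
#'
#' Frames-by-features numeric matrix with per-feature metadata, the common
#' currency of the pipeline.  Metadata rows carry at least `name` and `kind`
#' (one of contact, coordination, distance, lipid-contact, synthetic-contact,
#' synthetic-distance); fitted scaling statistics are stored in `scale_mean`
#' and `scale_sd` once computed.
#'
#' @param times Frame time stamps (strictly increasing).
#' @param values Numeric matrix, frames x features, no missing values.
#' @param meta Data frame with one row per feature; must contain unique
#'   `name`s matching `colnames(values)` and a `kind` column.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(times, values, meta) {
  values <- as.matrix(values)
  stopifnot(length(times) == nrow(values), !anyNA(values),
            all(diff(times) > 0) || length(times) <= 1)
  if (is.null(colnames(values))) colnames(values) <- meta$name
  stopifnot(identical(colnames(values), meta$name),
            !anyDuplicated(meta$name), "kind" %in% names(meta))
  structure(list(times = as.numeric(times), values = values, meta = meta),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$values), "frames x", ncol(x$values),
      "features\n")
  print(table(x$meta$kind))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset a feature matrix by feature name or index
#' @param fm A `feature_matrix`.
#' @param features Character names or integer/logical index of features.
#' @return A `feature_matrix` with the selected columns and metadata rows.
#' @export
fm_select <- function(fm, features) {
  stopifnot(inherits(fm, "feature_matrix"))
  idx <- if (is.character(features)) match(features, fm$meta$name) else features
  if (is.character(features) && anyNA(idx))
    stop("unknown feature(s): ", paste(features[is.na(idx)], collapse = ", "))
  feature_matrix(fm$times, fm$values[, idx, drop = FALSE],
                 fm$meta[idx, , drop = FALSE])
}

#' Row-bind feature matrices from several paths
#'
#' Pools frames across paths (metadata must agree); a `path` attribute
#' records the provenance of each pooled frame.
#' @param fms List of `feature_matrix` objects with identical features.
#' @return Pooled `feature_matrix` with attribute `path_id` (integer per row)
#'   and `frame_in_path`.
#' @export
fm_pool <- function(fms) {
  stopifnot(length(fms) >= 1)
  nm <- fms[[1]]$meta$name
  for (f in fms) stopifnot(identical(f$meta$name, nm))
  vals <- do.call(rbind, lapply(fms, function(f) f$values))
  path_id <- rep(seq_along(fms), vapply(fms, function(f) nrow(f$values),
                                        integer(1)))
  frame_in_path <- unlist(lapply(fms, function(f) seq_len(nrow(f$values))))
  # pooled times are synthetic (frame index) since paths overlap in time
  out <- feature_matrix(seq_len(nrow(vals)), vals, fms[[1]]$meta)
  attr(out, "path_id") <- path_id
  attr(out, "frame_in_path") <- frame_in_path
  out
}

#' Fit, apply and invert per-feature z-scaling
#'
#' `fm_fit_scaling` records per-feature mean and standard deviation in the
#' metadata; `fm_apply_scaling`/`fm_unscale` transform values with the
#' recorded statistics so that `fm_unscale(fm_apply_scaling(x)) == x` to
#' machine precision.
#'
#' @param fm A `feature_matrix`.
#' @param stats_from Optional `feature_matrix` whose recorded scaling is
#'   reused (e.g. freeze training-pool statistics for test data).
#' @return A `feature_matrix`.
#' @export
fm_fit_scaling <- function(fm) {
  m <- colMeans(fm$values)
  s <- apply(fm$values, 2, stats::sd)
  s[s == 0] <- 1   # constant features pass through unscaled
  fm$meta$scale_mean <- as.numeric(m)
  fm$meta$scale_sd <- as.numeric(s)
  fm
}

#' @rdname fm_fit_scaling
#' @export
fm_apply_scaling <- function(fm, stats_from = NULL) {
  src <- if (is.null(stats_from)) fm else stats_from
  if (is.null(src$meta$scale_mean)) src <- fm_fit_scaling(src)
  fm$meta$scale_mean <- src$meta$scale_mean
  fm$meta$scale_sd <- src$meta$scale_sd
  fm$values <- sweep(sweep(fm$values, 2, src$meta$scale_mean), 2,
                     src$meta$scale_sd, "/")
  attr(fm, "scaled") <- TRUE
  fm
}

#' @rdname fm_fit_scaling
#' @export
fm_unscale <- function(fm) {
  stopifnot(!is.null(fm$meta$scale_mean))
  fm$values <- sweep(sweep(fm$values, 2, fm$meta$scale_sd, "*"), 2,
                     fm$meta$scale_mean, "+")
  attr(fm, "scaled") <- FALSE
  fm
}

#' Write / read a feature matrix as TSV with a metadata header
#'
#' The on-disk format is plain TSV preceded by `#!` header lines holding a
#' JSON block (feature metadata, and any `extra` provenance such as seeds or
#' generator settings), so a file is self-describing.
#'
#' @param fm A `feature_matrix`.
#' @param path File path.
#' @param extra Named list serialized into the header.
#' @return `read_feature_tsv` returns a `feature_matrix` (header `extra`
#'   available as attribute `header`).
#' @export
write_feature_tsv <- function(fm, path, extra = list()) {
  hdr <- jsonlite::toJSON(list(meta = fm$meta, extra = extra),
                          dataframe = "columns", auto_unbox = TRUE,
                          digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#! ", hdr), con)
  df <- data.frame(time = fm$times, fm$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#! ", lines)
  stopifnot(length(hdr_lines) >= 1)
  hdr <- jsonlite::fromJSON(paste(sub("^#! ", "", lines[hdr_lines]),
                                  collapse = ""))
  body <- utils::read.table(text = lines[-hdr_lines], header = TRUE,
                            sep = "\t", check.names = FALSE)
  meta <- as.data.frame(hdr$meta, stringsAsFactors = FALSE)
  fm <- feature_matrix(body$time,
                       as.matrix(body[, meta$name, drop = FALSE]), meta)
  attr(fm, "header") <- hdr$extra
  fm
}
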