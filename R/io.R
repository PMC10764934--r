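#' Construct a single-subject ROI time-series object
#'
#' Wraps a T x R numeric matrix of region-of-interest (ROI) signals with its
#' acquisition metadata. Rows are frames (time points), columns are ROIs;
#' frames are indexed from 1 in R but written 0-based on disk.
#'
#' @param data numeric matrix, T rows (frames) x R columns (ROIs), no missing
#'   values, T >= 2 and R >= 2.
#' @param subject_id character scalar identifying the subject.
#' @param tr_seconds repetition time in seconds (time between frames);
#'   default 2.
#' @param standardized logical; \code{TRUE} once columns have been z-scored.
#' @return An object of class \code{roi_ts}.
#' @seealso [zscore_series()], [load_cohort()]
#' @export
roi_ts <- function(data, subject_id, tr_seconds = 2, standardized = FALSE) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("time series for subject '", subject_id, "' contains missing or non-finite values",
         call. = FALSE)
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop("time series for subject '", subject_id, "' must be at least 2 x 2 (got ",
         nrow(data), " x ", ncol(data), ")", call. = FALSE)
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id))
    stop("`subject_id` must be a non-empty string", call. = FALSE)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("`tr_seconds` must be a positive scalar", call. = FALSE)
  structure(
    list(subject_id = subject_id, data = unname(data),
         tr_seconds = as.numeric(tr_seconds),
         standardized = isTRUE(standardized)),
    class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject '%s': %d frames x %d ROIs, TR = %g s, %s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds,
              if (x$standardized) "standardized (z-units)" else "raw units"))
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$data)

#' Column-wise z-scoring of an ROI time series
#'
#' Converts each ROI's signal to zero mean and unit standard deviation
#' (sample SD, denominator T - 1). Clustering distances downstream are
#' correlation-based, so any consistent SD convention only rescales them.
#'
#' @param ts a \code{roi_ts} object that has not been standardized yet.
#' @return A standardized copy with \code{standardized = TRUE}.
#' @export
zscore_series <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  if (ts$standardized)
    stop("series for subject '", ts$subject_id,
         "' is already standardized; refusing to z-score twice", call. = FALSE)
  m <- colMeans(ts$data)
  s <- apply(ts$data, 2L, stats::sd)
  bad <- which(s <= 0 | !is.finite(s))
  if (length(bad))
    stop("zero-variance ROI column(s) for subject '", ts$subject_id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- ts
  out$data <- sweep(sweep(ts$data, 2L, m, "-"), 2L, s, "/")
  out$standardized <- TRUE
  out
}

#' Read a network atlas table
#'
#' The atlas maps each ROI to exactly one functional network (e.g. the
#' 6-network partition ATN, DMN, SMN, VN, SCN, CN of the 116 AAL regions).
#' Expected CSV header: \code{roi_index,roi_name,network}; \code{roi_index}
#' is 0-based and must cover 0..R-1 contiguously.
#'
#' @param path path to the atlas CSV.
#' @param networks optional character vector of allowed network labels; by
#'   default any non-empty label set is accepted.
#' @return A data.frame with columns \code{roi_index}, \code{roi_name},
#'   \code{network} (factor), ordered by \code{roi_index}.
#' @export
read_atlas <- function(path, networks = NULL) {
  if (!file.exists(path)) stop("atlas file not found: ", path, call. = FALSE)
  at <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_index", "roi_name", "network")
  if (!all(need %in% names(at)))
    stop("atlas must have columns ", paste(need, collapse = ", "), call. = FALSE)
  at <- at[order(at$roi_index), need]
  r <- nrow(at)
  if (!identical(as.integer(at$roi_index), 0:(r - 1L)))
    stop("atlas roi_index must be the contiguous range 0..R-1", call. = FALSE)
  if (any(!nzchar(at$network)) || anyNA(at$network))
    stop("atlas contains empty network labels", call. = FALSE)
  if (!is.null(networks)) {
    unknown <- setdiff(unique(at$network), networks)
    if (length(unknown))
      stop("unknown network label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  at$network <- factor(at$network, levels = unique(at$network))
  rownames(at) <- NULL
  at
}

#' Read a cohort manifest
#'
#' One row per subject with group membership, nuisance covariates and the
#' HAMD-17 symptom score. Expected CSV header:
#' \code{subject_id,group,age,sex,education,site,mean_fd,hamd}. HAMD may be
#' missing (typically for controls).
#'
#' @param path path to the manifest CSV.
#' @return A data.frame; \code{group}, \code{sex} and \code{site} are factors.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path, call. = FALSE)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex", "education", "site", "mean_fd", "hamd")
  miss <- setdiff(need, names(mf))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  mf <- mf[, need]
  dup <- mf$subject_id[duplicated(mf$subject_id)]
  if (length(dup))
    stop("duplicate subject id(s) in manifest: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(mf$mean_fd < 0, na.rm = TRUE))
    stop("mean_fd must be non-negative", call. = FALSE)
  for (v in c("group", "sex", "site")) mf[[v]] <- factor(mf[[v]])
  mf
}

#' Load and validate a full cohort
#'
#' Reads the manifest, one delimited time-series file per subject
#' (\code{<subject_id>.tsv}, T rows x R columns, no header) and the atlas,
#' and checks that every series has the same number of ROIs as the atlas.
#'
#' @param manifest_path path to the cohort manifest CSV.
#' @param series_dir directory containing per-subject \code{<subject_id>.tsv}.
#' @param atlas_path path to the atlas CSV.
#' @param tr_seconds repetition time in seconds applied to every series.
#' @return A list with elements \code{manifest} (data.frame), \code{series}
#'   (named list of \code{roi_ts}, in manifest order) and \code{atlas}.
#' @export
load_cohort <- function(manifest_path, series_dir, atlas_path, tr_seconds = 2) {
  manifest <- read_manifest(manifest_path)
  atlas <- read_atlas(atlas_path)
  r_atlas <- nrow(atlas)
  series <- vector("list", nrow(manifest))
  names(series) <- manifest$subject_id
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    f <- file.path(series_dir, paste0(sid, ".tsv"))
    if (!file.exists(f))
      stop("no time-series file for subject '", sid, "' (expected ", f, ")",
           call. = FALSE)
    mat <- as.matrix(utils::read.table(f, header = FALSE, sep = "\t"))
    storage.mode(mat) <- "double"
    if (ncol(mat) != r_atlas)
      stop("subject '", sid, "' has ", ncol(mat), " ROIs but the atlas has ",
           r_atlas, call. = FALSE)
    series[[i]] <- roi_ts(mat, sid, tr_seconds = tr_seconds)
  }
  list(manifest = manifest, series = series, atlas = atlas)
}

#' Write a cohort to disk
#'
#' Inverse of [load_cohort()]: writes \code{manifest.csv}, \code{atlas.csv}
#' and one \code{<subject_id>.tsv} per subject under \code{dir}. Numeric
#' values are printed with 17 significant digits so a load/write/load
#' round-trip reproduces matrices bit-for-bit.
#'
#' @param cohort list as returned by [load_cohort()] or [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$atlas, file.path(dir, "atlas.csv"), row.names = FALSE)
  sdir <- file.path(dir, "series")
  dir.create(sdir, showWarnings = FALSE)
  for (ts in cohort$series) {
    fmt <- apply(ts$data, c(1, 2), function(v) sprintf("%.17g", v))
    utils::write.table(fmt, file.path(sdir, paste0(ts$subject_id, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(dir)
}

#' Standardize every series in a cohort
#'
#' @param cohort list with a \code{series} element of \code{roi_ts} objects.
#' @return The cohort with all series z-scored.
#' @export
standardize_cohort <- function(cohort) {
  cohort$series <- lapply(cohort$series, zscore_series)
  cohort
}
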