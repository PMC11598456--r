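#' Canonical marker vocabulary
#'
#' The package refers to markers by a fixed canonical vocabulary. Input files
#' may use common synonyms (e.g. `LASI`, `L.ASIS`, `LTOE-2`); these are mapped
#' onto the canonical names at load time. The sacral crest `SACR` may be given
#' directly or is derived as the midpoint of `LPSIS`/`RPSIS`.
#'
#' @return Character vector of canonical marker names.
#' @export
canonical_markers <- function() {
  c("LASIS", "RASIS", "LPSIS", "RPSIS", "SACR",
    "LTOE2", "LTOE3", "RTOE2", "RTOE3", "LHEE", "RHEE")
}

# synonym table: canonical name -> regexes matched case-insensitively after
# stripping separators (".", "_", "-", " ")
.marker_synonyms <- list(
  LASIS = c("^LASIS$", "^LASI$"),
  RASIS = c("^RASIS$", "^RASI$"),
  LPSIS = c("^LPSIS$", "^LPSI$"),
  RPSIS = c("^RPSIS$", "^RPSI$"),
  SACR  = c("^SACR$", "^SACRUM$", "^SACRAL$", "^SACRALCREST$"),
  LTOE2 = c("^LTOE2$", "^LMT2$", "^L2MT$"),
  LTOE3 = c("^LTOE3$", "^LMT3$", "^L3MT$"),
  RTOE2 = c("^RTOE2$", "^RMT2$", "^R2MT$"),
  RTOE3 = c("^RTOE3$", "^RMT3$", "^R3MT$"),
  LHEE  = c("^LHEE$", "^LHEEL$", "^LCAL$"),
  RHEE  = c("^RHEE$", "^RHEEL$", "^RCAL$")
)

#' Map marker names onto the canonical vocabulary
#'
#' Names that match a known synonym (case-insensitively, ignoring `.`/`_`/`-`
#' separators) are replaced by the canonical name; unknown names are kept
#' verbatim. The mapping is idempotent.
#'
#' @param names Character vector of marker names.
#' @return Character vector of the same length.
#' @export
canonicalise_marker_names <- function(names) {
  stripped <- toupper(gsub("[._ -]", "", names))
  out <- names
  for (canon in names(.marker_synonyms)) {
    hit <- Reduce(`|`, lapply(.marker_synonyms[[canon]], grepl, x = stripped))
    out[hit] <- canon
  }
  out
}

#' Construct a marker trial set
#'
#' A `marker_trial` bundles named 3-D marker trajectories recorded in a
#' ground-fixed frame (metres, vertical axis = +z, gravity along -z) with the
#' sampling rate and trial metadata.
#'
#' @param markers Named list of T x 3 numeric matrices (metres).
#' @param rate Sampling frequency in Hz (> 0).
#' @param trial_id Trial label.
#' @param subject_height Subject stature in metres, or `NULL`.
#' @param subject_meta Free-form metadata list.
#' @return An object of class `marker_trial`.
#' @export
marker_trial <- function(markers, rate, trial_id = "trial",
                         subject_height = NULL, subject_meta = list()) {
  if (!is.list(markers) || is.null(names(markers)) || any(names(markers) == ""))
    stop("`markers` must be a named list of T x 3 matrices")
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (ncol(m) != 3L) stop("each marker series must have 3 columns")
    m
  })
  lens <- vapply(markers, nrow, integer(1))
  if (length(unique(lens)) != 1L)
    stop("inconsistent marker series lengths: ",
         paste(sprintf("%s=%d", names(lens), lens), collapse = ", "))
  if (lens[[1]] < 2L) stop("marker series must have at least 2 frames")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a positive scalar (Hz)")
  names(markers) <- canonicalise_marker_names(names(markers))
  structure(
    list(markers = markers, rate = as.numeric(rate),
         trial_id = as.character(trial_id),
         subject_height = subject_height, subject_meta = subject_meta),
    class = "marker_trial")
}

#' @export
print.marker_trial <- function(x, ...) {
  cat(sprintf("<marker_trial '%s': %d markers x %d frames @ %g Hz>\n",
              x$trial_id, length(x$markers), n_frames(x), x$rate))
  invisible(x)
}

#' Number of frames in a trial
#' @param trial A `marker_trial`.
#' @return Integer frame count.
#' @export
n_frames <- function(trial) nrow(trial$markers[[1]])

#' Frame times of a trial
#' @param trial A `marker_trial`.
#' @return Numeric vector of times in seconds, starting at 0.
#' @export
trial_times <- function(trial) (seq_len(n_frames(trial)) - 1L) / trial$rate

#' Check that required markers are present
#'
#' Derives `SACR` from the `LPSIS`/`RPSIS` midpoint when absent, then errors
#' with the names of any still-missing markers.
#'
#' @param trial A `marker_trial`.
#' @param required Character vector of canonical names.
#' @return The (possibly augmented) trial, invisibly usable.
#' @export
require_markers <- function(trial, required) {
  if ("SACR" %in% required && !("SACR" %in% names(trial$markers)) &&
      all(c("LPSIS", "RPSIS") %in% names(trial$markers))) {
    trial$markers$SACR <- (trial$markers$LPSIS + trial$markers$RPSIS) / 2
  }
  missing <- setdiff(required, names(trial$markers))
  if (length(missing))
    stop("missing required marker(s): ", paste(missing, collapse = ", "))
  trial
}

#' Fill short gaps in marker trajectories
#'
#' Linearly interpolates runs of `NA` no longer than `max_gap` frames; longer
#' gaps (or leading/trailing `NA`s) raise an error.
#'
#' @param trial A `marker_trial`.
#' @param max_gap Longest interpolatable gap, frames.
#' @return The gap-filled trial.
#' @export
fill_gaps <- function(trial, max_gap = 10L) {
  trial$markers <- lapply(trial$markers, function(m) {
    for (j in 1:3) {
      v <- m[, j]
      if (!anyNA(v)) next
      r <- rle(is.na(v))
      if (any(r$lengths[r$values] > max_gap))
        stop("marker gap longer than ", max_gap, " frames")
      if (is.na(v[1]) || is.na(v[length(v)]))
        stop("marker series starts or ends with a gap")
      m[, j] <- stats::approx(which(!is.na(v)), v[!is.na(v)],
                              xout = seq_along(v))$y
    }
    m
  })
  trial
}

.read_meta_sidecar <- function(path) {
  side <- paste0(sub("\\.[^.]+$", "", path), ".meta.yaml")
  if (file.exists(side)) yaml::read_yaml(side) else list()
}

#' Load a marker trial from file
#'
#' Supported formats: `trc` (tab-separated with a `DataRate`/`Units` header)
#' and `csv` (one `name_x,name_y,name_z` column triplet per marker, with an
#' optional `<stem>.meta.yaml` sidecar holding `rate`, `units`, `trial_id`,
#' `subject_height`, `y_up`). Positions are returned in metres regardless of
#' file units; marker names are canonicalised. Files recorded with a y-up
#' axis convention are rotated to z-up when `y_up = TRUE` (or when the
#' sidecar says so): (x, y, z) -> (z, x, y).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"trc"` or `"csv"`.
#' @param required Canonical marker names that must be present (after
#'   `SACR` derivation); `NULL` to skip the check.
#' @param y_up Is the file's vertical axis +y? Default `FALSE` (z-up).
#' @param rate Sampling rate override (Hz); required for CSV files without a
#'   sidecar.
#' @return A [marker_trial()].
#' @export
load_trial <- function(path, format = c("auto", "trc", "csv"),
                       required = NULL, y_up = FALSE, rate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, trc = "trc", csv = "csv",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  trial <- switch(format,
                  trc = .load_trc(path),
                  csv = .load_csv(path, rate = rate))
  meta <- trial$subject_meta
  if (isTRUE(meta$y_up) || isTRUE(y_up)) {
    trial$markers <- lapply(trial$markers, function(m)
      cbind(m[, 3], m[, 1], m[, 2], deparse.level = 0))
  }
  if (!is.null(required)) trial <- require_markers(trial, required)
  trial
}

.unit_scale <- function(units) {
  switch(tolower(units), mm = 1e-3, cm = 1e-2, m = 1,
         stop("unknown length unit '", units, "'"))
}

.load_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("malformed TRC file: too short")
  hdr_keys <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- stats::setNames(as.list(hdr_vals), hdr_keys)
  rate <- as.numeric(hdr[["DataRate"]])
  units <- if (!is.null(hdr[["Units"]])) hdr[["Units"]] else "mm"
  name_row <- strsplit(lines[4], "\t")[[1]]
  marker_names <- name_row[-(1:2)]
  marker_names <- marker_names[marker_names != ""]
  dat <- utils::read.table(text = lines[-(1:5)], sep = "\t", header = FALSE,
                           fill = TRUE)
  need <- 2L + 3L * length(marker_names)
  if (ncol(dat) < need) stop("malformed TRC file: expected ", need, " columns")
  scale <- .unit_scale(units)
  markers <- list()
  for (i in seq_along(marker_names)) {
    cols <- 2L + (3L * (i - 1L) + 1L):(3L * i)
    markers[[marker_names[i]]] <- unname(as.matrix(dat[, cols])) * scale
  }
  marker_trial(markers, rate = rate,
               trial_id = tools::file_path_sans_ext(basename(path)))
}

.load_csv <- function(path, rate = NULL) {
  meta <- .read_meta_sidecar(path)
  dat <- utils::read.csv(path, check.names = FALSE)
  nm <- names(dat)
  base <- unique(sub("_[xyz]$", "", nm[grepl("_[xyz]$", nm)]))
  if (!length(base)) stop("malformed CSV: no `name_x,name_y,name_z` columns")
  units <- if (!is.null(meta$units)) meta$units else "m"
  scale <- .unit_scale(units)
  markers <- lapply(base, function(b) {
    cols <- paste0(b, "_", c("x", "y", "z"))
    if (!all(cols %in% nm)) stop("incomplete column triplet for marker ", b)
    unname(as.matrix(dat[, cols])) * scale
  })
  names(markers) <- base
  rate <- if (!is.null(meta$rate)) as.numeric(meta$rate) else rate
  if (is.null(rate)) stop("CSV trial needs a sampling `rate` (sidecar or argument)")
  trial <- marker_trial(markers, rate = rate,
                        trial_id = if (!is.null(meta$trial_id)) meta$trial_id
                                   else tools::file_path_sans_ext(basename(path)))
  if (!is.null(meta$subject_height))
    trial$subject_height <- as.numeric(meta$subject_height)
  trial$subject_meta <- meta
  trial
}

#' Write a marker trial to file
#'
#' Inverse of [load_trial()] for the `trc` and `csv` formats; positions are
#' written in metres (TRC header `Units m`). CSV writes a `.meta.yaml`
#' sidecar with the sampling rate.
#'
#' @param trial A [marker_trial()].
#' @param path Output path.
#' @param format `"auto"`, `"trc"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, format = c("auto", "trc", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), trc = "trc", csv = "csv",
                     stop("cannot infer format for ", path))
  nms <- names(trial$markers)
  T <- n_frames(trial)
  if (format == "trc") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
    writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                     "Units", "OrigDataRate", "OrigDataStartFrame",
                     "OrigNumFrames", sep = "\t"), con)
    writeLines(paste(trial$rate, trial$rate, T, length(nms), "m",
                     trial$rate, 1, T, sep = "\t"), con)
    writeLines(paste(c("Frame#", "Time",
                       as.vector(rbind(nms, "", ""))), collapse = "\t"), con)
    writeLines(paste(c("", "", paste0(rep(c("X", "Y", "Z"), length(nms)),
                                      rep(seq_along(nms), each = 3))),
                     collapse = "\t"), con)
    body <- do.call(cbind, c(list(seq_len(T), trial_times(trial)),
                             unname(trial$markers)))
    utils::write.table(format(body, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    dat <- do.call(cbind, unname(trial$markers))
    colnames(dat) <- as.vector(t(outer(nms, c("_x", "_y", "_z"), paste0)))
    utils::write.csv(data.frame(dat, check.names = FALSE), path,
                     row.names = FALSE)
    side <- paste0(sub("\\.[^.]+$", "", path), ".meta.yaml")
    yaml::write_yaml(list(rate = trial$rate, units = "m",
                          trial_id = trial$trial_id,
                          subject_height = trial$subject_height), side)
  }
  invisible(path)
}
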