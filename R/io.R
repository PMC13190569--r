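#' Write a point cloud to PLY
#'
#' Supports ASCII and binary little-endian PLY with float vertex properties
#' `x`, `y`, `z`.
#'
#' @param points N x 3 numeric matrix (metres).
#' @param path output file path.
#' @param format `"ascii"` or `"binary_little_endian"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(points, path, format = c("ascii", "binary_little_endian")) {
  format <- match.arg(format)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  n <- nrow(points)
  header <- c("ply", paste("format", format, "1.0"),
              paste("element vertex", n),
              "property float x", "property float y", "property float z",
              "end_header")
  if (format == "ascii") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(apply(points, 1, function(r)
      paste(formatC(r, format = "g", digits = 9), collapse = " ")), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeBin(as.numeric(t(points)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a PLY point cloud (ASCII or binary little-endian)
#'
#' @param path PLY file path.
#' @return N x 3 numeric matrix with columns `x`, `y`, `z`.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0)
      edfm_stop("edfm_invalid_argument", "truncated PLY header in %s", path)
    header <- c(header, line)
    if (line == "end_header") break
  }
  if (header[1] != "ply")
    edfm_stop("edfm_invalid_argument", "%s is not a PLY file", path)
  fmt <- strsplit(grep("^format", header, value = TRUE)[1], " +")[[1]][2]
  n <- as.integer(strsplit(grep("^element vertex", header, value = TRUE)[1],
                           " +")[[1]][3])
  props <- grep("^property", header, value = TRUE)
  nprop <- length(props)
  if (nprop < 3)
    edfm_stop("edfm_invalid_argument", "PLY has fewer than 3 vertex properties")
  if (fmt == "ascii") {
    vals <- scan(con, what = numeric(), n = n * nprop, quiet = TRUE)
  } else if (fmt == "binary_little_endian") {
    vals <- readBin(con, numeric(), n = n * nprop, size = 4, endian = "little")
  } else {
    edfm_stop("edfm_invalid_argument", "unsupported PLY format %s", fmt)
  }
  m <- matrix(vals, ncol = nprop, byrow = TRUE)[, 1:3, drop = FALSE]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Write / read a weather record as CSV
#'
#' Dates are ISO-8601, derived from a start date plus the day index.
#'
#' @param weather an `edfm_weather` data.frame.
#' @param path CSV path.
#' @param start_date first day of the record.
#' @return `path` invisibly (writer); `edfm_weather` data.frame (reader).
#' @export
write_weather_csv <- function(weather, path, start_date = as.Date("2025-05-01")) {
  out <- cbind(date = format(start_date + weather$day - 1, "%Y-%m-%d"),
               as.data.frame(weather))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "t_mean", "t_min", "t_max", "par_mol")
  miss <- setdiff(need, names(df))
  if (length(miss))
    edfm_stop("edfm_invalid_argument",
              "weather CSV missing columns: %s", paste(miss, collapse = ", "))
  if (!any(grepl("^theta_", names(df))))
    edfm_stop("edfm_invalid_argument", "weather CSV has no theta_* columns")
  df$date <- NULL
  if (any(!is.finite(as.matrix(df))))
    edfm_stop("edfm_invalid_argument", "weather CSV contains non-finite values")
  class(df) <- c("edfm_weather", "data.frame")
  df
}

#' Join two timestamped streams on nearest timestamp
#'
#' Models the acquisition-synchronisation contract: records from different
#' sensor streams are matched to their nearest counterpart and the join is
#' rejected if any residual exceeds the tolerance.
#'
#' @param a,b data.frames each with a numeric `time` column (seconds).
#' @param tol maximum allowed |time difference| per matched pair, seconds.
#' @return data.frame of matched rows with columns of `a`, columns of `b`
#'   (suffixed `.b`) and the `residual`.
#' @export
align_streams <- function(a, b, tol = 0.1) {
  stopifnot("time" %in% names(a), "time" %in% names(b))
  idx <- vapply(a$time, function(t) which.min(abs(b$time - t)), integer(1))
  resid <- abs(a$time - b$time[idx])
  if (any(resid > tol))
    edfm_stop("edfm_alignment_error",
              "%d record(s) exceed the %.3g s alignment tolerance (worst %.3g s)",
              sum(resid > tol), tol, max(resid))
  bb <- b[idx, , drop = FALSE]
  names(bb) <- paste0(names(bb), ".b")
  cbind(a, bb, residual = resid)
}
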