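#' Raw force-extension trace
#'
#' Container for an optical-trap unzipping record: time, force and extension
#' series at a fixed acquisition rate, taken under either constant-velocity
#' (500 nm/s) or force-ramp (8 pN/s) loading.
#'
#' @param time time stamps (s), strictly increasing.
#' @param force force (pN).
#' @param extension DNA end-to-end extension (nm).
#' @param rate_hz acquisition rate (Hz).
#' @param loading \code{"constant_velocity"} or \code{"force_ramp"}.
#' @return An object of class \code{"unzip_trace"} (a data.frame with columns
#'   \code{time_s}, \code{force_pN}, \code{extension_nm}).
#' @export
unzip_trace <- function(time, force, extension, rate_hz = 1000,
                        loading = c("constant_velocity", "force_ramp")) {
  loading <- match.arg(loading)
  n <- length(time)
  if (n == 0L || length(force) != n || length(extension) != n)
    stop("time, force and extension must be nonempty and of equal length")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  structure(data.frame(time_s = time, force_pN = force,
                       extension_nm = extension),
            class = c("unzip_trace", "data.frame"),
            rate_hz = rate_hz, loading = loading)
}

#' @export
print.unzip_trace <- function(x, ...) {
  cat(sprintf("Unzipping trace: %d samples at %g Hz (%s)\n", nrow(x),
              attr(x, "rate_hz"), attr(x, "loading")))
  cat(sprintf("  force %.1f-%.1f pN, extension %.0f-%.0f nm\n",
              min(x$force_pN), max(x$force_pN), min(x$extension_nm),
              max(x$extension_nm)))
  invisible(x)
}

#' Decimate a trace by block averaging
#'
#' Reduces the acquisition rate by an integer factor, replacing each block of
#' consecutive samples with its mean (as in 10 kHz data decimated with
#' averaging to 1 kHz).
#'
#' @param trace an \code{\link{unzip_trace}}.
#' @param target_hz target rate; must divide the acquisition rate.
#' @return the decimated \code{\link{unzip_trace}}.
#' @export
decimate <- function(trace, target_hz) {
  stopifnot(inherits(trace, "unzip_trace"))
  rate <- attr(trace, "rate_hz")
  factor <- rate / target_hz
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop("target rate must divide the acquisition rate by an integer factor")
  factor <- as.integer(round(factor))
  if (factor == 1L) return(trace)
  n <- (nrow(trace) %/% factor) * factor
  bm <- function(v) colMeans(matrix(v[seq_len(n)], nrow = factor))
  unzip_trace(bm(trace$time_s), bm(trace$force_pN), bm(trace$extension_nm),
              rate_hz = target_hz, loading = attr(trace, "loading"))
}

#' Write / read a trace as a tab-separated file
#'
#' Plain-text trace exchange with units and acquisition metadata in header
#' comments; \code{read_trace} reproduces the in-memory record.
#'
#' @param trace an \code{\link{unzip_trace}}.
#' @param path file path.
#' @return \code{write_trace}: invisibly, the trace; \code{read_trace}: an
#'   \code{\link{unzip_trace}}.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "unzip_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# schema: unzip_trace v1",
               sprintf("# rate_hz: %g", attr(trace, "rate_hz")),
               sprintf("# loading: %s", attr(trace, "loading")),
               "# units: time_s=s force_pN=pN extension_nm=nm"), con)
  utils::write.table(as.data.frame(trace), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(trace)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  pick <- function(key, default) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1L]))
  }
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_s", "force_pN", "extension_nm")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("trace file missing column: ", miss[1L])
  for (cl in need)
    if (!is.numeric(d[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[cl]]))))[1L]
      stop(sprintf("malformed value in column %s at data line %d", cl, bad))
    }
  unzip_trace(d$time_s, d$force_pN, d$extension_nm,
              rate_hz = as.numeric(pick("rate_hz", 1000)),
              loading = pick("loading", "constant_velocity"))
}
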