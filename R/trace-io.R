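#' Write a dipolar trace to a plain-text file
#'
#' Traces are stored as ASCII with a `#`-prefixed `key: value` header
#' (sequence, tau0, units, seeds and any other metadata) followed by two
#' numeric columns: time (µs) and amplitude.  Numeric values are written
#' with 17 significant digits so that a read/write round trip preserves
#' the columns to full double precision and header values exactly.
#'
#' @param trace a [dipolar_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "dipolar_trace"))
  hdr <- c(sequence = trace$sequence,
           tau0 = .fmt_num(trace$tau0),
           units = "t:us amplitude:au")
  meta <- trace$meta
  meta$breakdown <- NULL
  for (k in names(meta)) {
    v <- meta[[k]]
    if (is.numeric(v) && length(v) == 1L) hdr[k] <- .fmt_num(v)
    else if (is.character(v) && length(v) == 1L) hdr[k] <- v
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(hdr), unname(hdr)), con)
  writeLines(sprintf("%s\t%s", .fmt_num(trace$t), .fmt_num(trace$amplitude)),
             con)
  invisible(path)
}

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Read a dipolar trace from a plain-text file
#'
#' Parses the `# key: value` header and the two numeric columns written by
#' [write_trace()].  Unknown header keys are preserved in `meta`.  A
#' legacy bare two-column file without header is accepted with a warning
#' and default metadata.  A malformed numeric row raises an error naming
#' the offending line.
#'
#' @param path file path.
#' @param require_tau0 error if a SIFTER/SIDRE trace lacks a `tau0`
#'   header entry (default `TRUE`).
#' @return a [dipolar_trace()].
#' @export
read_trace <- function(path, require_tau0 = TRUE) {
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr & nzchar(trimws(lines))]

  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  if (!length(hdr))
    warning("no header found; reading as legacy two-column trace with defaults")

  tvals <- numeric(length(body))
  avals <- numeric(length(body))
  for (i in seq_along(body)) {
    parts <- strsplit(trimws(body[i]), "[\t ,;]+")[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (length(num) < 2L || any(is.na(num[1])) || (is.na(num[2]) && parts[2] != "NA"))
      stop(sprintf("malformed numeric row at line %d of %s",
                   which(!is_hdr)[i], path))
    tvals[i] <- num[1]; avals[i] <- num[2]
  }

  sequence <- meta$sequence %||% "unknown"
  tau0 <- suppressWarnings(as.numeric(meta$tau0 %||% NA))
  if (require_tau0 && sequence %in% c("sifter", "sidre") && !is.finite(tau0))
    stop("trace file lacks required tau0 header: ", path)
  meta$sequence <- NULL; meta$tau0 <- NULL; meta$units <- NULL
  ## convert numeric-looking metadata back to numbers
  meta <- lapply(meta, function(v) {
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  })
  dipolar_trace(tvals, avals, tau0 = tau0, sequence = sequence, meta = meta)
}

#' Add white Gaussian detection noise to a trace
#'
#' Noise on the echo-integrated amplitude is modelled as additive white
#' Gaussian with standard deviation `max(|amplitude|) / snr`.  The seed is
#' recorded in the trace metadata; identical seeds give identical noise.
#'
#' @param trace a [dipolar_trace()].
#' @param snr signal-to-noise ratio (> 0); `Inf` returns the trace
#'   unchanged.
#' @param seed integer seed.
#' @export
add_noise <- function(trace, snr, seed = 1L) {
  stopifnot(inherits(trace, "dipolar_trace"), snr > 0)
  if (!is.finite(snr)) return(trace)
  sigma <- max(abs(trace$amplitude), na.rm = TRUE) / snr
  noise <- with_seed(seed, stats::rnorm(length(trace$t), 0, sigma))
  meta <- trace$meta
  meta$snr <- snr
  meta$noise_seed <- as.integer(seed)
  dipolar_trace(trace$t, trace$amplitude + noise, tau0 = trace$tau0,
                sequence = trace$sequence, meta = meta)
}
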