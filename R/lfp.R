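#' Construct an LFP recording
#'
#' A continuous local field potential trace stored as a tibble with columns
#' `time_s` and `voltage` (microvolts), carrying the sampling rate, region
#' label and start time as attributes. All package functions that consume an
#' LFP accept this object.
#'
#' @param voltage Numeric vector of samples (microvolts); all finite.
#' @param rate Sampling rate in Hz (> 0).
#' @param region Region label, one of `"mPFC"`, `"dHPC"`, `"vHPC"`.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return A tibble of class `lfp_rec` with columns `time_s`, `voltage`.
#' @export
#' @examples
#' lfp <- lfp_recording(sin(2 * pi * 8 * seq(0, 1, by = 1 / 500)), rate = 500, region = "vHPC")
lfp_recording <- function(voltage, rate, region = c("mPFC", "dHPC", "vHPC"),
                          t0 = 0) {
  region <- match.arg(region)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number (Hz)", call. = FALSE)
  }
  if (!all(is.finite(voltage))) {
    stop("all voltage samples must be finite", call. = FALSE)
  }
  out <- tibble::tibble(
    time_s = t0 + (seq_along(voltage) - 1) / rate,
    voltage = as.numeric(voltage)
  )
  attr(out, "rate") <- rate
  attr(out, "region") <- region
  attr(out, "t0") <- t0
  class(out) <- c("lfp_rec", class(out))
  out
}

#' @export
print.lfp_rec <- function(x, ...) {
  cat(sprintf(
    "<lfp_rec> region=%s rate=%g Hz duration=%.3f s (%d samples)\n",
    lfp_region(x), lfp_rate(x), nrow(x) / lfp_rate(x), nrow(x)
  ))
  NextMethod()
}

#' Sampling rate, region and start time of an LFP recording
#' @param x An `lfp_rec`.
#' @return A scalar (Hz, label, or seconds respectively).
#' @export
lfp_rate <- function(x) attr(x, "rate")

#' @rdname lfp_rate
#' @export
lfp_region <- function(x) attr(x, "region")

#' @rdname lfp_rate
#' @export
lfp_t0 <- function(x) attr(x, "t0")

#' Write / read an LFP recording as float32 + JSON sidecar
#'
#' The trace is stored as little-endian float32 samples in `<stem>.f32`
#' with a JSON sidecar `<stem>.json` holding `rate_hz`, `region`, `t0_s`
#' and `units` ("uV").
#'
#' @param lfp An `lfp_rec`.
#' @param stem Path stem (no extension).
#' @return `write_lfp` returns `stem` invisibly; `read_lfp` returns an
#'   `lfp_rec`.
#' @export
write_lfp <- function(lfp, stem) {
  stopifnot(inherits(lfp, "lfp_rec"))
  con <- file(paste0(stem, ".f32"), "wb")
  on.exit(close(con))
  writeBin(lfp$voltage, con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(
      rate_hz = lfp_rate(lfp), region = lfp_region(lfp),
      t0_s = lfp_t0(lfp), units = "uV", n_samples = nrow(lfp)
    ),
    paste0(stem, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  con <- file(paste0(stem, ".f32"), "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = meta$n_samples, size = 4L, endian = "little")
  lfp_recording(v, rate = meta$rate_hz, region = meta$region, t0 = meta$t0_s)
}

# Extract the numeric samples and rate from either an lfp_rec or a plain
# numeric vector plus explicit rate. Internal convenience.
as_trace <- function(x, rate = NULL) {
  if (inherits(x, "lfp_rec")) {
    list(v = x$voltage, rate = lfp_rate(x), t0 = lfp_t0(x))
  } else if (is.numeric(x)) {
    if (is.null(rate)) stop("rate must be supplied for a bare numeric trace", call. = FALSE)
    list(v = as.numeric(x), rate = rate, t0 = 0)
  } else {
    stop("expected an lfp_rec or a numeric vector", call. = FALSE)
  }
}
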