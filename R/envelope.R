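#' Envelope image from a beamformed RF frame
#'
#' Computes the per-scan-line analytic-signal magnitude (Hilbert-transform
#' envelope) of the RF samples. The analytic signal is formed in the
#' frequency domain by zeroing negative frequencies and doubling positive
#' ones, column by column; the output has the same shape as the input frame.
#'
#' @param frame An [rf_frame()] with at least 8 axial samples.
#' @return A list of class `"envelope_image"` with `values` (non-negative
#'   matrix) and the frame's acquisition metadata (`fs`, `f0`,
#'   `pulse_length`, `lateral_pitch`, `sound_speed`).
#' @export
envelope_from_rf <- function(frame) {
  if (!inherits(frame, "rf_frame")) stop("`frame` must be an rf_frame", call. = FALSE)
  x <- frame$samples
  n <- nrow(x)
  if (n < 8L) stop("frame must have at least 8 axial samples", call. = FALSE)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  X <- mvfft(x)
  analytic <- mvfft(X * h, inverse = TRUE) / n
  structure(list(values = Mod(analytic),
                 fs = frame$fs, f0 = frame$f0,
                 pulse_length = frame$pulse_length,
                 lateral_pitch = frame$lateral_pitch,
                 sound_speed = frame$sound_speed),
            class = "envelope_image")
}

#' @export
print.envelope_image <- function(x, ...) {
  cat(sprintf("<envelope_image> %d x %d, pulse %.3g mm\n",
              nrow(x$values), ncol(x$values), x$pulse_length))
  invisible(x)
}
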