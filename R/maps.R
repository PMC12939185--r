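#' Sliding-window geometry from the pulse length
#'
#' Converts a physical window side length, specified as a multiple of the
#' transducer pulse length, into per-axis sample counts. Windows are square
#' in physical units (mm) and converted per axis: axial side =
#' round(multiplier x pulse_length / axial sample spacing), lateral side =
#' round(multiplier x pulse_length / lateral pitch). Steps are
#' ceiling(side / 2), giving the 50 percent window overlap used throughout.
#' The customary multipliers are 3 (Nakagami), 5 (homodyned-K) and 1
#' (entropy) pulse lengths.
#'
#' @param pulse_length Pulse length in mm (> 0).
#' @param multiplier Window side in pulse lengths (typically 3, 5 or 1).
#' @param frame An [rf_frame()] or `envelope_image` supplying the sampling
#'   geometry.
#' @return A list of class `"window_spec"` with `side_axial`, `side_lateral`,
#'   `step_axial`, `step_lateral`, `multiplier`.
#' @export
window_spec_from_pulse <- function(pulse_length, multiplier, frame) {
  stop_if_not_scalar_pos(pulse_length, "pulse_length")
  stop_if_not_scalar_pos(multiplier, "multiplier")
  dz <- frame$sound_speed / (2 * frame$fs) * 1000
  side_ax <- as.integer(round(multiplier * pulse_length / dz))
  side_lat <- as.integer(round(multiplier * pulse_length / frame$lateral_pitch))
  if (side_ax < 1L || side_lat < 1L) {
    stop("window smaller than one sample spacing", call. = FALSE)
  }
  dims <- dim(if (inherits(frame, "rf_frame")) frame$samples else frame$values)
  if (side_ax > dims[1] || side_lat > dims[2]) {
    stop("window exceeds frame dimensions", call. = FALSE)
  }
  structure(list(side_axial = side_ax, side_lateral = side_lat,
                 step_axial = as.integer(ceiling(side_ax / 2)),
                 step_lateral = as.integer(ceiling(side_lat / 2)),
                 multiplier = multiplier),
            class = "window_spec")
}

#' Explicit window geometry
#'
#' Builds a `window_spec` directly from sample counts, with steps defaulting
#' to ceiling(side / 2) (50 percent overlap).
#'
#' @param side_axial,side_lateral Window sides in samples / lines (>= 1).
#' @param step_axial,step_lateral Strides; default 50 percent overlap.
#' @return A `window_spec`.
#' @export
window_spec <- function(side_axial, side_lateral,
                        step_axial = ceiling(side_axial / 2),
                        step_lateral = ceiling(side_lateral / 2)) {
  if (side_axial < 1L || side_lateral < 1L) stop("window sides must be >= 1", call. = FALSE)
  structure(list(side_axial = as.integer(side_axial),
                 side_lateral = as.integer(side_lateral),
                 step_axial = as.integer(step_axial),
                 step_lateral = as.integer(step_lateral),
                 multiplier = NA_real_),
            class = "window_spec")
}

new_parametric_map <- function(values, parameter_id, window, origin) {
  structure(list(values = values, parameter_id = parameter_id,
                 window = window, origin = origin),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map:%s> %d x %d cells (window %dx%d, step %dx%d), %d invalid\n",
              x$parameter_id, nrow(x$values), ncol(x$values),
              x$window$side_axial, x$window$side_lateral,
              x$window$step_axial, x$window$step_lateral,
              sum(!is.finite(x$values))))
  invisible(x)
}

map_grid_dims <- function(dims, window) {
  c(floor((dims[1] - window$side_axial) / window$step_axial) + 1L,
    floor((dims[2] - window$side_lateral) / window$step_lateral) + 1L)
}

# Window centers of a parametric map on the envelope grid (1-based, may be
# half-integer for even sides).
map_cell_centers <- function(map) {
  g <- dim(map$values)
  list(axial = map$origin[1] + (seq_len(g[1]) - 1) * map$window$step_axial,
       lateral = map$origin[2] + (seq_len(g[2]) - 1) * map$window$step_lateral)
}

window_sweep <- function(env_values, window, cell_fun) {
  dims <- dim(env_values)
  g <- map_grid_dims(dims, window)
  if (g[1] < 1L || g[2] < 1L) stop("window larger than image", call. = FALSE)
  n_out <- length(cell_fun(env_values[seq_len(window$side_axial),
                                      seq_len(window$side_lateral), drop = FALSE],
                           probe = TRUE))
  out <- array(NA_real_, c(g[1], g[2], n_out))
  for (j in seq_len(g[2])) {
    c0 <- (j - 1L) * window$step_lateral
    for (i in seq_len(g[1])) {
      r0 <- (i - 1L) * window$step_axial
      w <- env_values[(r0 + 1L):(r0 + window$side_axial),
                      (c0 + 1L):(c0 + window$side_lateral), drop = FALSE]
      out[i, j, ] <- cell_fun(w)
    }
  }
  out
}

#' Sliding-window parametric map
#'
#' Applies one of the envelope-statistics estimators to every window position
#' of an envelope image (stride = the window steps) and assembles the
#' estimates into a parametric map. The grid has
#' floor((dim - side) / step) + 1 cells per axis. Windows with fewer than 10
#' samples, or on which the estimator fails (for example zero variance), are
#' flagged invalid (`NA`) rather than raising an error.
#'
#' @param env An `envelope_image` (or plain non-negative matrix).
#' @param estimator_id One of `"m"` (Nakagami shape), `"alpha"`, `"k"`
#'   (homodyned-K), `"H"` (histogram entropy).
#' @param window A `window_spec`.
#' @param config An [estimator_config()].
#' @return A `parametric_map` whose `origin` records the envelope-grid
#'   coordinates of the first window center.
#' @export
sliding_window_map <- function(env, estimator_id, window,
                               config = estimator_config()) {
  values <- if (inherits(env, "envelope_image")) env$values else env
  if (!estimator_id %in% c("m", "alpha", "k", "H")) {
    stop(sprintf("unknown estimator_id '%s'", estimator_id), call. = FALSE)
  }
  cell_fun <- switch(
    estimator_id,
    m = function(w, probe = FALSE) {
      if (probe) return(0)
      if (length(w) < 10L) return(NA_real_)
      tryCatch(nakagami_m(as.vector(w))$m, error = function(e) NA_real_)
    },
    H = function(w, probe = FALSE) {
      if (probe) return(0)
      if (length(w) < 10L) return(NA_real_)
      tryCatch(entropy_histogram(as.vector(w), config$entropy_bins),
               error = function(e) NA_real_)
    },
    alpha = ,
    k = function(w, probe = FALSE) {
      if (probe) return(0)
      if (length(w) < 10L) return(NA_real_)
      est <- tryCatch(hk_estimate_xu(as.vector(w), config),
                      error = function(e) NULL)
      if (is.null(est)) return(NA_real_)
      if (estimator_id == "alpha") est$alpha else est$k
    })
  vals <- window_sweep(values, window, cell_fun)[, , 1, drop = TRUE]
  vals <- matrix(vals, map_grid_dims(dim(values), window)[1])
  new_parametric_map(vals, estimator_id, window,
                     origin = c((window$side_axial + 1) / 2,
                                (window$side_lateral + 1) / 2))
}

#' Homodyned-K alpha and k maps in one sweep
#'
#' Computes both homodyned-K parametric maps with a single XU inversion per
#' window position (roughly half the cost of two [sliding_window_map()]
#' calls).
#'
#' @inheritParams sliding_window_map
#' @return List with elements `alpha` and `k`, both `parametric_map`s.
#' @export
hk_parametric_maps <- function(env, window, config = estimator_config()) {
  values <- if (inherits(env, "envelope_image")) env$values else env
  cell_fun <- function(w, probe = FALSE) {
    if (probe) return(c(0, 0))
    if (length(w) < 10L) return(c(NA_real_, NA_real_))
    est <- tryCatch(hk_estimate_xu(as.vector(w), config), error = function(e) NULL)
    if (is.null(est)) return(c(NA_real_, NA_real_))
    c(est$alpha, est$k)
  }
  arr <- window_sweep(values, window, cell_fun)
  g <- map_grid_dims(dim(values), window)
  origin <- c((window$side_axial + 1) / 2, (window$side_lateral + 1) / 2)
  list(alpha = new_parametric_map(matrix(arr[, , 1], g[1]), "alpha", window, origin),
       k = new_parametric_map(matrix(arr[, , 2], g[1]), "k", window, origin))
}
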