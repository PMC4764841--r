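#' Construct a hemispherical MEG sensor array
#'
#' Places `n_sensors` magnetometers on a near-uniform spherical cap above a
#' single-sphere conductor head model, oriented radially, and marks the
#' parietal decoding subset: the 84 sensors closest to a posterior-superior
#' reference direction, mirroring the parietal sensor selection used for
#' movement decoding.
#'
#' @param n_sensors Number of magnetometers (default 160; must be >= 84).
#' @param head_radius Conductor sphere radius in metres (default 0.10).
#' @param standoff Radial gap between scalp and sensors in metres.
#' @param seed Integer seed controlling the small azimuthal dithering of the
#'   sensor lattice (real arrays are never perfectly regular).
#' @return An object of class `sensor_array`: list with `positions`
#'   (n_sensors x 3, metres), `orientations` (unit radial vectors),
#'   `parietal_mask` (logical, sums to 84), `n_sensors`, `head_radius`.
#' @export
#' @examples
#' arr <- make_sensor_array(160, seed = 7)
#' sum(arr$parietal_mask)
make_sensor_array <- function(n_sensors = 160, head_radius = 0.10,
                              standoff = 0.02, seed = 1) {
  if (!is.numeric(n_sensors) || n_sensors < 84) {
    stop_smf("invalid_config", "n_sensors must be >= 84 (got %s)", n_sensors)
  }
  n_sensors <- as.integer(n_sensors)
  r <- head_radius + standoff

  # Fibonacci lattice restricted to a cap: z in [sin(-10 deg), 1] so the cap
  # dips slightly below the equator, as whole-head arrays do.
  golden <- pi * (3 - sqrt(5))
  z_lo <- sin(-10 * pi / 180)
  i <- seq_len(n_sensors) - 0.5
  z <- z_lo + (1 - z_lo) * i / n_sensors
  jitter <- with_seed(seed, runif(n_sensors, -0.02, 0.02))
  phi <- golden * (seq_len(n_sensors) - 1) + jitter
  rho <- sqrt(pmax(0, 1 - z^2))
  pos <- r * cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
  orient <- pos / row_norms(pos)

  # Parietal subset: 84 sensors nearest (by angle) to the vertex-posterior
  # direction (negative y = posterior by convention here).
  ref <- c(0, -0.45, 0.89)
  ref <- ref / vnorm(ref)
  ang <- acos(pmin(1, pmax(-1, orient %*% ref)))
  mask <- logical(n_sensors)
  mask[order(ang)[seq_len(84L)]] <- TRUE

  structure(
    list(
      positions = pos,
      orientations = orient,
      parietal_mask = mask,
      n_sensors = n_sensors,
      head_radius = head_radius,
      seed = seed
    ),
    class = "sensor_array"
  )
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf(
    "<sensor_array> %d radial magnetometers (head radius %.3f m), %d parietal\n",
    x$n_sensors, x$head_radius, sum(x$parietal_mask)
  ))
  invisible(x)
}
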