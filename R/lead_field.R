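#' Build a toy cortical mesh inside the conductor sphere
#'
#' Distributes `n_vertices` current dipoles near-equidistantly on a spherical
#' shell inside the conductor, each carrying a unit orientation that plays the
#' role of the local cortical-surface normal. Because a folded cortex presents
#' normals at many angles to the skull, orientations are drawn at random but
#' constrained to keep a substantial tangential component; purely radial
#' dipoles are magnetically silent in a spherical conductor and would carry no
#' signal.
#'
#' @param n_vertices Number of dipole vertices (default 400; the full-scale
#'   analysis this emulates used 4004).
#' @param shell_radius Radius of the source shell in metres; must be strictly
#'   inside the conductor sphere.
#' @param head_radius Conductor sphere radius in metres.
#' @param min_tangential Lower bound on the tangential fraction of each
#'   orientation (default 0.3).
#' @param seed Integer seed for the orientation draw.
#' @return Object of class `cortical_mesh`: `positions` (n x 3 m),
#'   `orientations` (unit vectors), `n_vertices`, `spacing` (median
#'   nearest-neighbour distance, m), `head_radius`.
#' @export
make_cortical_mesh <- function(n_vertices = 400, shell_radius = 0.075,
                               head_radius = 0.10, min_tangential = 0.3,
                               seed = 1) {
  if (shell_radius >= head_radius) {
    stop_smf("geometry_error", "source shell must lie strictly inside the conductor sphere")
  }
  n_vertices <- as.integer(n_vertices)
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n_vertices) - 0.5
  # keep the source space inside the instrumented sensor cap: sources below
  # the cap rim are unobservable and cannot be localized
  z_lo <- -0.15
  z <- z_lo + (1 - z_lo) * i / n_vertices
  phi <- golden * (seq_len(n_vertices) - 1)
  rho <- sqrt(pmax(0, 1 - z^2))
  pos <- shell_radius * cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)

  radial <- pos / row_norms(pos)
  orient <- with_seed(seed, {
    o <- matrix(rnorm(3 * n_vertices), ncol = 3)
    o <- o / row_norms(o)
    for (k in seq_len(n_vertices)) {
      tang <- o[k, ] - sum(o[k, ] * radial[k, ]) * radial[k, ]
      while (vnorm(tang) < min_tangential) {
        o[k, ] <- rnorm(3)
        o[k, ] <- o[k, ] / vnorm(o[k, ])
        tang <- o[k, ] - sum(o[k, ] * radial[k, ]) * radial[k, ]
      }
    }
    o
  })

  # median nearest-neighbour spacing, used as the localization-error unit
  d2 <- as.matrix(stats::dist(pos))
  diag(d2) <- Inf
  spacing <- stats::median(apply(d2, 1, min))

  structure(
    list(
      positions = pos,
      orientations = orient,
      n_vertices = n_vertices,
      spacing = spacing,
      head_radius = head_radius,
      seed = seed
    ),
    class = "cortical_mesh"
  )
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf(
    "<cortical_mesh> %d dipole vertices, spacing %.1f mm, conductor radius %.0f mm\n",
    x$n_vertices, 1000 * x$spacing, 1000 * x$head_radius
  ))
  invisible(x)
}

# Sarvas (1987) magnetic field of a current dipole in a homogeneous
# conducting sphere centred at the origin. q: dipole moment (3-vector),
# r0: dipole location, r: field point (outside the sphere).
sarvas_field <- function(q, r0, r) {
  mu0_4pi <- 1e-7
  a_vec <- r - r0
  a <- vnorm(a_vec)
  R <- vnorm(r)
  if (a < .Machine$double.eps) return(c(0, 0, 0))
  F_ <- a * (R * a + R^2 - sum(r0 * r))
  adotr <- sum(a_vec * r)
  gradF <- (a^2 / R + adotr / a + 2 * a + 2 * R) * r -
    (a + 2 * R + adotr / a) * r0
  qxr0 <- c(
    q[2] * r0[3] - q[3] * r0[2],
    q[3] * r0[1] - q[1] * r0[3],
    q[1] * r0[2] - q[2] * r0[1]
  )
  mu0_4pi / F_^2 * (F_ * qxr0 - sum(qxr0 * r) * gradF)
}

#' Compute the sensor lead field of a cortical mesh
#'
#' Uses the closed-form magnetic forward solution for a current dipole in a
#' homogeneous conducting sphere (the standard single-sphere MEG head model),
#' projecting the field onto each sensor's orientation. Column j holds the
#' signal at every sensor produced by a unit dipole at mesh vertex j along its
#' orientation. A purely radial dipole produces (numerically) zero field.
#'
#' @param mesh A `cortical_mesh`.
#' @param array A `sensor_array`.
#' @param scale Multiplier applied to the raw field (default 1e9 so values
#'   are O(1) a.u. rather than tesla-scale).
#' @return Object of class `lead_field`: matrix `L` (n_sensors x n_vertices)
#'   with the mesh and array attached.
#' @export
compute_lead_field <- function(mesh, array, scale = 1e9) {
  stopifnot(inherits(mesh, "cortical_mesh"), inherits(array, "sensor_array"))
  if (any(row_norms(mesh$positions) >= array$head_radius)) {
    stop_smf("geometry_error", "mesh vertices must lie strictly inside the conductor sphere")
  }
  L <- matrix(0, nrow = array$n_sensors, ncol = mesh$n_vertices)
  for (j in seq_len(mesh$n_vertices)) {
    q <- mesh$orientations[j, ]
    r0 <- mesh$positions[j, ]
    for (i in seq_len(array$n_sensors)) {
      B <- sarvas_field(q, r0, array$positions[i, ])
      L[i, j] <- sum(B * array$orientations[i, ])
    }
  }
  structure(
    list(L = L * scale, mesh = mesh, array = array, scale = scale),
    class = "lead_field"
  )
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf(
    "<lead_field> %d sensors x %d vertices (single-sphere forward model)\n",
    nrow(x$L), ncol(x$L)
  ))
  invisible(x)
}
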