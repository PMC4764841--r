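probe_mesh <- function(positions, orientations) {
  structure(
    list(positions = positions, orientations = orientations,
         n_vertices = nrow(positions), spacing = 0.01, head_radius = 0.10,
         seed = NA),
    class = "cortical_mesh"
  )
}

test_that("a radial dipole is silent in the spherical conductor", {
  pos <- matrix(c(0.03, 0.01, 0.05), 1)
  radial <- pos / sqrt(sum(pos^2))
  tang <- c(-radial[2], radial[1], 0)
  tang <- tang / sqrt(sum(tang^2))
  arr <- tiny_array()
  lf_rad <- compute_lead_field(probe_mesh(pos, radial), arr)
  lf_tan <- compute_lead_field(probe_mesh(pos, matrix(tang, 1)), arr)
  expect_lt(max(abs(lf_rad$L)), 1e-12 * max(abs(lf_tan$L)))
})

test_that("the dipole field is linear in the moment", {
  p <- c(0.02, -0.01, 0.06)
  qa <- c(0, 1, 0)
  qb <- c(0, 0, 1)
  r <- c(0.05, -0.06, 0.09)
  B <- smfdecode:::sarvas_field
  expect_equal(B(2 * qa, p, r), 2 * B(qa, p, r), tolerance = 1e-12)
  expect_equal(B(qa + qb, p, r), B(qa, p, r) + B(qb, p, r),
               tolerance = 1e-12)
})

test_that("field magnitude decays with sensor distance", {
  pos <- matrix(c(0.0, -0.03, 0.06), 1)
  orient <- matrix(c(1, 0, 0), 1)
  dir <- pos[1, ] / sqrt(sum(pos^2))
  radii <- seq(0.12, 0.30, by = 0.02)
  # probe sensors along the radial line above the dipole, tangentially
  # oriented so the projected field is non-zero
  tang <- c(0, dir[3], -dir[2])
  tang <- tang / sqrt(sum(tang^2))
  mags <- vapply(radii, function(r) {
    B <- smfdecode:::sarvas_field(orient[1, ], pos[1, ], r * dir)
    abs(sum(B * tang))
  }, 0)
  expect_true(all(diff(mags) < 0))
})

test_that("geometry violations are rejected", {
  arr <- tiny_array()
  out <- probe_mesh(matrix(c(0.2, 0, 0), 1), matrix(c(0, 1, 0), 1))
  expect_error(compute_lead_field(out, arr), class = "geometry_error")
  expect_error(make_cortical_mesh(shell_radius = 0.12, head_radius = 0.10),
               class = "geometry_error")
  expect_error(inverse_config(lambda = -1), class = "invalid_config")
})

test_that("forward-then-inverse recovers single-dipole sources", {
  arr <- tiny_array()
  mesh <- cached("mesh200", function() make_cortical_mesh(200, seed = 5))
  lf <- cached("lf200", function() compute_lead_field(mesh, arr))
  W <- compute_inverse_filter(lf, inverse_config(lambda = 1e-6))
  set.seed(31)
  picks <- sample(mesh$n_vertices, 20)
  errs <- vapply(picks, function(j) {
    J <- apply_inverse(W, lf$L[, j, drop = FALSE])
    jhat <- which.max(abs(J))
    sqrt(sum((mesh$positions[jhat, ] - mesh$positions[j, ])^2))
  }, 0)
  expect_true(all(errs <= mesh$spacing + 1e-12))

  # zero data gives zero currents; lambda -> Inf shrinks currents to zero
  expect_true(all(apply_inverse(W, matrix(0, 84, 10)) == 0))
  norms <- vapply(c(1e-4, 1, 1e4, 1e8), function(lam) {
    Wl <- compute_inverse_filter(lf, inverse_config(lambda = lam))
    sum(apply_inverse(Wl, lf$L[, 7, drop = FALSE])^2)
  }, 0)
  expect_true(all(diff(norms) < 0))
})

test_that("eSCP F-maps are spatially enriched around the active patches", {
  # full task-scale session (40 trials per type); the linear minimum-norm
  # inverse spreads activity, so the check is for enrichment near the
  # injected patches, not for focal maps
  ses <- cached("full_session", function() {
    simulate_open_loop(sim_config(seed = 3), tiny_array())
  })
  lf <- ses$truth$lead_field
  est <- estimate_currents(ses, lf, inverse_config(lambda = 0.1))
  expect_equal(dim(est$escp), c(80L, lf$mesh$n_vertices))
  expect_true(all(is.finite(est$escp)))
  amap <- escp_anova_map(est)
  expect_true(all(amap$F >= 0))
  expect_true(all(amap$p >= 0 & amap$p <= 1))
  # normalization is per-vertex affine: F identical on raw and z maps
  amap_raw <- escp_anova_map(est, normalized = FALSE)
  expect_equal(amap$F, amap_raw$F, tolerance = 1e-9)

  patches <- unique(unlist(ses$truth$patch_vertices))
  d <- as.matrix(dist(lf$mesh$positions))
  near_all <- vapply(seq_len(lf$mesh$n_vertices), function(v) {
    min(d[v, patches]) <= 2 * lf$mesh$spacing
  }, TRUE)
  expect_true(any(amap$masked))
  # masked vertices are enriched near the patches relative to chance, and
  # the strongest F-values sit at the patches
  expect_gt(mean(near_all[amap$masked]), mean(near_all))
  expect_gte(sum(near_all[order(-amap$F)[1:5]]), 2)
})

test_that("per-vertex ANOVA map has exact two-group structure", {
  set.seed(33)
  m <- matrix(rnorm(40 * 30), 40)
  g <- rep(c("grasp", "open"), each = 20)
  amap <- escp_anova_map(m, g)
  for (j in c(1, 13, 30)) {
    tt <- t.test(m[g == "grasp", j], m[g == "open", j], var.equal = TRUE)
    expect_equal(amap$F[j], unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(amap$p[j], tt$p.value, tolerance = 1e-9)
  }
  # duplicated trials across groups: identical means, F = 0
  dup <- rbind(m[1:20, ], m[1:20, ])
  amap0 <- escp_anova_map(dup, g)
  expect_true(all(amap0$F < 1e-20))
  expect_error(escp_anova_map(m, c("grasp", rep("open", 39))),
               class = "dof_error")
})

test_that("the null F-map masks about 5 percent of vertices", {
  set.seed(34)
  m <- matrix(rnorm(40 * 4000), 40)
  g <- rep(c("grasp", "open"), each = 20)
  amap <- escp_anova_map(m, g)
  k <- sum(amap$masked)
  band <- qbinom(c(0.005, 0.995), 4000, 0.05)
  expect_gte(k, band[1])
  expect_lte(k, band[2])
})

test_that("an unregularized rank-deficient system raises a conditioning error", {
  arr <- tiny_array()
  mesh <- cached("mesh200", function() make_cortical_mesh(200, seed = 5))
  lf <- cached("lf200", function() compute_lead_field(mesh, arr))
  # fewer vertices than sensors makes the gram matrix rank-deficient
  lf_small <- lf
  lf_small$L <- lf$L[, 1:10]
  expect_error(compute_inverse_filter(lf_small, inverse_config(lambda = 0)),
               class = "conditioning_error")
})
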