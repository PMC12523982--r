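# Shared fixture builders; everything is generated in code at test time.

opt1 <- function() optics_config(pixel_size = 1)
opt05 <- function() optics_config(pixel_size = 0.5)

hemisphere_spec <- function(radius = 15)
  cell_phantom_spec("spherical_cap", footprint_radii = radius, height = radius)

flat_cap_spec <- function(radius = 15, sphericity = 0.24)
  cell_phantom_spec("spherical_cap", footprint_radii = radius,
                    height = cap_ratio_for_sphericity(sphericity) * radius)

# Brute-force dry-mass oracle: direct pixel summation of the rendered
# raster over the truth footprint (here: all nonzero pixels of a
# single-object image), independent of measure().
brute_force_mass <- function(image) {
  sum(image$opd) * image$optics$pixel_size^2 / image$optics$alpha
}

# Independent numeric oracle for the analytic cap formulas: midpoint
# quadrature of the solid of revolution.
quad_cap_volume <- function(a, h) {
  R <- (a^2 + h^2) / (2 * h)
  stats::integrate(function(r) 2 * pi * r * (sqrt(R^2 - r^2) - (R - h)),
                   0, a, rel.tol = 1e-10)$value
}

quad_cap_surface <- function(a, h) {
  R <- (a^2 + h^2) / (2 * h)
  # integrable edge singularity; adaptive quadrature handles it
  stats::integrate(function(r) 2 * pi * r * R / sqrt(R^2 - r^2),
                   0, a, rel.tol = 1e-10)$value
}

# random phantom spec with well-formed radii for every model
random_phantom_spec <- function() {
  model <- sample(c("spherical_cap", "ellipsoidal_cap", "gaussian_bump"), 1)
  ar <- if (model == "spherical_cap") 1 else runif(1, 1.05, 1.7)
  a <- runif(1, 9, 16)
  cell_phantom_spec(model, footprint_radii = c(a, a / ar),
                    height = runif(1, 1.5, a / ar / 1.6),
                    orientation = runif(1, 0, pi),
                    dry_mass = runif(1, 10, 60))
}

# Analytic-footprint mask of a circular-cap phantom rendered on a
# canvas (truth footprint, for oracle-based measurements).
truth_footprint_map <- function(spec, optics, canvas) {
  px <- optics$pixel_size
  ctr <- if (any(is.na(spec$centroid))) canvas * px / 2 else spec$centroid
  xs <- ((seq_len(canvas[1])) - 0.5) * px - ctr[1]
  ys <- ((seq_len(canvas[2])) - 0.5) * px - ctr[2]
  co <- cos(spec$orientation); si <- sin(spec$orientation)
  u <- outer(xs, ys, function(x, y) co * x + si * y)
  v <- outer(xs, ys, function(x, y) -si * x + co * y)
  q <- (u / spec$footprint_radii[1])^2 + (v / spec$footprint_radii[2])^2
  label_map(matrix(as.integer(q <= 1), canvas[1], canvas[2]), px)
}
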