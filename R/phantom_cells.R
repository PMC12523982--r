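#' Analytic geometry of spherical-cap phantoms
#'
#' A spherical cap with base (footprint) radius `a` and apex height `h`
#' is the portion of a sphere of radius `R = (a^2 + h^2) / (2h)` cut by
#' a plane. Closed forms used throughout the phantom generator:
#' volume `V = pi h (3 a^2 + h^2) / 6`, curved (upper) surface area
#' `S = pi (a^2 + h^2)`.
#'
#' The package's sphericity convention references the hemisphere: for
#' a solid of volume `V` with measured upper surface `S`, sphericity is
#' `2 pi r^2 / S` with `r = (3 V / (2 pi))^(1/3)` the radius of the
#' equal-volume hemisphere. A hemispherical cap (`h = a`) therefore has
#' sphericity exactly 1, and flatter caps score lower.
#'
#' @param a base radius, um.
#' @param h apex height, um.
#' @name cap_geometry
NULL

#' @rdname cap_geometry
#' @export
cap_volume <- function(a, h) pi * h * (3 * a^2 + h^2) / 6

#' @rdname cap_geometry
#' @export
cap_surface <- function(a, h) pi * (a^2 + h^2)

#' Sphericity of a solid from volume and upper-surface area
#'
#' `2 pi r^2 / S` with `r` the equal-volume-hemisphere radius.
#'
#' @param volume solid volume, um^3.
#' @param surface upper-surface area, um^2.
#' @return dimensionless sphericity (1 for a hemisphere).
#' @export
hemisphere_sphericity <- function(volume, surface) {
  r <- (3 * volume / (2 * pi))^(1 / 3)
  2 * pi * r^2 / surface
}

#' Analytic sphericity of a spherical cap from its height/radius ratio
#'
#' For `k = h / a` the closed form is
#' `2 (k (3 + k^2) / 4)^(2/3) / (1 + k^2)`; equal to 1 at `k = 1`
#' (hemisphere) and strictly increasing on (0, 1].
#'
#' @param k height over base radius, in (0, 1].
#' @return dimensionless sphericity.
#' @export
cap_sphericity <- function(k) {
  stopifnot(all(k > 0))
  2 * (k * (3 + k^2) / 4)^(2 / 3) / (1 + k^2)
}

#' Height/radius ratio of a spherical cap with given sphericity
#'
#' Inverts [cap_sphericity()] on (0, 1] by root finding.
#'
#' @param sphericity target analytic sphericity in (0, 1].
#' @return the ratio `h / a`.
#' @export
cap_ratio_for_sphericity <- function(sphericity) {
  stopifnot(length(sphericity) == 1L, sphericity > 0, sphericity <= 1)
  if (sphericity == 1) return(1)
  stats::uniroot(function(k) cap_sphericity(k) - sphericity,
                 lower = 1e-8, upper = 1, tol = 1e-12)$root
}

#' Specification of a single cell phantom
#'
#' Describes an idealised adherent cell as a smooth solid standing on
#' the substrate: a spherical cap, an ellipsoidal cap (a spherical cap
#' stretched anisotropically over an elliptical footprint) or a
#' truncated Gaussian bump. Rendering converts the thickness profile
#' to optical path difference via the refractive index contrast and
#' rescales globally so the integrated dry mass matches `dry_mass`
#' exactly on the pixel raster.
#'
#' @param model one of `"spherical_cap"`, `"ellipsoidal_cap"`,
#'   `"gaussian_bump"`.
#' @param footprint_radii base semi-axes, um. One value (circular) or
#'   two (major, minor); a spherical cap requires equal semi-axes.
#' @param height apex thickness, um (> 0).
#' @param centroid length-2 numeric, phantom centre in image
#'   coordinates, um; may be `NA` for later placement.
#' @param orientation base-ellipse major-axis angle, radians.
#' @param dry_mass target dry mass, pg, or `NA` for the "geometric"
#'   mass implied by the thickness profile and optics (no rescaling).
#' @return An object of class `cell_phantom_spec`.
#' @export
cell_phantom_spec <- function(model = c("spherical_cap", "ellipsoidal_cap",
                                        "gaussian_bump"),
                              footprint_radii, height,
                              centroid = c(NA_real_, NA_real_),
                              orientation = 0, dry_mass = NA_real_) {
  model <- match.arg(model)
  if (length(footprint_radii) == 1L) footprint_radii <- rep(footprint_radii, 2L)
  stopifnot(length(footprint_radii) == 2L, all(footprint_radii > 0),
            length(height) == 1L)
  if (height <= 0) stop("phantom height must be positive")
  if (footprint_radii[1] < footprint_radii[2])
    stop("major semi-axis must be >= minor semi-axis")
  if (model == "spherical_cap" &&
      abs(footprint_radii[1] - footprint_radii[2]) > 1e-12)
    stop("a spherical cap requires equal footprint semi-axes")
  if (!is.na(dry_mass) && dry_mass <= 0) stop("dry_mass must be positive")
  structure(list(model = model,
                 footprint_radii = as.numeric(footprint_radii),
                 height = as.numeric(height),
                 centroid = as.numeric(centroid),
                 orientation = as.numeric(orientation),
                 dry_mass = as.numeric(dry_mass)),
            class = "cell_phantom_spec")
}

# Thickness at normalised elliptical radius q (q <= 1 inside footprint).
# For caps the profile is the affine-stretched spherical cap of base
# radius `a` (major semi-axis), so a == b recovers the exact cap.
# The Gaussian bump is truncated at 2.5 sigma (q = 1).
.profile_fun <- function(model, a, h) {
  switch(model,
    spherical_cap = ,
    ellipsoidal_cap = {
      R <- (a^2 + h^2) / (2 * h)
      function(q) {
        t <- sqrt(pmax(R^2 - (a * q)^2, 0)) - (R - h)
        ifelse(q <= 1, pmax(t, 0), 0)
      }
    },
    gaussian_bump = {
      s <- 1 / 2.5
      function(q) ifelse(q <= 1, h * exp(-q^2 / (2 * s^2)), 0)
    })
}

# Analytic (continuous-solid) truth for a phantom spec, independent of
# any raster. Surface area of stretched caps and bumps comes from 1-D
# quadrature of the exact surface-integral reduction.
.analytic_truth <- function(spec) {
  a <- spec$footprint_radii[1]; b <- spec$footprint_radii[2]; h <- spec$height
  area <- pi * a * b
  if (spec$model %in% c("spherical_cap", "ellipsoidal_cap")) {
    volume <- (b / a) * cap_volume(a, h)
    if (abs(a - b) < 1e-12) {
      surface <- cap_surface(a, h)
    } else {
      surface <- .stretched_surface(spec)
    }
  } else {
    s <- 1 / 2.5
    volume <- 2 * pi * a * b * h * s^2 * (1 - exp(-1 / (2 * s^2)))
    surface <- .stretched_surface(spec)
  }
  list(area = area, volume = volume, surface = surface,
       sphericity = min(hemisphere_sphericity(volume, surface), 1),
       lw_ratio = a / b)
}

# Upper-surface area of t(u, v) = f(q), q^2 = (u/a)^2 + (v/b)^2, by
# 2-D quadrature in polar-like coordinates u = a q cos w, v = b q sin w:
# S = int_0^1 int_0^{2pi} sqrt(a^2 b^2 + f'(q)^2 q^2 (b^2 cos^2 w + a^2 sin^2 w)) q dw dq
.stretched_surface <- function(spec) {
  a <- spec$footprint_radii[1]; b <- spec$footprint_radii[2]
  f <- .profile_fun(spec$model, a, spec$height)
  dq <- 1e-6
  fp <- function(q) (f(pmin(q + dq, 1)) - f(pmax(q - dq, 0))) /
    (pmin(q + dq, 1) - pmax(q - dq, 0))
  qs <- seq(0.5 / 400, 1 - 0.5 / 400, length.out = 400)
  ws <- seq(0.5 / 200, 1 - 0.5 / 200, length.out = 200) * 2 * pi
  g <- outer(qs, ws, function(q, w)
    sqrt(a^2 * b^2 + fp(q)^2 * q^2 * (b^2 * cos(w)^2 + a^2 * sin(w)^2)) * q)
  sum(g) * (1 / 400) * (2 * pi / 200)
}

# Rasterise one phantom onto pixel centres; returns OPD matrix patch and
# the index window. Pixel i has centre (i - 0.5) * pixel_size.
.render_patch <- function(spec, optics, canvas_px) {
  px <- optics$pixel_size
  a <- spec$footprint_radii[1]; b <- spec$footprint_radii[2]
  cx <- spec$centroid[1]; cy <- spec$centroid[2]
  if (any(is.na(spec$centroid))) stop("phantom centroid not set")
  rmax <- max(a, b)
  i0 <- max(1L, floor((cx - rmax) / px - 1))
  i1 <- min(canvas_px[1], ceiling((cx + rmax) / px + 1))
  j0 <- max(1L, floor((cy - rmax) / px - 1))
  j1 <- min(canvas_px[2], ceiling((cy + rmax) / px + 1))
  xs <- ((i0:i1) - 0.5) * px - cx
  ys <- ((j0:j1) - 0.5) * px - cy
  co <- cos(spec$orientation); si <- sin(spec$orientation)
  u <- outer(xs, ys, function(x, y) co * x + si * y)
  v <- outer(xs, ys, function(x, y) -si * x + co * y)
  q <- sqrt((u / a)^2 + (v / b)^2)
  t <- .profile_fun(spec$model, a, spec$height)(q)
  list(opd = delta_ri(optics) * t, i = i0:i1, j = j0:j1)
}

#' Render a single cell phantom into a phase image
#'
#' The thickness profile of the chosen solid is converted to OPD as
#' `(object_ri - medium_ri) * t(x, y)`, rasterised at pixel centres,
#' then (when `dry_mass` is set) globally rescaled so that
#' `sum(OPD) * pixel_area / alpha` equals the requested dry mass to
#' machine precision. The truth record carries the closed-form area,
#' volume, upper-surface area, sphericity and axis ratio of the
#' continuous solid.
#'
#' @param spec a [cell_phantom_spec()]; its centroid must be set. If
#'   the centroid is `NA` the phantom is centred on the canvas.
#' @param optics an [optics_config()].
#' @param canvas integer length-2, canvas size in pixels.
#' @param time_h,well_id passed to [phase_image()].
#' @return list with `image` (a [phase_image()]) and `truth` (one-row
#'   data frame: id, model, centroid, area um^2, volume um^3,
#'   surface um^2, sphericity, lw_ratio, dry_mass pg, is_debris).
#' @export
render_cell <- function(spec, optics = optics_config(), canvas = c(128L, 128L),
                        time_h = NA_real_, well_id = NA_character_) {
  stopifnot(inherits(spec, "cell_phantom_spec"))
  px <- optics$pixel_size
  if (any(is.na(spec$centroid)))
    spec$centroid <- canvas * px / 2
  rmax <- max(spec$footprint_radii)
  lo <- spec$centroid - rmax; hi <- spec$centroid + rmax
  if (any(lo < 2 * px) || any(hi > canvas * px - 2 * px))
    stop(sprintf(
      "phantom '%s' (footprint %.3g x %.3g um at %.4g, %.4g) does not fit canvas %d x %d px with a 2-pixel margin",
      spec$model, spec$footprint_radii[1], spec$footprint_radii[2],
      spec$centroid[1], spec$centroid[2], canvas[1], canvas[2]))
  opd <- matrix(0, canvas[1], canvas[2])
  patch <- .render_patch(spec, optics, canvas)
  opd[patch$i, patch$j] <- opd[patch$i, patch$j] + patch$opd
  mass_geo <- sum(opd) * px^2 / optics$alpha
  mass <- spec$dry_mass
  if (is.na(mass)) {
    mass <- mass_geo
  } else {
    if (mass_geo <= 0) stop("phantom rendered with zero mass; check geometry")
    opd <- opd * (mass / mass_geo)
  }
  tr <- .analytic_truth(spec)
  truth <- data.frame(id = 1L, model = spec$model,
                      x = spec$centroid[1], y = spec$centroid[2],
                      area = tr$area, volume = tr$volume, surface = tr$surface,
                      sphericity = tr$sphericity, lw_ratio = tr$lw_ratio,
                      dry_mass = mass, is_debris = tr$area < 400,
                      stringsAsFactors = FALSE)
  list(image = phase_image(opd, optics, time_h = time_h, well_id = well_id),
       truth = truth)
}

#' Sample spherical/ellipsoidal cap specs for a phantom population
#'
#' Convenience generator for populations with controlled analytic
#' truth: footprint areas drawn uniformly in `area_range`, a fixed
#' height/radius ratio (set directly or solved from a target analytic
#' sphericity), a fixed base-ellipse axis ratio and random
#' orientations.
#'
#' @param n number of specs.
#' @param area_range footprint-area range, um^2 (uniform draw).
#' @param sphericity target analytic sphericity (circular caps only);
#'   ignored when `k` is given.
#' @param k height over major semi-axis ratio; default solves
#'   `sphericity`, or 1 (hemisphere) when neither is given.
#' @param height fixed apex height, um, overriding `k`/`sphericity`;
#'   a population of uniform height has uniform peak phase contrast,
#'   which keeps a single global threshold valid across mixed sizes.
#' @param axis_ratio base-ellipse major/minor ratio (>= 1); 1 gives
#'   spherical caps.
#' @param dry_mass per-spec dry mass, pg; `NA` keeps the geometric mass.
#' @param seed integer seed for the draws.
#' @return list of [cell_phantom_spec()] (centroids unset).
#' @export
sample_cap_specs <- function(n, area_range = c(500, 900), sphericity = NULL,
                             k = NULL, axis_ratio = 1, dry_mass = NA_real_,
                             seed = 1L, height = NULL) {
  stopifnot(n >= 1, axis_ratio >= 1)
  if (is.null(k))
    k <- if (is.null(sphericity)) 1 else cap_ratio_for_sphericity(sphericity)
  draws <- .with_seed(seed, list(areas = stats::runif(n, area_range[1], area_range[2]),
                                 angles = stats::runif(n, 0, pi)))
  areas <- draws$areas
  angles <- draws$angles
  model <- if (axis_ratio > 1) "ellipsoidal_cap" else "spherical_cap"
  lapply(seq_len(n), function(i) {
    a <- sqrt(areas[i] * axis_ratio / pi)
    b <- a / axis_ratio
    h <- if (is.null(height)) k * a else height
    cell_phantom_spec(model, footprint_radii = c(a, b), height = h,
                      orientation = angles[i], dry_mass = dry_mass)
  })
}

# Evaluate `code` under an explicit seed, restoring the caller's RNG
# state afterwards. All package randomness flows through this helper so
# no operation depends on hidden global state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Render a composite field of cell and debris phantoms
#'
#' Places the supplied cell specs (plus optionally generated debris
#' specks) on a shared canvas without overlap, by seeded rejection
#' sampling with a hard cap of `max_attempts` placement attempts per
#' object, and renders the composite OPD image. Debris specks are
#' small spherical caps whose analytic footprint area is drawn
#' uniformly from `debris_area_range` (strictly below the 400 um^2
#' debris gate).
#'
#' Truth flags each object as debris iff its analytic area is below
#' 400 um^2, so the truth debris percentage is
#' `100 * n_debris / n_total`.
#'
#' @param cell_specs list of [cell_phantom_spec()]. Specs with set
#'   centroids keep them; specs with `NA` centroids are placed.
#' @param n_debris number of debris specks to generate (default 0).
#' @param debris_area_range analytic-area range for debris, um^2; must
#'   lie strictly below 400.
#' @param debris_k height/radius ratio of debris caps.
#' @param optics an [optics_config()].
#' @param canvas canvas size in pixels.
#' @param seed integer seed driving placement and debris draws.
#' @param min_gap minimum clearance between footprint bounding circles, um.
#' @param noise_sd additive Gaussian pixel noise, um OPD (0 = none).
#' @param max_attempts placement attempts per object before failing.
#' @param time_h,well_id passed to [phase_image()].
#' @return list with `image` (a [phase_image()]) and `truth` (data
#'   frame, one row per object in placement order).
#' @export
render_field <- function(cell_specs, n_debris = 0L,
                         debris_area_range = c(50, 370), debris_k = 0.4,
                         optics = optics_config(), canvas = c(512L, 512L),
                         seed = 1L, min_gap = 4, noise_sd = 0,
                         max_attempts = 10000L,
                         time_h = NA_real_, well_id = NA_character_) {
  stopifnot(is.list(cell_specs) || length(cell_specs) == 0)
  .with_seed(seed, {
    specs <- cell_specs
    if (n_debris > 0) {
      stopifnot(debris_area_range[2] < 400, debris_area_range[1] > 0)
      areas <- stats::runif(n_debris, debris_area_range[1], debris_area_range[2])
      specs <- c(specs, lapply(areas, function(A) {
        a <- sqrt(A / pi)
        cell_phantom_spec("spherical_cap", footprint_radii = a,
                          height = debris_k * a)
      }))
    }
    n <- length(specs)
    if (n == 0) {
      return(list(image = phase_image(matrix(0, canvas[1], canvas[2]), optics,
                                      time_h = time_h, well_id = well_id),
                  truth = .empty_truth()))
    }
    px <- optics$pixel_size
    extent <- canvas * px
    rad <- vapply(specs, function(s) max(s$footprint_radii), 0)
    # grid-bucket occupancy for fast collision tests against placed discs
    bucket <- 2 * max(rad) + min_gap
    nbx <- max(1L, ceiling(extent[1] / bucket))
    nby <- max(1L, ceiling(extent[2] / bucket))
    occ <- vector("list", nbx * nby)
    placed <- matrix(NA_real_, n, 3)  # x, y, r
    clamp <- function(v, lo, hi) min(max(v, lo), hi)
    add_occ <- function(i, x, y) {
      b <- (clamp(ceiling(y / bucket), 1L, nby) - 1L) * nbx +
        clamp(ceiling(x / bucket), 1L, nbx)
      occ[[b]] <<- c(occ[[b]], i)
    }
    collide <- function(x, y, r) {
      bx <- clamp(ceiling(x / bucket), 1L, nbx)
      by <- clamp(ceiling(y / bucket), 1L, nby)
      ids <- unlist(lapply(max(by - 1, 1):min(by + 1, nby), function(iy)
        occ[(iy - 1L) * nbx + (max(bx - 1, 1):min(bx + 1, nbx))]),
        use.names = FALSE)
      if (length(ids) == 0) return(FALSE)
      dx <- placed[ids, 1] - x
      dy <- placed[ids, 2] - y
      any(dx * dx + dy * dy < (placed[ids, 3] + r + min_gap)^2)
    }
    for (i in seq_len(n)) {
      s <- specs[[i]]
      r <- rad[i]
      margin <- r + 2 * px
      if (!any(is.na(s$centroid))) {
        placed[i, ] <- c(s$centroid, r)
        add_occ(i, s$centroid[1], s$centroid[2])
        next
      }
      if (2 * margin >= min(extent))
        stop(sprintf("phantom footprint (radius %.3g um) too large for canvas", r))
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        x <- stats::runif(1, margin, extent[1] - margin)
        y <- stats::runif(1, margin, extent[2] - margin)
        if (!collide(x, y, r)) {
          specs[[i]]$centroid <- c(x, y)
          placed[i, ] <- c(x, y, r)
          add_occ(i, x, y)
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf(
          "could not place object %d of %d after %d attempts (achieved packing density %.2f)",
          i, n, max_attempts,
          sum(pi * placed[seq_len(i - 1), 3]^2, na.rm = TRUE) / prod(extent)))
    }
    opd <- matrix(0, canvas[1], canvas[2])
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      s <- specs[[i]]
      patch <- .render_patch(s, optics, canvas)
      mass_geo <- sum(patch$opd) * px^2 / optics$alpha
      mass <- s$dry_mass
      if (is.na(mass)) mass <- mass_geo
      else patch$opd <- patch$opd * (mass / mass_geo)
      opd[patch$i, patch$j] <- opd[patch$i, patch$j] + patch$opd
      tr <- .analytic_truth(s)
      rows[[i]] <- data.frame(id = i, model = s$model,
                              x = s$centroid[1], y = s$centroid[2],
                              area = tr$area, volume = tr$volume,
                              surface = tr$surface, sphericity = tr$sphericity,
                              lw_ratio = tr$lw_ratio, dry_mass = mass,
                              is_debris = tr$area < 400,
                              stringsAsFactors = FALSE)
    }
    if (noise_sd > 0)
      opd <- pmax(opd + matrix(stats::rnorm(length(opd), 0, noise_sd),
                               nrow(opd), ncol(opd)), 0)
    truth <- do.call(rbind, rows)
    list(image = phase_image(opd, optics, time_h = time_h, well_id = well_id),
         truth = truth)
  })
}

.empty_truth <- function() {
  data.frame(id = integer(), model = character(), x = numeric(), y = numeric(),
             area = numeric(), volume = numeric(), surface = numeric(),
             sphericity = numeric(), lw_ratio = numeric(), dry_mass = numeric(),
             is_debris = logical(), stringsAsFactors = FALSE)
}

#' Debris percentage of a phantom-truth table
#' @param truth truth data frame from [render_field()].
#' @return percentage of objects flagged as debris.
#' @export
truth_debris_percent <- function(truth) {
  if (nrow(truth) == 0) return(0)
  100 * sum(truth$is_debris) / nrow(truth)
}

#' Simulate a morphology time-lapse with deterministic shape drift
#'
#' Renders the same phantom population at successive frames while
#' drifting each cell's shape: the base-ellipse axis ratio changes by
#' `lw_per_h` per hour and the analytic sphericity by
#' `sphericity_per_h` per hour (footprint area is held fixed; the cap
#' height/radius ratio is re-solved each frame). Cell positions are
#' placed once at frame 1 and held, emulating slow-moving adherent
#' cells between coarse time bins.
#'
#' @param specs list of [cell_phantom_spec()] (the frame-0 population;
#'   circular or elliptical caps).
#' @param shape_drift list with elements `lw_per_h` and
#'   `sphericity_per_h` (either may be 0).
#' @param frames number of frames (>= 2).
#' @param interval_h hours between frames.
#' @param optics,canvas,seed,min_gap as in [render_field()].
#' @return list with `images` (list of [phase_image()]) and `truth`
#'   (data frame per frame: time_h, n, mean_sphericity, mean_lw).
#' @export
simulate_timelapse <- function(specs, shape_drift = list(lw_per_h = 0,
                                                         sphericity_per_h = 0),
                               frames = 2L, interval_h = 3,
                               optics = optics_config(),
                               canvas = c(512L, 512L), seed = 1L,
                               min_gap = 4) {
  stopifnot(frames >= 2)
  lw0 <- vapply(specs, function(s) s$footprint_radii[1] / s$footprint_radii[2], 0)
  s0 <- vapply(specs, function(s)
    cap_sphericity(s$height / s$footprint_radii[1]), 0)
  areas <- vapply(specs, function(s) pi * prod(s$footprint_radii), 0)
  base <- render_field(specs, optics = optics, canvas = canvas, seed = seed,
                       min_gap = min_gap)
  centres <- base$truth[, c("x", "y")]
  images <- vector("list", frames)
  truth <- vector("list", frames)
  for (f in seq_len(frames)) {
    t_h <- (f - 1) * interval_h
    lw <- pmax(lw0 + shape_drift$lw_per_h * t_h, 1)
    sp <- pmin(pmax(s0 + shape_drift$sphericity_per_h * t_h, 1e-4), 1)
    fspecs <- lapply(seq_along(specs), function(i) {
      a <- sqrt(areas[i] * lw[i] / pi)
      b <- a / lw[i]
      k <- cap_ratio_for_sphericity(sp[i])
      cell_phantom_spec(if (lw[i] > 1) "ellipsoidal_cap" else "spherical_cap",
                        footprint_radii = c(a, b), height = k * a,
                        centroid = as.numeric(centres[i, ]),
                        orientation = specs[[i]]$orientation)
    })
    out <- render_field(fspecs, optics = optics, canvas = canvas, seed = seed,
                        min_gap = min_gap, time_h = t_h)
    images[[f]] <- out$image
    truth[[f]] <- data.frame(time_h = t_h, n = nrow(out$truth),
                             mean_sphericity = mean(out$truth$sphericity),
                             mean_lw = mean(out$truth$lw_ratio))
  }
  list(images = images, truth = do.call(rbind, truth))
}
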