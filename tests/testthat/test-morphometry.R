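test_that("segmentation finds isolated phantoms one-to-one", {
  opt <- opt05()
  rc <- render_cell(hemisphere_spec(15), opt, canvas = c(128L, 128L))
  lab <- segment(rc$image)
  expect_equal(n_objects(lab), 1L)

  # all-zero image: empty label map, not an error
  z <- phase_image(matrix(0, 32, 32), opt)
  expect_equal(n_objects(segment(z)), 0L)

  # 20 non-overlapping cells: 20 objects, each holding one truth centroid
  specs <- sample_cap_specs(20, area_range = c(450, 700), sphericity = 0.3,
                            seed = 21)
  fld <- render_field(specs, optics = opt1(), canvas = c(600L, 600L), seed = 22)
  lab2 <- segment(fld$image, smoothing_scale = 1)
  expect_equal(n_objects(lab2), 20L)
  at <- lab2$labels[cbind(round(fld$truth$x), round(fld$truth$y))]
  expect_true(all(at > 0))
  expect_equal(length(unique(at)), 20L)
})

test_that("watershed separates touching cells into their seeded objects", {
  opt <- opt1()
  s1 <- cell_phantom_spec("spherical_cap", 12, height = 6, centroid = c(50, 60))
  s2 <- cell_phantom_spec("spherical_cap", 12, height = 6, centroid = c(74, 60))
  fld <- render_field(list(s1, s2), optics = opt, canvas = c(124L, 124L),
                      seed = 1, min_gap = -100)
  lab <- segment(fld$image, smoothing_scale = 1, watershed_tolerance = 0.02)
  expect_equal(n_objects(lab), 2L)
  expect_true(lab$labels[50, 60] != lab$labels[74, 60])
})

test_that("size gate partitions objects exhaustively at the 400 um^2 boundary", {
  # constructed label map with areas exactly 399, 400, 401 um^2 (1 um/px)
  m <- matrix(0L, 100, 140)
  put <- function(m, id, npx, row0) {
    cols <- ceiling(npx / 20)
    filled <- 0
    for (cc in seq_len(cols)) {
      take <- min(20, npx - filled)
      m[row0 + seq_len(take) - 1, 10 + (id - 1) * 40 + cc] <- id
      filled <- filled + take
    }
    m
  }
  m <- put(m, 1L, 399L, 10); m <- put(m, 2L, 400L, 10); m <- put(m, 3L, 401L, 10)
  lab <- label_map(m, pixel_size = 1)
  g <- apply_size_gate(lab, min_area = 400, strict = TRUE)
  expect_equal(g$summary$n_total, 3L)
  expect_equal(g$summary$n_cells, 1L)   # only 401 survives a strict gate
  expect_equal(g$summary$n_debris, 2L)  # 399 and 400 classed debris
  g2 <- apply_size_gate(lab, min_area = 400, strict = FALSE)
  expect_equal(g2$summary$n_cells, 2L)  # >= keeps 400
  # partition identity on any input
  expect_equal(g$summary$n_cells + g$summary$n_debris, g$summary$n_total)

  # empty label map: zero counts, debris percent 0 by convention
  e <- apply_size_gate(label_map(matrix(0L, 8, 8), 1))
  expect_equal(unlist(e$summary), c(n_total = 0, n_cells = 0, n_debris = 0,
                                    debris_percent = 0))
})

test_that("measured debris percentage equals the seeded fraction", {
  opt <- opt1()
  specs <- sample_cap_specs(46, area_range = c(430, 700), height = 1, seed = 31)
  fld <- render_field(specs, n_debris = 4, debris_area_range = c(60, 360),
                      optics = opt, canvas = c(700L, 700L), seed = 32)
  lab <- segment(fld$image, smoothing_scale = 1, split_touching = FALSE)
  g <- apply_size_gate(lab)
  expect_equal(g$summary$n_total, 50L)
  expect_equal(g$summary$debris_percent, truth_debris_percent(fld$truth))
})

test_that("measure reproduces analytic dry mass, thickness and shape", {
  opt <- opt05()
  # forced single-object mask on a zero image: all metrics zero
  z <- phase_image(matrix(0, 32, 32), opt)
  mask <- label_map(matrix(1L, 32, 32), 0.5)
  rz <- measure(z, mask)
  expect_equal(rz$dry_mass, 0)
  expect_equal(rz$mean_optical_thickness, 0)
  expect_equal(rz$max_optical_thickness, 0)

  # hemisphere: sphericity 1 within 2% discretisation tolerance
  rc <- render_cell(hemisphere_spec(15), opt, canvas = c(128L, 128L))
  rec <- measure(rc$image, segment(rc$image))
  expect_equal(rec$sphericity, 1, tolerance = 0.02)

  # seeded 12 pg Gaussian bump recovered within 0.5%
  sp <- cell_phantom_spec("gaussian_bump", footprint_radii = c(12, 9),
                          height = 4, dry_mass = 12, orientation = 0.4)
  rcg <- render_cell(sp, opt, canvas = c(128L, 128L))
  recg <- measure(rcg$image, segment(rcg$image))
  expect_equal(recg$dry_mass, 12, tolerance = 0.005)

  # ellipsoidal cap axis ratio 1.66 within 2%
  spe <- cell_phantom_spec("ellipsoidal_cap", footprint_radii = c(16.6, 10),
                           height = 3, orientation = 1.1)
  rce <- render_cell(spe, opt, canvas = c(128L, 128L))
  rece <- measure(rce$image, segment(rce$image))
  expect_equal(rece$length_width_ratio, 1.66, tolerance = 0.02)
})

test_that("dry mass agrees with brute-force truth-footprint summation on random phantoms", {
  opt <- opt05()
  set.seed(77)
  for (i in 1:20) {
    sp <- random_phantom_spec()
    rc <- render_cell(sp, opt, canvas = c(128L, 128L))
    oracle <- brute_force_mass(rc$image)
    rec <- measure(rc$image, segment(rc$image))
    expect_equal(rec$dry_mass, oracle, tolerance = 0.005)
    expect_equal(oracle, sp$dry_mass, tolerance = 1e-12)
  }
})

test_that("shape metrics are rotation invariant within 2%", {
  opt <- opt05()
  base <- cell_phantom_spec("ellipsoidal_cap", footprint_radii = c(14, 9),
                            height = 2.5, orientation = 0)
  rot <- cell_phantom_spec("ellipsoidal_cap", footprint_radii = c(14, 9),
                           height = 2.5, orientation = 37 * pi / 180)
  r0 <- measure(render_cell(base, opt, c(128L, 128L))$image,
                segment(render_cell(base, opt, c(128L, 128L))$image))
  r1 <- measure(render_cell(rot, opt, c(128L, 128L))$image,
                segment(render_cell(rot, opt, c(128L, 128L))$image))
  expect_lt(abs(r1$length_width_ratio / r0$length_width_ratio - 1), 0.02)
  expect_lt(abs(r1$sphericity / r0$sphericity - 1), 0.02)
})

test_that("measured sphericity increases with cap height at fixed volume", {
  opt <- opt05()
  # strict growth below the clip region; near-hemispherical caps clip
  # to 1 against discretisation overshoot, so the top end is only
  # required to be nondecreasing
  ks <- c(0.08, 0.15, 0.3, 0.45, 0.6, 0.8, 1)
  vol <- cap_volume(12, 12 * 0.5)
  sph <- vapply(ks, function(k) {
    a <- stats::uniroot(function(a) cap_volume(a, k * a) - vol,
                        c(2, 60))$root
    rc <- render_cell(cell_phantom_spec("spherical_cap", a, height = k * a),
                      opt, canvas = c(160L, 160L))
    measure(rc$image, segment(rc$image))$sphericity
  }, 0)
  expect_true(all(diff(sph[1:5]) > 0))
  expect_true(all(diff(sph) >= 0))
  expect_lte(max(sph), 1)
})

test_that("field dry mass is conserved within 1%", {
  opt <- opt1()
  specs <- sample_cap_specs(25, area_range = c(450, 800), sphericity = 0.3,
                            dry_mass = 40, seed = 51)
  fld <- render_field(specs, optics = opt, canvas = c(700L, 700L), seed = 52)
  lab <- segment(fld$image, smoothing_scale = 1)
  rec <- measure(fld$image, lab)
  expect_equal(sum(rec$dry_mass), sum(fld$truth$dry_mass), tolerance = 0.01)
})

test_that("fluorescence pairing thresholds background and averages per object", {
  opt <- opt05()
  rc <- render_cell(hemisphere_spec(12), opt, canvas = c(96L, 96L))
  lab <- segment(rc$image)
  rec <- measure(rc$image, lab)
  # uniform 49 AU: everything below the 50 AU background threshold
  expect_equal(pair_fluorescence(rec, lab, matrix(49, 96, 96))$fluorescence_mean, 0)
  expect_equal(pair_fluorescence(rec, lab, matrix(200, 96, 96))$fluorescence_mean, 200)
  # half the object at 0, half at 100 -> mean 50
  half <- matrix(0, 96, 96); half[1:48, ] <- 100
  npix_hi <- sum(lab$labels[1:48, ] > 0); npix <- sum(lab$labels > 0)
  expect_equal(pair_fluorescence(rec, lab, half)$fluorescence_mean,
               100 * npix_hi / npix)
  expect_error(pair_fluorescence(rec, lab, matrix(0, 10, 10)), "does not match")
})

test_that("sphericity grouping splits at the boundary and flags empty groups", {
  rec <- data.frame(sphericity = c(0.20, 0.30), fluorescence_mean = c(10, 90))
  s <- split_by_sphericity(rec, boundary = 0.25)
  expect_equal(s$mean_fluorescence[s$group == "below"], 10)
  expect_equal(s$mean_fluorescence[s$group == "above"], 90)
  rec2 <- data.frame(sphericity = c(0.1, 0.2), fluorescence_mean = c(5, 6))
  s2 <- split_by_sphericity(rec2)
  expect_true(s2$empty[s2$group == "above"])
  expect_equal(s2$n[s2$group == "above"], 0)
  expect_error(split_by_sphericity(data.frame(sphericity = 0.3)), "fluorescence")
})

test_that("high-sphericity phantoms assigned brighter fluorescence separate by group", {
  # one field per morphology (Otsu thresholds assume comparable peak
  # phase per field; see the vignette on mixed-height populations),
  # records pooled afterwards as in a multi-well experiment
  opt <- opt1()
  measure_group <- function(sph, fluor_level, seed) {
    specs <- sample_cap_specs(6, area_range = c(500, 650), sphericity = sph,
                              seed = seed)
    fld <- render_field(specs, optics = opt, canvas = c(450L, 450L),
                        seed = seed + 1)
    lab <- segment(fld$image, smoothing_scale = 1)
    rec <- measure(fld$image, lab)
    pair_fluorescence(rec, lab, matrix(fluor_level, 450, 450))
  }
  rec <- rbind(measure_group(0.18, 100, 61), measure_group(0.45, 500, 63))
  s <- split_by_sphericity(rec, 0.25)
  expect_equal(s$n, c(6, 6))
  ratio <- s$mean_fluorescence[s$group == "above"] /
    s$mean_fluorescence[s$group == "below"]
  expect_equal(ratio, 5, tolerance = 0.01)
})
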