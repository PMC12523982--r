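render_and_graph <- function(g, canvas, tw = 16, ...) {
  rn <- render_network(g, tube_width = tw, optics = opt1(), canvas = canvas)
  skeletonize_and_graph(make_tube_mask(rn$image), pixel_size = 1, ...)
}

test_that("elementary phantoms reproduce seed-graph counts exactly", {
  cases <- list(
    list(g = y_graph(100, c(200, 200)), canvas = c(400L, 400L)),
    list(g = line_graph(250, c(25, 50)), canvas = c(300L, 100L)),
    list(g = ring_graph(80, c(150, 150)), canvas = c(300L, 300L)),
    list(g = brick_lattice_graph(3, 3, 120, 80), canvas = c(500L, 400L)))
  for (cs in cases) {
    truth <- seed_graph_metrics(cs$g)
    got <- network_metrics(render_and_graph(cs$g, cs$canvas))
    expect_equal(got$n_segments, truth$n_segments)
    expect_equal(got$n_junctions, truth$n_junctions)
    expect_equal(got$n_extremities, truth$n_extremities)
    expect_equal(got$n_branches, truth$n_branches)
    expect_equal(got$total_length, truth$total_length, tolerance = 0.03)
  }
})

test_that("tree identity holds on acyclic phantoms", {
  for (g in list(y_graph(100, c(200, 200)), line_graph(250, c(25, 50)))) {
    m <- network_metrics(render_and_graph(
      g, if (nrow(g$nodes) == 2) c(300L, 100L) else c(400L, 400L)))
    expect_equal(m$n_segments, m$n_junctions + m$n_extremities - 1)
  }
})

test_that("every branch touches an extremity and extremities are degree 1", {
  ng <- render_and_graph(y_graph(100, c(200, 200)), c(400L, 400L))
  ext <- ng$nodes$id[ng$nodes$kind == "extremity"]
  expect_true(all(ng$nodes$degree[ng$nodes$kind == "extremity"] == 1))
  for (e in seq_len(nrow(ng$edges))) {
    br <- ng$edges$is_branch[e]
    has_ext <- ng$edges$from[e] %in% ext || ng$edges$to[e] %in% ext
    expect_equal(br, has_ext)
  }
  # each extremity belongs to exactly one edge
  for (x in ext)
    expect_equal(sum(ng$edges$from == x) + sum(ng$edges$to == x), 1L)
})

test_that("graph extraction is idempotent on a 1-pixel skeleton", {
  # hand-built plus-sign skeleton: thinning must leave it untouched
  sk <- matrix(FALSE, 120, 120)
  sk[20:100, 60] <- TRUE
  sk[60, 20:100] <- TRUE
  expect_identical(qpihuvec:::.thin_guo_hall(sk), sk)
  ng <- skeletonize_and_graph(sk, pixel_size = 1, prune_length = 5)
  m <- network_metrics(ng)
  expect_equal(m$n_segments, 4)
  expect_equal(m$n_junctions, 1)
  expect_equal(m$n_extremities, 4)
  expect_equal(m$total_length, 160, tolerance = 0.02)
  # a diagonal 1-px line survives thinning too
  d <- matrix(FALSE, 80, 80)
  d[cbind(10:70, 10:70)] <- TRUE
  expect_identical(qpihuvec:::.thin_guo_hall(d), d)
  md <- network_metrics(skeletonize_and_graph(d, 1))
  expect_equal(md$n_segments, 1)
  expect_equal(md$total_length, 60 * sqrt(2), tolerance = 0.02)
})

test_that("metrics are invariant to translation and 90-degree rotation", {
  g0 <- y_graph(100, c(170, 170))
  m0 <- network_metrics(render_and_graph(g0, c(340L, 340L)))
  # translate
  gt <- y_graph(100, c(190, 150))
  mt <- network_metrics(render_and_graph(gt, c(340L, 340L)))
  # rotate the seed graph 90 degrees about the canvas centre
  gr <- y_graph(100, c(170, 170))
  gr$nodes[, c("x", "y")] <- cbind(340 - gr$nodes$y, gr$nodes$x)
  gr$edges$polyline <- lapply(gr$edges$polyline, function(p)
    cbind(340 - p[, 2], p[, 1]))
  mr <- network_metrics(render_and_graph(gr, c(340L, 340L)))
  for (m in list(mt, mr)) {
    expect_equal(m$n_segments, m0$n_segments)
    expect_equal(m$n_junctions, m0$n_junctions)
    expect_equal(m$n_extremities, m0$n_extremities)
    expect_equal(m$n_branches, m0$n_branches)
    expect_equal(m$total_length, m0$total_length, tolerance = 0.02)
  }
})

test_that("increasing prune_length never increases branch count", {
  # Y with one short stub arm: prune thresholds sweep it away
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  arm <- c(100, 100, 30)
  nodes <- data.frame(id = 1:4,
                      x = c(200, 200 + arm * cos(ang)),
                      y = c(200, 200 + arm * sin(ang)))
  g <- seed_graph(nodes, data.frame(from = 1L, to = 2:4))
  rn <- render_network(g, tube_width = 12, optics = opt1(),
                       canvas = c(400L, 400L))
  mask <- make_tube_mask(rn$image)
  branches <- vapply(c(5, 20, 40, 120), function(pl)
    network_metrics(skeletonize_and_graph(mask, 1, prune_length = pl))$n_branches,
    0)
  expect_true(all(diff(branches) <= 0))
  # at prune 5 the stub survives (3 branches); at 40 it is gone
  expect_equal(branches[1], 3)
  expect_lt(branches[3], 3)
})

test_that("boundary-touching branches are flagged, interior ones are not", {
  g <- y_graph(100, c(200, 200))
  rn <- render_network(g, optics = opt1(), canvas = c(400L, 400L))
  ng <- skeletonize_and_graph(make_tube_mask(rn$image), 1)
  ng <- flag_boundary_branches(ng, image_extent(rn$image), margin = 2)
  expect_false(any(ng$edges$touches_boundary))

  # tube running to 1 px from the frame edge
  g2 <- line_graph(190, origin = c(9, 50))
  rn2 <- render_network(g2, tube_width = 14, optics = opt1(),
                        canvas = c(208L, 100L))
  ng2 <- skeletonize_and_graph(make_tube_mask(rn2$image), 1)
  ng2 <- flag_boundary_branches(ng2, image_extent(rn2$image), margin = 10)
  expect_true(any(ng2$edges$touches_boundary))
  # flagged branches can be excluded from the metric downstream
  m_with <- network_metrics(ng2)
  m_wo <- network_metrics(ng2, exclude_boundary_branches = TRUE)
  expect_lte(m_wo$n_branches, m_with$n_branches)
})

test_that("tube mask matches analytic stadium area and handles empty input", {
  opt <- opt1()
  g <- y_graph(100, c(200, 200))
  rn <- render_network(g, tube_width = 16, optics = opt, canvas = c(400L, 400L))
  mask <- make_tube_mask(rn$image)
  # independent dense-grid oracle for the stadium-union area
  xs <- seq(0.25, 400, by = 0.5); r <- 8
  segs <- lapply(seq_len(nrow(g$edges)), function(e) g$edges$polyline[[e]])
  inside <- matrix(FALSE, length(xs), length(xs))
  for (p in segs) {
    a <- p[1, ]; b <- p[2, ]; ab <- b - a; l2 <- sum(ab^2)
    dx <- outer(xs - a[1], rep(1, length(xs)))
    dy <- outer(rep(1, length(xs)), xs - a[2])
    tt <- pmin(pmax((dx * ab[1] + dy * ab[2]) / l2, 0), 1)
    inside <- inside | ((dx - tt * ab[1])^2 + (dy - tt * ab[2])^2 <= r^2)
  }
  oracle_area <- sum(inside) * 0.25
  expect_equal(sum(mask) * 1, oracle_area, tolerance = 0.05)
  # single straight tube: one 8-connected component
  rn2 <- render_network(line_graph(200, c(25, 40)), optics = opt,
                        canvas = c(250L, 80L))
  m2 <- make_tube_mask(rn2$image)
  expect_equal(max(qpihuvec:::.label8(m2)), 1L)
  # all-zero image: empty mask and empty graph downstream
  z <- phase_image(matrix(0, 64, 64), opt)
  mz <- make_tube_mask(z)
  expect_false(any(mz))
  mg <- network_metrics(skeletonize_and_graph(mz, 1))
  expect_equal(mg$n_segments, 0)
  expect_equal(mg$total_length, 0)
  expect_true(is.na(mg$median_segment_length))
})

test_that("time-course normalisation anchors the baseline at 100%", {
  series <- data.frame(time_h = 1:4,
                       n_segments = c(40, 30, 20, 20),
                       n_junctions = c(10, 8, 6, 5),
                       total_length = c(4000, 3600, 3000, 2800),
                       median_segment_length = c(80, 95, 120, 130))
  out <- normalize_timecourse(series, baseline_time_h = 1)
  expect_equal(out$pct_n_segments, c(100, 75, 50, 50))
  expect_equal(out$pct_total_length[1], 100)
  # halving identity
  expect_equal(out$pct_n_segments[3], 50)
  # zero baseline flags the metric undefined
  series$n_junctions[1] <- 0
  out2 <- normalize_timecourse(series, 1)
  expect_true(all(is.na(out2$pct_n_junctions)))
  expect_error(normalize_timecourse(series, baseline_time_h = 9), "baseline")
})

test_that("simulated coalescence yields monotone normalised segment counts", {
  # merge ties progressively: 3, 2, 1 rungs of a ladder between two rails
  mk <- function(n_ties) {
    xs <- seq(60, 340, length.out = 5)
    nodes <- data.frame(id = 1:2, x = c(50, 350), y = c(60, 60))
    edges <- data.frame(from = 1, to = 2)
    edges$polyline <- list(cbind(c(50, 350), c(60, 60)))
    nodes2 <- data.frame(id = 3:4, x = c(50, 350), y = c(160, 160))
    edges2 <- data.frame(from = 3, to = 4)
    edges2$polyline <- list(cbind(c(50, 350), c(160, 160)))
    ties <- lapply(seq_len(n_ties), function(i)
      cbind(c(xs[i + 1], xs[i + 1]), c(60, 160)))
    g <- list()
    nodes <- rbind(nodes, nodes2)
    edges <- rbind(edges, edges2)
    for (tphe in ties) edges <- rbind(edges, data.frame(
      from = NA, to = NA, polyline = I(list(tphe))))
    # rebuild with explicit tie nodes so degrees validate
    nid <- 4
    for (i in seq_len(n_ties)) {
      x <- xs[i + 1]
      nodes <- rbind(nodes, data.frame(id = nid + 1, x = x, y = 60),
                     data.frame(id = nid + 2, x = x, y = 160))
      nid <- nid + 2
    }
    # edges: rails split at tie points, plus ties
    rail <- function(y, ids) {
      pts <- c(if (y == 60) 1 else 3, ids, if (y == 60) 2 else 4)
      data.frame(from = pts[-length(pts)], to = pts[-1])
    }
    top_ids <- if (n_ties) 4 + seq(1, 2 * n_ties, by = 2) else integer()
    bot_ids <- if (n_ties) 4 + seq(2, 2 * n_ties, by = 2) else integer()
    e <- rbind(rail(60, top_ids), rail(160, bot_ids),
               if (n_ties) data.frame(from = top_ids, to = bot_ids))
    seed_graph(nodes, e)
  }
  mets <- lapply(1:3, function(i) {
    g <- mk(4 - i)  # 3, 2, 1 ties: tubes coalesce over time
    rn <- render_network(g, tube_width = 14, optics = opt1(),
                         canvas = c(400L, 220L))
    network_metrics(skeletonize_and_graph(make_tube_mask(rn$image), 1),
                    time_h = i)
  })
  out <- normalize_timecourse(do.call(rbind, mets), baseline_time_h = 1)
  expect_true(all(diff(out$pct_n_segments) < 0))
  expect_true(all(diff(out$pct_n_junctions) < 0))
  # median segment length grows as the network coalesces
  expect_true(all(diff(out$median_segment_length) > 0))
})
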