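#' Seeded planar graph describing a tube network
#'
#' Ground-truth representation of a capillary-like network: nodes are
#' either junctions (meeting points of three or more segments) or
#' extremities (free ends), and each edge is a polyline between two
#' nodes. Degree-2 points are not nodes; they belong inside a segment
#' polyline, and `collapse_degree2 = TRUE` (the default) folds any
#' degree-2 nodes of the input into the polylines of their incident
#' edges. A segment that terminates in at least one extremity is a
#' branch.
#'
#' @param nodes data frame with columns `id`, `x`, `y` (um).
#' @param edges data frame with columns `from`, `to` (node ids);
#'   optionally a list column `polyline` of n x 2 coordinate matrices
#'   (um) including both endpoints. Straight edges are the default.
#' @param collapse_degree2 fold degree-2 nodes into polylines.
#' @return object of class `seed_graph` with `nodes` (id, x, y, kind,
#'   degree) and `edges` (from, to, length, is_branch, polyline).
#' @export
seed_graph <- function(nodes, edges, collapse_degree2 = TRUE) {
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            all(c("from", "to") %in% names(edges)))
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (is.null(edges$polyline)) {
    edges$polyline <- lapply(seq_len(nrow(edges)), function(e) {
      i <- match(edges$from[e], nodes$id)
      j <- match(edges$to[e], nodes$id)
      rbind(c(nodes$x[i], nodes$y[i]), c(nodes$x[j], nodes$y[j]))
    })
  }
  deg <- function() {
    d <- table(factor(c(edges$from, edges$to), levels = nodes$id))
    as.integer(d)
  }
  if (collapse_degree2) {
    repeat {
      d <- deg()
      k <- which(d == 2L)
      # self-loop nodes count twice and must stay
      k <- k[vapply(k, function(i) {
        id <- nodes$id[i]
        sum(edges$from == id & edges$to == id) == 0
      }, TRUE)]
      if (length(k) == 0) break
      id <- nodes$id[k[1]]
      inc <- which(edges$from == id | edges$to == id)
      orient <- function(e, endpoint_last) {
        p <- edges$polyline[[e]]
        last_is_id <- edges$to[e] == id
        if (endpoint_last != last_is_id) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
        p
      }
      e1 <- inc[1]; e2 <- inc[2]
      p1 <- orient(e1, TRUE)   # ends at the node
      p2 <- orient(e2, FALSE)  # starts at the node
      other1 <- if (edges$to[e1] == id) edges$from[e1] else edges$to[e1]
      other2 <- if (edges$from[e2] == id) edges$to[e2] else edges$from[e2]
      edges$from[e1] <- other1
      edges$to[e1] <- other2
      edges$polyline[[e1]] <- rbind(p1, p2[-1, , drop = FALSE])
      edges <- edges[-e2, , drop = FALSE]
      nodes <- nodes[-k[1], , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  d <- deg()
  if (any(d == 0))
    stop("seed graph has isolated nodes")
  self_anchor <- nodes$id %in% edges$from[edges$from == edges$to]
  if (any(d == 2 & !self_anchor))
    stop("degree-2 nodes are not allowed in a seed graph; they belong inside a segment polyline")
  nodes$degree <- d
  nodes$kind <- ifelse(self_anchor & d == 2L, "loop_anchor",
                       ifelse(d == 1L, "extremity", "junction"))
  polylen <- function(p) sum(sqrt(rowSums(diff(p)^2)))
  edges$length <- vapply(edges$polyline, polylen, 0)
  if (any(edges$length <= 0)) stop("zero-length edge in seed graph")
  ext <- nodes$id[nodes$kind == "extremity"]
  edges$is_branch <- edges$from %in% ext | edges$to %in% ext
  structure(list(nodes = nodes, edges = edges), class = "seed_graph")
}

#' Brute-force truth tallies of a seed graph
#'
#' Counts computed directly from the node/edge tables: segments are
#' edges, junctions are nodes of degree >= 3, extremities nodes of
#' degree 1, branches edges incident to at least one extremity.
#'
#' @param graph a [seed_graph()].
#' @return one-row data frame: n_segments, n_junctions, n_extremities,
#'   n_branches, total_length, median_segment_length.
#' @export
seed_graph_metrics <- function(graph) {
  stopifnot(inherits(graph, "seed_graph"))
  data.frame(n_segments = nrow(graph$edges),
             n_junctions = sum(graph$nodes$kind == "junction"),
             n_extremities = sum(graph$nodes$kind == "extremity"),
             n_branches = sum(graph$edges$is_branch),
             total_length = sum(graph$edges$length),
             median_segment_length = stats::median(graph$edges$length))
}

#' @export
print.seed_graph <- function(x, ...) {
  m <- seed_graph_metrics(x)
  cat(sprintf("seed_graph: %d segments, %d junctions, %d extremities, %d branches, total %.4g um\n",
              m$n_segments, m$n_junctions, m$n_extremities, m$n_branches,
              m$total_length))
  invisible(x)
}

#' Elementary seed graphs
#'
#' Constructors for the reference networks used in tests and examples:
#' a Y (one junction, three arms), a straight line, a closed ring
#' (approximated by a polygon; no nodes in the graph sense, kept as a
#' self-loop edge) and a running-bond "brick" lattice whose interior
#' nodes are all T-junctions and whose outer tie ends are extremities.
#'
#' @param arm,length,radius,origin geometry in um.
#' @param rows,cols number of brick rows/columns.
#' @param brick_w,brick_h brick width and height, um.
#' @name elementary_graphs
NULL

#' @rdname elementary_graphs
#' @export
y_graph <- function(arm = 100, origin = c(200, 200)) {
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  nodes <- data.frame(id = 1:4,
                      x = c(origin[1], origin[1] + arm * cos(ang)),
                      y = c(origin[2], origin[2] + arm * sin(ang)))
  edges <- data.frame(from = 1L, to = 2:4)
  seed_graph(nodes, edges)
}

#' @rdname elementary_graphs
#' @export
line_graph <- function(length = 250, origin = c(50, 50)) {
  nodes <- data.frame(id = 1:2, x = c(origin[1], origin[1] + length),
                      y = c(origin[2], origin[2]))
  seed_graph(nodes, data.frame(from = 1L, to = 2L))
}

#' @rdname elementary_graphs
#' @export
ring_graph <- function(radius = 80, origin = c(150, 150), n_vertices = 72) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)
  poly <- cbind(origin[1] + radius * cos(th), origin[2] + radius * sin(th))
  nodes <- data.frame(id = 1L, x = poly[1, 1], y = poly[1, 2])
  edges <- data.frame(from = 1L, to = 1L)
  edges$polyline <- list(poly)
  seed_graph(nodes, edges, collapse_degree2 = FALSE)
}

#' @rdname elementary_graphs
#' @export
brick_lattice_graph <- function(rows = 3, cols = 3, brick_w = 120,
                                brick_h = 80, origin = c(60, 60)) {
  # horizontal courses at y = origin2 + r * brick_h for r in 0..rows;
  # vertical ties staggered half a brick between alternate courses.
  key <- function(x, y) sprintf("%.6f_%.6f", x, y)
  xs <- origin[1] + (0:cols) * brick_w
  pts <- list(); pid <- integer(0)
  getid <- function(x, y) {
    k <- key(x, y)
    if (is.null(pts[[k]])) {
      pts[[k]] <<- c(x, y, length(pts) + 1)
    }
    as.integer(pts[[k]][3])
  }
  ef <- integer(0); et <- integer(0)
  # ties: verticals between courses r and r+1 at staggered x positions
  for (r in 0:(rows - 1)) {
    off <- if (r %% 2 == 0) 0 else brick_w / 2
    tx <- origin[1] + off + (0:cols) * brick_w
    tx <- tx[tx <= origin[1] + cols * brick_w + 1e-9]
    for (x in tx) {
      y0 <- origin[2] + r * brick_h
      y1 <- y0 + brick_h
      ef <- c(ef, getid(x, y0)); et <- c(et, getid(x, y1))
    }
  }
  # horizontal courses split at every tie abutting them
  for (r in 0:rows) {
    ys <- origin[2] + r * brick_h
    tie_x <- sort(unique(vapply(pts, function(p)
      if (abs(p[2] - ys) < 1e-9) p[1] else NA_real_, 0)))
    tie_x <- tie_x[!is.na(tie_x)]
    tie_x <- sort(unique(c(origin[1], tie_x, origin[1] + cols * brick_w)))
    for (i in seq_len(length(tie_x) - 1)) {
      ef <- c(ef, getid(tie_x[i], ys)); et <- c(et, getid(tie_x[i + 1], ys))
    }
  }
  mat <- do.call(rbind, pts)
  nodes <- data.frame(id = as.integer(mat[, 3]), x = mat[, 1], y = mat[, 2])
  nodes <- nodes[order(nodes$id), ]
  seed_graph(nodes, data.frame(from = ef, to = et))
}

#' Render a seed graph as a phase image of tubes
#'
#' Draws each edge polyline as a stadium-shaped tube: every pixel
#' within `tube_width / 2` of the polyline receives OPD `tube_opd`
#' (overlaps do not add). Rounded tube ends place the medial axis
#' endpoints at the seed-graph node coordinates.
#'
#' @param graph a [seed_graph()]. Junction nodes must have degree >= 3
#'   and extremities degree 1 (enforced at construction).
#' @param tube_width full tube width, um.
#' @param tube_opd OPD inside the tube, um.
#' @param optics an [optics_config()].
#' @param canvas canvas size in pixels; edges must lie inside it.
#' @param time_h,well_id passed to [phase_image()].
#' @return list with `image` (a [phase_image()]) and `truth`
#'   (the [seed_graph_metrics()] row, plus per-segment lengths in
#'   attribute `"segment_lengths"`).
#' @export
render_network <- function(graph, tube_width = 16, tube_opd = 0.3,
                           optics = optics_config(pixel_size = 1),
                           canvas = c(400L, 400L),
                           time_h = NA_real_, well_id = NA_character_) {
  stopifnot(inherits(graph, "seed_graph"), tube_width > 0, tube_opd > 0)
  px <- optics$pixel_size
  extent <- canvas * px
  allpts <- do.call(rbind, graph$edges$polyline)
  r <- tube_width / 2
  if (any(allpts[, 1] < r) || any(allpts[, 2] < r) ||
      any(allpts[, 1] > extent[1] - r) || any(allpts[, 2] > extent[2] - r))
    stop("seed-graph polylines (plus tube radius) must lie inside the canvas")
  opd <- matrix(0, canvas[1], canvas[2])
  for (e in seq_len(nrow(graph$edges))) {
    p <- graph$edges$polyline[[e]]
    for (s in seq_len(nrow(p) - 1)) {
      a <- p[s, ]; b <- p[s + 1, ]
      lo <- pmin(a, b) - r; hi <- pmax(a, b) + r
      i0 <- max(1L, floor(lo[1] / px)); i1 <- min(canvas[1], ceiling(hi[1] / px) + 1L)
      j0 <- max(1L, floor(lo[2] / px)); j1 <- min(canvas[2], ceiling(hi[2] / px) + 1L)
      xs <- ((i0:i1) - 0.5) * px
      ys <- ((j0:j1) - 0.5) * px
      ab <- b - a
      len2 <- sum(ab^2)
      dx <- outer(xs - a[1], rep(1, length(ys)))
      dy <- outer(rep(1, length(xs)), ys - a[2])
      tt <- pmin(pmax((dx * ab[1] + dy * ab[2]) / len2, 0), 1)
      d2 <- (dx - tt * ab[1])^2 + (dy - tt * ab[2])^2
      blk <- opd[i0:i1, j0:j1]
      blk[d2 <= r^2] <- tube_opd
      opd[i0:i1, j0:j1] <- blk
    }
  }
  truth <- seed_graph_metrics(graph)
  attr(truth, "segment_lengths") <- graph$edges$length
  list(image = phase_image(opd, optics, time_h = time_h, well_id = well_id),
       truth = truth)
}
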