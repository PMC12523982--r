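#' Binary tube mask from a phase image
#'
#' Foreground = pixels of the Gaussian-smoothed OPD raster above the
#' Otsu threshold; enclosed holes smaller than `max_hole_area` are
#' filled and connected specks below `min_object_area` (the debris
#' gate) are removed. An image with empty foreground yields an empty
#' mask (downstream metrics are then all zero).
#'
#' @param image a [phase_image()].
#' @param smoothing_scale Gaussian sigma, um (0 = none).
#' @param min_object_area remove foreground components below this
#'   area, um^2.
#' @param max_hole_area fill enclosed background holes below this
#'   area, um^2.
#' @return logical matrix.
#' @export
make_tube_mask <- function(image, smoothing_scale = 2,
                           min_object_area = 400, max_hole_area = 400) {
  stopifnot(inherits(image, "phase_image"))
  px <- image$optics$pixel_size
  m <- image$opd
  if (!all(is.finite(m))) stop("image must be finite-valued")
  if (max(m) <= 0) return(matrix(FALSE, nrow(m), ncol(m)))
  sm <- if (smoothing_scale > 0) EBImage::gblur(m, sigma = smoothing_scale / px) else m
  th <- EBImage::otsu(EBImage::Image(sm / max(sm)), range = c(0, 1)) * max(sm)
  fg <- sm > th
  if (!any(fg)) return(matrix(FALSE, nrow(m), ncol(m)))
  # fill small enclosed holes: background components not touching the
  # border and below the area cap
  bg_lab <- .label8(!fg)
  if (max(bg_lab) > 0) {
    border_ids <- unique(c(bg_lab[1, ], bg_lab[nrow(bg_lab), ],
                           bg_lab[, 1], bg_lab[, ncol(bg_lab)]))
    areas <- tabulate(bg_lab[bg_lab > 0L], nbins = max(bg_lab)) * px^2
    fill <- setdiff(which(areas < max_hole_area), border_ids)
    fg[bg_lab %in% fill] <- TRUE
  }
  fg_lab <- .label8(fg)
  if (max(fg_lab) > 0) {
    areas <- tabulate(fg_lab[fg_lab > 0L], nbins = max(fg_lab)) * px^2
    fg[fg_lab %in% which(areas < min_object_area)] <- FALSE
  }
  fg
}

# Guo-Hall thinning to a 1-pixel-wide 8-connected skeleton,
# vectorised over the whole raster per sub-iteration. Chosen over
# Zhang-Suen because it keeps diagonal strokes one pixel wide, which
# the neighbour-count node classification depends on.
.thin_guo_hall <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P <- matrix(FALSE, nr + 2, nc + 2)
      P[2:(nr + 1), 2:(nc + 1)] <- m
      i <- 2:(nr + 1); j <- 2:(nc + 1)
      p2 <- P[i - 1, j];     p3 <- P[i - 1, j + 1]
      p4 <- P[i, j + 1];     p5 <- P[i + 1, j + 1]
      p6 <- P[i + 1, j];     p7 <- P[i + 1, j - 1]
      p8 <- P[i, j - 1];     p9 <- P[i - 1, j - 1]
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
        (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      mm <- if (sub == 1) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
      cond <- m & C == 1 & N >= 2 & N <= 3 & !mm
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Arc length of a pixel path, um: the path is resampled every `step`
# pixels and chord lengths summed. Unbiased for straight tubes of any
# orientation (the raw 1/sqrt(2) chain metric overestimates
# intermediate angles by up to ~8%) and negligibly biased for
# curvature radii above the resampling step.
.arc_length <- function(poly_px, pixel_size, step = 5L) {
  n <- nrow(poly_px)
  if (n < 2) return(0)
  idx <- unique(c(seq(1L, n, by = step), n))
  p <- poly_px[idx, , drop = FALSE]
  sum(sqrt(rowSums(diff(p)^2))) * pixel_size
}

# 8-neighbour count of TRUE pixels, zero-padded.
.neighbour_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  P <- matrix(0L, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- m
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  P[i - 1, j] + P[i - 1, j + 1] + P[i, j + 1] + P[i + 1, j + 1] +
    P[i + 1, j] + P[i + 1, j - 1] + P[i, j - 1] + P[i - 1, j - 1]
}

#' Skeletonise a tube mask and extract its network graph
#'
#' Thins the mask to a one-pixel skeleton (Guo-Hall), classifies
#' skeleton pixels by 8-neighbour count (1 = endpoint, >= 3 = junction
#' pixel), merges junction pixels within `junction_merge_radius` into
#' single junction nodes, and traces the maximal degree-2 pixel paths
#' between nodes into edges. Edge polylines are extended to the node
#' centroids and their arc length measured as the Euclidean length of
#' the path resampled every 5 pixels, which is orientation-unbiased
#' (a raw chain-step metric overestimates diagonal tubes by up to
#' ~8%). Spur edges — terminating in an extremity — shorter than
#' `prune_length` are removed iteratively, splicing any node thereby
#' reduced to degree 2 back into a single segment. Closed loops with
#' no classified node become one self-edge with `is_branch = FALSE`.
#'
#' @param mask logical/binary matrix (from [make_tube_mask()]), or an
#'   already 1-pixel skeleton (thinning is idempotent).
#' @param pixel_size um per pixel.
#' @param prune_length minimum extremity-terminated segment length to
#'   survive pruning, um.
#' @param junction_merge_radius junction-pixel merge radius, um.
#' @return object of class `network_graph`: `nodes` (id, x, y um,
#'   kind in junction/extremity/loop_anchor, degree), `edges`
#'   (segment_id, from, to, length um, is_branch, touches_boundary),
#'   `polylines` (list of n x 2 um coordinate matrices), `pixel_size`.
#'   An empty mask yields an empty graph.
#' @export
skeletonize_and_graph <- function(mask, pixel_size = 1, prune_length = 15,
                                  junction_merge_radius = 5) {
  m <- mask != 0
  sk <- .thin_guo_hall(m)
  if (!any(sk)) return(.empty_network(pixel_size))
  nbr <- .neighbour_count(sk)
  deg <- ifelse(sk, nbr, 0L)
  endpoint <- sk & deg == 1L
  junction_px <- sk & deg >= 3L
  nr <- nrow(sk); nc <- ncol(sk)

  # node id raster: junction pixels share an id when their dilations
  # (by the merge radius) connect; endpoints get singleton ids
  node_id <- matrix(0L, nr, nc)
  n_j <- 0L
  if (any(junction_px)) {
    r_px <- max(1L, round(junction_merge_radius / pixel_size))
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    dil <- EBImage::dilate(EBImage::Image(junction_px * 1), brush) > 0
    dl <- .label8(dil)
    jl <- matrix(0L, nr, nc)
    jl[junction_px] <- dl[junction_px]
    jl <- .relabel(jl)
    n_j <- max(jl)
    node_id[junction_px] <- jl[junction_px]
  }
  ep_idx <- which(endpoint)
  node_id[ep_idx] <- n_j + seq_along(ep_idx)
  n_nodes <- n_j + length(ep_idx)
  is_node <- node_id > 0L

  # node coordinates: cluster centroids (pixel-centre convention)
  nidx <- which(is_node)
  nij <- arrayInd(nidx, dim(sk))
  # coordinates kept in pixel-index units until final conversion
  ndt <- data.table::data.table(id = node_id[nidx],
                                x = as.numeric(nij[, 1]),
                                y = as.numeric(nij[, 2]))
  ncoord <- ndt[, list(x = mean(x), y = mean(y)), by = "id"]
  data.table::setorder(ncoord, id)

  off <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  step_len <- sqrt(rowSums(off^2))
  edges <- list(); polylines <- list(); ne <- 0L
  used <- matrix(FALSE, nr, nc)   # consumed path pixels
  add_edge <- function(from, to, len, poly) {
    ne <<- ne + 1L
    edges[[ne]] <<- c(from, to, len)
    polylines[[ne]] <<- poly
  }
  # walks from every node pixel into every unconsumed path neighbour
  node_pixels <- which(is_node)
  for (p in node_pixels) {
    pi <- (p - 1L) %% nr + 1L
    pj <- (p - 1L) %/% nr + 1L
    for (k in 1:8) {
      qi <- pi + off[k, 1]; qj <- pj + off[k, 2]
      if (qi < 1 || qi > nr || qj < 1 || qj > nc || !sk[qi, qj]) next
      if (is_node[qi, qj]) {
        # direct node-node adjacency: emit once (ordered), skip same cluster
        if (node_id[qi, qj] != node_id[pi, pj] &&
            (qi + (qj - 1L) * nr) > p) {
          add_edge(node_id[pi, pj], node_id[qi, qj], step_len[k] * pixel_size,
                   rbind(c(pi, pj), c(qi, qj)))
        }
        next
      }
      if (used[qi, qj]) next
      # trace the degree-2 chain
      poly <- rbind(c(pi, pj), c(qi, qj))
      len <- step_len[k] * pixel_size
      used[qi, qj] <- TRUE
      prev <- c(pi, pj); cur <- c(qi, qj)
      repeat {
        nxt <- NULL
        for (k2 in 1:8) {
          ti <- cur[1] + off[k2, 1]; tj <- cur[2] + off[k2, 2]
          if (ti < 1 || ti > nr || tj < 1 || tj > nc || !sk[ti, tj]) next
          if (ti == prev[1] && tj == prev[2]) next
          nxt <- c(ti, tj, step_len[k2])
          # prefer a node pixel as terminator if both are adjacent
          if (is_node[ti, tj]) break
        }
        if (is.null(nxt)) { # dead end without node (shouldn't occur): stop
          add_edge(node_id[pi, pj], NA_integer_, len, poly)
          break
        }
        len <- len + nxt[3] * pixel_size
        poly <- rbind(poly, nxt[1:2])
        if (is_node[nxt[1], nxt[2]]) {
          add_edge(node_id[pi, pj], node_id[nxt[1], nxt[2]], len, poly)
          break
        }
        if (used[nxt[1], nxt[2]]) break  # safety against revisits
        used[nxt[1], nxt[2]] <- TRUE
        prev <- cur; cur <- nxt[1:2]
      }
    }
  }
  # isolated closed loops: path pixels never consumed
  loop_left <- which(sk & !is_node & !used)
  loop_anchor_rows <- list()
  while (length(loop_left) > 0) {
    p <- loop_left[1]
    pi <- (p - 1L) %% nr + 1L; pj <- (p - 1L) %/% nr + 1L
    used[pi, pj] <- TRUE
    poly <- rbind(c(pi, pj))
    len <- 0
    prev <- c(NA, NA); cur <- c(pi, pj)
    repeat {
      nxt <- NULL
      for (k2 in 1:8) {
        ti <- cur[1] + off[k2, 1]; tj <- cur[2] + off[k2, 2]
        if (ti < 1 || ti > nr || tj < 1 || tj > nc || !sk[ti, tj]) next
        if (!is.na(prev[1]) && ti == prev[1] && tj == prev[2]) next
        if (used[ti, tj] && !(ti == pi && tj == pj)) next
        if (ti == pi && tj == pj && nrow(poly) < 3) next
        nxt <- c(ti, tj, step_len[k2])
        break
      }
      if (is.null(nxt)) break
      len <- len + nxt[3] * pixel_size
      poly <- rbind(poly, nxt[1:2])
      if (nxt[1] == pi && nxt[2] == pj) break  # loop closed
      used[nxt[1], nxt[2]] <- TRUE
      prev <- cur; cur <- nxt[1:2]
    }
    n_nodes <- n_nodes + 1L
    ncoord <- rbind(ncoord,
                    data.table::data.table(id = n_nodes,
                                           x = as.numeric(pi),
                                           y = as.numeric(pj)))
    loop_anchor_rows[[length(loop_anchor_rows) + 1L]] <- n_nodes
    add_edge(n_nodes, n_nodes, len, poly)
    loop_left <- which(sk & !is_node & !used)
  }
  if (ne == 0) return(.empty_network(pixel_size))
  em <- do.call(rbind, edges)
  edf <- data.frame(from = as.integer(em[, 1]), to = as.integer(em[, 2]),
                    length = em[, 3])
  # extend each edge polyline to its terminal node-cluster centroids so
  # segment lengths span node to node, then measure resampled arc length
  anchors <- unlist(loop_anchor_rows)
  cx <- ncoord$x[match(seq_len(n_nodes), ncoord$id)]
  cy <- ncoord$y[match(seq_len(n_nodes), ncoord$id)]
  for (e in seq_len(nrow(edf))) {
    if (edf$from[e] %in% anchors) next  # closed loops carry no nodes
    p <- polylines[[e]]
    p <- rbind(c(cx[edf$from[e]], cy[edf$from[e]]), p)
    if (!is.na(edf$to[e]))
      p <- rbind(p, c(cx[edf$to[e]], cy[edf$to[e]]))
    polylines[[e]] <- p
  }
  edf$length <- vapply(seq_len(nrow(edf)), function(e)
    .arc_length(polylines[[e]], pixel_size), 0)
  # drop degenerate intra-junction edges created by the merge
  same <- !is.na(edf$to) & edf$from == edf$to &
    edf$length < 2 * junction_merge_radius &
    !(edf$from %in% anchors)
  if (any(same)) {
    edf <- edf[!same, , drop = FALSE]
    polylines <- polylines[!same]
  }
  nodes <- data.frame(id = ncoord$id, x = ncoord$x, y = ncoord$y)
  g <- .simplify_network(nodes, edf, polylines, pixel_size, prune_length)
  .refine_junction_nodes(g, sk_mask = m)
}

# Junction-position refinement. Thinning displaces the meeting point
# of a thick T- or Y-junction into the joining arm by a large fraction
# of the tube radius, which shortens short segments noticeably. For
# each junction we estimate the local tube radius from the distance
# transform of the mask, fit the direction of every incident branch
# over a window just outside the junction blob, and move the node to
# the least-squares intersection of those branch axes; incident edge
# polylines are re-anchored and lengths re-measured.
.refine_junction_nodes <- function(g, sk_mask) {
  if (nrow(g$nodes) == 0 || nrow(g$edges) == 0) return(g)
  jn <- which(g$nodes$kind == "junction")
  if (length(jn) == 0) return(g)
  px <- g$pixel_size
  dmm <- matrix(EBImage::distmap(EBImage::Image(sk_mask * 1)),
                nrow(sk_mask), ncol(sk_mask))
  radius <- numeric(nrow(g$nodes))
  for (ni in jn) {
    i0 <- min(max(round(g$nodes$x[ni] / px + 0.5), 1), nrow(dmm))
    j0 <- min(max(round(g$nodes$y[ni] / px + 0.5), 1), ncol(dmm))
    r <- dmm[i0, j0] * px
    radius[ni] <- r
    c0 <- c(g$nodes$x[ni], g$nodes$y[ni])
    id <- g$nodes$id[ni]
    inc <- which(g$edges$from == id | g$edges$to == id)
    A <- matrix(0, 2, 2); b <- c(0, 0); nl <- 0L
    for (e in inc) {
      p <- g$polylines[[e]]
      if (is.na(g$edges$to[e])) next
      if (g$edges$from[e] != id) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      d <- sqrt((p[, 1] - c0[1])^2 + (p[, 2] - c0[2])^2)
      w <- p[d >= 1.5 * r & d <= 4 * r, , drop = FALSE]
      if (nrow(w) < 3) next
      ctr <- colMeans(w)
      u <- eigen(stats::cov(w), symmetric = TRUE)$vectors[, 1]
      P <- diag(2) - tcrossprod(u)
      A <- A + P; b <- b + P %*% ctr; nl <- nl + 1L
    }
    if (nl >= 2 && abs(det(A)) > 1e-8) {
      xn <- drop(solve(A, b))
      if (sum((xn - c0)^2) <= (2 * r)^2) {
        g$nodes$x[ni] <- xn[1]; g$nodes$y[ni] <- xn[2]
      }
    }
  }
  # re-anchor polylines at the refined junction positions
  for (e in seq_len(nrow(g$edges))) {
    p <- g$polylines[[e]]
    for (end in 1:2) {
      id <- if (end == 1) g$edges$from[e] else g$edges$to[e]
      if (is.na(id)) next
      ni <- match(id, g$nodes$id)
      if (g$nodes$kind[ni] != "junction") next
      cn <- c(g$nodes$x[ni], g$nodes$y[ni])
      if (end == 2) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      d <- sqrt((p[, 1] - cn[1])^2 + (p[, 2] - cn[2])^2)
      cut <- which(d > 1.5 * radius[ni])
      p <- if (length(cut)) rbind(cn, p[min(cut):nrow(p), , drop = FALSE])
      else rbind(cn, p[nrow(p), , drop = FALSE])
      if (end == 2) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    }
    g$polylines[[e]] <- p
    g$edges$length[e] <- .arc_length(p, 1)
  }
  g
}

.empty_network <- function(pixel_size) {
  structure(list(nodes = data.frame(id = integer(), x = numeric(),
                                    y = numeric(), kind = character(),
                                    degree = integer()),
                 edges = data.frame(segment_id = integer(), from = integer(),
                                    to = integer(), length = numeric(),
                                    is_branch = logical(),
                                    touches_boundary = logical()),
                 polylines = list(), pixel_size = pixel_size),
            class = "network_graph")
}

# prune short spurs, splice degree-2 nodes, classify node kinds
.simplify_network <- function(nodes, edf, polylines, pixel_size,
                              prune_length) {
  repeat {
    deg <- .node_degrees(nodes$id, edf)
    # spur = edge with exactly one degree-1 endpoint whose other
    # endpoint has degree >= 3, shorter than the pruning threshold
    d_from <- deg[match(edf$from, nodes$id)]
    d_to <- deg[match(edf$to, nodes$id)]
    spur <- !is.na(edf$to) & edf$from != edf$to &
      ((d_from == 1 & d_to >= 3) | (d_to == 1 & d_from >= 3)) &
      edf$length < prune_length
    if (any(spur)) {
      # remove the single shortest spur per pass: pruning one spur can
      # legitimise its siblings (a two-armed path is not a spur)
      drop <- which(spur)[which.min(edf$length[spur])]
      edf <- edf[-drop, , drop = FALSE]
      polylines <- polylines[-drop]
      next
    }
    # splice nodes of degree 2 (not loop anchors)
    deg <- .node_degrees(nodes$id, edf)
    selfn <- nodes$id %in% edf$from[!is.na(edf$to) & edf$from == edf$to]
    cand <- nodes$id[deg == 2 & !selfn]
    spliced <- FALSE
    for (id in cand) {
      inc <- which((edf$from == id | edf$to == id) & !is.na(edf$to))
      if (length(inc) == 1) {
        # both ends of the same edge: becomes a self-loop; keep
        next
      }
      if (length(inc) != 2) next
      e1 <- inc[1]; e2 <- inc[2]
      orient <- function(e, tail_id) {
        p <- polylines[[e]]
        if (edf$to[e] != tail_id) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
        p
      }
      p1 <- orient(e1, id)
      other1 <- if (edf$to[e1] == id) edf$from[e1] else edf$to[e1]
      p2 <- orient(e2, id)
      other2 <- if (edf$to[e2] == id) edf$from[e2] else edf$to[e2]
      edf$from[e1] <- other1
      edf$to[e1] <- other2
      polylines[[e1]] <- rbind(p1, p2[rev(seq_len(nrow(p2))), , drop = FALSE][-1, , drop = FALSE])
      edf$length[e1] <- .arc_length(polylines[[e1]], pixel_size)
      edf <- edf[-e2, , drop = FALSE]
      polylines <- polylines[-e2]
      spliced <- TRUE
      break
    }
    if (!spliced) break
  }
  if (nrow(edf) == 0) return(.empty_network(pixel_size))
  deg <- .node_degrees(nodes$id, edf)
  keep <- deg > 0
  nodes <- nodes[keep, , drop = FALSE]
  deg <- deg[keep]
  selfn <- nodes$id %in% edf$from[!is.na(edf$to) & edf$from == edf$to]
  nodes$kind <- ifelse(deg == 1, "extremity",
                       ifelse(selfn & deg == 2, "loop_anchor", "junction"))
  nodes$degree <- deg
  ext <- nodes$id[nodes$kind == "extremity"]
  edf$is_branch <- (edf$from %in% ext) | (!is.na(edf$to) & edf$to %in% ext)
  edf$touches_boundary <- FALSE
  edf$segment_id <- seq_len(nrow(edf))
  rownames(edf) <- NULL
  rownames(nodes) <- NULL
  # coordinates to um (pixel-centre convention)
  polylines <- lapply(polylines, function(p) (p - 0.5) * pixel_size)
  nodes$x <- (nodes$x - 0.5) * pixel_size
  nodes$y <- (nodes$y - 0.5) * pixel_size
  structure(list(nodes = nodes,
                 edges = edf[, c("segment_id", "from", "to", "length",
                                 "is_branch", "touches_boundary")],
                 polylines = polylines, pixel_size = pixel_size),
            class = "network_graph")
}

.node_degrees <- function(ids, edf) {
  ends <- c(edf$from, edf$to)
  ends <- ends[!is.na(ends)]
  as.integer(table(factor(ends, levels = ids)))
}

#' @export
print.network_graph <- function(x, ...) {
  m <- network_metrics(x)
  cat(sprintf("network_graph: %d segments, %d junctions, %d extremities, %d branches, total %.4g um\n",
              m$n_segments, m$n_junctions, m$n_extremities, m$n_branches,
              m$total_length))
  invisible(x)
}

#' Tubulogenesis metrics of a network graph
#'
#' Segment number and length, junction and branch number, extremity
#' number and total network length — the skeleton-graph summary of a
#' tube-formation image.
#'
#' @param graph a `network_graph` (see [skeletonize_and_graph()]).
#' @param time_h acquisition time stored in the output row.
#' @param exclude_boundary_branches drop branches flagged as touching
#'   the image boundary before counting (see
#'   [flag_boundary_branches()]).
#' @return one-row data frame: n_segments, n_junctions, n_branches,
#'   n_extremities, total_length, median_segment_length, time_h. The
#'   median of an empty graph is `NA`.
#' @export
network_metrics <- function(graph, time_h = NA_real_,
                            exclude_boundary_branches = FALSE) {
  stopifnot(inherits(graph, "network_graph"))
  e <- graph$edges
  if (exclude_boundary_branches)
    e <- e[!(e$is_branch & e$touches_boundary), , drop = FALSE]
  data.frame(n_segments = nrow(e),
             n_junctions = sum(graph$nodes$kind == "junction"),
             n_branches = sum(e$is_branch),
             n_extremities = sum(graph$nodes$kind == "extremity"),
             total_length = if (nrow(e)) sum(e$length) else 0,
             median_segment_length = if (nrow(e)) stats::median(e$length) else NA_real_,
             time_h = time_h)
}

#' Flag branches whose polylines touch the image boundary
#'
#' Tube ends clipped by the field of view masquerade as branches; this
#' marks (never deletes) any edge whose polyline enters the margin
#' band so downstream metrics can be computed with and without them.
#'
#' @param graph a `network_graph`.
#' @param image_extent length-2 numeric, image extent in um.
#' @param margin band width, um (default two pixels).
#' @return the graph with `edges$touches_boundary` set.
#' @export
flag_boundary_branches <- function(graph, image_extent,
                                   margin = 2 * graph$pixel_size) {
  stopifnot(inherits(graph, "network_graph"), length(image_extent) == 2)
  if (nrow(graph$edges) == 0) return(graph)
  graph$edges$touches_boundary <- vapply(graph$polylines, function(p) {
    any(p[, 1] < margin | p[, 2] < margin |
          p[, 1] > image_extent[1] - margin |
          p[, 2] > image_extent[2] - margin)
  }, TRUE)
  graph
}

#' Normalise a tubulogenesis time course to its baseline frame
#'
#' Expresses count and length metrics as a percentage of the value at
#' the baseline time (so the baseline row reads 100%); the median
#' segment length is kept both raw and normalised.
#'
#' @param series data frame of [network_metrics()] rows (must contain
#'   `time_h` including `baseline_time_h`).
#' @param baseline_time_h baseline frame time, hours.
#' @return `series` with added `pct_` columns; metrics whose baseline
#'   value is 0 get `NA` percentages.
#' @export
normalize_timecourse <- function(series, baseline_time_h = 1) {
  stopifnot(is.data.frame(series), "time_h" %in% names(series))
  i <- which(series$time_h == baseline_time_h)
  if (length(i) != 1)
    stop("series must contain exactly one row at the baseline time")
  cols <- c("n_segments", "n_junctions", "n_branches", "n_extremities",
            "total_length", "median_segment_length")
  cols <- intersect(cols, names(series))
  for (cl in cols) {
    base <- series[[cl]][i]
    series[[paste0("pct_", cl)]] <-
      if (is.finite(base) && base != 0) 100 * series[[cl]] / base else NA_real_
  }
  series
}
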