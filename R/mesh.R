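## Deterministic mapped (transfinite) triangulation of the bifurcation lumen.
## The domain is split along the lumen midline into an upper half (LMS upper
## half -> LAD) and a lower half (LMS lower half -> LCx); each half is a
## curved channel between an inner curve (midline, then carina wall) and an
## outer curve (outer wall), meshed as a ruled grid of quads split into
## triangles. The halves share their midline nodes exactly, so the merged
## mesh is conforming. Streamwise spacing is h with an h/2 refinement band
## across each plaque extent; cross-stream node count is set by the largest
## branch diameter.

.dedup_poly <- function(p) {
  keep <- c(TRUE, rowSums(abs(diff(p))) > 1e-9)
  p[keep, , drop = FALSE]
}

.poly_arc <- function(p) c(0, cumsum(sqrt(rowSums(diff(p)^2))))

.interp_poly <- function(p, s) {
  arc <- .poly_arc(p)
  cbind(stats::approx(arc, p[, 1], s, rule = 2)$y,
        stats::approx(arc, p[, 2], s, rule = 2)$y)
}

## place m+1 stations along polyline p, spacing ~hfun(point) (local target)
.place_stations <- function(p, hfun, m = NULL) {
  p <- .dedup_poly(p)
  arc <- .poly_arc(p)
  mids <- (p[-nrow(p), , drop = FALSE] + p[-1, , drop = FALSE]) / 2
  w <- diff(arc) / hfun(mids)
  W <- c(0, cumsum(w))
  if (is.null(m)) m <- max(2L, round(W[length(W)]))
  targ <- W[length(W)] * (0:m) / m
  s <- stats::approx(W, arc, targ, ties = "ordered")$y
  s[1] <- 0; s[m + 1] <- arc[length(arc)]
  list(pts = .interp_poly(p, s), m = m)
}

## local target spacing: h/2 inside a plaque band (extent +/- 0.5 mm along
## the branch axis, within one radius + 0.5 mm of the axis), else h
.h_local_fun <- function(outline, h) {
  plaques <- outline$plaques
  br <- outline$branches
  function(pts) {
    hl <- rep(h, nrow(pts))
    for (pl in plaques) {
      b <- br[[pl$branch]]
      rel <- cbind(pts[, 1] - b$origin[1], pts[, 2] - b$origin[2])
      t <- rel[, 1] * b$dir[1] + rel[, 2] * b$dir[2]
      d <- abs(rel[, 1] * (-b$dir[2]) + rel[, 2] * b$dir[1])
      inband <- t >= pl$center_s - pl$length / 2 - 0.5 &
        t <= pl$center_s + pl$length / 2 + 0.5 & d <= b$radius + 0.5
      hl[inband] <- h / 2
    }
    hl
  }
}

.half_curves <- function(outline, half) {
  p <- outline$paths
  mid_idx <- function(arc) ceiling(nrow(arc) / 2)
  if (half == "upper") {
    fa <- p$fillet_upper; k <- mid_idx(fa)
    list(inner1 = p$median,
         inner2 = .dedup_poly(rbind(p$carina_upper, p$lad_inner)),
         outer1 = .dedup_poly(rbind(p$lms_upper, fa[1:k, , drop = FALSE])),
         outer2 = .dedup_poly(rbind(fa[k:nrow(fa), , drop = FALSE], p$lad_outer)))
  } else {
    fa <- p$fillet_lower; k <- mid_idx(fa)
    list(inner1 = p$median,
         inner2 = .dedup_poly(rbind(p$carina_lower, p$lcx_inner)),
         outer1 = .dedup_poly(rbind(p$lms_lower, fa[1:k, , drop = FALSE])),
         outer2 = .dedup_poly(rbind(fa[k:nrow(fa), , drop = FALSE], p$lcx_outer)))
  }
}

#' Triangulate the lumen outline
#'
#' Deterministic mapped triangulation with tagged boundary edges. See the
#' package vignette for the meshing strategy. The mesh is identical on
#' repeat runs for the same outline, h and seed (the generator is fully
#' deterministic; \code{seed} is recorded for provenance).
#'
#' @param outline A \code{lumen_outline}.
#' @param h Characteristic element size, mm; must resolve the narrowest
#'   throat. An h/2 refinement band is applied across each plaque.
#' @param seed Integer recorded with the mesh.
#' @return A \code{vessel_mesh}: node coordinates (mm), triangles (counter-
#'   clockwise), boundary edges tagged inlet / outlet_lad / outlet_lcx /
#'   wall, and wall-node metadata (branch, axial coordinate, tangent,
#'   inward normal, two-node wall-normal stencil for shear evaluation).
#' @export
generate_mesh <- function(outline, h = 0.15, seed = 1L) {
  stopifnot(inherits(outline, "lumen_outline"), h > 0)
  minw <- min(vapply(outline$branches,
                     function(b) min(b$off_left - b$off_right), numeric(1)))
  if (h >= minw / 2) {
    stop(sprintf(
      "mesh size h = %g mm too coarse: minimum lumen width is %.3f mm; need h < %.3f mm",
      h, minw, minw / 2))
  }
  hfun <- .h_local_fun(outline, h)
  med <- .place_stations(outline$paths$median, hfun)  # shared midline stations

  build_half <- function(half) {
    cv <- .half_curves(outline, half)
    in2 <- .place_stations(cv$inner2, hfun)
    ou1 <- .place_stations(cv$outer1, hfun, m = med$m)
    ou2 <- .place_stations(cv$outer2, hfun, m = in2$m)
    inner <- rbind(med$pts, in2$pts[-1, , drop = FALSE])
    outer <- rbind(ou1$pts, ou2$pts[-1, , drop = FALSE])
    list(inner = inner, outer = outer, m1 = med$m, m = med$m + in2$m)
  }
  up <- build_half("upper")
  lo <- build_half("lower")
  ncross <- ceiling(max(outline$spec$lms_diameter / 2,
                        outline$spec$lad_diameter,
                        outline$spec$lcx_diameter) / h)

  ## node table: upper half fully, lower half reusing shared midline (j = 0)
  eta <- (0:ncross) / ncross
  grid_id <- function(m) matrix(0L, m + 1, ncross + 1)
  nodes <- matrix(0, 0, 2)
  idu <- grid_id(up$m); idl <- grid_id(lo$m)
  add_node <- function(p) {
    nodes <<- rbind(nodes, p)
    nrow(nodes)
  }
  for (i in 0:up$m) {
    a <- up$inner[i + 1, ]; b <- up$outer[i + 1, ]
    for (j in 0:ncross) idu[i + 1, j + 1] <- add_node(a + eta[j + 1] * (b - a))
  }
  for (i in 0:lo$m) {
    a <- lo$inner[i + 1, ]; b <- lo$outer[i + 1, ]
    for (j in 0:ncross) {
      if (j == 0 && i <= lo$m1) {
        idl[i + 1, 1] <- idu[i + 1, 1]  # shared midline node
      } else {
        idl[i + 1, j + 1] <- add_node(a + eta[j + 1] * (b - a))
      }
    }
  }

  tris <- list()
  emit_quads <- function(id, m) {
    for (i in 1:m) for (j in 1:ncross) {
      A <- id[i, j]; B <- id[i + 1, j]; C <- id[i + 1, j + 1]; D <- id[i, j + 1]
      if ((i + j) %% 2 == 0) {
        tris[[length(tris) + 1]] <<- rbind(c(A, B, C), c(A, C, D))
      } else {
        tris[[length(tris) + 1]] <<- rbind(c(A, B, D), c(B, C, D))
      }
    }
  }
  emit_quads(idu, up$m)
  emit_quads(idl, lo$m)
  tri <- do.call(rbind, tris)

  ## enforce counter-clockwise orientation
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  a2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  flip <- a2 < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]
  if (any(abs(a2) < 1e-12))
    stop("meshing produced a degenerate (zero-area) triangle")

  ## boundary tags keyed on unordered node pairs
  tag_map <- new.env(hash = TRUE)
  set_tag <- function(n1, n2, tag) {
    key <- paste(min(n1, n2), max(n1, n2))
    if (!is.null(tag_map[[key]]))
      stop("doubly tagged boundary edge")  # partition invariant
    tag_map[[key]] <- tag
  }
  for (i in 1:up$m) {  # outer wall, upper
    set_tag(idu[i, ncross + 1], idu[i + 1, ncross + 1], "wall")
  }
  for (i in 1:lo$m) set_tag(idl[i, ncross + 1], idl[i + 1, ncross + 1], "wall")
  for (i in (up$m1 + 1):up$m) set_tag(idu[i, 1], idu[i + 1, 1], "wall")
  for (i in (lo$m1 + 1):lo$m) set_tag(idl[i, 1], idl[i + 1, 1], "wall")
  for (j in 1:ncross) {
    set_tag(idu[1, j], idu[1, j + 1], "inlet")
    set_tag(idl[1, j], idl[1, j + 1], "inlet")
    set_tag(idu[up$m + 1, j], idu[up$m + 1, j + 1], "outlet_lad")
    set_tag(idl[lo$m + 1, j], idl[lo$m + 1, j + 1], "outlet_lcx")
  }

  ## boundary edges from the triangulation, oriented with interior on the left
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e_all <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  keys <- ek(e_all[, 1], e_all[, 2])
  cnt <- table(keys)
  bnd <- e_all[cnt[keys] == 1L, , drop = FALSE]
  tags <- vapply(seq_len(nrow(bnd)), function(i) {
    tg <- tag_map[[ek(bnd[i, 1], bnd[i, 2])]]
    if (is.null(tg)) stop("untagged boundary edge") else tg
  }, character(1))

  ## wall node metadata with two-node inward stencils for shear recovery
  wall_rows <- list()
  add_wall <- function(id, m1, m, branch2, jw, s1, s2) {
    # jw: boundary column (ncross+1 outer wall, 1 inner wall)
    idx <- if (jw == ncross + 1) 1:(m + 1) else (m1 + 1):(m + 1)
    for (i in idx) {
      nd <- id[i, jw]
      nb1 <- id[i, jw + if (jw == 1) 1 else -1]
      nb2 <- id[i, jw + if (jw == 1) 2 else -2]
      ip <- max(min(i, m), 1)
      tvec <- nodes[id[ip + 1, jw], ] - nodes[id[ip, jw], ]
      tvec <- tvec / sqrt(sum(tvec^2))
      dvec <- nodes[nb1, ] - nodes[nd, ]
      d1 <- sqrt(sum(dvec^2))
      d2 <- sqrt(sum((nodes[nb2, ] - nodes[nd, ])^2))
      nv <- c(-tvec[2], tvec[1])
      if (sum(nv * dvec) < 0) nv <- -nv  # inward normal
      branch <- if (jw == ncross + 1 && i <= m1 + 1) "lms" else branch2
      wall_rows[[length(wall_rows) + 1]] <<- data.frame(
        node = nd, branch = branch, tx = tvec[1], ty = tvec[2],
        nx = nv[1], ny = nv[2], stencil1 = nb1, stencil2 = nb2,
        d1 = d1, d2 = d2, stringsAsFactors = FALSE)
    }
  }
  add_wall(idu, up$m1, up$m, "lad", ncross + 1)
  add_wall(idu, up$m1, up$m, "lad", 1)
  add_wall(idl, lo$m1, lo$m, "lcx", ncross + 1)
  add_wall(idl, lo$m1, lo$m, "lcx", 1)
  wall <- do.call(rbind, wall_rows)
  # axial coordinate along the node's branch
  br <- outline$branches
  wall$s <- vapply(seq_len(nrow(wall)), function(i) {
    b <- br[[wall$branch[i]]]
    sum((nodes[wall$node[i], ] - b$origin) * b$dir)
  }, numeric(1))

  structure(list(nodes = nodes, tri = tri,
                 edges = data.frame(n1 = bnd[, 1], n2 = bnd[, 2], tag = tags,
                                    stringsAsFactors = FALSE),
                 wall = wall, h = h, seed = as.integer(seed),
                 n_nodes = nrow(nodes), n_tri = nrow(tri)),
            class = "vessel_mesh")
}

#' Structured channel mesh for solver validation
#'
#' A straight 2-D channel (inlet at x = 0, outlet at x = length, walls at
#' y = +/- width/2) meshed with the same node/element conventions as
#' [generate_mesh()]; used by the plane-Poiseuille and oscillatory-flow
#' validation cases.
#'
#' @param length,width Channel dimensions, mm.
#' @param h Element size, mm.
#' @return A \code{vessel_mesh} with tags inlet / outlet_lad / wall.
#' @export
channel_mesh <- function(length = 12, width = 4, h = 0.2) {
  m <- max(2L, ceiling(length / h)); n <- max(2L, ceiling(width / h))
  xs <- seq(0, length, length.out = m + 1)
  ys <- seq(-width / 2, width / 2, length.out = n + 1)
  id <- matrix(seq_len((m + 1) * (n + 1)), m + 1, n + 1)
  nodes <- cbind(rep(xs, n + 1), rep(ys, each = m + 1))
  tris <- vector("list", m * n)
  k <- 0
  for (i in 1:m) for (j in 1:n) {
    A <- id[i, j]; B <- id[i + 1, j]; C <- id[i + 1, j + 1]; D <- id[i, j + 1]
    k <- k + 1
    tris[[k]] <- if ((i + j) %% 2 == 0) rbind(c(A, B, C), c(A, C, D))
    else rbind(c(A, B, D), c(B, C, D))
  }
  tri <- do.call(rbind, tris)
  edges <- rbind(
    data.frame(n1 = id[1, 2:(n + 1)], n2 = id[1, 1:n], tag = "inlet"),
    data.frame(n1 = id[m + 1, 1:n], n2 = id[m + 1, 2:(n + 1)], tag = "outlet_lad"),
    data.frame(n1 = id[1:m, 1], n2 = id[2:(m + 1), 1], tag = "wall"),
    data.frame(n1 = id[2:(m + 1), n + 1], n2 = id[1:m, n + 1], tag = "wall"))
  dy <- width / n
  wall <- rbind(
    data.frame(node = id[, 1], branch = "lms", tx = 1, ty = 0, nx = 0, ny = 1,
               stencil1 = id[, 2], stencil2 = id[, 3], d1 = dy, d2 = 2 * dy,
               s = xs),
    data.frame(node = id[, n + 1], branch = "lms", tx = 1, ty = 0, nx = 0,
               ny = -1, stencil1 = id[, n], stencil2 = id[, n - 1], d1 = dy,
               d2 = 2 * dy, s = xs))
  structure(list(nodes = nodes, tri = tri, edges = edges, wall = wall, h = h,
                 seed = 1L, n_nodes = nrow(nodes), n_tri = nrow(tri)),
            class = "vessel_mesh")
}

#' Boundary length by tag
#'
#' @param mesh A \code{vessel_mesh}.
#' @return Named numeric vector of summed boundary edge lengths (mm) per tag.
#' @export
boundary_lengths <- function(mesh) {
  len <- sqrt(rowSums((mesh$nodes[mesh$edges$n2, , drop = FALSE] -
                       mesh$nodes[mesh$edges$n1, , drop = FALSE])^2))
  tapply(len, mesh$edges$tag, sum)
}

#' @export
print.vessel_mesh <- function(x, ...) {
  cat(sprintf("vessel_mesh: %d nodes, %d triangles, h = %g mm\n",
              x$n_nodes, x$n_tri, x$h))
  tl <- boundary_lengths(x)
  cat("  boundary (mm):", paste(names(tl), round(tl, 2), collapse = ", "), "\n")
  invisible(x)
}
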