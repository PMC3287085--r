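## Hemodynamic post-processing: pressure-gradient magnitude (PSG), wall
## shear stress, cross-sectional velocity profiles at the A-O planes,
## recirculation fractions, and the four-arm study summary.

## ---- interpolation utilities ---------------------------------------------

.elem_bbox <- function(mesh) {
  tri <- mesh$tri; X <- mesh$nodes
  list(xmin = pmin(X[tri[, 1], 1], X[tri[, 2], 1], X[tri[, 3], 1]),
       xmax = pmax(X[tri[, 1], 1], X[tri[, 2], 1], X[tri[, 3], 1]),
       ymin = pmin(X[tri[, 1], 2], X[tri[, 2], 2], X[tri[, 3], 2]),
       ymax = pmax(X[tri[, 1], 2], X[tri[, 2], 2], X[tri[, 3], 2]))
}

## locate points (mm) in the triangulation; returns element index and
## barycentric weights, NA if outside
.locate_points <- function(mesh, pts, tol = 1e-8) {
  bb <- .elem_bbox(mesh)
  X <- mesh$nodes; tri <- mesh$tri
  out_el <- integer(nrow(pts)); out_w <- matrix(NA_real_, nrow(pts), 3)
  for (i in seq_len(nrow(pts))) {
    px <- pts[i, 1]; py <- pts[i, 2]
    cand <- which(bb$xmin - tol <= px & px <= bb$xmax + tol &
                  bb$ymin - tol <= py & py <= bb$ymax + tol)
    found <- 0L
    for (e in cand) {
      a <- X[tri[e, 1], ]; b <- X[tri[e, 2], ]; cx <- X[tri[e, 3], ]
      det <- (b[1] - a[1]) * (cx[2] - a[2]) - (cx[1] - a[1]) * (b[2] - a[2])
      w2 <- ((px - a[1]) * (cx[2] - a[2]) - (cx[1] - a[1]) * (py - a[2])) / det
      w3 <- ((b[1] - a[1]) * (py - a[2]) - (px - a[1]) * (b[2] - a[2])) / det
      w1 <- 1 - w2 - w3
      if (w1 >= -tol && w2 >= -tol && w3 >= -tol) {
        found <- e; out_w[i, ] <- c(w1, w2, w3); break
      }
    }
    out_el[i] <- found
  }
  list(elem = out_el, w = out_w)
}

.interp_nodal <- function(mesh, field, pts) {
  loc <- .locate_points(mesh, pts)
  if (any(loc$elem == 0L)) stop("interpolation point outside the mesh")
  tri <- mesh$tri
  if (is.matrix(field)) {
    sapply(seq_len(ncol(field)), function(k)
      rowSums(loc$w * matrix(field[tri[loc$elem, ], k], nrow(pts), 3)))
  } else {
    rowSums(loc$w * matrix(field[tri[loc$elem, ]], nrow(pts), 3))
  }
}

## area-weighted recovery of element values to nodes
.recover_nodal <- function(mesh, elem_vals) {
  tri <- mesh$tri
  X <- mesh$nodes
  a2 <- (X[tri[, 2], 1] - X[tri[, 1], 1]) * (X[tri[, 3], 2] - X[tri[, 1], 2]) -
    (X[tri[, 3], 1] - X[tri[, 1], 1]) * (X[tri[, 2], 2] - X[tri[, 1], 2])
  A <- abs(a2) / 2
  flat <- as.vector(tri)
  num <- rowsum(rep(A * elem_vals, 3), flat)
  den <- rowsum(rep(A, 3), flat)
  out <- numeric(nrow(X))
  out[as.integer(rownames(num))] <- num / den
  out
}

.elem_grad_mm <- function(mesh, f) {
  # gradient per mm of geometry; callers convert units
  X <- mesh$nodes; tri <- mesh$tri
  x1 <- X[tri[, 1], 1]; y1 <- X[tri[, 1], 2]
  x2 <- X[tri[, 2], 1]; y2 <- X[tri[, 2], 2]
  x3 <- X[tri[, 3], 1]; y3 <- X[tri[, 3], 2]
  a2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / a2
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) / a2
  f3 <- matrix(f[as.vector(tri)], nrow(tri), 3)
  cbind(rowSums(b * f3), rowSums(cc * f3))
}

## ---- PSG ------------------------------------------------------------------

#' Magnitude of the local pressure gradient (PSG)
#'
#' |grad p| = sqrt((dp/dx)^2 + (dp/dy)^2) in Pa/m (kg m^-2 s^-2), the
#' hemodynamic stress statistic reported at stenoses. Element-wise P1
#' gradients are recovered to nodes by area-weighted averaging of the
#' gradient vector (so the result is rotation-equivariant).
#'
#' @param state A stored state (list with \code{p} in Pa) or
#'   \code{flow_state}.
#' @param mesh The \code{vessel_mesh} the state lives on.
#' @return List with \code{nodal} (per-node PSG, Pa/m) and \code{elem}
#'   (per-element PSG, Pa/m).
#' @export
pressure_gradient_magnitude <- function(state, mesh) {
  g <- .elem_grad_mm(mesh, state$p) * 1000  # per mm -> per m
  gx <- .recover_nodal(mesh, g[, 1])
  gy <- .recover_nodal(mesh, g[, 2])
  list(nodal = sqrt(gx^2 + gy^2), elem = sqrt(g[, 1]^2 + g[, 2]^2))
}

## ---- WSS ------------------------------------------------------------------

#' Wall shear stress along the lumen wall
#'
#' At each wall node the wall-normal derivative of velocity is taken from a
#' one-sided quadratic fit through the no-slip wall value and the two nodes
#' of the mesh's inward stencil, corrected for the stencil's obliquity to
#' the wall normal. The wall shear rate is the tangential component of that
#' derivative; the active rheology is evaluated at the wall shear rate to
#' give WSS = mu(gdot_w) * gdot_w in Pa. Where the stencil is too oblique
#' (saddle/carina transition nodes) the recovered velocity-gradient tensor
#' is used instead.
#'
#' @param state A stored state or \code{flow_state} (velocity in m/s).
#' @param mesh The \code{vessel_mesh}.
#' @param rheology A blood model.
#' @return A data frame (wall node, branch, axial coordinate s in mm, wall
#'   shear rate 1/s, viscosity Pa s, wss Pa).
#' @export
wall_shear_stress <- function(state, mesh, rheology) {
  w <- mesh$wall
  u <- state$u
  d1 <- w$d1 / 1000; d2 <- w$d2 / 1000  # mm -> m
  den <- d1 * d2 * (d2 - d1)
  gxd <- (d2^2 * u[w$stencil1, 1] - d1^2 * u[w$stencil2, 1]) / den
  gyd <- (d2^2 * u[w$stencil1, 2] - d1^2 * u[w$stencil2, 2]) / den
  # stencil direction and obliquity to the inward normal
  dvec <- (mesh$nodes[w$stencil1, , drop = FALSE] -
           mesh$nodes[w$node, , drop = FALSE])
  dlen <- sqrt(rowSums(dvec^2))
  dhat <- dvec / dlen
  align <- dhat[, 1] * w$nx + dhat[, 2] * w$ny
  gt <- (gxd * w$tx + gyd * w$ty) / align  # tangential du/dn
  gdot <- abs(gt)
  ## fallback for badly aligned stencils: recovered gradient tensor
  bad <- which(align < 0.35)
  if (length(bad)) {
    gux <- .elem_grad_mm(mesh, u[, 1]) * 1000
    guy <- .elem_grad_mm(mesh, u[, 2]) * 1000
    rxx <- .recover_nodal(mesh, gux[, 1]); rxy <- .recover_nodal(mesh, gux[, 2])
    ryx <- .recover_nodal(mesh, guy[, 1]); ryy <- .recover_nodal(mesh, guy[, 2])
    nd <- w$node[bad]
    nx <- w$nx[bad]; ny <- w$ny[bad]
    # traction direction of the rate-of-strain tensor
    sx <- 2 * rxx[nd] * nx + (rxy[nd] + ryx[nd]) * ny
    sy <- (rxy[nd] + ryx[nd]) * nx + 2 * ryy[nd] * ny
    tn <- sx * nx + sy * ny
    gdot[bad] <- sqrt(pmax((sx - tn * nx)^2 + (sy - tn * ny)^2, 0))
  }
  mu_w <- apparent_viscosity(gdot, rheology)
  data.frame(node = w$node, branch = w$branch, s = w$s,
             shear_rate = gdot, mu = mu_w, wss = mu_w * gdot)
}

## ---- sections -------------------------------------------------------------

#' Sample a velocity profile across a section plane
#'
#' Velocity interpolated at \code{n} equispaced points along the plane's
#' segment; the streamwise component is signed by the plane's streamwise
#' direction. End points lie on the no-slip wall and are set to zero.
#'
## precompute sample points and their element locations for one plane, so
## that many states can be sampled on the same plane cheaply
.section_cache <- function(mesh, plane, n = 101) {
  p0 <- c(plane$x0, plane$y0); p1 <- c(plane$x1, plane$y1)
  tt <- seq(0, 1, length.out = n)
  pts <- cbind(p0[1] + tt * (p1[1] - p0[1]), p0[2] + tt * (p1[2] - p0[2]))
  # Keep sampling robustly inside the triangulated domain: the mesh boundary
  # is the chord polyline of the curved outline, so exact wall points can sit
  # a few microns outside it. Pull the two wall end points 0.5% of the width
  # inward (their velocities are overwritten with the no-slip zero anyway).
  ptsq <- pts
  ptsq[1, ] <- pts[1, ] + 5e-3 * (pts[2, ] - pts[1, ])
  ptsq[n, ] <- pts[n, ] + 5e-3 * (pts[n - 1, ] - pts[n, ])
  loc <- .locate_points(mesh, ptsq)
  miss <- which(loc$elem == 0L)
  # points within a few samples of the walls may fall in the sliver between
  # the curved outline and the mesh's chord boundary; they carry the no-slip
  # zero. Anything further inboard is genuinely outside the domain.
  if (any(tt[miss] > 0.08 & tt[miss] < 0.92))
    stop("interpolation point outside the mesh")
  loc$elem[miss] <- 1L
  loc$w[miss, ] <- 0  # interpolates to exactly zero
  list(pts = pts, tt = tt, loc = loc, n = n)
}

#' @param state A stored state or \code{flow_state}.
#' @param mesh The \code{vessel_mesh}.
#' @param plane One row of a section table from [define_sections()] or
#'   [section_plane()].
#' @param n Number of sample points (>= 50).
#' @param cache Optional precomputed sampling cache (internal use).
#' @return A \code{section_profile} data frame: normalized transverse
#'   position, coordinates (mm), velocity components and the signed
#'   streamwise/transverse components (m/s); attributes \code{label},
#'   \code{width_mm} and \code{flow_m2s} (streamwise flux through the
#'   plane).
#' @export
sample_section <- function(state, mesh, plane, n = 101, cache = NULL) {
  stopifnot(n >= 50)
  if (is.null(cache)) cache <- .section_cache(mesh, plane, n)
  pts <- cache$pts; tt <- cache$tt; loc <- cache$loc; n <- cache$n
  tri <- mesh$tri
  uv <- cbind(rowSums(loc$w * matrix(state$u[tri[loc$elem, ], 1], n, 3)),
              rowSums(loc$w * matrix(state$u[tri[loc$elem, ], 2], n, 3)))
  uv[1, ] <- 0; uv[n, ] <- 0  # no-slip walls
  dir <- c(plane$dir_x, plane$dir_y)
  cr <- c(-dir[2], dir[1])
  us <- uv[, 1] * dir[1] + uv[, 2] * dir[2]
  uc <- uv[, 1] * cr[1] + uv[, 2] * cr[2]
  width <- sqrt((plane$x1 - plane$x0)^2 + (plane$y1 - plane$y0)^2)
  flow <- sum((us[-1] + us[-n]) / 2) * (width / (n - 1)) / 1000  # m^2/s
  out <- data.frame(t = tt, x = pts[, 1], y = pts[, 2],
                    u = uv[, 1], v = uv[, 2], u_stream = us, u_cross = uc)
  attr(out, "label") <- plane$label
  attr(out, "width_mm") <- width
  attr(out, "flow_m2s") <- flow
  class(out) <- c("section_profile", "data.frame")
  out
}

#' Fraction of reversed (recirculating) flow in a profile
#'
#' Fraction of profile samples whose streamwise velocity component is
#' negative; positive values flag a recirculation zone distal to a plaque.
#'
#' @param profile A \code{section_profile}.
#' @param threshold Velocities below \code{-threshold} (m/s) count as
#'   reversed; default 0 (any negative sample).
#' @return Fraction in [0, 1].
#' @export
recirculation_fraction <- function(profile, threshold = 0) {
  mean(profile$u_stream < -threshold)
}

## ---- study summary --------------------------------------------------------

.section_groups <- list(lms = LETTERS[1:5], lad = LETTERS[6:10],
                        lcx = LETTERS[11:15])

## nodes of a mesh lying within an axial window of a branch
.region_nodes <- function(mesh, outline, branch, s_range, pad_radius = 0.75) {
  b <- outline$branches[[branch]]
  rel <- cbind(mesh$nodes[, 1] - b$origin[1], mesh$nodes[, 2] - b$origin[2])
  t <- rel[, 1] * b$dir[1] + rel[, 2] * b$dir[2]
  d <- abs(rel[, 1] * (-b$dir[2]) + rel[, 2] * b$dir[1])
  which(t >= s_range[1] & t <= s_range[2] & d <= b$radius + pad_radius)
}

.plaque_extent <- function(pl, pad = 1) {
  pl$center_s + c(-1, 1) * (pl$length / 2 + pad * pl$length)
}

#' Summarize a multi-arm hemodynamic study
#'
#' Reduces the stored states of up to four run arms (plaque on/off crossed
#' with Newtonian / generalized power law rheology) to per-region, per-time
#' summaries at the reporting phases: velocity ranges per section group
#' (mm/s), PSG ranges over each plaque region (Pa/m), WSS ranges over each
#' plaque's wall (Pa), recirculation fractions per section, the LAD:LCx
#' flow split, throat velocity amplification (section-mean streamwise speed
#' at the throat over an unstenosed reference plane of the same branch),
#' and paired plaque/no-plaque PSG and GPL/Newtonian WSS comparisons.
#'
#' @param arms Named list of \code{flow_history} objects; names from
#'   \{"plaque_newtonian", "plaque_gpl", "noplaque_newtonian",
#'   "noplaque_gpl"\}.
#' @param outlines List with elements \code{plaque} and/or \code{noplaque}:
#'   the \code{lumen_outline} each arm was meshed from.
#' @param plaques The plaque list defining regions (defaults to the plaque
#'   outline's).
#' @param times Reporting phases within the cycle, s.
#' @param require_all Error if any of the four arms is missing (the full
#'   paired study); otherwise comparisons that lack an arm are NA.
#' @return A \code{summary_report} object (see [report_to_json()]).
#' @export
summarize_study <- function(arms, outlines,
                            plaques = outlines$plaque$plaques,
                            times = c(0.4, 0.7), require_all = TRUE) {
  all_arms <- c("plaque_newtonian", "plaque_gpl",
                "noplaque_newtonian", "noplaque_gpl")
  stopifnot(all(names(arms) %in% all_arms))
  if (require_all && !all(all_arms %in% names(arms)))
    stop("missing run arm(s): ", paste(setdiff(all_arms, names(arms)),
                                       collapse = ", "))
  geom_of <- function(arm) if (startsWith(arm, "plaque")) "plaque" else "noplaque"
  sections <- lapply(outlines, define_sections, plaques = plaques)
  caches <- lapply(names(outlines), function(g) {
    mesh <- NULL
    for (arm in names(arms)) if (geom_of(arm) == g) mesh <- arms[[arm]]$mesh
    if (is.null(mesh)) return(NULL)
    secs <- sections[[g]]
    lapply(seq_len(nrow(secs)), function(i) .section_cache(mesh, secs[i, ]))
  })
  names(caches) <- names(outlines)

  vel <- psg <- wss <- rec <- spl <- amp <- recc <- list()
  for (arm in names(arms)) {
    hist <- arms[[arm]]
    outl <- outlines[[geom_of(arm)]]
    secs <- sections[[geom_of(arm)]]
    cch <- caches[[geom_of(arm)]]
    mesh <- hist$mesh
    rheol <- hist$rheology
    ## recirculation over the whole stored cycle (max fraction per section)
    frmax <- rep(0, nrow(secs)); frphase <- rep(NA_real_, nrow(secs))
    for (st in hist$states) {
      if (is.null(st)) next
      for (i in seq_len(nrow(secs))) {
        fr <- recirculation_fraction(sample_section(st, mesh, secs[i, ],
                                                    cache = cch[[i]]))
        if (fr > frmax[i]) { frmax[i] <- fr; frphase[i] <- st$phase }
      }
    }
    recc[[length(recc) + 1]] <- data.frame(
      arm = arm, section = secs$label, branch = secs$branch,
      max_fraction = frmax, at_phase = frphase)
    for (tm in times) {
      st <- state_at(hist, tm)
      profs <- lapply(seq_len(nrow(secs)), function(i)
        sample_section(st, mesh, secs[i, ], cache = cch[[i]]))
      names(profs) <- secs$label
      for (br in names(.section_groups)) {
        sp <- do.call(c, lapply(profs[.section_groups[[br]]], function(pr)
          sqrt(pr$u_stream^2 + pr$u_cross^2) * 1000))
        vel[[length(vel) + 1]] <- data.frame(
          arm = arm, time = tm, region = br,
          vmin_mm_s = min(sp), vmax_mm_s = max(sp))
      }
      for (i in seq_along(profs)) {
        rec[[length(rec) + 1]] <- data.frame(
          arm = arm, time = tm, section = secs$label[i],
          branch = secs$branch[i],
          fraction = recirculation_fraction(profs[[i]]))
      }
      pg <- pressure_gradient_magnitude(st, mesh)
      ws <- wall_shear_stress(st, mesh, rheol)
      for (pl in plaques) {
        ext <- .plaque_extent(pl)
        nid <- .region_nodes(mesh, outl, pl$branch, ext)
        wsel <- ws[ws$branch == pl$branch & ws$s >= ext[1] & ws$s <= ext[2], ]
        psg[[length(psg) + 1]] <- data.frame(
          arm = arm, time = tm, region = pl$branch,
          psg_min = min(pg$nodal[nid]), psg_max = max(pg$nodal[nid]))
        wss[[length(wss) + 1]] <- data.frame(
          arm = arm, time = tm, region = pl$branch,
          wss_min = min(wsel$wss), wss_max = max(wsel$wss))
        ## throat amplification: section-mean streamwise speed ratio
        ref_s <- pl$center_s - pl$length / 2 - 1
        cz <- outl$clean[[pl$branch]]
        if (ref_s < cz[1]) ref_s <- pl$center_s + pl$length / 2 + 1
        thr <- sample_section(st, mesh,
                              section_plane(outl, pl$branch, pl$center_s, "throat"))
        ref <- sample_section(st, mesh,
                              section_plane(outl, pl$branch, ref_s, "ref"))
        amp[[length(amp) + 1]] <- data.frame(
          arm = arm, time = tm, region = pl$branch, ref_s = ref_s,
          amplification = mean(abs(thr$u_stream)) / mean(abs(ref$u_stream)))
      }
      fl <- state_at(hist, tm)$fluxes
      spl[[length(spl) + 1]] <- data.frame(
        arm = arm, time = tm,
        q_in = -fl[["inlet"]], q_lad = fl[["outlet_lad"]],
        q_lcx = fl[["outlet_lcx"]],
        lad_share = fl[["outlet_lad"]] / (fl[["outlet_lad"]] + fl[["outlet_lcx"]]))
    }
  }
  vel <- do.call(rbind, vel); psg <- do.call(rbind, psg)
  wss <- do.call(rbind, wss); rec <- do.call(rbind, rec)
  spl <- do.call(rbind, spl); amp <- do.call(rbind, amp)
  recc <- do.call(rbind, recc)
  rownames(vel) <- rownames(psg) <- rownames(wss) <- rownames(rec) <-
    rownames(spl) <- rownames(amp) <- rownames(recc) <- NULL

  ## paired comparisons
  cmp <- list()
  getv <- function(df, arm, tm, region, col) {
    v <- df[[col]][df$arm == arm & df$time == tm & df$region == region]
    if (length(v) == 1) v else NA_real_
  }
  for (pl in plaques) for (tm in times) {
    cmp[[length(cmp) + 1]] <- data.frame(
      comparison = "psg_plaque_over_noplaque", region = pl$branch, time = tm,
      value = getv(psg, "plaque_newtonian", tm, pl$branch, "psg_max") /
        getv(psg, "noplaque_newtonian", tm, pl$branch, "psg_max"))
    cmp[[length(cmp) + 1]] <- data.frame(
      comparison = "wss_gpl_over_newtonian", region = pl$branch, time = tm,
      value = getv(wss, "plaque_gpl", tm, pl$branch, "wss_max") /
        getv(wss, "plaque_newtonian", tm, pl$branch, "wss_max"))
  }
  cmp <- do.call(rbind, cmp); rownames(cmp) <- NULL

  structure(list(schema = "coroflow-summary/1", times = times,
                 arms = sort(names(arms)),
                 velocity = vel, psg = psg, wss = wss,
                 recirculation = rec, recirculation_cycle = recc,
                 flow_split = spl, amplification = amp, comparisons = cmp),
            class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  cat("Hemodynamic summary (", paste(x$arms, collapse = ", "), ")\n", sep = "")
  cat("  reporting phases:", paste(x$times, collapse = ", "), "s\n")
  cat("  PSG ranges (Pa/m) over plaque regions:\n")
  print(x$psg, row.names = FALSE)
  cat("  WSS ranges (Pa) over plaque walls:\n")
  print(x$wss, row.names = FALSE)
  invisible(x)
}
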