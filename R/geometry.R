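## Parametric synthetic left-coronary bifurcation: left main stem (LMS)
## dividing into left anterior descending (LAD) and left circumflex (LCx),
## with raised-cosine plaques. All geometry in millimetres, 2-D x-y plane.
## The LMS axis runs along +x from (-lms_length, 0) to the junction at the
## origin; daughter axes leave the origin at +/- half the bifurcation angle.

.rot90 <- function(v) c(-v[2], v[1])

.line_intersect <- function(p1, d1, p2, d2) {
  A <- cbind(d1, -d2)
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (abs(det) < 1e-12) stop("parallel lines in junction construction")
  t <- solve(A, p2 - p1)
  list(point = p1 + t[1] * d1, t1 = t[1], t2 = t[2])
}

## Round the corner where two wall lines meet at P; w1, w2 are unit directions
## pointing away from the corner along each wall. The tangent circle's center
## lies on the bisector (tissue side for both the outer saddle corners and the
## carina apex); the arc replaces the sharp corner.
.fillet_corner <- function(P, w1, w2, r, ds) {
  cosang <- sum(w1 * w2)
  theta <- acos(max(-1, min(1, cosang)))
  if (theta < 1e-6 || theta > pi - 1e-3) {
    stop(sprintf("degenerate junction corner (wall angle %.2f deg); ",
                 theta * 180 / pi),
         "adjust bifurcation_angle or fillet_radius")
  }
  ell <- r / tan(theta / 2)
  bis <- (w1 + w2) / sqrt(sum((w1 + w2)^2))
  C <- P + (r / sin(theta / 2)) * bis
  T1 <- P + ell * w1
  T2 <- P + ell * w2
  a1 <- atan2(T1[2] - C[2], T1[1] - C[1])
  a2 <- atan2(T2[2] - C[2], T2[1] - C[1])
  dphi <- (a2 - a1) %% (2 * pi)
  if (dphi > pi) dphi <- dphi - 2 * pi  # short way around
  nseg <- max(4L, ceiling(abs(dphi) * r / ds))
  ang <- a1 + dphi * seq(0, 1, length.out = nseg + 1)
  arc <- cbind(C[1] + r * cos(ang), C[2] + r * sin(ang))
  list(center = C, T1 = T1, T2 = T2, ell = ell, arc = arc,
       front = C - r * bis, theta = theta)
}

#' Parametric description of the left coronary bifurcation
#'
#' Lumen dimensions of the idealized vessel tree: an LMS trunk that divides
#' into LAD and LCx daughter branches at a prescribed angle, with circular
#' fillets smoothing the junction corners and the carina (flow divider) apex.
#' Defaults are typical adult left-coronary dimensions.
#'
#' @param lms_diameter,lad_diameter,lcx_diameter Lumen diameters, mm.
#' @param lms_length,lad_length,lcx_length Branch lengths along their
#'   centerlines, mm.
#' @param bifurcation_angle Angle between the LAD and LCx centerlines,
#'   degrees (0 < angle < 180); split symmetrically about the LMS axis.
#' @param fillet_radius Junction smoothing radius, mm.
#' @return A \code{vessel_spec} object.
#' @export
vessel_spec <- function(lms_diameter = 4.5, lad_diameter = 3.5,
                        lcx_diameter = 3.0, lms_length = 10,
                        lad_length = 25, lcx_length = 25,
                        bifurcation_angle = 80, fillet_radius = 1.0) {
  sp <- list(lms_diameter = lms_diameter, lad_diameter = lad_diameter,
             lcx_diameter = lcx_diameter, lms_length = lms_length,
             lad_length = lad_length, lcx_length = lcx_length,
             bifurcation_angle = bifurcation_angle,
             fillet_radius = fillet_radius)
  dias <- c(lms_diameter, lad_diameter, lcx_diameter)
  if (any(dias <= 0)) stop("all diameters must be > 0")
  if (lad_diameter > lms_diameter || lcx_diameter > lms_diameter)
    stop("daughter diameters must not exceed lms_diameter")
  if (bifurcation_angle <= 0 || bifurcation_angle >= 180)
    stop("bifurcation_angle must lie strictly between 0 and 180 degrees")
  if (fillet_radius <= 0) stop("fillet_radius must be > 0")
  structure(sp, class = "vessel_spec")
}

#' Parametric description of a stenosing plaque
#'
#' A raised-cosine wall bump along one branch: the local lumen width is
#' multiplied by 1 - delta * g(s), g(s) = (1 + cos(2 pi (s - s0)/L))/2 for
#' |s - s0| <= L/2, giving a C1 wall and a throat diameter of
#' (1 - delta) * D at s0. Symmetric plaques narrow both walls equally;
#' eccentric plaques put the whole bump on one wall.
#'
#' @param branch One of \code{"lms"}, \code{"lad"}, \code{"lcx"}.
#' @param center_s Arc-length position of the throat along the branch
#'   centerline, mm (0 at the branch origin; the LMS origin is its inlet).
#' @param length Plaque extent L, mm.
#' @param stenosis_fraction Fractional diameter reduction delta in [0, 1).
#' @param eccentric If TRUE the bump sits on one wall only.
#' @return A \code{plaque_spec} object.
#' @export
plaque_spec <- function(branch, center_s, length = 4,
                        stenosis_fraction = 0.6, eccentric = FALSE) {
  branch <- match.arg(tolower(branch), c("lms", "lad", "lcx"))
  if (stenosis_fraction < 0 || stenosis_fraction >= 1)
    stop("stenosis_fraction must lie in [0, 1)")
  if (length <= 0) stop("plaque length must be > 0")
  structure(list(branch = branch, center_s = center_s, length = length,
                 stenosis_fraction = stenosis_fraction, eccentric = eccentric),
            class = "plaque_spec")
}

#' Default plaque configuration
#'
#' Two symmetric 4 mm plaques of 60 percent diameter stenosis: one at
#' mid-LMS and one in the proximal LAD immediately distal to the ostium
#' (clear of the carina fillet).
#'
#' @return A list of two [plaque_spec()] objects.
#' @export
default_plaques <- function() {
  list(plaque_spec("lms", center_s = 5.0),
       plaque_spec("lad", center_s = 5.5))
}

## raised-cosine bump weight g(s) in [0,1], zero outside the extent
.plaque_g <- function(s, pl) {
  g <- numeric(length(s))
  inside <- abs(s - pl$center_s) <= pl$length / 2
  g[inside] <- 0.5 * (1 + cos(2 * pi * (s[inside] - pl$center_s) / pl$length))
  g
}

.sample_wall <- function(br, side, s_from, s_to, ds) {
  sg <- br$s
  off <- if (side == "left") br$off_left else br$off_right
  s <- seq(s_from, s_to, by = ds)
  if (s[length(s)] < s_to - 1e-9) s <- c(s, s_to)
  o <- stats::approx(sg, off, xout = s, rule = 2)$y
  n <- .rot90(br$dir)
  cbind(br$origin[1] + s * br$dir[1] + o * n[1],
        br$origin[2] + s * br$dir[2] + o * n[2])
}

.branch_frame <- function(spec) {
  half <- spec$bifurcation_angle * pi / 360  # half-angle in radians
  list(
    lms = list(origin = c(-spec$lms_length, 0), dir = c(1, 0),
               length = spec$lms_length, radius = spec$lms_diameter / 2),
    lad = list(origin = c(0, 0), dir = c(cos(half), sin(half)),
               length = spec$lad_length, radius = spec$lad_diameter / 2),
    lcx = list(origin = c(0, 0), dir = c(cos(half), -sin(half)),
               length = spec$lcx_length, radius = spec$lcx_diameter / 2))
}

.build_geometry <- function(spec, plaques, ds = 0.05) {
  br <- .branch_frame(spec)
  # signed wall offsets per branch (left = +90 deg of the axis direction)
  for (nm in names(br)) {
    b <- br[[nm]]
    b$s <- seq(0, b$length, by = ds)
    if (b$s[length(b$s)] < b$length - 1e-9) b$s <- c(b$s, b$length)
    b$off_left <- rep(b$radius, length(b$s))
    b$off_right <- rep(-b$radius, length(b$s))
    br[[nm]] <- b
  }

  ## ---- junction corners (on nominal walls; plaques are kept clear) ----
  r <- spec$fillet_radius
  nL <- .rot90(br$lms$dir)
  n2 <- .rot90(br$lad$dir)
  n3 <- .rot90(br$lcx$dir)
  # outer saddle corner LMS-left / LAD-left
  Pu <- .line_intersect(br$lms$origin + br$lms$radius * nL, br$lms$dir,
                        br$lad$origin + br$lad$radius * n2, br$lad$dir)$point
  fu <- .fillet_corner(Pu, -br$lms$dir, br$lad$dir, r, ds)
  # outer saddle corner LMS-right / LCx-right
  Pl <- .line_intersect(br$lms$origin - br$lms$radius * nL, br$lms$dir,
                        br$lcx$origin - br$lcx$radius * n3, br$lcx$dir)$point
  fl <- .fillet_corner(Pl, -br$lms$dir, br$lcx$dir, r, ds)
  # carina apex LAD-right / LCx-left
  Pc <- .line_intersect(br$lad$origin - br$lad$radius * n2, br$lad$dir,
                        br$lcx$origin + br$lcx$radius * n3, br$lcx$dir)$point
  fc <- .fillet_corner(Pc, br$lad$dir, br$lcx$dir, r, ds)

  proj <- function(p, b) sum((p - b$origin) * b$dir)  # axial coordinate
  # wall extents: tangent points bound the clean (plaque-admissible) zones
  s_fu <- proj(fu$T1, br$lms); t_fu <- proj(fu$T2, br$lad)
  s_fl <- proj(fl$T1, br$lms); t_fl <- proj(fl$T2, br$lcx)
  t_cu <- proj(fc$T1, br$lad); t_cl <- proj(fc$T2, br$lcx)
  margin <- 0.2
  clean <- list(
    lms = c(margin, min(s_fu, s_fl) - margin),
    lad = c(max(t_fu, t_cu) + margin, br$lad$length - margin),
    lcx = c(max(t_fl, t_cl) + margin, br$lcx$length - margin))
  for (nm in names(clean)) {
    if (clean[[nm]][1] >= clean[[nm]][2])
      stop("junction smoothing leaves no usable wall on branch ", nm,
           "; reduce fillet_radius or the bifurcation angle")
  }
  if (proj(fc$front, br$lms) + spec$lms_length < spec$lms_length - 1e-9)
    stop("carina fillet reaches upstream of the junction; reduce fillet_radius")
  for (nm in c("lad", "lcx")) {
    if (clean[[nm]][1] >= br[[nm]]$length / 2)
      stop("junction region occupies most of branch ", nm,
           "; lengthen the branch or reduce fillet_radius")
  }

  ## ---- plaques modulate the signed offsets ----
  plaques <- lapply(plaques, function(p) p)
  seen <- list(lms = list(), lad = list(), lcx = list())
  for (pl in plaques) {
    b <- br[[pl$branch]]
    ext <- pl$center_s + c(-1, 1) * pl$length / 2
    cz <- clean[[pl$branch]]
    if (ext[1] < cz[1] || ext[2] > cz[2]) {
      stop(sprintf(paste0(
        "plaque on %s spans [%.2f, %.2f] mm but must lie within the clean ",
        "wall zone [%.2f, %.2f] mm (clear of junction smoothing and ends)"),
        pl$branch, ext[1], ext[2], cz[1], cz[2]))
    }
    for (prev in seen[[pl$branch]]) {
      pe <- prev$center_s + c(-1, 1) * prev$length / 2
      if (ext[1] < pe[2] && pe[1] < ext[2])
        stop("overlapping plaques on branch ", pl$branch)
    }
    seen[[pl$branch]] <- c(seen[[pl$branch]], list(pl))
    g <- .plaque_g(b$s, pl)
    d <- pl$stenosis_fraction
    if (isTRUE(pl$eccentric)) {
      b$off_left <- b$off_left - 2 * d * g * b$radius
    } else {
      b$off_left <- b$off_left * (1 - d * g)
      b$off_right <- b$off_right * (1 - d * g)
    }
    if (any(b$off_left - b$off_right <= 0))
      stop("plaque closes the lumen on branch ", pl$branch)
    br[[pl$branch]] <- b
  }

  ## ---- flow-oriented boundary paths ----
  paths <- list()
  paths$lms_upper <- .sample_wall(br$lms, "left", 0, s_fu, ds)
  paths$fillet_upper <- fu$arc                      # T1 (LMS) -> T2 (LAD)
  paths$lad_outer <- .sample_wall(br$lad, "left", t_fu, br$lad$length, ds)
  paths$lms_lower <- .sample_wall(br$lms, "right", 0, s_fl, ds)
  paths$fillet_lower <- fl$arc                      # T1 (LMS) -> T2 (LCx)
  paths$lcx_outer <- .sample_wall(br$lcx, "right", t_fl, br$lcx$length, ds)
  paths$lad_inner <- .sample_wall(br$lad, "right", t_cu, br$lad$length, ds)
  paths$lcx_inner <- .sample_wall(br$lcx, "left", t_cl, br$lcx$length, ds)
  # split carina arc at its upstream tip (the rounded apex "front" point)
  arc <- fc$arc                                     # T1 (LAD side) -> T2 (LCx)
  dfr <- rowSums((arc - matrix(fc$front, nrow(arc), 2, byrow = TRUE))^2)
  isplit <- which.min(dfr)
  paths$carina_upper <- arc[isplit:1, , drop = FALSE]        # front -> T1 (LAD)
  paths$carina_lower <- arc[isplit:nrow(arc), , drop = FALSE] # front -> T2 (LCx)
  # lumen midline from the inlet to the carina front point
  midoff <- (br$lms$off_left + br$lms$off_right) / 2
  med <- cbind(br$lms$origin[1] + br$lms$s, midoff)
  paths$median <- rbind(med, fc$front)
  paths$inlet <- {
    o0 <- c(stats::approx(br$lms$s, br$lms$off_right, 0, rule = 2)$y,
            stats::approx(br$lms$s, br$lms$off_left, 0, rule = 2)$y)
    rbind(c(br$lms$origin[1], o0[1]), c(br$lms$origin[1], o0[2]))
  }
  out_seg <- function(b) {
    n <- .rot90(b$dir); e <- b$origin + b$length * b$dir
    oL <- b$off_left[length(b$off_left)]; oR <- b$off_right[length(b$off_right)]
    rbind(e + oR * n, e + oL * n)  # right corner -> left corner
  }
  paths$outlet_lad <- out_seg(br$lad)
  paths$outlet_lcx <- out_seg(br$lcx)

  ## ---- closed polygon, counter-clockwise ----
  segs <- list(paths$lms_lower, paths$fillet_lower, paths$lcx_outer,
               paths$outlet_lcx, paths$lcx_inner[nrow(paths$lcx_inner):1, ],
               paths$carina_lower[nrow(paths$carina_lower):1, ],
               paths$carina_upper, paths$lad_inner, paths$outlet_lad,
               paths$lad_outer[nrow(paths$lad_outer):1, ],
               paths$fillet_upper[nrow(paths$fillet_upper):1, ],
               paths$lms_upper[nrow(paths$lms_upper):1, ],
               paths$inlet[2:1, ])
  poly <- do.call(rbind, segs)
  keep <- c(TRUE, rowSums(abs(diff(poly))) > 1e-9)
  poly <- poly[keep, , drop = FALSE]
  if (sqrt(sum((poly[1, ] - poly[nrow(poly), ])^2)) < 1e-9)
    poly <- poly[-nrow(poly), , drop = FALSE]
  area2 <- sum(poly[, 1] * poly[c(2:nrow(poly), 1), 2] -
               poly[c(2:nrow(poly), 1), 1] * poly[, 2])
  if (area2 < 0) poly <- poly[nrow(poly):1, , drop = FALSE]

  structure(list(spec = spec, plaques = plaques, ds = ds, branches = br,
                 corners = list(upper = fu, lower = fl, carina = fc),
                 extents = list(s_fu = s_fu, t_fu = t_fu, s_fl = s_fl,
                                t_fl = t_fl, t_cu = t_cu, t_cl = t_cl),
                 clean = clean, paths = paths, polygon = poly),
            class = "lumen_outline")
}

#' Build the bifurcation lumen outline
#'
#' Assembles the three branch wall curves, smooths the two outer junction
#' corners and the carina apex with circular fillets of \code{fillet_radius},
#' and returns the closed lumen outline. Away from the junction the lumen
#' width equals the branch diameter.
#'
#' @param spec A [vessel_spec()].
#' @param ds Wall sampling step, mm.
#' @return A \code{lumen_outline} object with per-branch signed wall offsets,
#'   boundary paths and the assembled counter-clockwise polygon.
#' @export
build_bifurcation <- function(spec, ds = 0.05) {
  stopifnot(inherits(spec, "vessel_spec"))
  .build_geometry(spec, list(), ds = ds)
}

#' Insert a plaque into a lumen outline
#'
#' Applies the raised-cosine narrowing of the plaque to the branch's signed
#' wall offsets and rebuilds the outline. The modification is local: offsets
#' outside the plaque extent are unchanged. Overlapping plaques on one
#' branch, and plaques reaching into the junction-smoothing zone, are
#' rejected.
#'
#' @param outline A \code{lumen_outline}.
#' @param plaque A [plaque_spec()].
#' @return The modified \code{lumen_outline}.
#' @export
apply_plaque <- function(outline, plaque) {
  stopifnot(inherits(outline, "lumen_outline"), inherits(plaque, "plaque_spec"))
  .build_geometry(outline$spec, c(outline$plaques, list(plaque)),
                  ds = outline$ds)
}

#' Percent diameter stenosis of a branch
#'
#' 100 * (1 - minimum lumen width / nominal branch diameter), the standard
#' percent-diameter-stenosis measure evaluated on the sampled wall offsets.
#'
#' @param outline A \code{lumen_outline}.
#' @param branch \code{"lms"}, \code{"lad"} or \code{"lcx"}.
#' @return Stenosis in percent (0 for an unstenosed branch).
#' @export
measure_stenosis <- function(outline, branch) {
  branch <- match.arg(tolower(branch), c("lms", "lad", "lcx"))
  b <- outline$branches[[branch]]
  width <- b$off_left - b$off_right
  100 * (1 - min(width) / (2 * b$radius))
}

#' Cross-section plane through a branch at a given arc position
#'
#' The in-plane segment is the chord of the lumen through the branch-axis
#' point at axial position \code{s}, perpendicular to the branch axis,
#' clipped against the lumen outline polygon (so sections remain well
#' defined in the junction region where the walls are fillet arcs). The
#' branch axis is the unit streamwise direction.
#'
#' @param outline A \code{lumen_outline}.
#' @param branch Branch name.
#' @param s Axial position, mm.
#' @param label Plane label.
#' @return A one-row data frame (label, branch, s, endpoints, direction).
#' @export
section_plane <- function(outline, branch, s, label = "") {
  branch <- match.arg(tolower(branch), c("lms", "lad", "lcx"))
  b <- outline$branches[[branch]]
  if (s < 0 || s > b$length) stop("section position outside branch ", branch)
  n <- .rot90(b$dir)
  P <- b$origin + s * b$dir
  ## intersect the perpendicular line P + tau n with every polygon edge and
  ## take the interval that contains the axis point
  poly <- outline$polygon
  np <- nrow(poly)
  a <- poly; bb <- poly[c(2:np, 1), ]
  ex <- bb[, 1] - a[, 1]; ey <- bb[, 2] - a[, 2]
  det <- n[1] * (-ey) - (-ex) * n[2]
  ok <- abs(det) > 1e-12
  rx <- a[, 1] - P[1]; ry <- a[, 2] - P[2]
  tau <- (rx * (-ey) + ex * ry) / det
  w <- (n[1] * ry - n[2] * rx) / det
  hits <- sort(tau[ok & w >= 0 & w < 1])
  lo <- hits[hits <= 1e-9]; hi <- hits[hits >= -1e-9]
  if (!length(lo) || !length(hi))
    stop("section at s = ", s, " mm on ", branch, " lies outside the lumen")
  t0 <- max(lo); t1 <- min(hi)
  if (t1 - t0 < 1e-6)
    stop("section at s = ", s, " mm on ", branch, " lies outside the lumen")
  p0 <- P + t0 * n
  p1 <- P + t1 * n
  data.frame(label = label, branch = branch, s = s,
             x0 = p0[1], y0 = p0[2], x1 = p1[1], y1 = p1[2],
             dir_x = b$dir[1], dir_y = b$dir[2], stringsAsFactors = FALSE)
}

#' Define the fifteen measurement sections A-O
#'
#' Three groups of five planes at \code{spacing} mm, laid out around the
#' plaques the way the flow is read off them: A-E walk up the LMS plaque
#' with A-B prestenotic and E at the throat; F-J walk down the LAD plaque
#' with F at the throat and I-J at the postplaque expansion (where
#' post-stenotic recirculation appears); K-O sit on the proximal LCx
#' starting at the ostium, distal to the LMS plaque. Group positions
#' default to the plaque positions in \code{plaques} (so the same stations
#' can be applied to the paired no-plaque geometry).
#'
#' @param outline A \code{lumen_outline} (with or without plaques applied).
#' @param plaques Plaque list defining the group positions; defaults to the
#'   outline's own plaques.
#' @param spacing Within-group plane spacing, mm.
#' @param lcx_start Axial start of the K-O group on the LCx, mm (default
#'   1.0: the proximal segment at the ostium).
#' @return A 15-row data frame of section planes.
#' @export
define_sections <- function(outline, plaques = outline$plaques,
                            spacing = 0.5, lcx_start = 1.0) {
  center_of <- function(branch, fallback) {
    for (pl in plaques) if (pl$branch == branch) return(pl$center_s)
    fallback
  }
  c_lms <- center_of("lms", 5.0)
  c_lad <- center_of("lad", 5.5)
  offs <- spacing * (0:4)
  groups <- list(
    list(labels = LETTERS[1:5], branch = "lms", s = c_lms - spacing * 4 + offs),
    list(labels = LETTERS[6:10], branch = "lad", s = c_lad + offs),
    list(labels = LETTERS[11:15], branch = "lcx", s = lcx_start + offs))
  rows <- list()
  for (g in groups) {
    b <- outline$branches[[g$branch]]
    if (min(g$s) < 0.1 || max(g$s) > b$length - 0.1)
      stop("section group on ", g$branch, " extends outside the usable branch",
           " extent [0.1, ", round(b$length - 0.1, 2), "] mm")
    for (i in seq_along(g$s))
      rows[[length(rows) + 1]] <- section_plane(outline, g$branch, g$s[i],
                                                g$labels[i])
  }
  do.call(rbind, rows)
}

#' Test points against the lumen polygon
#'
#' Even-odd ray-casting point-in-polygon test.
#'
#' @param outline A \code{lumen_outline}.
#' @param pts n x 2 matrix of points (mm).
#' @return Logical vector, TRUE for points inside the lumen.
#' @export
in_lumen <- function(outline, pts) {
  poly <- outline$polygon
  pts <- matrix(pts, ncol = 2)
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  vapply(seq_len(nrow(pts)), function(i) {
    px <- pts[i, 1]; py <- pts[i, 2]
    crosses <- ((ys > py) != (ye > py)) &
      (px < xs + (py - ys) * (xe - xs) / (ye - ys))
    sum(crosses) %% 2L == 1L
  }, logical(1))
}

#' Check that the outline polygon is simple
#'
#' Brute-force segment-pair intersection test on a decimated copy of the
#' outline polygon; used to reject geometrically inconsistent
#' angle/fillet/plaque combinations.
#'
#' @param outline A \code{lumen_outline}.
#' @param decimate Keep every k-th vertex for the check.
#' @return TRUE invisibly; errors if the outline self-intersects.
#' @export
assert_simple_outline <- function(outline, decimate = 8L) {
  poly <- outline$polygon[seq(1, nrow(outline$polygon), by = decimate), ]
  n <- nrow(poly)
  a <- poly; b <- poly[c(2:n, 1), ]
  cross2 <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    if (i == 1) j <- j[j != n]
    d1 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
    d2 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
    d3 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
    d4 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit))
      stop("lumen outline self-intersects; the requested angle, fillet and ",
           "plaque combination is geometrically inconsistent")
  }
  invisible(TRUE)
}

#' @export
print.lumen_outline <- function(x, ...) {
  cat(sprintf(paste0(
    "Left coronary lumen outline: LMS %.2f mm x %.1f mm -> ",
    "LAD %.2f mm / LCx %.2f mm at %g deg, fillet %g mm\n"),
    x$spec$lms_diameter, x$spec$lms_length, x$spec$lad_diameter,
    x$spec$lcx_diameter, x$spec$bifurcation_angle, x$spec$fillet_radius))
  if (length(x$plaques)) {
    for (pl in x$plaques) {
      cat(sprintf("  plaque: %s at s = %g mm, L = %g mm, delta = %g (%s) -> %.1f%% stenosis\n",
                  toupper(pl$branch), pl$center_s, pl$length,
                  pl$stenosis_fraction,
                  if (pl$eccentric) "eccentric" else "symmetric",
                  measure_stenosis(x, pl$branch)))
    }
  } else cat("  no plaques\n")
  invisible(x)
}
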