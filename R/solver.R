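## Transient laminar incompressible Navier-Stokes on the triangulated lumen.
##
## Discretization: equal-order P1/P1 finite elements with PSPG pressure
## stabilization, backward-Euler time stepping, and Picard treatment of the
## convective velocity and (for the generalized power law) the apparent
## viscosity field. Within each step, inner iterations are defect
## corrections preconditioned by a sparse LU factorization of the Picard
## matrix; the factorization is reused across iterations and steps and
## refreshed when the iteration stops contracting. The reported residual is
## the true nonlinear residual of the discrete system (momentum rows
## normalized by rho U_ref^2 D_ref, continuity rows by U_ref D_ref), so
## convergence is measured against the actual equations, not the
## preconditioner. Boundary conditions: prescribed parabolic inlet velocity,
## no-slip rigid walls, traction-free (zero reference pressure) outlets.
## SUPG is not needed: the cell Reynolds number is below one everywhere at
## coronary flow rates and this mesh size.

#' Solver configuration
#'
#' The default schedule is 80 timesteps of 0.0125 s per 1.0 s cardiac
#' cycle, two cycles (the first discarded as the start-up transient), and
#' an inner-iteration residual target of 1e-4.
#'
#' @param dt Timestep, s.
#' @param steps_per_cycle Steps per cardiac cycle; dt * steps_per_cycle must
#'   equal the waveform period.
#' @param cycles Number of cycles to run; the last one is stored.
#' @param residual_target Normalized nonlinear residual target per step.
#' @param max_inner_iterations Inner (Picard/defect) iteration cap per step.
#' @param rho Fluid density, kg/m^3.
#' @param refactor_interval Steps between routine preconditioner refreshes.
#' @return A \code{solver_config} object.
#' @export
solver_config <- function(dt = 0.0125, steps_per_cycle = 80, cycles = 2,
                          residual_target = 1e-4, max_inner_iterations = 100,
                          rho = 1060, refactor_interval = 8) {
  stopifnot(dt > 0, steps_per_cycle >= 1, cycles >= 1, residual_target > 0,
            max_inner_iterations >= 1, rho > 0)
  structure(list(dt = dt, steps_per_cycle = steps_per_cycle, cycles = cycles,
                 residual_target = residual_target,
                 max_inner_iterations = max_inner_iterations, rho = rho,
                 refactor_interval = refactor_interval),
            class = "solver_config")
}

## ---- precomputed assembly context ----------------------------------------

.build_context <- function(mesh, config) {
  X <- mesh$nodes / 1000  # mm -> m
  tri <- mesh$tri
  n <- nrow(X); ne <- nrow(tri)
  x1 <- X[tri[, 1], 1]; y1 <- X[tri[, 1], 2]
  x2 <- X[tri[, 2], 1]; y2 <- X[tri[, 2], 2]
  x3 <- X[tri[, 3], 1]; y3 <- X[tri[, 3], 2]
  area <- ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
  if (any(area <= 0)) stop("mesh contains non-positively-oriented triangles")
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / (2 * area)  # d(phi_i)/dx
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) / (2 * area) # d(phi_i)/dy
  he <- sqrt(2 * area)
  flat <- as.vector(tri)
  ml <- as.vector(rowsum(rep(area / 3, 3), flat))     # lumped node areas
  scat <- Matrix::sparseMatrix(i = flat, j = seq_len(3 * ne), x = 1,
                               dims = c(n, 3 * ne))

  ## Dirichlet data: inlet nodes with normalized transverse position eta,
  ## wall nodes with zero velocity
  edges <- mesh$edges
  node_tag <- function(tag) sort(unique(c(edges$n1[edges$tag == tag],
                                          edges$n2[edges$tag == tag])))
  inlet_nodes <- node_tag("inlet")
  wall_nodes <- node_tag("wall")
  ipts <- X[inlet_nodes, , drop = FALSE]
  idir <- ipts[which.max(rowSums((ipts - matrix(colMeans(ipts), nrow(ipts), 2,
                                                byrow = TRUE))^2)), ] - colMeans(ipts)
  idir <- idir / sqrt(sum(idir^2))          # along-inlet unit vector
  span <- as.vector(ipts %*% idir)
  eta <- (span - (max(span) + min(span)) / 2) / (max(span) - min(span))
  # inflow direction: inward normal of the inlet segment
  flow_dir <- c(idir[2], -idir[1])
  probe <- colMeans(ipts) + 1e-4 * flow_dir
  interior <- colMeans(X)
  if (sum((probe - interior)^2) > sum((colMeans(ipts) - 1e-4 * flow_dir - interior)^2))
    flow_dir <- -flow_dir
  # inlet corner nodes are also wall nodes; no-slip wins (profile is 0 there)
  inlet_only <- setdiff(inlet_nodes, wall_nodes)
  eta <- eta[match(inlet_only, inlet_nodes)]

  dir_nodes <- c(inlet_only, wall_nodes)
  dir_rows <- c(dir_nodes, dir_nodes + n)   # ux and uy rows
  free_mom <- setdiff(seq_len(2 * n), dir_rows)

  ## boundary flux quadrature (oriented edges, outward normal)
  flux_edges <- lapply(split(seq_len(nrow(edges)), edges$tag), function(ix) {
    p1 <- X[edges$n1[ix], , drop = FALSE]; p2 <- X[edges$n2[ix], , drop = FALSE]
    d <- p2 - p1
    len <- sqrt(rowSums(d^2))
    list(n1 = edges$n1[ix], n2 = edges$n2[ix], len = len,
         nx = d[, 2] / len, ny = -d[, 1] / len)
  })

  list(X = X, tri = tri, n = n, ne = ne, area = area, b = b, cc = cc, he = he,
       ml = ml, scat = scat, flat = flat,
       inlet_nodes = inlet_only, inlet_eta = eta, flow_dir = flow_dir,
       wall_nodes = wall_nodes, dir_nodes = dir_nodes, dir_rows = dir_rows,
       free_mom = free_mom, flux_edges = flux_edges,
       inlet_width = max(span) - min(span))
}

.elem_mean <- function(ctx, f) {
  (f[ctx$tri[, 1]] + f[ctx$tri[, 2]] + f[ctx$tri[, 3]]) / 3
}
.elem_grad <- function(ctx, f) {
  fx <- rowSums(ctx$b * matrix(f[ctx$flat], ctx$ne, 3))
  fy <- rowSums(ctx$cc * matrix(f[ctx$flat], ctx$ne, 3))
  cbind(fx, fy)
}
.scatter3 <- function(ctx, w1, w2, w3) {
  as.vector(ctx$scat %*% c(w1, w2, w3))
}

.elem_viscosity <- function(ctx, ux, uy, rheology) {
  if (inherits(rheology, "newtonian_model")) return(rep(rheology$mu, ctx$ne))
  gx <- .elem_grad(ctx, ux); gy <- .elem_grad(ctx, uy)
  gdot <- shear_rate_magnitude(cbind(gx[, 1], gx[, 2], gy[, 1], gy[, 2]))
  apparent_viscosity(gdot, rheology)
}

.tau_pspg <- function(ctx, amag, mu_e, rho, dt) {
  1 / sqrt((2 / dt)^2 + (2 * amag / ctx$he)^2 + (4 * (mu_e / rho) / ctx$he^2)^2)
}

## True nonlinear residual of the backward-Euler step at state x,
## with un = velocities at the previous step and g = inlet values at t_new.
.nonlinear_residual <- function(ctx, x, un, g, rho, dt, rheology) {
  n <- ctx$n
  ux <- x[1:n]; uy <- x[(n + 1):(2 * n)]; p <- x[(2 * n + 1):(3 * n)]
  gx <- .elem_grad(ctx, ux); gy <- .elem_grad(ctx, uy); gp <- .elem_grad(ctx, p)
  ax <- .elem_mean(ctx, ux); ay <- .elem_mean(ctx, uy)
  mu_e <- .elem_viscosity(ctx, ux, uy, rheology)
  A <- ctx$area
  convx <- rho * (ax * gx[, 1] + ay * gx[, 2])
  convy <- rho * (ax * gy[, 1] + ay * gy[, 2])
  dxx <- gx[, 1]; dyy <- gy[, 2]; dxy <- (gx[, 2] + gy[, 1]) / 2
  pe <- .elem_mean(ctx, p)
  w <- A / 3
  rx <- rho * ctx$ml / dt * (ux - un[, 1]) +
    .scatter3(ctx, w * convx, w * convx, w * convx) +
    .scatter3(ctx,
              A * (mu_e * (2 * dxx * ctx$b[, 1] + 2 * dxy * ctx$cc[, 1]) - pe * ctx$b[, 1]),
              A * (mu_e * (2 * dxx * ctx$b[, 2] + 2 * dxy * ctx$cc[, 2]) - pe * ctx$b[, 2]),
              A * (mu_e * (2 * dxx * ctx$b[, 3] + 2 * dxy * ctx$cc[, 3]) - pe * ctx$b[, 3]))
  ry <- rho * ctx$ml / dt * (uy - un[, 2]) +
    .scatter3(ctx, w * convy, w * convy, w * convy) +
    .scatter3(ctx,
              A * (mu_e * (2 * dxy * ctx$b[, 1] + 2 * dyy * ctx$cc[, 1]) - pe * ctx$cc[, 1]),
              A * (mu_e * (2 * dxy * ctx$b[, 2] + 2 * dyy * ctx$cc[, 2]) - pe * ctx$cc[, 2]),
              A * (mu_e * (2 * dxy * ctx$b[, 3] + 2 * dyy * ctx$cc[, 3]) - pe * ctx$cc[, 3]))
  ## continuity with PSPG on the element-wise momentum residual
  amag <- sqrt(ax^2 + ay^2)
  tau <- .tau_pspg(ctx, amag, mu_e, rho, dt)
  unx_e <- .elem_mean(ctx, un[, 1]); uny_e <- .elem_mean(ctx, un[, 2])
  rmx <- rho * (ax - unx_e) / dt + convx + gp[, 1]
  rmy <- rho * (ay - uny_e) / dt + convy + gp[, 2]
  divu <- gx[, 1] + gy[, 2]
  rp <- .scatter3(ctx, w * divu, w * divu, w * divu) +
    .scatter3(ctx,
              (tau / rho) * A * (ctx$b[, 1] * rmx + ctx$cc[, 1] * rmy),
              (tau / rho) * A * (ctx$b[, 2] * rmx + ctx$cc[, 2] * rmy),
              (tau / rho) * A * (ctx$b[, 3] * rmx + ctx$cc[, 3] * rmy))
  ## Dirichlet rows: scaled mismatch (rows replaced in the matrix likewise)
  dscale <- rho * ctx$ml / dt
  rx[ctx$wall_nodes] <- dscale[ctx$wall_nodes] * ux[ctx$wall_nodes]
  ry[ctx$wall_nodes] <- dscale[ctx$wall_nodes] * uy[ctx$wall_nodes]
  rx[ctx$inlet_nodes] <- dscale[ctx$inlet_nodes] * (ux[ctx$inlet_nodes] - g[, 1])
  ry[ctx$inlet_nodes] <- dscale[ctx$inlet_nodes] * (uy[ctx$inlet_nodes] - g[, 2])
  ## the step wants N(x) = 0; return r = -N(x)
  list(r = -c(rx, ry, rp), mu_e = mu_e)
}

.normalize_residual <- function(ctx, r, rho, U_ref, D_ref) {
  n <- ctx$n
  mom <- sqrt(mean(r[1:(2 * n)]^2)) / (rho * U_ref^2 * D_ref)
  cont <- sqrt(mean(r[(2 * n + 1):(3 * n)]^2)) / (U_ref * D_ref)
  c(momentum = mom, continuity = cont, total = max(mom, cont))
}

## Explicit Picard matrix at convective field (ax, ay), viscosity mu_e
.assemble_matrix <- function(ctx, ax, ay, mu_e, rho, dt) {
  n <- ctx$n; ne <- ctx$ne; A <- ctx$area
  tri <- ctx$tri; b <- ctx$b; cc <- ctx$cc
  amag <- sqrt(ax^2 + ay^2)
  tau <- .tau_pspg(ctx, amag, mu_e, rho, dt)
  ii <- vector("list", 40); jj <- vector("list", 40); xx <- vector("list", 40)
  k <- 0
  put <- function(ri, cj, val) {
    k <<- k + 1; ii[[k]] <<- ri; jj[[k]] <<- cj; xx[[k]] <<- val
  }
  for (i in 1:3) for (j in 1:3) {
    conv <- rho * (A / 3) * (ax * b[, j] + ay * cc[, j])
    kxx <- A * mu_e * (2 * b[, i] * b[, j] + cc[, i] * cc[, j])
    kyy <- A * mu_e * (2 * cc[, i] * cc[, j] + b[, i] * b[, j])
    kxy <- A * mu_e * (cc[, i] * b[, j])
    kyx <- A * mu_e * (b[, i] * cc[, j])
    put(tri[, i], tri[, j], conv + kxx)                    # ux,ux
    put(tri[, i] + n, tri[, j] + n, conv + kyy)            # uy,uy
    put(tri[, i], tri[, j] + n, kxy)
    put(tri[, i] + n, tri[, j], kyx)
    put(tri[, i], tri[, j] + 2 * n, -A * b[, i] / 3)       # pressure gradient
    put(tri[, i] + n, tri[, j] + 2 * n, -A * cc[, i] / 3)
    dvx <- A * b[, j] / 3 + tau * A * b[, i] * (1 / (3 * dt) + ax * b[, j] + ay * cc[, j])
    dvy <- A * cc[, j] / 3 + tau * A * cc[, i] * (1 / (3 * dt) + ax * b[, j] + ay * cc[, j])
    put(tri[, i] + 2 * n, tri[, j], dvx)                   # continuity + PSPG
    put(tri[, i] + 2 * n, tri[, j] + n, dvy)
    put(tri[, i] + 2 * n, tri[, j] + 2 * n,
        (tau / rho) * A * (b[, i] * b[, j] + cc[, i] * cc[, j]))
  }
  # lumped mass on the momentum diagonal
  put(1:n, 1:n, rep(0, n)); put((n + 1):(2 * n), (n + 1):(2 * n), rep(0, n))
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(3 * n, 3 * n))
  dg <- rho * ctx$ml / dt
  M <- M + Matrix::Diagonal(3 * n, c(dg, dg, rep(0, n)))
  ## replace Dirichlet momentum rows by scaled identity
  dr <- ctx$dir_rows
  dvals <- rep(1, 3 * n); dvals[dr] <- 0
  M <- Matrix::Diagonal(x = dvals) %*% M +
    Matrix::sparseMatrix(i = dr, j = dr, x = dg[c(ctx$dir_nodes, ctx$dir_nodes)],
                         dims = c(3 * n, 3 * n))
  M
}

## ---- public solver interface ---------------------------------------------

#' Initialize a flow state on a mesh
#'
#' Zero velocity and pressure at t = 0, with the assembly context (element
#' geometry, boundary operators, scatter maps) precomputed and carried in
#' the state.
#'
#' @param mesh A \code{vessel_mesh}.
#' @param config A [solver_config()].
#' @return A \code{flow_state}: time, nodal velocity (m/s), pressure (Pa),
#'   per-element apparent viscosity (Pa s), and solver internals.
#' @export
initialize_flow <- function(mesh, config = solver_config()) {
  stopifnot(inherits(mesh, "vessel_mesh"), inherits(config, "solver_config"))
  ctx <- .build_context(mesh, config)
  ops <- new.env(parent = emptyenv())
  ops$ctx <- ctx
  ops$fac <- NULL
  ops$fac_age <- Inf
  structure(list(time = 0, u = matrix(0, ctx$n, 2), p = rep(0, ctx$n),
                 mu_e = NULL, residual = NA_real_, iterations = 0L,
                 mesh = mesh, ops = ops),
            class = "flow_state")
}

.inlet_values <- function(ctx, inflow, t) {
  inlet_profile(inflow, t, ctx$inlet_eta, ctx$flow_dir)
}

#' Advance a flow state by one timestep
#'
#' One backward-Euler step. Inner iterations update the convective velocity
#' and (for shear-thinning rheology) the viscosity field and apply
#' LU-preconditioned defect corrections until the normalized nonlinear
#' residual falls below \code{config$residual_target} or
#' \code{config$max_inner_iterations} is reached (then a warning is issued
#' and the residual recorded).
#'
#' @param state A \code{flow_state}.
#' @param config A [solver_config()].
#' @param inflow A \code{waveform} for the inlet.
#' @param rheology A blood model from [newtonian_model()] or [gpl_model()].
#' @param U_ref,D_ref Residual normalization scales (m/s, m); defaults are
#'   the waveform's peak mean velocity and the inlet width.
#' @param inlet_fun Optional override of the parabolic inlet profile: a
#'   function (t, eta) returning an n x 2 velocity matrix (m/s) for the
#'   inlet nodes at normalized transverse positions eta (used by the
#'   oscillatory-flow validation cases).
#' @return The advanced \code{flow_state} with \code{residual},
#'   \code{iterations} and \code{inner_residuals} recorded.
#' @export
advance <- function(state, config, inflow, rheology,
                    U_ref = NULL, D_ref = NULL, inlet_fun = NULL) {
  ops <- state$ops
  ctx <- ops$ctx
  rho <- config$rho; dt <- config$dt
  if (is.null(U_ref)) {
    grid <- seq(0, inflow$period, by = inflow$period / 200)
    U_ref <- max(abs(eval_waveform(inflow, grid)))
  }
  if (is.null(D_ref)) D_ref <- ctx$inlet_width
  t_new <- state$time + dt
  g <- if (is.null(inlet_fun)) .inlet_values(ctx, inflow, t_new) else
    inlet_fun(t_new, ctx$inlet_eta)
  un <- state$u
  n <- ctx$n
  x <- c(state$u[, 1], state$u[, 2], state$p)

  res_hist <- numeric(0)
  res_prev <- Inf
  solved_once <- FALSE
  for (it in seq_len(config$max_inner_iterations)) {
    nr <- .nonlinear_residual(ctx, x, un, g, rho, dt, rheology)
    res <- .normalize_residual(ctx, nr$r, rho, U_ref, D_ref)[["total"]]
    res_hist <- c(res_hist, res)
    if (res < config$residual_target && solved_once) break
    if (it == config$max_inner_iterations) {
      warning(sprintf("timestep at t = %.4f s stopped at residual %.3g after %d iterations",
                      t_new, res, it))
      break
    }
    stale <- ops$fac_age >= config$refactor_interval
    stagnant <- solved_once && res > 0.5 * res_prev
    if (is.null(ops$fac) || stale || stagnant) {
      ux <- x[1:n]; uy <- x[(n + 1):(2 * n)]
      ax <- .elem_mean(ctx, ux); ay <- .elem_mean(ctx, uy)
      M <- .assemble_matrix(ctx, ax, ay, nr$mu_e, rho, dt)
      ops$fac <- Matrix::lu(M)
      ops$fac_age <- 0
    }
    dx <- as.vector(Matrix::solve(ops$fac, nr$r))
    x <- x + dx
    res_prev <- res
    solved_once <- TRUE
  }
  ops$fac_age <- ops$fac_age + 1

  state$u <- cbind(x[1:n], x[(n + 1):(2 * n)])
  state$p <- x[(2 * n + 1):(3 * n)]
  state$mu_e <- .elem_viscosity(ctx, state$u[, 1], state$u[, 2], rheology)
  state$time <- t_new
  state$residual <- res_hist[length(res_hist)]
  state$iterations <- length(res_hist) - 1L
  state$inner_residuals <- res_hist
  state
}

#' Normalized residual of a flow state
#'
#' Recomputes the nonlinear discrete residual of the backward-Euler step
#' that produced \code{state} (momentum normalized by rho U_ref^2 D_ref,
#' continuity by U_ref D_ref; the reported value is the maximum of the
#' two).
#'
#' @param state Current \code{flow_state}.
#' @param prev_state State at the previous timestep.
#' @inheritParams advance
#' @return Named vector (momentum, continuity, total).
#' @export
flow_residual <- function(state, prev_state, config, inflow, rheology,
                          U_ref = NULL, D_ref = NULL) {
  ctx <- state$ops$ctx
  if (is.null(U_ref)) {
    grid <- seq(0, inflow$period, by = inflow$period / 200)
    U_ref <- max(abs(eval_waveform(inflow, grid)))
  }
  if (is.null(D_ref)) D_ref <- ctx$inlet_width
  g <- .inlet_values(ctx, inflow, state$time)
  x <- c(state$u[, 1], state$u[, 2], state$p)
  nr <- .nonlinear_residual(ctx, x, prev_state$u, g, config$rho, config$dt,
                            rheology)
  .normalize_residual(ctx, nr$r, config$rho, U_ref, D_ref)
}

#' Boundary volume fluxes of a state
#'
#' Outward volume flux (2-D, m^2/s) through each tagged boundary by
#' trapezoidal edge quadrature, consistent with the finite-element boundary
#' integral.
#'
#' @param state A \code{flow_state}.
#' @return Named vector of outward fluxes per boundary tag.
#' @export
boundary_fluxes <- function(state) {
  ctx <- state$ops$ctx
  u <- state$u
  vapply(ctx$flux_edges, function(e) {
    un1 <- u[e$n1, 1] * e$nx + u[e$n1, 2] * e$ny
    un2 <- u[e$n2, 1] * e$nx + u[e$n2, 2] * e$ny
    sum(e$len / 2 * (un1 + un2))
  }, numeric(1))
}

#' Run cardiac cycles and store the final cycle
#'
#' Runs \code{config$cycles} cycles of \code{config$steps_per_cycle} steps
#' and stores every state of the last cycle (earlier cycles shed the
#' start-up transient). With the default schedule, peak systole (t = 0.4 s)
#' and mid-diastole (t = 0.7 s) are stored steps 32 and 56.
#'
#' @param mesh A \code{vessel_mesh}.
#' @param config A [solver_config()].
#' @param inflow A \code{waveform}; its period must equal
#'   dt * steps_per_cycle.
#' @param rheology A blood model.
#' @param keep Which steps of the final cycle to retain in full (velocity,
#'   pressure, viscosity); default all.
#' @param verbose Print per-cycle progress.
#' @param inlet_fun Optional inlet profile override, see [advance()].
#' @return A \code{flow_history}: stored states, per-step residual /
#'   iteration log for all cycles, mesh, config and waveform.
#' @export
run_cycles <- function(mesh, config, inflow, rheology,
                       keep = seq_len(config$steps_per_cycle),
                       verbose = FALSE, inlet_fun = NULL) {
  if (abs(config$dt * config$steps_per_cycle - inflow$period) > 1e-9) {
    stop(sprintf("dt * steps_per_cycle = %g does not equal the waveform period %g s",
                 config$dt * config$steps_per_cycle, inflow$period))
  }
  state <- initialize_flow(mesh, config)
  spc <- config$steps_per_cycle
  log <- data.frame(cycle = integer(0), step = integer(0), time = numeric(0),
                    residual = numeric(0), iterations = integer(0))
  states <- vector("list", spc)
  for (cyc in seq_len(config$cycles)) {
    for (k in seq_len(spc)) {
      state <- advance(state, config, inflow, rheology, inlet_fun = inlet_fun)
      log <- rbind(log, data.frame(cycle = cyc, step = k, time = state$time,
                                   residual = state$residual,
                                   iterations = state$iterations))
      if (cyc == config$cycles && k %in% keep) {
        states[[k]] <- list(time = state$time, phase = k * config$dt,
                            u = state$u, p = state$p, mu_e = state$mu_e,
                            residual = state$residual,
                            fluxes = boundary_fluxes(state))
      }
    }
    if (verbose) {
      message(sprintf("cycle %d/%d done (max residual %.3g)", cyc,
                      config$cycles, max(log$residual[log$cycle == cyc])))
    }
  }
  structure(list(states = states, log = log, mesh = mesh, config = config,
                 inflow = inflow, rheology = rheology,
                 final_state = state),
            class = "flow_history")
}

#' Retrieve the stored state at a cycle phase
#'
#' @param history A \code{flow_history}.
#' @param phase Time within the cycle, s (must be a stored step).
#' @return The stored state list (time, u, p, mu_e, fluxes).
#' @export
state_at <- function(history, phase) {
  k <- round(phase / history$config$dt)
  if (abs(k * history$config$dt - phase) > 1e-9 || k < 1 ||
      k > history$config$steps_per_cycle || is.null(history$states[[k]]))
    stop("no stored state at phase ", phase, " s")
  history$states[[k]]
}

#' @export
print.flow_history <- function(x, ...) {
  stored <- sum(!vapply(x$states, is.null, logical(1)))
  cat(sprintf("flow_history: %d cycles x %d steps (dt = %g s), %d stored states\n",
              x$config$cycles, x$config$steps_per_cycle, x$config$dt, stored))
  last <- x$log[x$log$cycle == max(x$log$cycle), ]
  cat(sprintf("  final cycle: max residual %.3g, mean inner iterations %.1f\n",
              max(last$residual), mean(last$iterations)))
  invisible(x)
}
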