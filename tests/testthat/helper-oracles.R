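# Independent geometric oracles and shared (memoized) expensive fixtures.

## winding-number point-in-polygon, independent of the package's ray caster
pip_oracle <- function(poly, px, py) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  a1 <- atan2(ys - py, xs - px)
  a2 <- atan2(ye - py, xe - px)
  d <- a2 - a1
  d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
  abs(sum(d)) > pi
}

## brute-force proper-intersection test over all non-adjacent segment pairs
polygon_is_simple_oracle <- function(poly) {
  n <- nrow(poly)
  a <- poly; b <- poly[c(2:n, 1), ]
  crs <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    if (i == 1) j <- j[j != n]
    d1 <- crs(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
    d2 <- crs(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
    d3 <- crs(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
    d4 <- crs(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

## memoized fixtures shared across test files (computed at most once per run)
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, fn) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- fn()
  .fixture_env[[name]]
}

default_outline <- function() fixture("outline0", function() {
  build_bifurcation(vessel_spec())
})

plaqued_outline <- function() fixture("outline1", function() {
  ol <- default_outline()
  for (pl in default_plaques()) ol <- apply_plaque(ol, pl)
  ol
})

coarse_plaque_mesh <- function() fixture("mesh_coarse", function() {
  generate_mesh(plaqued_outline(), h = 0.45)
})

## constant-inflow waveform for steady fixtures
steady_waveform <- function(v = 0.02) {
  t <- seq(0, 1, length.out = 41)[-41]
  fit_fourier(cbind(t, rep(v, 40)), K = 1, period = 1)
}

## steady plane-Poiseuille run on a straight channel (shared oracle fixture)
poiseuille_run <- function() fixture("poiseuille", function() {
  msh <- channel_mesh(length = 12, width = 4, h = 0.2)
  cfg <- solver_config(dt = 0.1, steps_per_cycle = 10, cycles = 4)
  list(mesh = msh, cfg = cfg, U = 0.02, width = 0.004,
       hist = run_cycles(msh, cfg, steady_waveform(0.02), newtonian_model()))
})

## oscillatory channel flow driven by the analytic profile (shared fixture)
womersley_run <- function() fixture("womersley", function() {
  rho <- 1060; mu <- 0.0035; nu <- mu / rho
  H <- 0.002; om <- 2 * pi; G <- 50
  lam <- sqrt(1i * om / nu)
  Uhat <- function(y) (G / (1i * rho * om)) * (1 - cosh(lam * y) / cosh(lam * H))
  msh <- channel_mesh(length = 12, width = 4, h = 0.2)
  inlet_fun <- function(t, eta) cbind(Re(Uhat(eta * 2 * H) * exp(1i * om * t)), 0)
  tt <- seq(0, 1, length.out = 41)[-41]
  wf <- fit_fourier(cbind(tt, Re(Uhat(0) * exp(1i * om * tt))), K = 2, period = 1)
  cfg <- solver_config(dt = 0.0125, steps_per_cycle = 80, cycles = 3)
  hist <- run_cycles(msh, cfg, wf, newtonian_model(), inlet_fun = inlet_fun)
  list(mesh = msh, hist = hist, Uhat = Uhat, om = om, H = H)
})

## reduced-size four-arm study (coarse mesh, one cycle, dt 0.025)
reduced_config <- function(out_dir = tempfile("study")) {
  cfg <- default_study_config(out_dir = out_dir)
  cfg$mesh$h <- 0.45
  cfg$solver <- solver_config(dt = 0.025, steps_per_cycle = 40, cycles = 1)
  cfg$output$fields <- "none"
  cfg
}

reduced_study <- function() fixture("reduced_study", function() {
  run_study(reduced_config(), write_outputs = FALSE, verbose = FALSE)
})

## full default-conditions study (the acceptance workload); timed
default_study <- function() fixture("default_study", function() {
  t0 <- proc.time()
  res <- run_study(default_study_config(out_dir = tempfile("study")),
                   write_outputs = FALSE, verbose = FALSE)
  res$elapsed_s <- (proc.time() - t0)[["elapsed"]]
  res
})
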