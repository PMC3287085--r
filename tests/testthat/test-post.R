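test_that("pressure gradient magnitude: constant, linear and quadratic fields", {
  msh <- channel_mesh(length = 6, width = 4, h = 0.2)
  n <- msh$n_nodes
  mk_state <- function(p) list(time = 0, u = matrix(0, n, 2), p = p, mu_e = NULL)
  # uniform pressure -> zero gradient
  expect_equal(max(pressure_gradient_magnitude(mk_state(rep(7, n)), msh)$nodal), 0)
  # p = 100 x Pa (x in metres) -> |grad p| = 100 Pa/m everywhere
  p_lin <- 100 * msh$nodes[, 1] / 1000
  pg <- pressure_gradient_magnitude(mk_state(p_lin), msh)
  expect_equal(range(pg$nodal), c(100, 100), tolerance = 1e-9)
  expect_equal(range(pg$elem), c(100, 100), tolerance = 1e-9)
  # p = x^2 + 3 y (metres): compare with a central finite-difference oracle
  xm <- msh$nodes[, 1] / 1000; ym <- msh$nodes[, 2] / 1000
  p_q <- xm^2 + 3 * ym
  pgq <- pressure_gradient_magnitude(mk_state(p_q), msh)
  dd <- 1e-6
  fd <- sqrt(((((xm + dd)^2 - (xm - dd)^2) / (2 * dd))^2) + 3^2)
  interior <- xm > 0.0005 & xm < 0.0055 & abs(ym) < 0.0015
  expect_lt(max(abs(pgq$nodal[interior] - fd[interior]) / fd[interior]), 0.01)
})

test_that("PSG is rotation-equivariant", {
  msh <- channel_mesh(length = 6, width = 4, h = 0.4)
  n <- msh$n_nodes
  set.seed(5)
  p <- sin(msh$nodes[, 1]) + 0.3 * msh$nodes[, 2]^2
  pg0 <- pressure_gradient_magnitude(list(p = p, u = matrix(0, n, 2)), msh)
  th <- 0.63
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  msh_r <- msh
  msh_r$nodes <- msh$nodes %*% R
  pg1 <- pressure_gradient_magnitude(list(p = p, u = matrix(0, n, 2)), msh_r)
  expect_equal(pg1$nodal, pg0$nodal, tolerance = 1e-10)
})

test_that("wall shear stress matches the Poiseuille closed form 6 mu U / h", {
  pz <- poiseuille_run()
  s <- pz$hist$states[[10]]
  ws <- wall_shear_stress(s, pz$mesh, newtonian_model())
  expected <- 6 * 0.0035 * pz$U / pz$width  # 0.105 Pa
  # away from the inlet/outlet ends
  sel <- ws$s > 2 & ws$s < 10
  expect_lt(max(abs(ws$wss[sel] - expected)) / expected, 0.05)
  # symmetric channel: opposite walls agree within 1%
  ny <- pz$mesh$wall$ny[match(ws$node, pz$mesh$wall$node)]
  top <- ws[sel & ny < 0, ]; bot <- ws[sel & ny > 0, ]
  m <- merge(top, bot, by = "s")
  expect_gt(nrow(m), 10)
  expect_lt(max(abs(m$wss.x - m$wss.y) / expected), 0.01)
  # zero flow -> identically zero WSS
  s0 <- list(u = matrix(0, pz$mesh$n_nodes, 2), p = rep(0, pz$mesh$n_nodes))
  expect_equal(max(wall_shear_stress(s0, pz$mesh, newtonian_model())$wss), 0)
})

test_that("section sampling: no-slip endpoints, parabolic shape, flux consistency", {
  pz <- poiseuille_run()
  s <- pz$hist$states[[10]]
  plane <- data.frame(label = "M", branch = "lms", s = 6,
                      x0 = 6, y0 = -2, x1 = 6, y1 = 2, dir_x = 1, dir_y = 0)
  pr <- sample_section(s, pz$mesh, plane, n = 101)
  expect_equal(pr$u_stream[1], 0)
  expect_equal(pr$u_stream[101], 0)
  expect_equal(max(pr$u_stream) / mean(pr$u_stream), 1.5, tolerance = 0.02)
  # integral of the streamwise component equals the boundary flux within 1%
  expect_equal(attr(pr, "flow_m2s"), -s$fluxes[["inlet"]], tolerance = 0.01)
  expect_error(sample_section(s, pz$mesh,
                              data.frame(label = "X", branch = "lms", s = 0,
                                         x0 = -5, y0 = 0, x1 = 1, y1 = 0,
                                         dir_x = 1, dir_y = 0)),
               "outside")
})

test_that("recirculation fraction counts reversed samples", {
  pz <- poiseuille_run()
  s <- pz$hist$states[[10]]
  plane <- data.frame(label = "M", branch = "lms", s = 6,
                      x0 = 6, y0 = -2, x1 = 6, y1 = 2, dir_x = 1, dir_y = 0)
  pr <- sample_section(s, pz$mesh, plane, n = 101)
  expect_equal(recirculation_fraction(pr), 0)
  pr2 <- pr
  pr2$u_stream[1:50] <- -pr2$u_stream[1:50]
  # sample 1 is the zero wall value, samples 2-50 become strictly negative
  expect_equal(recirculation_fraction(pr2), 49 / 101, tolerance = 1e-12)
})

test_that("summarize_study: zero-flow arms give all-zero ranges and round-trip losslessly", {
  ol0 <- default_outline()
  ol1 <- plaqued_outline()
  msh0 <- fixture("mesh0_coarse", function() generate_mesh(ol0, h = 0.45))
  msh1 <- coarse_plaque_mesh()
  cfg <- solver_config(dt = 0.025, steps_per_cycle = 40, cycles = 1)
  wf <- default_waveform()
  mk_hist <- function(mesh, rheol) {
    n <- mesh$n_nodes
    zs <- list(u = matrix(0, n, 2), p = rep(0, n), mu_e = NULL,
               time = 0, fluxes = c(inlet = 0, outlet_lad = 0, outlet_lcx = 0))
    states <- rep(list(NULL), 40)
    states[[16]] <- zs; states[[28]] <- zs
    structure(list(states = states, mesh = mesh, config = cfg, inflow = wf,
                   rheology = rheol,
                   log = data.frame(cycle = 1, step = 1, time = 0.025,
                                    residual = 0, iterations = 1)),
              class = "flow_history")
  }
  arms <- list(plaque_newtonian = mk_hist(msh1, newtonian_model()),
               plaque_gpl = mk_hist(msh1, gpl_model()),
               noplaque_newtonian = mk_hist(msh0, newtonian_model()),
               noplaque_gpl = mk_hist(msh0, gpl_model()))
  rep0 <- summarize_study(arms, list(plaque = ol1, noplaque = ol0),
                          plaques = default_plaques())
  expect_true(all(rep0$velocity$vmin_mm_s == 0 & rep0$velocity$vmax_mm_s == 0))
  expect_true(all(rep0$psg$psg_min == 0 & rep0$psg$psg_max == 0))
  expect_true(all(rep0$wss$wss_min == 0 & rep0$wss$wss_max == 0))
  expect_true(all(rep0$recirculation$fraction == 0))
  # serialization round trip
  path <- tempfile(fileext = ".json")
  report_to_json(rep0, path)
  rep1 <- report_from_json(path)
  for (nm in c("velocity", "psg", "wss", "recirculation", "flow_split")) {
    expect_equal(rep1[[nm]], rep0[[nm]])
  }
  # a missing arm is rejected for the full paired study
  expect_error(summarize_study(arms[1:3], list(plaque = ol1, noplaque = ol0),
                               plaques = default_plaques()),
               "missing run arm")
})
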