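us16 <- build_unit_system(flow_scenario(), 16, 0.05)

test_that("equilibrium PDFs match the second-order expansion", {
  m <- lattice_model("D2Q9")
  # rest state: f_eq = w
  expect_equal(c(lbm_equilibrium(1, c(0, 0), m)), m$w, tolerance = 1e-15)
  # hand evaluation for e = (1, 0), u = (0.1, 0):
  # (1/9) (1 + 0.3 + 0.045 - 0.015) = 0.1477...
  feq <- lbm_equilibrium(1, c(0.1, 0), m)
  i <- which(m$e[, 1] == 1L & m$e[, 2] == 0L)
  expect_equal(feq[i, 1], (1 / 9) * 1.33, tolerance = 1e-14)
  expect_error(lbm_equilibrium(1, c(0.6, 0), m), "sound speed")
  expect_error(lbm_equilibrium(-1, c(0, 0), m), "positive")
})

test_that("moments invert the equilibrium for randomized states", {
  set.seed(42)
  for (nm in c("D2Q9", "D3Q19")) {
    m <- lattice_model(nm)
    n <- 40L
    rho <- runif(n, 0.8, 1.2)
    u <- matrix(runif(m$d * n, -0.15, 0.15), m$d, n)
    feq <- lbm_equilibrium(rho, u, m)
    expect_equal(colSums(feq), rho, tolerance = 1e-14) # mass identity
    mom <- lbm_moments(feq, m)
    expect_equal(mom$rho, rho, tolerance = 1e-13)
    expect_equal(mom$u, u, tolerance = 1e-13)
  }
  expect_error(lbm_moments(matrix(0, 9, 2), lattice_model("D2Q9")),
               "degenerate")
})

test_that("BGK collision conserves nodal mass and momentum, tau = 1 gives equilibrium", {
  set.seed(7)
  st <- closed_box_state()
  act <- which(st$cls != 0L)
  st$f[, act] <- st$f[, act] * (1 + 0.1 * runif(length(act) * 9))
  mass0 <- colSums(st$f[, act])
  mom0 <- t(st$model$e) %*% st$f[, act]
  st1 <- lbm_collide(st)
  expect_equal(colSums(st1$f[, act]), mass0, tolerance = 1e-14)
  expect_equal(t(st$model$e) %*% st1$f[, act], mom0, tolerance = 1e-14)
  # tau = 1: post-collision state is the local equilibrium
  st$units$tau <- 1
  st2 <- lbm_collide(st)
  mom <- lbm_moments(st$f[, act], st$model)
  feq <- lbm_equilibrium(mom$rho, mom$u, st$model)
  expect_equal(st2$f[, act], feq, tolerance = 1e-13)
})

test_that("rest equilibrium is a fixed point of collide + stream in a closed box", {
  st <- closed_box_state(bump = 1)
  f0 <- st$f
  st <- lbm_step(st, boundary = FALSE)
  st <- lbm_step(st, boundary = FALSE)
  expect_equal(st$f, f0, tolerance = 1e-15)
})

test_that("streaming advects a lone PDF one cell and conserves mass exactly", {
  st <- closed_box_state(bump = 1)
  i_dir <- which(st$model$e[, 1] == 1L & st$model$e[, 2] == 0L)
  node <- st$strides[2] * 8 + 12 # an interior node
  st$f[, ] <- 0
  st$f[i_dir, node] <- 1
  st1 <- lbm_stream(st)
  expect_equal(st1$f[i_dir, node + 1L], 1)
  expect_equal(sum(st1$f), 1)
  # random PDFs: streaming with bounce-back is a permutation of the values
  set.seed(11)
  act <- which(st$cls != 0L)
  st$f[, act] <- matrix(runif(9 * length(act)), 9)
  st2 <- lbm_stream(st)
  expect_equal(sum(st2$f[, act]), sum(st$f[, act]), tolerance = 1e-12)
  expect_equal(sort(c(st2$f[, act])), sort(c(st$f[, act]))) # permutation
})

test_that("bounce-back reflects wall-blocked PDFs at their origin", {
  st <- closed_box_state(bump = 1)
  # node adjacent to the bottom wall; direction pointing into the wall
  node <- st$strides[2] * 1 + 5 # j = 2 (first fluid row), i = 5
  i_down <- which(st$model$e[, 1] == 0L & st$model$e[, 2] == -1L)
  st$f[, ] <- 0
  st$f[i_down, node] <- 0.7
  st1 <- lbm_bounce_back(st)
  expect_equal(st1$f[st$model$opp[i_down], node], 0.7)
  st2 <- lbm_stream(st)
  expect_equal(st2$f[st$model$opp[i_down], node], 0.7) # stays at the origin
})

test_that("inlet imposes the parabolic profile and outlet copies upstream", {
  mk <- channel_mask(res = 16L)
  st <- lbm_init(mk, us16)
  st <- lbm_apply_inlet(st)
  u <- aneuflow:::lbm_velocity(st)
  # centreline inlet node carries the peak, wall-adjacent nodes almost none
  inlet_u <- u[1, st$inlet_idx]
  expect_equal(max(inlet_u), us16$u_lattice_max * (1 - (1 / 16)^2),
               tolerance = 1e-12)
  expect_lt(min(inlet_u), 0.13 * us16$u_lattice_max)
  # discrete mean of the plane profile matches the analytic 2/3 u_max
  expect_equal(mean(inlet_u) / us16$u_lattice_max, 2 / 3, tolerance = 2e-3)
  # uniform equilibrium at unit density: outlet copy is exact
  st$f[, st$cls != 0L] <- lbm_equilibrium(1, c(0.03, 0), st$model)[, 1]
  f_before <- st$f[, st$outlet_idx]
  st <- lbm_apply_outlet(st)
  expect_equal(st$f[, st$outlet_idx], f_before, tolerance = 1e-13)
  expect_true(all(colSums(st$f[, st$outlet_idx]) > 0))
})

test_that("3D parabolic inflow has pipe-profile mean of about u_max/2", {
  us3 <- build_unit_system(flow_scenario(dimensionality = 3L), 16, 0.05)
  mk3 <- build_domain(vessel_spec(3e-3, 12.1875e-3, 3L), aneurysm_spec("none"),
                      resolution = 16)
  st <- lbm_init(mk3, us3)
  expect_equal(mean(st$inlet_u[1, ]) / us3$u_lattice_max, 0.5,
               tolerance = 0.06) # raster disc quadrature
})

test_that("fused kernel equals the composition of the R operations", {
  us10 <- build_unit_system(flow_scenario(), 10, 0.05)
  mk <- build_domain(vessel_spec(3e-3, 12.3e-3), aneurysm_spec("medium"),
                     resolution = 10)
  stR <- stK <- lbm_init(mk, us10)
  for (i in 1:20) stR <- lbm_step(stR)
  stK <- aneuflow:::lbm_run_kernel(stK, 20)
  expect_equal(stK$f, stR$f, tolerance = 1e-14)
})

test_that("steady-state iteration converges on a channel and honours the criterion", {
  mk <- channel_mask(res = 12L, length_m = 12.25e-3)
  us12 <- build_unit_system(flow_scenario(), 12, 0.05)
  st <- run_to_steady(lbm_init(mk, us12),
                      steady_state_criterion(1e-6, 200, 40000))
  expect_true(st$convergence$converged)
  expect_lt(st$convergence$residual, 1e-6)
  # restarting an already-steady state returns after one check interval
  st$convergence <- NULL
  st2 <- run_to_steady(st, steady_state_criterion(1e-6, 200, 40000))
  expect_identical(st2$convergence$steps - st$step, 200L)
  # velocity field is symmetric about the channel centreline
  sp <- velocity_magnitude(velocity_field(st2))
  mid_col <- sp[round(nrow(sp) / 2), which(mk$class[round(nrow(sp) / 2), ] != 0L)]
  expect_equal(mid_col, rev(mid_col), tolerance = 1e-10)
  # wall position: quadratic extrapolation of the three near-wall nodes to
  # half a cell beyond the last fluid node (exact for a parabola) gives
  # nearly zero velocity there
  wall_extrap <- 1.875 * mid_col[1] - 1.25 * mid_col[2] + 0.375 * mid_col[3]
  expect_lt(abs(wall_extrap) / max(mid_col), 0.01)
})

test_that("zero tolerance never converges and raises the max-steps flag", {
  st <- closed_box_state(bump = 1)
  expect_warning(
    st <- run_to_steady(st, steady_state_criterion(0, 50, 200)),
    "not converged")
  expect_false(st$convergence$converged)
  expect_identical(st$convergence$steps, 200L)
})

test_that("global mass is conserved in a closed domain over many steps", {
  st <- closed_box_state(bump = 1.05)
  act <- which(st$cls != 0L)
  m0 <- sum(st$f[, act])
  st <- aneuflow:::lbm_run_kernel(st, 2000)
  expect_lt(abs(sum(st$f[, act]) - m0) / m0, 1e-13)
})
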