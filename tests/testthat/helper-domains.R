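# Shared fixture builders. Everything is generated in code; no stored data.

blood <- fluid_properties() # 1060 kg/m^3, 0.004 Pa.s

channel_mask <- function(res = 16L, length_m = 12e-3) {
  build_domain(vessel_spec(3e-3, length_m), aneurysm_spec("none"),
               resolution = res)
}

# Closed rectangular box of fluid (all-solid border, no inlet/outlet),
# initialised at rest with an optional density bump.
closed_box_state <- function(dims = c(24L, 18L), bump = 1.05) {
  cls <- array(CLS <- 1L, dims)
  cls[1, ] <- 0L; cls[dims[1], ] <- 0L; cls[, 1] <- 0L; cls[, dims[2]] <- 0L
  mask <- structure(
    list(grid = list(origin = c(0, 0), dims = dims, dx = 1e-4),
         class = cls, phi = array(-1, dims),
         vessel = vessel_spec(3e-3, 12e-3), aneurysm = aneurysm_spec("none"),
         stent = NULL, resolution = 10L),
    class = "domain_mask")
  us <- build_unit_system(flow_scenario(), 10, 0.05)
  st <- lbm_init(mask, us)
  if (bump != 1) {
    n <- prod(dims)
    rho0 <- rep(1, n)
    rho0[round(n / 3)] <- bump
    act <- which(c(cls) != 0L)
    st$f[, act] <- lbm_equilibrium(rho0, matrix(0, 2, n), st$model)[, act]
  }
  st
}

# Analytic plane Poiseuille flow_field on a channel mask (m/s).
analytic_channel_field <- function(mask, u_max = 0.05) {
  g <- mask$grid
  yy <- g$origin[2] + (seq_len(g$dims[2]) - 0.5) * g$dx
  ux <- outer(rep(1, g$dims[1]), u_max * pmax(1 - (2 * yy / mask$vessel$D - 1)^2, 0))
  ux[mask$class == 0L] <- 0
  aneuflow:::flow_field(mask, array(c(ux, 0 * ux), c(g$dims, 2)),
                        solver = "analytic")
}

# A flow_field with velocity components given by functions of (x, y).
synthetic_field_2d <- function(mask, fx, fy) {
  g <- mask$grid
  p <- aneuflow:::grid_centers(g)
  ux <- array(fx(p[, 1], p[, 2]), g$dims)
  uy <- array(fy(p[, 1], p[, 2]), g$dims)
  aneuflow:::flow_field(mask, array(c(ux, uy), c(g$dims, 2)),
                        solver = "synthetic")
}
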