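#' Incompressible Navier-Stokes reference solver (2D)
#'
#' Solves the incompressible Navier-Stokes equations
#' rho (du/dt + u . grad u) = -grad p + mu lap u, div u = 0
#' (the divergence of the Newtonian stress tensor sigma = -p I +
#' mu (grad u + grad u^T) reduces to -grad p + mu lap u for constant mu and
#' solenoidal u) to steady state on the same cell-centred mask as the
#' lattice Boltzmann solver, using Chorin-style pressure projection on a
#' staggered (MAC) grid: explicit central advection and diffusion, then a
#' pressure Poisson solve enforcing a discretely divergence-free field. The
#' Poisson operator is assembled once per mask and factored with a sparse
#' Cholesky decomposition.
#'
#' Boundary handling mirrors the lattice solver's contracts: parabolic
#' velocity Dirichlet inflow, zero-gradient outflow (with pressure pinned to
#' zero in the outlet column), and no-slip on solid cells via ghost-face
#' reflection, which places the wall exactly on the cell faces bounding the
#' solid region.
#'
#' @param mask A 2D [build_domain()] mask.
#' @param scenario A [flow_scenario()].
#' @param dt Time step in seconds; `NULL` picks 0.5 x the explicit
#'   diffusive/advective stability bound.
#' @param criterion A [steady_state_criterion()] on the relative velocity
#'   change per check interval.
#' @param top_wall_u Tangential velocity (m/s) of the upper wall (planar
#'   Couette option). Default 0 (rigid walls).
#' @param inlet_profile `"parabolic"` (default, peak `scenario$u_max`) or a
#'   function of the wall-normal coordinate y (meters) returning the inflow
#'   velocity in m/s.
#' @param verbose Print residual history.
#' @return A `flow_field` (cell-centred velocity in m/s) with additional
#'   fields `staggered` (face velocities `U`, `V`), `p` (pressure, Pa, up to
#'   a constant), and `max_divergence` (largest post-projection divergence
#'   magnitude over the run, normalised by u_max / dx).
#' @export
solve_ns <- function(mask, scenario, dt = NULL,
                     criterion = steady_state_criterion(check_interval = 100L,
                                                        max_steps = 100000L),
                     top_wall_u = 0, inlet_profile = "parabolic",
                     verbose = FALSE) {
  stopifnot(inherits(mask, "domain_mask"), inherits(scenario, "flow_scenario"))
  if (mask$vessel$dimensionality != 2L) {
    stop("the Navier-Stokes reference solver supports 2D domains only",
         call. = FALSE)
  }
  g <- mask$grid
  nx <- g$dims[1]; ny <- g$dims[2]; dx <- g$dx
  C <- mask$class
  rho <- scenario$fluid$rho; mu <- scenario$fluid$mu; nu <- scenario$fluid$nu

  if (is.null(dt)) {
    dt_diff <- 0.25 * dx^2 / nu
    dt_adv <- dx / max(scenario$u_max, top_wall_u, 1e-12)
    dt <- 0.5 * min(dt_diff, dt_adv)
  } else {
    if (dt > 0.25 * dx^2 / nu) {
      warning(sprintf(
        "dt = %.3g s exceeds the explicit diffusive stability bound %.3g s",
        dt, 0.25 * dx^2 / nu), call. = FALSE)
    }
  }

  # padded cell classes: x-padding inherits inlet/outlet so the boundary
  # faces of those columns are classified as inflow / outflow
  Cp <- matrix(CLS_SOLID, nx + 2, ny + 2)
  Cp[2:(nx + 1), 2:(ny + 1)] <- C
  Cp[1, 2:(ny + 1)][C[1, ] == CLS_INLET] <- CLS_INLET
  Cp[nx + 2, 2:(ny + 1)][C[nx, ] == CLS_OUTLET] <- CLS_OUTLET

  # ---- face classification -------------------------------------------------
  # U faces (nx+1) x ny: left cell Cp[i, j+1], right cell Cp[i+1, j+1]
  UL <- Cp[1:(nx + 1), 2:(ny + 1)]
  UR <- Cp[2:(nx + 2), 2:(ny + 1)]
  isF <- function(m) m == CLS_FLUID
  activeU <- (isF(UL) & isF(UR)) | (isF(UL) & UR == CLS_OUTLET) |
    (UL == CLS_OUTLET & isF(UR))
  inletU <- (UL == CLS_INLET | UR == CLS_INLET) &
    UL != CLS_SOLID & UR != CLS_SOLID
  ghostU <- UL == CLS_SOLID & UR == CLS_SOLID
  outletU <- UL == CLS_OUTLET & UR == CLS_OUTLET
  # remaining faces (touching solid, mixed) are held at 0

  # V faces nx x (ny+1): down cell Cp[i+1, j], up cell Cp[i+1, j+1]
  VD <- Cp[2:(nx + 1), 1:(ny + 1)]
  VU <- Cp[2:(nx + 1), 2:(ny + 2)]
  activeV <- isF(VD) & isF(VU)
  ghostV <- VD == CLS_SOLID & VU == CLS_SOLID
  outletV <- VD == CLS_OUTLET & VU == CLS_OUTLET

  # inflow profile at U-face heights
  yy <- g$origin[2] + (seq_len(ny) - 0.5) * dx
  prof_fn <- if (is.function(inlet_profile)) {
    inlet_profile
  } else {
    function(y) scenario$u_max * pmax(1 - (2 * y / mask$vessel$D - 1)^2, 0)
  }
  profU <- matrix(prof_fn(yy), nx + 1, ny, byrow = TRUE)

  # moving-wall option: a ghost U face belongs to the top wall if the face
  # directly below it is wet
  wetU <- activeU | inletU | outletU
  below_wet <- cbind(FALSE, wetU[, 1:(ny - 1)])
  topGhostU <- ghostU & below_wet

  # ---- pressure Poisson operator over fluid cells -------------------------
  fluid_cells <- which(C == CLS_FLUID)
  np <- length(fluid_cells)
  pid <- array(0L, dim(C))
  pid[fluid_cells] <- seq_len(np)
  ci <- ((fluid_cells - 1L) %% nx) + 1L
  cj <- ((fluid_cells - 1L) %/% nx) + 1L
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diagv <- numeric(np)
  for (dir in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    niL <- ci + dir[1]; njL <- cj + dir[2]
    inb <- niL >= 1L & niL <= nx & njL >= 1L & njL <= ny
    ncls <- rep(CLS_SOLID, np)
    ncls[inb] <- C[cbind(niL[inb], njL[inb])]
    isfl <- ncls == CLS_FLUID
    diagv <- diagv + as.numeric(isfl | ncls == CLS_OUTLET)
    ii <- c(ii, which(isfl))
    jj <- c(jj, pid[cbind(niL[isfl], njL[isfl])])
    vv <- c(vv, rep(-1, sum(isfl)))
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(np), ii), j = c(seq_len(np), jj),
                            x = c(diagv, vv), dims = c(np, np))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)

  # pressure gradients for face correction: p index of left/right (down/up)
  # cell per active face; 0 id means p = 0 (outlet)
  au <- which(activeU)
  aui <- ((au - 1L) %% (nx + 1L)) + 1L
  auj <- ((au - 1L) %/% (nx + 1L)) + 1L
  pidx_L <- ifelse(aui - 1L >= 1L & aui - 1L <= nx, pid[cbind(pmax(aui - 1L, 1L), auj)], 0L)
  pidx_R <- ifelse(aui <= nx, pid[cbind(pmin(aui, nx), auj)], 0L)
  av <- which(activeV)
  avi <- ((av - 1L) %% nx) + 1L
  avj <- ((av - 1L) %/% nx) + 1L
  pidx_D <- pid[cbind(avi, pmax(avj - 1L, 1L))]
  pidx_U2 <- pid[cbind(avi, pmin(avj, ny))]

  # ---- time stepping -------------------------------------------------------
  U <- matrix(0, nx + 1, ny)
  V <- matrix(0, nx, ny + 1)
  U[inletU] <- profU[inletU]

  shift <- function(M, di, dj) {
    # value of M at (i - di, j - dj); out-of-range entries 0 (never used:
    # active faces sit >= 2 cells from the array edge thanks to the padding)
    n1 <- nrow(M); n2 <- ncol(M)
    out <- matrix(0, n1, n2)
    si <- max(1, 1 + di):min(n1, n1 + di)
    sj <- max(1, 1 + dj):min(n2, n2 + dj)
    out[si, sj] <- M[si - di, sj - dj]
    out
  }
  pvec0 <- c(0) # p lookup helper: index 0 -> 0

  step_fluid <- function(U, V) {
    # zero-gradient outflow
    U[outletU] <- shift(U, 1L, 0L)[outletU]
    V[outletV] <- shift(V, 1L, 0L)[outletV]

    # neighbour values with ghost reflection across walls
    UE <- shift(U, -1L, 0L); UW <- shift(U, 1L, 0L)
    UN <- shift(U, 0L, -1L); US <- shift(U, 0L, 1L)
    gN <- shift(ghostU, 0L, -1L) > 0 # neighbour above is a ghost face
    gS <- shift(ghostU, 0L, 1L) > 0
    gS_top <- shift(topGhostU, 0L, -1L) > 0 # moving top wall above
    UN[gN] <- -U[gN]
    UN[gS_top] <- 2 * top_wall_u - U[gS_top]
    US[gS] <- -U[gS]

    VE <- shift(V, -1L, 0L); VW <- shift(V, 1L, 0L)
    VN <- shift(V, 0L, -1L); VS <- shift(V, 0L, 1L)
    hE <- shift(ghostV, -1L, 0L) > 0
    hW <- shift(ghostV, 1L, 0L) > 0
    VE[hE] <- -V[hE]
    VW[hW] <- -V[hW]

    # advection velocities at the other component's faces;
    # V faces surrounding U(i,j): (i-1, j), (i, j), (i-1, j+1), (i, j+1)
    Vext <- rbind(V, 0) # (nx+1) x (ny+1): row i -> V(i, ), last row unused
    vbarU <- 0.25 * (shift(Vext, 1L, 0L)[, 1:ny] + Vext[, 1:ny] +
                       shift(Vext, 1L, -1L)[, 1:ny] + shift(Vext, 0L, -1L)[, 1:ny])
    Uext <- cbind(U, 0) # (nx+1) x (ny+1)
    ubarV <- 0.25 * (Uext[1:nx, ] + Uext[2:(nx + 1), ] +
                       shift(Uext, 0L, 1L)[1:nx, ] + shift(Uext, 0L, 1L)[2:(nx + 1), ])

    lapU <- (UE + UW + UN + US - 4 * U) / dx^2
    advU <- U * (UE - UW) / (2 * dx) + vbarU * (UN - US) / (2 * dx)
    Ustar <- U
    Ustar[activeU] <- U[activeU] + dt * (nu * lapU[activeU] - advU[activeU])

    lapV <- (VE + VW + VN + VS - 4 * V) / dx^2
    advV <- ubarV * (VE - VW) / (2 * dx) + V * (VN - VS) / (2 * dx)
    Vstar <- V
    Vstar[activeV] <- V[activeV] + dt * (nu * lapV[activeV] - advV[activeV])

    # projection
    div <- (Ustar[2:(nx + 1), ] - Ustar[1:nx, ] +
              Vstar[, 2:(ny + 1)] - Vstar[, 1:ny]) / dx
    b <- -(rho * dx^2 / dt) * div[fluid_cells]
    p <- as.numeric(Matrix::solve(ch, b))
    pL <- c(pvec0, p)[pidx_L + 1L]
    pR <- c(pvec0, p)[pidx_R + 1L]
    Ustar[au] <- Ustar[au] - (dt / rho) * (pR - pL) / dx
    pD <- c(pvec0, p)[pidx_D + 1L]
    pU <- c(pvec0, p)[pidx_U2 + 1L]
    Vstar[av] <- Vstar[av] - (dt / rho) * (pU - pD) / dx
    list(U = Ustar, V = Vstar, p = p)
  }

  u_prev <- c(U[activeU], V[activeV])
  converged <- FALSE
  residual <- Inf
  max_div <- 0
  steps <- 0L
  p <- numeric(np)
  hist_step <- integer(0); hist_res <- numeric(0)
  while (steps < criterion$max_steps) {
    nsub <- min(criterion$check_interval, criterion$max_steps - steps)
    for (s in seq_len(nsub)) {
      res <- step_fluid(U, V)
      U <- res$U; V <- res$V; p <- res$p
    }
    steps <- steps + nsub
    # post-projection divergence (normalised by u_max / dx)
    div <- (U[2:(nx + 1), ] - U[1:nx, ] + V[, 2:(ny + 1)] - V[, 1:ny]) / dx
    max_div <- max(max_div, max(abs(div[fluid_cells])) * dx /
                     max(scenario$u_max, 1e-12))
    u_now <- c(U[activeU], V[activeV])
    if (any(!is.finite(u_now))) {
      stop(sprintf("NS solver diverged at step %d (dt = %.3g s)", steps, dt),
           call. = FALSE)
    }
    residual <- max(abs(u_now - u_prev)) / max(max(abs(u_now)), .Machine$double.eps)
    hist_step <- c(hist_step, steps); hist_res <- c(hist_res, residual)
    if (verbose) message(sprintf("NS step %6d  residual %.3e", steps, residual))
    u_prev <- u_now
    if (criterion$tolerance > 0 && residual < criterion$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("NS not converged after %d steps (residual %.3e)",
                    steps, residual), call. = FALSE)
  }

  # cell-centred velocity
  uc <- 0.5 * (U[1:nx, ] + U[2:(nx + 1), ])
  vc <- 0.5 * (V[, 1:ny] + V[, 2:(ny + 1)])
  wet_cells <- C != CLS_SOLID
  uc[!wet_cells] <- 0
  vc[!wet_cells] <- 0
  fld <- flow_field(mask, array(c(uc, vc), c(nx, ny, 2)), solver = "ns",
                    convergence = list(converged = converged, steps = steps,
                                       residual = residual,
                                       history = data.frame(step = hist_step,
                                                            residual = hist_res)))
  fld$staggered <- list(U = U, V = V)
  pr <- array(NA_real_, dim(C))
  pr[fluid_cells] <- p
  fld$p <- pr
  fld$max_divergence <- max_div
  fld
}

#' Discrete velocity divergence
#'
#' For a field produced by [solve_ns()] the divergence is evaluated on the
#' staggered faces with the same stencil the projection enforces, so it
#' reports the solver's actual incompressibility defect. For any other
#' `flow_field` (cell-centred data), second-order central differences are
#' used in the interior.
#'
#' @param field A `flow_field`.
#' @return Array (grid dims) of div u in 1/s (`NA` on solid nodes for the
#'   staggered path outside the fluid).
#' @export
ns_divergence <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  dims <- field$grid$dims
  dx <- field$grid$dx
  if (!is.null(field$staggered)) {
    nx <- dims[1]; ny <- dims[2]
    U <- field$staggered$U; V <- field$staggered$V
    div <- (U[2:(nx + 1), ] - U[1:nx, ] + V[, 2:(ny + 1)] - V[, 1:ny]) / dx
    div[field$mask$class == CLS_SOLID] <- NA_real_
    return(div)
  }
  if (length(dims) != 2L) stop("divergence implemented for 2D fields", call. = FALSE)
  ux <- field$u[, , 1]; uy <- field$u[, , 2]
  ddx <- function(M) (rbind(M[-1, ], M[nrow(M), ]) - rbind(M[1, ], M[-nrow(M), ])) /
    (2 * dx) * rep(1, 1)
  ddy <- function(M) (cbind(M[, -1], M[, ncol(M)]) - cbind(M[, 1], M[, -ncol(M)])) /
    (2 * dx)
  # one-sided at the array edges (spacing dx there)
  dudx <- ddx(ux); dudx[1, ] <- (ux[2, ] - ux[1, ]) / dx
  dudx[dims[1], ] <- (ux[dims[1], ] - ux[dims[1] - 1, ]) / dx
  dvdy <- ddy(uy); dvdy[, 1] <- (uy[, 2] - uy[, 1]) / dx
  dvdy[, dims[2]] <- (uy[, dims[2]] - uy[, dims[2] - 1]) / dx
  dudx + dvdy
}
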