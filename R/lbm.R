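#' Steady-state stopping rule
#'
#' Iteration stops when the maximum nodal velocity change over one check
#' interval, relative to the current maximum speed, falls below `tolerance`,
#' or when `max_steps` is reached (in which case the result is flagged
#' non-converged).
#'
#' @param tolerance Relative velocity change per check interval. A tolerance
#'   of 0 never converges and always exhausts `max_steps`.
#' @param check_interval Steps between convergence checks.
#' @param max_steps Hard iteration cap (>= check_interval).
#' @return An object of class `steady_state_criterion`.
#' @export
steady_state_criterion <- function(tolerance = 1e-6, check_interval = 200L,
                                   max_steps = 200000L) {
  if (tolerance < 0) stop("`tolerance` must be >= 0", call. = FALSE)
  check_interval <- as.integer(check_interval)
  max_steps <- as.integer(max_steps)
  if (check_interval < 1L || max_steps < check_interval) {
    stop("`max_steps` must be >= `check_interval` >= 1", call. = FALSE)
  }
  structure(list(tolerance = tolerance, check_interval = check_interval,
                 max_steps = max_steps),
            class = "steady_state_criterion")
}

#' Equilibrium particle distribution functions
#'
#' The low-Mach (second-order in velocity) Maxwell-Boltzmann expansion
#' f_i^eq = w_i rho (1 + 3 e_i.u + (9/2)(e_i.u)^2 - (3/2) u.u), in lattice
#' units. By construction sum_i f_i^eq = rho and sum_i f_i^eq e_i = rho u.
#'
#' @param rho Density vector (length n, > 0).
#' @param u Lattice velocity, d x n matrix (columns = nodes), |u| below the
#'   lattice sound speed 1/sqrt(3).
#' @param model A [lattice_model()].
#' @return q x n matrix of equilibrium PDFs.
#' @export
lbm_equilibrium <- function(rho, u, model) {
  stopifnot(inherits(model, "lattice_model"))
  if (is.null(dim(u))) u <- matrix(u, nrow = model$d)
  n <- length(rho)
  stopifnot(ncol(u) == n, nrow(u) == model$d)
  if (any(rho <= 0)) stop("`rho` must be positive", call. = FALSE)
  speed2 <- colSums(u^2)
  if (any(speed2 >= 1 / 3)) {
    stop("velocity at or above the lattice sound speed 1/sqrt(3): low-Mach ",
         "assumption violated", call. = FALSE)
  }
  eu <- model$e %*% u                                   # q x n
  m <- 1 + 3 * eu + 4.5 * eu^2 - matrix(1.5 * speed2, model$q, n, byrow = TRUE)
  m * (model$w %o% rho)
}

#' Hydrodynamic moments of a PDF set
#'
#' Density rho = sum_i f_i and velocity u = (1/rho) sum_i f_i e_i.
#'
#' @param f q x n matrix of PDFs (finite).
#' @param model A [lattice_model()].
#' @return List with `rho` (length n) and `u` (d x n, lattice units).
#' @export
lbm_moments <- function(f, model) {
  stopifnot(inherits(model, "lattice_model"))
  if (is.null(dim(f))) f <- matrix(f, nrow = model$q)
  if (any(!is.finite(f))) stop("`f` must be finite", call. = FALSE)
  rho <- colSums(f)
  if (any(rho <= 0)) {
    stop("degenerate node: non-positive density from the given PDFs",
         call. = FALSE)
  }
  u <- (t(model$e) %*% f) / rep(rho, each = model$d)
  list(rho = rho, u = u)
}

#' Initialize the lattice Boltzmann state
#'
#' All non-solid nodes start at rest equilibrium with unit lattice density;
#' the flow is then driven by the inlet condition.
#'
#' @param mask A [build_domain()] mask.
#' @param units A [build_unit_system()] unit system.
#' @return An object of class `lbm_state` holding the PDF matrix `f`
#'   (q x n), the lattice model, mask, unit system, step counter, and
#'   precomputed boundary index tables.
#' @export
lbm_init <- function(mask, units) {
  stopifnot(inherits(mask, "domain_mask"), inherits(units, "unit_system"))
  model <- lattice_model(if (mask$vessel$dimensionality == 2L) "D2Q9" else "D3Q19")
  dims <- mask$grid$dims
  n <- prod(dims)
  cls <- c(mask$class)
  f <- matrix(0, model$q, n)
  act <- cls != CLS_SOLID
  f[, act] <- model$w # rest equilibrium at rho = 1

  strides <- cumprod(c(1L, dims[-length(dims)]))
  inlet_idx <- which(cls == CLS_INLET)
  outlet_idx <- which(cls == CLS_OUTLET)
  inlet_src <- inlet_idx + strides[1]
  outlet_src <- outlet_idx - strides[1]
  # prescribed lattice inlet velocity: parabolic along the vessel section
  inlet_u <- matrix(0, model$d, length(inlet_idx))
  if (length(inlet_idx) > 0L) {
    p <- grid_centers(mask$grid)[inlet_idx, , drop = FALSE]
    inlet_u[1, ] <- units$u_lattice_max * inflow_shape(p, mask$vessel)
  }
  structure(
    list(f = f, model = model, mask = mask, units = units, step = 0L,
         cls = cls, dims = dims, strides = strides,
         inlet_idx = inlet_idx, inlet_src = inlet_src, inlet_u = inlet_u,
         outlet_idx = outlet_idx, outlet_src = outlet_src),
    class = "lbm_state"
  )
}

# Dimensionless parabolic inflow shape (1 at the centreline, 0 at the wall),
# evaluated at physical points p. 2D: 1 - (2y/D - 1)^2; 3D: 1 - (r/R)^2.
inflow_shape <- function(p, vessel) {
  if (vessel$dimensionality == 2L) {
    s <- 1 - (2 * p[, 2] / vessel$D - 1)^2
  } else {
    R <- vessel$D / 2
    s <- 1 - (p[, 2]^2 + p[, 3]^2) / R^2
  }
  pmax(s, 0)
}

#' BGK collision
#'
#' Relaxes the PDFs of every non-solid node toward the local equilibrium:
#' f_i <- f_i - (f_i - f_i^eq) / tau. Collision conserves nodal mass and
#' momentum exactly; with tau = 1 the post-collision state is the local
#' equilibrium itself.
#'
#' @param state An `lbm_state`.
#' @return The updated state.
#' @export
lbm_collide <- function(state) {
  stopifnot(inherits(state, "lbm_state"))
  act <- which(state$cls != CLS_SOLID)
  f <- state$f[, act, drop = FALSE]
  if (any(!is.finite(f))) {
    stop(sprintf("NaN/Inf in PDFs (instability): tau = %.4f", state$units$tau),
         call. = FALSE)
  }
  mom <- lbm_moments(f, state$model)
  feq <- lbm_equilibrium(mom$rho, mom$u, state$model)
  # fold the equilibrium's rounding defect into the rest direction so that
  # collision conserves nodal mass exactly, not just to round-off
  feq[1, ] <- feq[1, ] + (mom$rho - colSums(feq))
  state$f[, act] <- f - (f - feq) / state$units$tau
  state
}

#' Streaming with half-way bounce-back
#'
#' `lbm_stream()` advects each PDF one cell along its direction between
#' non-solid nodes; a PDF whose target node is solid (or outside the grid)
#' is instead reflected into the opposite direction at its originating node,
#' which places the effective no-slip wall half a cell beyond the last fluid
#' node. `lbm_bounce_back()` applies only that reflection component.
#' Streaming is a permutation of PDF values, so it conserves mass exactly.
#'
#' @param state An `lbm_state`.
#' @return The updated state.
#' @export
lbm_stream <- function(state) {
  stopifnot(inherits(state, "lbm_state"))
  mv <- stream_moves(state)
  fnew <- state$f
  fnew[, mv$act] <- 0
  for (i in seq_len(state$model$q)) {
    ok <- mv$open[, i]
    src <- mv$act
    fnew[cbind(i, mv$target[ok, i])] <- state$f[cbind(i, src[ok])]
    if (any(!ok)) {
      fnew[cbind(state$model$opp[i], src[!ok])] <- state$f[cbind(i, src[!ok])]
    }
  }
  state$f <- fnew
  state
}

#' @rdname lbm_stream
#' @export
lbm_bounce_back <- function(state) {
  stopifnot(inherits(state, "lbm_state"))
  mv <- stream_moves(state)
  fnew <- state$f
  for (i in seq_len(state$model$q)) {
    blocked <- mv$act[!mv$open[, i]]
    if (length(blocked) > 0L) {
      fnew[cbind(state$model$opp[i], blocked)] <- state$f[cbind(i, blocked)]
    }
  }
  state$f <- fnew
  state
}

# Per-direction stream targets for all active nodes: target linear index and
# whether the link is open (in bounds and not solid).
stream_moves <- function(state) {
  act <- which(state$cls != CLS_SOLID)
  d <- state$model$d
  q <- state$model$q
  coord <- arrayInd(act, state$dims)
  target <- matrix(0L, length(act), q)
  open <- matrix(FALSE, length(act), q)
  for (i in seq_len(q)) {
    tgt <- act
    inb <- rep(TRUE, length(act))
    for (k in seq_len(d)) {
      ck <- coord[, k] + state$model$e[i, k]
      inb <- inb & ck >= 1L & ck <= state$dims[k]
      tgt <- tgt + state$model$e[i, k] * state$strides[k]
    }
    ok <- inb
    ok[inb] <- state$cls[tgt[inb]] != CLS_SOLID
    target[, i] <- tgt
    open[, i] <- ok
  }
  list(act = act, target = target, open = open)
}

#' Inlet and outlet boundary conditions
#'
#' `lbm_apply_inlet()` imposes a velocity Dirichlet condition: each inlet
#' node is set to the equilibrium PDFs of the prescribed parabolic profile
#' velocity, with the density extrapolated from the nearest interior fluid
#' node. `lbm_apply_outlet()` imposes a zero-gradient (Neumann) outflow on
#' the velocity by copying the PDFs of the adjacent upstream node with the
#' density re-centred on the reference value 1 (the non-equilibrium part is
#' copied unchanged, the equilibrium part rebuilt at unit density), which
#' pins the pressure level of the open system; for a node already at unit
#' density the operation is an exact copy.
#'
#' @param state An `lbm_state`.
#' @return The updated state.
#' @export
lbm_apply_inlet <- function(state) {
  stopifnot(inherits(state, "lbm_state"))
  if (length(state$inlet_idx) == 0L) stop("no inlet nodes", call. = FALSE)
  rho <- colSums(state$f[, state$inlet_src, drop = FALSE])
  state$f[, state$inlet_idx] <- lbm_equilibrium(rho, state$inlet_u, state$model)
  state
}

#' @rdname lbm_apply_inlet
#' @export
lbm_apply_outlet <- function(state) {
  stopifnot(inherits(state, "lbm_state"))
  if (length(state$outlet_idx) == 0L) stop("no outlet nodes", call. = FALSE)
  fs <- state$f[, state$outlet_src, drop = FALSE]
  mom <- lbm_moments(fs, state$model)
  state$f[, state$outlet_idx] <- fs -
    lbm_equilibrium(mom$rho, mom$u, state$model) +
    lbm_equilibrium(rep(1, length(state$outlet_idx)), mom$u, state$model)
  state
}

#' One full lattice Boltzmann update (pure R path)
#'
#' collide -> stream (with bounce-back) -> inlet -> outlet. This is the
#' reference composition of the exported operations; [run_to_steady()] uses
#' a fused compiled kernel that a test verifies against this path.
#'
#' @param state An `lbm_state`.
#' @param boundary Apply inlet/outlet conditions (disable for closed boxes).
#' @return The updated state.
#' @export
lbm_step <- function(state, boundary = TRUE) {
  state <- lbm_collide(state)
  state <- lbm_stream(state)
  if (boundary && length(state$inlet_idx) > 0L) state <- lbm_apply_inlet(state)
  if (boundary && length(state$outlet_idx) > 0L) state <- lbm_apply_outlet(state)
  state$step <- state$step + 1L
  state
}

# Run nsteps through the compiled kernel.
lbm_run_kernel <- function(state, nsteps) {
  state$f <- lbm_run_chunk(
    state$f, state$cls, as.integer(state$dims), state$model$e, state$model$w,
    as.integer(state$model$opp - 1L), state$units$tau,
    as.integer(state$inlet_idx - 1L), state$inlet_u,
    as.integer(state$inlet_src - 1L), as.integer(state$outlet_idx - 1L),
    as.integer(state$outlet_src - 1L), as.integer(nsteps))
  state$step <- state$step + as.integer(nsteps)
  state
}

#' Iterate to the stationary flow
#'
#' Repeats the lattice Boltzmann update until the maximum nodal velocity
#' change over one check interval drops below the criterion tolerance
#' (relative to the current maximum speed), or `max_steps` is exhausted.
#' Deterministic for fixed inputs. Divergence (speeds at the lattice sound
#' speed, or non-finite PDFs) raises a stability error with diagnostics.
#'
#' @param state An `lbm_state` (freshly built by [lbm_init()]).
#' @param criterion A [steady_state_criterion()].
#' @param use_kernel Use the fused compiled stepping kernel (default) or the
#'   pure-R operation path.
#' @param verbose Print residual history.
#' @return The final state with a `convergence` field: list with `converged`,
#'   `steps`, `residual`, `history` (data.frame of step/residual).
#' @export
run_to_steady <- function(state, criterion = steady_state_criterion(),
                          use_kernel = TRUE, verbose = FALSE) {
  stopifnot(inherits(state, "lbm_state"),
            inherits(criterion, "steady_state_criterion"))
  u_prev <- lbm_velocity(state)
  hist_step <- integer(0)
  hist_res <- numeric(0)
  converged <- FALSE
  residual <- Inf
  done <- 0L
  while (done < criterion$max_steps) {
    nsub <- min(criterion$check_interval, criterion$max_steps - done)
    if (use_kernel) {
      state <- lbm_run_kernel(state, nsub)
    } else {
      for (s in seq_len(nsub)) state <- lbm_step(state)
    }
    done <- done + nsub
    u <- lbm_velocity(state)
    if (any(!is.finite(u))) {
      stop(sprintf("LBM diverged (non-finite velocity) at step %d; tau = %.4f",
                   state$step, state$units$tau), call. = FALSE)
    }
    umax <- max(abs(u))
    if (umax >= 1 / sqrt(3)) {
      stop(sprintf(
        "LBM unstable: max |u| = %.3f reached the lattice sound speed (tau = %.4f)",
        umax, state$units$tau), call. = FALSE)
    }
    residual <- max(abs(u - u_prev)) / max(umax, .Machine$double.eps)
    hist_step <- c(hist_step, state$step)
    hist_res <- c(hist_res, residual)
    if (verbose) {
      message(sprintf("step %7d  residual %.3e  max|u| %.4f", state$step,
                      residual, umax))
    }
    u_prev <- u
    if (criterion$tolerance > 0 && residual < criterion$tolerance) {
      converged <- TRUE
      break
    }
  }
  state$convergence <- list(
    converged = converged, steps = state$step, residual = residual,
    history = data.frame(step = hist_step, residual = hist_res)
  )
  if (!converged) {
    warning(sprintf("not converged after %d steps (residual %.3e)",
                    state$step, residual), call. = FALSE)
  }
  state
}

# Lattice velocity matrix (d x n, zeros at solid nodes).
lbm_velocity <- function(state) {
  lbm_moments_cpp(state$f, state$model$e, state$cls)$u
}

# Lattice density vector (zeros at solid nodes).
lbm_density <- function(state) {
  lbm_moments_cpp(state$f, state$model$e, state$cls)$rho
}

#' Extract the physical velocity field
#'
#' Converts the lattice velocity of every node to m/s and packages it with
#' the grid and mask as a `flow_field`, the common container consumed by the
#' analysis functions and produced by both solvers.
#'
#' @param state An `lbm_state` (typically after [run_to_steady()]).
#' @return An object of class `flow_field`: list with `grid`, `u` (array of
#'   dims x d, m/s), `mask`, `solver`, `convergence`.
#' @export
velocity_field <- function(state) {
  stopifnot(inherits(state, "lbm_state"))
  u_lat <- lbm_velocity(state)
  u <- to_physical(u_lat, state$units)
  flow_field(state$mask, aperm(array(u, c(state$model$d, state$dims)),
                               c(seq_len(state$model$d) + 1L, 1L)),
             solver = "lbm", convergence = state$convergence)
}

# Construct the common flow-field container. u is an array dims x d (m/s).
flow_field <- function(mask, u, solver, convergence = NULL) {
  structure(list(grid = mask$grid, u = u, mask = mask, solver = solver,
                 convergence = convergence),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  sp <- velocity_magnitude(x)
  cat(sprintf("<flow_field %s, %s grid, max |u| = %.2f mm/s>\n", x$solver,
              paste(x$grid$dims, collapse = " x "), 1000 * max(sp)))
  invisible(x)
}

#' Velocity magnitude array of a flow field
#'
#' @param field A `flow_field`.
#' @return Array (grid dims) of |u| in m/s.
#' @export
velocity_magnitude <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  d <- length(field$grid$dims)
  m <- 0
  for (k in seq_len(d)) {
    uk <- slice_component(field$u, k, d)
    m <- m + uk^2
  }
  sqrt(m)
}

# k-th velocity component as an array of grid dims.
slice_component <- function(u, k, d) {
  idx <- c(rep(list(quote(expr = )), d), list(k))
  do.call(`[`, c(list(u), idx))
}
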