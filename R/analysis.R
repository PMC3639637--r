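#' Sample velocity magnitude along a cutline
#'
#' Interpolates |u| bilinearly (trilinearly in 3D) from the cell-centred
#' field at evenly spaced points along the cutline. Solid nodes contribute 0
#' to the interpolation, and sample points outside the grid report 0, so a
#' cutline crossing a wall or stent strut shows the no-flow region directly.
#'
#' @param field A `flow_field`.
#' @param line A `cutline_spec` (see [make_cutlines()]).
#' @return An object of class `cutline_profile`: data.frame-like list with
#'   `name`, `position` (m, arc length from the start point), `points`
#'   (n x d matrix), `velocity` (velocity magnitude, m/s), `solver`.
#' @export
sample_cutline <- function(field, line) {
  stopifnot(inherits(field, "flow_field"), inherits(line, "cutline_spec"))
  g <- field$grid
  d <- length(g$dims)
  t <- seq(0, 1, length.out = line$n_samples)
  pts <- outer(t, line$end - line$start) +
    matrix(line$start, line$n_samples, d, byrow = TRUE)
  lo <- g$origin
  hi <- g$origin + g$dims * g$dx
  if (all(apply(pts, 1, function(p) any(p < lo | p > hi)))) {
    stop("cutline lies entirely outside the domain bounding box", call. = FALSE)
  }
  speed <- velocity_magnitude(field)
  speed[field$mask$class == CLS_SOLID] <- 0
  vals <- interp_field(speed, g, pts)
  structure(
    list(name = line$name, position = t * line$length, points = pts,
         velocity = vals, solver = field$solver, n_samples = line$n_samples),
    class = "cutline_profile"
  )
}

# Multilinear interpolation of a scalar array at physical points; points
# outside the grid (or beyond the last cell centre) are clamped cell-wise,
# with fully-outside points returning 0 via the solid-zero convention of the
# caller. Cell-centred data: centre of cell k at origin + (k - 0.5) dx.
interp_field <- function(arr, grid, pts) {
  d <- length(grid$dims)
  s <- sweep(pts, 2, grid$origin) / grid$dx + 0.5 # fractional node coordinate
  i0 <- pmin(pmax(floor(s), 1), matrix(grid$dims, nrow(pts), d, byrow = TRUE) - 1)
  fr <- pmin(pmax(s - i0, 0), 1)
  out <- numeric(nrow(pts))
  for (corner in 0:(2^d - 1)) {
    bits <- (corner %/% 2^(seq_len(d) - 1)) %% 2
    idx <- i0 + matrix(bits, nrow(pts), d, byrow = TRUE)
    w <- rep(1, nrow(pts))
    for (k in seq_len(d)) {
      w <- w * ifelse(bits[k] == 1, fr[, k], 1 - fr[, k])
    }
    out <- out + w * arr[idx]
  }
  out
}

#' @export
print.cutline_profile <- function(x, ...) {
  cat(sprintf("<cutline_profile '%s' (%s): %d samples, peak %.2f mm/s>\n",
              x$name, x$solver, x$n_samples, 1000 * max(x$velocity)))
  invisible(x)
}

#' @export
as.data.frame.cutline_profile <- function(x, ...) {
  data.frame(cutline = x$name, position_mm = 1000 * x$position,
             velocity_mm_s = 1000 * x$velocity, solver = x$solver)
}

#' Plot cutline profiles
#'
#' @param x A `cutline_profile`.
#' @param ... Further `cutline_profile`s to overlay (e.g. the other solver).
#' @export
plot.cutline_profile <- function(x, ...) {
  extra <- Filter(function(e) inherits(e, "cutline_profile"), list(...))
  all_p <- c(list(x), extra)
  ymax <- max(vapply(all_p, function(p) max(p$velocity), numeric(1)))
  graphics::plot(1000 * x$position, 1000 * x$velocity, type = "l",
                 xlab = "position along cutline [mm]",
                 ylab = "velocity magnitude [mm/s]",
                 main = sprintf("cutline '%s'", x$name),
                 ylim = c(0, 1.05 * 1000 * ymax))
  for (k in seq_along(extra)) {
    graphics::lines(1000 * extra[[k]]$position, 1000 * extra[[k]]$velocity,
                    lty = k + 1, col = k + 1)
  }
  if (length(extra) > 0) {
    graphics::legend("topright", legend = vapply(all_p, `[[`, "", "solver"),
                     lty = seq_along(all_p), col = seq_along(all_p), bty = "n")
  }
  invisible(x)
}

#' Mean velocity magnitude inside the aneurysm sac
#'
#' Unweighted arithmetic mean of |u| over the fluid nodes of the sac (the
#' region outside the unperturbed lumen), in mm/s. This is the stagnation
#' measure that drops when a stent is placed across the neck.
#'
#' @param field A `flow_field` on an aneurysm-bearing domain.
#' @param sac Optional integer node set (defaults to [sac_region()] of the
#'   field's mask).
#' @return Mean sac velocity magnitude in mm/s.
#' @export
sac_mean_velocity <- function(field, sac = NULL) {
  stopifnot(inherits(field, "flow_field"))
  if (is.null(sac)) sac <- sac_region(field$mask)
  if (length(sac) == 0L) stop("empty sac node set", call. = FALSE)
  speed <- velocity_magnitude(field)
  1000 * mean(speed[sac])
}

#' Peak velocity magnitude at the aneurysm neck
#'
#' Maximum of the mid-cutline velocity profile restricted to the neck
#' opening segment: the sample points within one neck half-width of the neck
#' centre that lie on the sac side of the wall line (outside the unperturbed
#' lumen), i.e. the aperture through which the vessel feeds the sac. This
#' excludes the intravascular portion of the 45-degree cutline, whose
#' velocities belong to the parent-vessel jet rather than to the neck.
#' Reported in mm/s.
#'
#' @param field A `flow_field`.
#' @param mid The `mid` `cutline_spec` (from [make_cutlines()]).
#' @return Peak neck velocity in mm/s.
#' @export
neck_peak_velocity <- function(field, mid) {
  stopifnot(inherits(field, "flow_field"), inherits(mid, "cutline_spec"))
  prof <- sample_cutline(field, mid)
  nk <- neck_geometry(field$mask)
  dist <- sqrt(rowSums(sweep(prof$points, 2, nk$center)^2))
  sac_side <- if (field$mask$vessel$dimensionality == 2L) {
    prof$points[, 2] >= field$mask$vessel$D - 1e-12
  } else {
    prof$points[, 2]^2 + prof$points[, 3]^2 >=
      (field$mask$vessel$D / 2)^2 * (1 - 1e-12)
  }
  seg <- dist <= nk$halfwidth & sac_side
  if (!any(seg)) stop("no cutline samples fall on the neck segment", call. = FALSE)
  1000 * max(prof$velocity[seg])
}

#' Velocity-magnitude drop in the vessel at the neck
#'
#' The open neck lets the parent-vessel profile widen into the aperture, so
#' the peak velocity of the vessel cross-section at the neck's axial
#' position sags below its upstream value. This function returns that drop:
#' max |u| over the lumen section at the pre-cutline position minus max |u|
#' over the lumen section at the neck centre position, in mm/s. The drop
#' grows with aneurysm stage.
#'
#' @param field A `flow_field` on a 2D aneurysm-bearing domain.
#' @param offset_m Axial distance of the upstream reference section from the
#'   neck centre (default 1.25 vessel widths, the pre-cutline position).
#' @return Velocity drop in mm/s.
#' @export
neck_velocity_drop <- function(field, offset_m = NULL) {
  stopifnot(inherits(field, "flow_field"))
  mask <- field$mask
  if (mask$vessel$dimensionality != 2L) {
    stop("`neck_velocity_drop` is defined for 2D domains", call. = FALSE)
  }
  if (mask$aneurysm$stage == "none") {
    stop("no aneurysm in this domain", call. = FALSE)
  }
  if (is.null(offset_m)) offset_m <- 1.25 * mask$vessel$D
  g <- field$grid
  sp <- velocity_magnitude(field)
  xc <- mask$vessel$L * mask$aneurysm$neck_center_frac
  yy <- g$origin[2] + (seq_len(g$dims[2]) - 0.5) * g$dx
  lumen_rows <- which(yy > 0 & yy < mask$vessel$D)
  col_at <- function(x) as.integer(round((x - g$origin[1]) / g$dx + 0.5))
  1000 * (max(sp[col_at(xc - offset_m), lumen_rows]) -
            max(sp[col_at(xc), lumen_rows]))
}

#' Vorticity of a 2D velocity field
#'
#' omega = dv/dx - du/dy via second-order central differences (one-sided at
#' the array edges), in 1/s.
#'
#' @param field A 2D `flow_field`.
#' @return Array (nx x ny) of vorticity.
#' @export
vorticity_2d <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  dims <- field$grid$dims
  if (length(dims) != 2L) stop("`vorticity_2d` requires a 2D field", call. = FALSE)
  dx <- field$grid$dx
  ux <- field$u[, , 1]; uy <- field$u[, , 2]
  nx <- dims[1]; ny <- dims[2]
  dvdx <- (uy[c(2:nx, nx), ] - uy[c(1, 1:(nx - 1)), ]) /
    (dx * c(1, rep(2, nx - 2), 1))
  dudy <- (ux[, c(2:ny, ny)] - ux[, c(1, 1:(ny - 1))]) %*%
    diag(1 / (dx * c(1, rep(2, ny - 2), 1)))
  dvdx - dudy
}

#' Compare two cutline profiles
#'
#' Relative L2 difference ||a - b||_2 / ||a||_2 and maximum pointwise
#' absolute difference between two profiles of the same cutline, the metric
#' used to quantify agreement between the lattice Boltzmann and
#' Navier-Stokes solutions.
#'
#' @param a,b `cutline_profile`s with matching name and sample count. `a` is
#'   the reference for the relative norm and must not be identically zero.
#' @return List with `rel_l2`, `max_abs` (m/s), `name`.
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "cutline_profile"), inherits(b, "cutline_profile"))
  if (a$name != b$name) {
    stop(sprintf("mismatched cutlines: '%s' vs '%s'", a$name, b$name),
         call. = FALSE)
  }
  if (a$n_samples != b$n_samples) {
    stop("profiles have different sample counts", call. = FALSE)
  }
  na <- sqrt(sum(a$velocity^2))
  if (na == 0) {
    stop("reference profile is identically zero; relative norm undefined",
         call. = FALSE)
  }
  list(name = a$name,
       rel_l2 = sqrt(sum((a$velocity - b$velocity)^2)) / na,
       max_abs = max(abs(a$velocity - b$velocity)))
}

#' Flow summary of a run
#'
#' The scalar observables of a steady run: sac mean and neck peak velocity
#' (mm/s), the largest vorticity magnitude inside the sac (1/s), and the
#' stented flag.
#'
#' @param field A `flow_field` on an aneurysm-bearing 2D domain.
#' @param cutlines Cutlines from [make_cutlines()] (built from the mask's
#'   specs when omitted).
#' @return An object of class `flow_summary`.
#' @export
flow_summary <- function(field, cutlines = NULL) {
  stopifnot(inherits(field, "flow_field"))
  mask <- field$mask
  if (mask$aneurysm$stage == "none") {
    stop("flow_summary requires an aneurysm-bearing domain", call. = FALSE)
  }
  if (is.null(cutlines)) cutlines <- make_cutlines(mask$aneurysm, mask$vessel)
  sac <- sac_region(mask)
  sac_mean <- sac_mean_velocity(field, sac)
  neck_peak <- neck_peak_velocity(field, cutlines$mid)
  max_vort <- if (mask$vessel$dimensionality == 2L) {
    max(abs(vorticity_2d(field)[sac]))
  } else {
    NA_real_
  }
  structure(
    list(sac_mean_mm_s = sac_mean, neck_peak_mm_s = neck_peak,
         max_vorticity_sac_s = max_vort, stented = !is.null(mask$stent),
         solver = field$solver,
         converged = isTRUE(field$convergence$converged),
         steps = field$convergence$steps),
    class = "flow_summary"
  )
}

#' @export
print.flow_summary <- function(x, ...) {
  cat(sprintf("<flow_summary (%s%s)>\n", x$solver,
              if (x$stented) ", stented" else ""))
  cat(sprintf("  sac mean velocity : %6.3f mm/s\n", x$sac_mean_mm_s))
  cat(sprintf("  neck peak velocity: %6.2f mm/s\n", x$neck_peak_mm_s))
  cat(sprintf("  max sac vorticity : %6.2f 1/s\n", x$max_vorticity_sac_s))
  cat(sprintf("  converged after %d steps\n", x$steps))
  invisible(x)
}
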