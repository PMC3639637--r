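# Node classification codes used throughout the solvers.
CLS_SOLID <- 0L
CLS_FLUID <- 1L
CLS_INLET <- 2L
CLS_OUTLET <- 3L

#' Vessel specification
#'
#' A straight vessel segment: a planar channel in 2D or a circular tube in
#' 3D, of width (diameter) D, aligned with the x axis. The length must be at
#' least 4 D so that the pre and post cutlines clear the aneurysm region.
#'
#' @param width_m Vessel width / diameter D in meters. Default 3e-3.
#' @param length_m Vessel length in meters (>= 4 * width). Default 15e-3.
#' @param dimensionality 2 or 3.
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(width_m = 3e-3, length_m = 15e-3, dimensionality = 2L) {
  if (width_m <= 0) stop("`width_m` must be positive", call. = FALSE)
  if (length_m < 4 * width_m) {
    stop("`length_m` must be at least 4 * width_m (room for pre/post cutlines)",
         call. = FALSE)
  }
  dimensionality <- as.integer(dimensionality)
  if (!dimensionality %in% c(2L, 3L)) {
    stop("`dimensionality` must be 2 or 3", call. = FALSE)
  }
  structure(list(D = width_m, L = length_m, dimensionality = dimensionality),
            class = "vessel_spec")
}

#' Aneurysm sac specification
#'
#' The sac is a circular (2D) or spherical (3D) bulge seated on the vessel
#' wall, communicating with the lumen through a neck of prescribed width: the
#' sac centre is placed at distance sqrt(r^2 - (neck/2)^2) beyond the wall so
#' that the chord cut by the wall line equals the neck width. Two growth
#' stages are provided; both share the neck, and the larger sac strictly
#' contains the medium one outside the lumen.
#'
#' @param stage `"none"`, `"medium"` or `"larger"`.
#' @param sac_radius_m Sac radius in meters; defaults to 2.25e-3 (medium) or
#'   3.0e-3 (larger).
#' @param neck_width_m Width of the neck opening in meters. Default 2e-3.
#' @param neck_center_frac Position of the neck centre along the vessel, as a
#'   fraction of vessel length. Default 0.5.
#' @param neck_angle_deg Angle of the mid cutline through the neck relative
#'   to the vessel axis. Default 45.
#' @return An object of class `aneurysm_spec`.
#' @export
aneurysm_spec <- function(stage = c("none", "medium", "larger"),
                          sac_radius_m = NULL, neck_width_m = 2e-3,
                          neck_center_frac = 0.5, neck_angle_deg = 45) {
  stage <- match.arg(stage)
  if (is.null(sac_radius_m)) {
    sac_radius_m <- switch(stage, none = 0, medium = 2.25e-3, larger = 3.0e-3)
  }
  if (stage != "none") {
    if (neck_width_m >= 2 * sac_radius_m) {
      stop("`neck_width_m` must be smaller than the sac diameter", call. = FALSE)
    }
    if (neck_width_m <= 0 || sac_radius_m <= 0) {
      stop("sac radius and neck width must be positive", call. = FALSE)
    }
  }
  if (neck_center_frac <= 0 || neck_center_frac >= 1) {
    stop("`neck_center_frac` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(stage = stage, sac_radius = sac_radius_m, neck_width = neck_width_m,
         neck_center_frac = neck_center_frac, neck_angle = neck_angle_deg),
    class = "aneurysm_spec"
  )
}

#' Endoluminal stent specification
#'
#' The stent is modelled as n evenly spaced circular struts spanning the neck
#' opening flush with the vessel wall, leaving n - 1 flow gaps. The default
#' (5 struts of 0.2 mm across a 2 mm neck) yields 4 gaps.
#'
#' @param n_struts Number of struts (>= 2). Default 5.
#' @param strut_diameter_m Strut diameter in meters. Default 2e-4.
#' @param spacing_m Centre-to-centre strut spacing in meters; by default the
#'   struts evenly span the neck (spacing = neck width / (n_struts - 1)).
#' @return An object of class `stent_spec`.
#' @export
stent_spec <- function(n_struts = 5L, strut_diameter_m = 2e-4,
                       spacing_m = NULL) {
  n_struts <- as.integer(n_struts)
  if (is.na(n_struts) || n_struts < 2L) {
    stop("`n_struts` must be >= 2", call. = FALSE)
  }
  if (strut_diameter_m <= 0) {
    stop("`strut_diameter_m` must be positive", call. = FALSE)
  }
  structure(list(n_struts = n_struts, strut_diameter = strut_diameter_m,
                 spacing = spacing_m),
            class = "stent_spec")
}

# ---- signed distance primitives -------------------------------------------
# Convention: phi < 0 strictly inside the fluid, > 0 in solid; |phi| is the
# distance to the interface (exact for these primitives, composed fields are
# exact near the interface).

#' Signed distance fields and level-set rasterization
#'
#' `sdf_circle()` is the signed distance to a circle/sphere (negative
#' inside), `sdf_slab()` to the slab `lo <= x_axis <= hi` (negative inside;
#' a 2D channel of width D is `sdf_slab(p, 2, 0, D)`), and `sdf_tube()` to
#' the interior of a circular tube of radius R aligned with the x axis.
#' `sdf_union()` combines shape fields by pointwise minimum (CSG union) and
#' `sdf_difference()` carves the second region out of the first.
#' `rasterize_levelset()` evaluates the union of a list of shape functions on
#' a grid of cell centres.
#'
#' @param p n x d matrix of point coordinates (meters).
#' @param center,r Circle/sphere centre (length d) and radius.
#' @param axis Coordinate index the slab constrains.
#' @param lo,hi Slab bounds along `axis`.
#' @param center_yz,R Tube axis position in the transverse plane and tube
#'   radius.
#' @param ... Numeric phi vectors of equal length.
#' @param a,b Numeric phi vectors.
#' @param shapes List of functions, each mapping an n x d point matrix to a
#'   signed-distance vector.
#' @param grid A grid as stored in a `domain_mask` (fields `origin`, `dims`,
#'   `dx`).
#' @return Signed distance vector (or array for `rasterize_levelset`).
#' @name levelset
NULL

#' @rdname levelset
#' @export
sdf_circle <- function(p, center, r) {
  p <- rbind(p)
  sqrt(rowSums(sweep(p, 2, center)^2)) - r
}

#' @rdname levelset
#' @export
sdf_slab <- function(p, axis, lo, hi) {
  x <- rbind(p)[, axis]
  pmax(lo - x, x - hi)
}

#' @rdname levelset
#' @export
sdf_tube <- function(p, center_yz, R) {
  p <- rbind(p)
  sqrt((p[, 2] - center_yz[1])^2 + (p[, 3] - center_yz[2])^2) - R
}

#' @rdname levelset
#' @export
sdf_union <- function(...) {
  do.call(pmin, list(...))
}

#' @rdname levelset
#' @export
sdf_difference <- function(a, b) {
  pmax(a, -b)
}

#' @rdname levelset
#' @export
rasterize_levelset <- function(shapes, grid) {
  if (length(shapes) == 0L) stop("`shapes` must be nonempty", call. = FALSE)
  p <- grid_centers(grid)
  phi <- do.call(pmin, lapply(shapes, function(s) s(p)))
  array(phi, dim = grid$dims)
}

# Cell-centre coordinates of every grid node, as an n x d matrix (meters).
grid_centers <- function(grid) {
  axes <- lapply(seq_along(grid$dims), function(k) {
    grid$origin[k] + (seq_len(grid$dims[k]) - 0.5) * grid$dx
  })
  g <- do.call(expand.grid, axes)
  as.matrix(g)
}

# ---- domain construction ---------------------------------------------------

# Sac centre position: seated on the outer wall (top in 2D, +y side in 3D),
# offset so the wall chord equals the neck width.
sac_center <- function(vessel, aneurysm) {
  h <- sqrt(aneurysm$sac_radius^2 - (aneurysm$neck_width / 2)^2)
  xc <- vessel$L * aneurysm$neck_center_frac
  if (vessel$dimensionality == 2L) {
    c(xc, vessel$D + h)
  } else {
    R <- vessel$D / 2
    c(xc, R + h, 0) + c(0, 0, 0) # tube axis at (y, z) = (0, 0)
  }
}

# Strut centre x positions across the neck opening.
strut_positions <- function(aneurysm, stent) {
  spacing <- stent$spacing
  if (is.null(spacing)) spacing <- aneurysm$neck_width / (stent$n_struts - 1)
  xc <- aneurysm$neck_center_x
  xc + (seq_len(stent$n_struts) - (stent$n_struts + 1) / 2) * spacing
}

#' Build the simulation domain mask
#'
#' Rasterizes vessel, sac and (optionally) stent level sets onto a regular
#' grid of cell-centred nodes and classifies each node as solid, fluid, inlet
#' or outlet. In 2D the vessel occupies `0 <= y <= D` with the sac bulging
#' from the upper wall; in 3D the tube axis runs along x at `(y, z) = (0, 0)`
#' with the sac seated on the `+y` wall. The grid is padded with solid cells
#' so that the fluid region is watertight; inlet and outlet are the fluid
#' nodes of the first and last grid column.
#'
#' @param vessel A [vessel_spec()].
#' @param aneurysm An [aneurysm_spec()]. Default: no aneurysm.
#' @param stent A [stent_spec()] or `NULL` (unstented).
#' @param resolution Lattice cells across the vessel width (>= 8). Default 30.
#' @return An object of class `domain_mask`: list with `grid` (origin, dims,
#'   dx), `class` (integer array: 0 solid, 1 fluid, 2 inlet, 3 outlet),
#'   `phi` (signed distance array, negative in fluid), and the originating
#'   specs.
#' @export
build_domain <- function(vessel, aneurysm = aneurysm_spec("none"),
                         stent = NULL, resolution = 30L) {
  stopifnot(inherits(vessel, "vessel_spec"), inherits(aneurysm, "aneurysm_spec"))
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 8L) {
    stop("`resolution` must be >= 8", call. = FALSE)
  }
  if (!is.null(stent) && !inherits(stent, "stent_spec")) {
    stop("`stent` must be a stent_spec or NULL", call. = FALSE)
  }
  if (!is.null(stent) && aneurysm$stage == "none") {
    stop("a stent requires an aneurysm (no neck to span)", call. = FALSE)
  }
  d <- vessel$dimensionality
  dx <- vessel$D / resolution
  pad <- 2L # solid padding cells beyond each wall

  has_sac <- aneurysm$stage != "none"
  if (has_sac) {
    ctr <- sac_center(vessel, aneurysm)
    sac_top <- ctr[2] + aneurysm$sac_radius
    # sac must not reach the inlet/outlet columns
    if (ctr[1] - aneurysm$sac_radius < 2 * dx ||
        ctr[1] + aneurysm$sac_radius > vessel$L - 2 * dx) {
      stop("aneurysm sac overlaps the inlet/outlet region; lengthen the vessel",
           call. = FALSE)
    }
  } else {
    sac_top <- if (d == 2L) vessel$D else vessel$D / 2
  }

  nx <- as.integer(round(vessel$L / dx))
  if (d == 2L) {
    ylo <- -pad * dx
    yhi <- sac_top + pad * dx
    dims <- c(nx, as.integer(ceiling((yhi - ylo) / dx)))
    origin <- c(0, ylo)
  } else {
    R <- vessel$D / 2
    ylo <- -R - pad * dx
    yhi <- sac_top + pad * dx
    # the sac sphere can be wider than the tube in z
    zhalf <- max(R, if (has_sac) aneurysm$sac_radius else 0) + pad * dx
    dims <- c(nx, as.integer(ceiling((yhi - ylo) / dx)),
              as.integer(ceiling(2 * zhalf / dx)))
    zlo <- -zhalf
    origin <- c(0, ylo, zlo)
  }
  grid <- list(origin = origin, dims = dims, dx = dx)
  p <- grid_centers(grid)

  phi_vessel <- if (d == 2L) {
    sdf_slab(p, 2L, 0, vessel$D)
  } else {
    sdf_tube(p, c(0, 0), vessel$D / 2)
  }
  phi <- phi_vessel
  if (has_sac) {
    phi <- sdf_union(phi, sdf_circle(p, ctr, aneurysm$sac_radius))
  }
  if (!is.null(stent)) {
    an <- aneurysm
    an$neck_center_x <- vessel$L * aneurysm$neck_center_frac
    xs <- strut_positions(an, stent)
    r_strut <- stent$strut_diameter / 2
    wall_y <- if (d == 2L) vessel$D else vessel$D / 2
    for (x0 in xs) {
      # 2D: circular strut on the wall line; 3D: rod along z across the neck
      phi_strut <- if (d == 2L) {
        sdf_circle(p, c(x0, wall_y), r_strut)
      } else {
        sqrt((p[, 1] - x0)^2 + (p[, 2] - wall_y)^2) - r_strut
      }
      phi <- sdf_difference(phi, phi_strut)
    }
  }
  phi <- array(phi, dim = dims)

  cls <- array(CLS_SOLID, dim = dims)
  cls[phi < 0] <- CLS_FLUID
  # inlet / outlet: fluid nodes on the first / last column
  idx_first <- slice_index(dims, 1L, 1L)
  idx_last <- slice_index(dims, 1L, dims[1])
  cls[idx_first][cls[idx_first] == CLS_FLUID] <- CLS_INLET
  cls[idx_last][cls[idx_last] == CLS_FLUID] <- CLS_OUTLET

  structure(
    list(grid = grid, class = cls, phi = phi, vessel = vessel,
         aneurysm = aneurysm, stent = stent, resolution = resolution),
    class = "domain_mask"
  )
}

# Linear indices of the slice where coordinate `axis` equals `value`.
slice_index <- function(dims, axis, value) {
  idx <- lapply(dims, seq_len)
  idx[[axis]] <- value
  g <- do.call(expand.grid, idx)
  as.integer(as.matrix(g) %*% cumprod(c(1L, dims[-length(dims)])) -
               sum(cumprod(c(1L, dims[-length(dims)]))) + 1L)
}

#' @export
print.domain_mask <- function(x, ...) {
  cat(sprintf("<domain_mask %s, %s grid, dx = %.3g m>\n",
              paste0(x$vessel$dimensionality, "D"),
              paste(x$grid$dims, collapse = " x "), x$grid$dx))
  cat(sprintf("  fluid %d, inlet %d, outlet %d, solid %d; stage = %s%s\n",
              sum(x$class == CLS_FLUID), sum(x$class == CLS_INLET),
              sum(x$class == CLS_OUTLET), sum(x$class == CLS_SOLID),
              x$aneurysm$stage,
              if (is.null(x$stent)) "" else sprintf(", stented (%d struts)",
                                                    x$stent$n_struts)))
  invisible(x)
}

#' Sac node set
#'
#' Linear indices of the fluid nodes lying inside the aneurysm sac, i.e.
#' outside the unperturbed vessel lumen (above the wall line in 2D, beyond
#' the tube radius in 3D). Together with [lumen_region()] this partitions the
#' fluid nodes.
#'
#' @param mask A `domain_mask` built with an aneurysm stage other than
#'   `"none"`.
#' @return Integer vector of linear node indices.
#' @export
sac_region <- function(mask) {
  stopifnot(inherits(mask, "domain_mask"))
  if (mask$aneurysm$stage == "none") {
    stop("no aneurysm in this domain (stage = \"none\")", call. = FALSE)
  }
  p <- grid_centers(mask$grid)
  outside <- if (mask$vessel$dimensionality == 2L) {
    p[, 2] > mask$vessel$D
  } else {
    p[, 2]^2 + p[, 3]^2 > (mask$vessel$D / 2)^2
  }
  which(outside & c(mask$class) %in% c(CLS_FLUID, CLS_INLET, CLS_OUTLET))
}

#' @rdname sac_region
#' @export
lumen_region <- function(mask) {
  stopifnot(inherits(mask, "domain_mask"))
  fl <- which(c(mask$class) %in% c(CLS_FLUID, CLS_INLET, CLS_OUTLET))
  if (mask$aneurysm$stage == "none") return(fl)
  setdiff(fl, sac_region(mask))
}

#' Watertightness check
#'
#' Verifies that the fluid region is sealed: every grid-border node is solid
#' except on the inlet/outlet faces, and a flood fill (face connectivity)
#' started from the inlet reaches the outlet and every fluid node, without
#' isolated pockets.
#'
#' @param mask A `domain_mask`.
#' @return `TRUE` invisibly; stops with a descriptive error otherwise.
#' @export
check_watertight <- function(mask) {
  stopifnot(inherits(mask, "domain_mask"))
  dims <- mask$grid$dims
  cls <- c(mask$class)
  d <- length(dims)
  # border nodes on non-axial faces must be solid
  for (ax in seq_len(d)[-1]) {
    for (v in c(1L, dims[ax])) {
      idx <- slice_index(dims, ax, v)
      if (any(cls[idx] != CLS_SOLID)) {
        stop("domain leaks: non-solid node on a closed border face", call. = FALSE)
      }
    }
  }
  wet <- cls != CLS_SOLID
  visited <- logical(length(cls))
  frontier <- which(cls == CLS_INLET)
  if (length(frontier) == 0L) stop("no inlet nodes", call. = FALSE)
  visited[frontier] <- TRUE
  strides <- cumprod(c(1L, dims[-d]))
  coord <- arrayInd(seq_along(cls), dims)
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (ax in seq_len(d)) {
      for (s in c(-1L, 1L)) {
        ok <- coord[frontier, ax] + s >= 1L & coord[frontier, ax] + s <= dims[ax]
        nb <- frontier[ok] + s * strides[ax]
        nb <- nb[wet[nb] & !visited[nb]]
        visited[nb] <- TRUE
        nxt <- c(nxt, nb)
      }
    }
    frontier <- unique(nxt)
  }
  if (!any(visited[cls == CLS_OUTLET])) {
    stop("flood fill from inlet does not reach the outlet", call. = FALSE)
  }
  if (any(wet & !visited)) {
    stop(sprintf("%d fluid node(s) unreachable from the inlet (isolated pocket)",
                 sum(wet & !visited)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Custom cutline
#'
#' Builds a sampling segment between two physical points; [make_cutlines()]
#' provides the three standard ones.
#'
#' @param name Cutline label.
#' @param start,end Endpoints in meters (length-d numeric).
#' @param n_samples Number of evenly spaced samples.
#' @return A `cutline_spec`.
#' @export
cutline_spec <- function(name, start, end, n_samples = 101L) {
  stopifnot(length(start) == length(end), length(start) %in% c(2L, 3L))
  len <- sqrt(sum((end - start)^2))
  if (len <= 0) stop("cutline has zero length", call. = FALSE)
  structure(list(name = name, start = start, end = end,
                 n_samples = as.integer(n_samples), length = len),
            class = "cutline_spec")
}

#' Cutline specification and construction
#'
#' `make_cutlines()` builds the three standard sampling segments: `pre` and
#' `post` span the vessel width (3 mm for the default vessel) perpendicular
#' to the axis before and after the neck; `mid` crosses the neck centre at
#' the neck angle (45 degrees) to the vessel axis, with length 5 mm for the
#' medium stage and 6 mm for the larger stage so that it spans lumen, neck
#' and sac.
#'
#' @param aneurysm An [aneurysm_spec()] with stage other than `"none"`.
#' @param vessel A [vessel_spec()].
#' @param n_samples Samples per cutline. Default 101.
#' @param offset_m Distance of the pre/post lines from the neck centre along
#'   the axis. Default 1.25 * vessel width.
#' @return A named list of three `cutline_spec` objects (`pre`, `mid`,
#'   `post`), each with fields `name`, `start`, `end`, `n_samples`, `length`.
#' @export
make_cutlines <- function(aneurysm, vessel, n_samples = 101L,
                          offset_m = NULL) {
  stopifnot(inherits(aneurysm, "aneurysm_spec"), inherits(vessel, "vessel_spec"))
  if (aneurysm$stage == "none") {
    stop("cutlines are defined relative to the aneurysm neck; stage is \"none\"",
         call. = FALSE)
  }
  if (is.null(offset_m)) offset_m <- 1.25 * vessel$D
  d <- vessel$dimensionality
  xc <- vessel$L * aneurysm$neck_center_frac
  wall_y <- if (d == 2L) vessel$D else vessel$D / 2
  ylo <- if (d == 2L) 0 else -vessel$D / 2
  mid_len <- switch(aneurysm$stage, medium = 5e-3, larger = 6e-3)
  ang <- aneurysm$neck_angle * pi / 180
  dir <- c(cos(ang), sin(ang))
  ctr <- c(xc, wall_y)
  pt <- function(x, y) if (d == 2L) c(x, y) else c(x, y, 0)
  mk <- function(name, start, end) {
    structure(list(name = name, start = start, end = end,
                   n_samples = as.integer(n_samples),
                   length = sqrt(sum((end - start)^2))),
              class = "cutline_spec")
  }
  list(
    pre = mk("pre", pt(xc - offset_m, ylo), pt(xc - offset_m, ylo + vessel$D)),
    mid = mk("mid", pt(ctr[1] - mid_len / 2 * dir[1], ctr[2] - mid_len / 2 * dir[2]),
             pt(ctr[1] + mid_len / 2 * dir[1], ctr[2] + mid_len / 2 * dir[2])),
    post = mk("post", pt(xc + offset_m, ylo), pt(xc + offset_m, ylo + vessel$D))
  )
}

# Neck centre and aperture half-width in physical coordinates (2D/3D).
neck_geometry <- function(mask) {
  v <- mask$vessel
  an <- mask$aneurysm
  xc <- v$L * an$neck_center_frac
  wall_y <- if (v$dimensionality == 2L) v$D else v$D / 2
  list(center = if (v$dimensionality == 2L) c(xc, wall_y) else c(xc, wall_y, 0),
       halfwidth = an$neck_width / 2)
}

#' Number of flow gaps across the neck line
#'
#' Counts maximal runs of non-solid nodes along the row of nodes nearest the
#' wall line within the neck aperture: with the default 5-strut stent this is
#' the 4 gaps through which fluid enters and leaves the sac.
#'
#' @param mask A stented (or unstented) 2D `domain_mask`.
#' @return Integer number of connected fluid intervals.
#' @export
count_neck_gaps <- function(mask) {
  stopifnot(inherits(mask, "domain_mask"))
  if (mask$vessel$dimensionality != 2L) {
    stop("gap counting is defined for 2D domains", call. = FALSE)
  }
  nk <- neck_geometry(mask)
  g <- mask$grid
  j <- round((nk$center[2] - g$origin[2]) / g$dx + 0.5) # row at the wall line
  i_range <- which(abs(g$origin[1] + (seq_len(g$dims[1]) - 0.5) * g$dx -
                         nk$center[1]) <= nk$halfwidth)
  open <- mask$class[cbind(i_range, j)] != CLS_SOLID
  runs <- rle(open)
  sum(runs$values)
}
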