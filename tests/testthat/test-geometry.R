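test_that("signed distance primitives give exact distances", {
  p <- rbind(c(2e-3, 1e-3), c(0, 0), c(5e-3, 1e-3))
  phi <- sdf_circle(p, c(2e-3, 1e-3), 1e-3)
  expect_equal(phi[1], -1e-3)                         # centre: -r
  expect_equal(phi[2], sqrt(4 + 1) * 1e-3 - 1e-3)     # outside
  # channel interior at mid-height: -D/2 = -1.5 mm
  expect_equal(sdf_slab(rbind(c(1e-3, 1.5e-3)), 2, 0, 3e-3), -1.5e-3)
  # CSG union is the pointwise minimum
  a <- c(-1, 2, 0.5); b <- c(0.5, -3, 0.5)
  expect_equal(sdf_union(a, b), pmin(a, b))
  expect_equal(sdf_difference(a, b), pmax(a, -b))
})

test_that("rasterized level set classifies fluid as phi < 0", {
  grid <- list(origin = c(0, 0), dims = c(20L, 20L), dx = 1e-4)
  shapes <- list(function(p) sdf_circle(p, c(1e-3, 1e-3), 0.5e-3))
  phi <- rasterize_levelset(shapes, grid)
  expect_identical(dim(phi), c(20L, 20L))
  ctr <- aneuflow:::grid_centers(grid)
  d <- sqrt((ctr[, 1] - 1e-3)^2 + (ctr[, 2] - 1e-3)^2)
  expect_equal(c(phi), d - 0.5e-3)
  expect_error(rasterize_levelset(list(), grid), "nonempty")
})

test_that("straight channel mask is a full-width rectangular duct", {
  mk <- channel_mask(res = 30L, length_m = 12e-3)
  wet <- sum(mk$class != 0L)
  expect_identical(wet, 30L * as.integer(12e-3 / 1e-4)) # 30 x L/dx
  expect_identical(sum(mk$class == 2L), 30L) # inlet column spans the width
  expect_identical(sum(mk$class == 3L), 30L)
  expect_silent(check_watertight(mk))
})

test_that("vessel and aneurysm specs enforce their invariants", {
  expect_error(vessel_spec(3e-3, 5e-3), "4")
  expect_error(aneurysm_spec("medium", neck_width_m = 5e-3), "smaller")
  expect_error(aneurysm_spec("medium", neck_center_frac = 1.2), "0, 1")
  expect_error(stent_spec(1), ">= 2")
  # sac reaching the inlet region is refused
  expect_error(
    build_domain(vessel_spec(3e-3, 13e-3), aneurysm_spec("larger",
                                                         neck_center_frac = 0.15),
                 resolution = 30),
    "inlet/outlet")
})

test_that("the larger sac strictly contains the medium sac", {
  v <- vessel_spec(3e-3, 15e-3)
  mkM <- build_domain(v, aneurysm_spec("medium"), resolution = 30)
  mkL <- build_domain(v, aneurysm_spec("larger"), resolution = 30)
  # compare by physical node coordinates (grids differ in height)
  key <- function(mk, idx) {
    p <- aneuflow:::grid_centers(mk$grid)[idx, , drop = FALSE]
    paste(round(p[, 1] / mk$grid$dx - 0.5), round(p[, 2] / mk$grid$dx - 0.5))
  }
  sacM <- key(mkM, sac_region(mkM))
  sacL <- key(mkL, sac_region(mkL))
  expect_true(all(sacM %in% sacL))
  expect_gt(length(sacL), length(sacM))
})

test_that("sac and lumen partition the wet nodes", {
  mk <- build_domain(vessel_spec(3e-3, 15e-3), aneurysm_spec("medium"),
                     resolution = 20)
  sac <- sac_region(mk)
  lum <- lumen_region(mk)
  wet <- which(c(mk$class) != 0L)
  expect_length(intersect(sac, lum), 0)
  expect_setequal(c(sac, lum), wet)
  expect_gt(length(sac), 0)
  expect_error(sac_region(channel_mask()), "none")
})

test_that("aneurysm domains are watertight at several resolutions", {
  for (res in c(12L, 30L)) {
    mk <- build_domain(vessel_spec(3e-3, 15e-3), aneurysm_spec("larger"),
                       stent_spec(), resolution = res)
    expect_silent(check_watertight(mk))
  }
  mk3 <- build_domain(vessel_spec(3e-3, 12.25e-3, 3L), aneurysm_spec("medium"),
                      resolution = 12)
  expect_silent(check_watertight(mk3))
})

test_that("default stent leaves exactly four gaps and only removes fluid", {
  v <- vessel_spec(3e-3, 15e-3)
  mk0 <- build_domain(v, aneurysm_spec("larger"), resolution = 30)
  mk1 <- build_domain(v, aneurysm_spec("larger"), stent_spec(), resolution = 30)
  expect_identical(count_neck_gaps(mk1), 4L)
  expect_identical(count_neck_gaps(mk0), 1L) # open neck is a single interval
  # stent insertion only converts fluid nodes to solid, never the reverse
  expect_identical(dim(mk0$class), dim(mk1$class))
  changed <- which(mk0$class != mk1$class)
  expect_gt(length(changed), 0)
  expect_true(all(mk0$class[changed] == 1L & mk1$class[changed] == 0L))
  expect_error(build_domain(v, aneurysm_spec("none"), stent_spec()), "stent")
})

test_that("fluid area converges under grid refinement", {
  v <- vessel_spec(3e-3, 15e-3)
  area <- vapply(c(30L, 60L), function(res) {
    mk <- build_domain(v, aneurysm_spec("medium"), resolution = res)
    sum(mk$class != 0L) * mk$grid$dx^2
  }, numeric(1))
  expect_lt(abs(area[2] - area[1]) / area[1], 0.02)
})

test_that("cutlines have the prescribed lengths and orientation", {
  v <- vessel_spec(3e-3, 15e-3)
  clM <- make_cutlines(aneurysm_spec("medium"), v)
  clL <- make_cutlines(aneurysm_spec("larger"), v)
  expect_equal(clM$pre$length, 3e-3, tolerance = 1e-12)
  expect_equal(clM$post$length, 3e-3, tolerance = 1e-12)
  expect_equal(clM$mid$length, 5e-3, tolerance = 1e-12)
  expect_equal(clL$mid$length, 6e-3, tolerance = 1e-12)
  # mid runs at 45 degrees to the vessel axis through the neck centre
  dirM <- clM$mid$end - clM$mid$start
  expect_equal(dirM[1], dirM[2], tolerance = 1e-12)
  expect_equal((clM$mid$start + clM$mid$end) / 2, c(7.5e-3, 3e-3),
               tolerance = 1e-12)
  # pre/post are perpendicular to the axis
  expect_equal(clM$pre$start[1], clM$pre$end[1])
  expect_error(make_cutlines(aneurysm_spec("none"), v), "none")
})
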