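test_that("cutline sampling interpolates fields and respects the sample count", {
  mk <- channel_mask(res = 16L)
  f <- synthetic_field_2d(mk, function(x, y) 0.02 + 0 * x, function(x, y) 0 * x)
  cl <- cutline_spec("probe", c(2e-3, 0.5e-3), c(8e-3, 2.5e-3), 57L)
  prof <- sample_cutline(f, cl)
  expect_length(prof$velocity, 57L)
  expect_equal(prof$velocity, rep(0.02, 57L), tolerance = 1e-12)
  expect_equal(max(prof$position), cl$length)
  # analytic Poiseuille field: vertical cutline recovers the parabola
  # (samples at the walls mix in solid zeros, so the L2 band is loose)
  mk30 <- channel_mask(res = 30L)
  fp <- analytic_channel_field(mk30, u_max = 0.05)
  clv <- cutline_spec("pre", c(6e-3, 0), c(6e-3, 3e-3), 101L)
  pv <- sample_cutline(fp, clv)
  expect_equal(max(pv$velocity), 0.05, tolerance = 0.01)
  # the centre sample sits on the peak plateau of the interpolant
  expect_equal(pv$velocity[51], max(pv$velocity), tolerance = 1e-12)
  ana <- 0.05 * pmax(1 - (2 * seq(0, 3e-3, length.out = 101) / 3e-3 - 1)^2, 0)
  expect_lt(sqrt(sum((pv$velocity - ana)^2) / sum(ana^2)), 0.05)
  # a line fully outside the bounding box is refused
  out <- cutline_spec("x", c(-1, -1), c(-0.9, -1))
  expect_error(sample_cutline(fp, out), "outside")
})

test_that("sac mean velocity averages speed over the sac nodes in mm/s", {
  mk <- build_domain(vessel_spec(3e-3, 15e-3), aneurysm_spec("medium"),
                     resolution = 16)
  f0 <- synthetic_field_2d(mk, function(x, y) 0 * x, function(x, y) 0 * x)
  expect_equal(sac_mean_velocity(f0), 0)
  f2 <- synthetic_field_2d(mk, function(x, y) 2e-3 + 0 * x, function(x, y) 0 * x)
  expect_equal(sac_mean_velocity(f2), 2, tolerance = 1e-12)
  expect_error(sac_mean_velocity(f2, sac = integer(0)), "empty")
})

test_that("neck peak restricts to the aperture segment of the mid cutline", {
  mk <- build_domain(vessel_spec(3e-3, 15e-3), aneurysm_spec("medium"),
                     resolution = 16)
  cl <- make_cutlines(mk$aneurysm, mk$vessel)
  f0 <- synthetic_field_2d(mk, function(x, y) 0 * x, function(x, y) 0 * x)
  expect_equal(neck_peak_velocity(f0, cl$mid), 0)
  fu <- synthetic_field_2d(mk, function(x, y) 4e-3 + 0 * x, function(x, y) 0 * x)
  expect_equal(neck_peak_velocity(fu, cl$mid), 4, tolerance = 0.05)
  # a field increasing along y peaks at the outer end of the neck segment:
  # the peak must exceed the wall-line value but stay below the sac-top value
  fy <- synthetic_field_2d(mk, function(x, y) y, function(x, y) 0 * x)
  pk <- 1000 * neck_peak_velocity(fy, cl$mid) / 1000
  expect_gt(pk, 1000 * 3e-3 * 0.9)
  expect_lt(pk, 1000 * (3e-3 + mk$aneurysm$neck_width / 2) * 1.1)
})

test_that("vorticity recovers analytic rotation and shear rates", {
  mk <- channel_mask(res = 16L)
  interior <- cbind(rep(10:50, 4), rep(6:9, each = 41))
  # rigid rotation about the domain centre: omega = 2 Omega
  Om <- 30
  fr <- synthetic_field_2d(mk, function(x, y) -Om * (y - 1.5e-3),
                           function(x, y) Om * (x - 6e-3))
  expect_equal(vorticity_2d(fr)[interior], rep(2 * Om, nrow(interior)),
               tolerance = 1e-9)
  # plane shear u = (gamma y, 0): omega = -gamma
  fs <- synthetic_field_2d(mk, function(x, y) 40 * y, function(x, y) 0 * x)
  expect_equal(vorticity_2d(fs)[interior], rep(-40, nrow(interior)),
               tolerance = 1e-9)
  fu <- synthetic_field_2d(mk, function(x, y) 0.01 + 0 * x, function(x, y) 0 * x)
  expect_equal(max(abs(vorticity_2d(fu))), 0, tolerance = 1e-12)
})

test_that("profile comparison metrics behave as norms", {
  mk <- channel_mask(res = 16L)
  fp <- analytic_channel_field(mk)
  cl <- cutline_spec("pre", c(6e-3, 0), c(6e-3, 3e-3))
  a <- sample_cutline(fp, cl)
  b <- a
  expect_equal(compare_profiles(a, b)$rel_l2, 0)
  expect_equal(compare_profiles(a, b)$max_abs, 0)
  b$velocity <- 1.1 * a$velocity
  cmp <- compare_profiles(a, b)
  expect_equal(cmp$rel_l2, 0.1, tolerance = 1e-12)
  expect_equal(cmp$max_abs, 0.1 * max(a$velocity), tolerance = 1e-12)
  z <- a; z$velocity <- 0 * a$velocity
  expect_error(compare_profiles(z, a), "zero")
  b$name <- "post"
  expect_error(compare_profiles(a, b), "mismatched")
  b$name <- "pre"; b$n_samples <- 11L
  expect_error(compare_profiles(a, b), "sample counts")
})

test_that("flow summary reports finite observables with sac mean below neck peak", {
  us <- build_unit_system(flow_scenario(), 12, 0.05)
  mk <- build_domain(vessel_spec(3e-3, 15e-3), aneurysm_spec("medium"),
                     resolution = 12)
  st <- run_to_steady(lbm_init(mk, us), steady_state_criterion(1e-6, 200, 60000))
  s <- flow_summary(velocity_field(st))
  expect_true(s$converged)
  expect_false(s$stented)
  expect_true(is.finite(s$sac_mean_mm_s) && is.finite(s$neck_peak_mm_s) &&
                is.finite(s$max_vorticity_sac_s))
  expect_lt(s$sac_mean_mm_s, s$neck_peak_mm_s)
  expect_gt(s$sac_mean_mm_s, 0)
})
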