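test_that("configurations validate, fill defaults and reject unknown keys", {
  cfg <- validate_config(list())
  expect_identical(cfg$scenario$density_kg_m3, 1060)
  expect_identical(cfg$geometry$stage, "medium")
  expect_error(validate_config(list(scenario = list(bogus = 1))), "bogus")
  expect_error(validate_config(list(nonsense = list())), "nonsense")
  expect_error(validate_config(list(solver = list(type = "fem"))), "lbm")
  expect_error(validate_config(list(geometry = list(stage = "huge"))), "stage")
  expect_error(validate_config(list(geometry = list(stage = "none",
                                                    stent = TRUE))), "stent")
})

test_that("configurations round-trip through YAML files", {
  cfg <- preset_config("larger-2d-stented")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  cfg2 <- read_run_config(path)
  expect_identical(validate_config(cfg)$scenario, cfg2$scenario)
  expect_identical(validate_config(cfg)$geometry, cfg2$geometry)
  expect_true(cfg2$geometry$stent)
})

test_that("presets cover the documented scenario set", {
  expect_identical(preset_config("poiseuille-2d")$geometry$stage, "none")
  expect_identical(preset_config("larger-2d")$geometry$stage, "larger")
  p3 <- preset_config("medium-3d-small")
  expect_identical(p3$geometry$dimensionality, 3L)
  expect_lt(p3$scenario$cells_across_width, 30L)
  expect_error(preset_config("no-such"), "arg")
})

test_that("a truncated run is bit-reproducible and writes all artifacts", {
  cfg <- preset_config("medium-2d")
  cfg$scenario$cells_across_width <- 16L
  cfg$solver$max_steps <- 400L
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressWarnings({
    r1 <- run_scenario(cfg, out_dir = d1)
    r2 <- run_scenario(cfg, out_dir = d2)
  })
  expect_setequal(list.files(d1),
                  c("config.yaml", "convergence_lbm.csv", "field_lbm.vtk",
                    "profiles.csv", "summary.json"))
  expect_identical(readLines(file.path(d1, "profiles.csv")),
                   readLines(file.path(d2, "profiles.csv")))
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))
  pr <- utils::read.csv(file.path(d1, "profiles.csv"))
  expect_setequal(unique(pr$cutline), c("pre", "mid", "post"))
  expect_true(all(pr$velocity_mm_s >= 0))
})

test_that("VTK export writes a legacy structured-points header", {
  cfg <- preset_config("medium-2d")
  cfg$scenario$cells_across_width <- 12L
  cfg$solver$max_steps <- 200L
  suppressWarnings(res <- run_scenario(cfg))
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_field(res$fields$lbm, path)
  head <- readLines(path, n = 9)
  expect_identical(head[1], "# vtk DataFile Version 3.0")
  expect_identical(head[4], "DATASET STRUCTURED_POINTS")
  dims <- res$fields$lbm$grid$dims
  expect_identical(head[5], sprintf("DIMENSIONS %d %d 1", dims[1], dims[2]))
  expect_true(any(grepl("VECTORS velocity double", head)))
})

test_that("solver comparison reports one metric set per cutline", {
  cfg <- preset_config("medium-2d")
  cfg$scenario$cells_across_width <- 12L
  cfg$solver$max_steps <- 300L
  suppressWarnings(out <- run_comparison(cfg))
  expect_named(out$comparison, c("pre", "mid", "post"))
  for (cmp in out$comparison) {
    expect_true(is.finite(cmp$rel_l2) && is.finite(cmp$max_abs))
  }
  expect_named(out$result$fields, c("lbm", "ns"))
})

test_that("3D Navier-Stokes requests are rejected as unsupported", {
  cfg <- preset_config("medium-3d-small")
  cfg$solver$type <- "both"
  expect_error(run_scenario(cfg), "2D-only")
})

test_that("stented preset flags the stent and keeps four gaps", {
  # keep the default 30-cell resolution: the 0.2 mm struts need it to raster
  cfg <- preset_config("larger-2d-stented")
  cfg$solver$max_steps <- 300L
  suppressWarnings(res <- run_scenario(cfg))
  expect_true(res$summaries$lbm$stented)
  expect_identical(count_neck_gaps(res$mask), 4L)
})
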