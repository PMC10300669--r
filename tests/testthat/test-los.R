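# Point-to-point line of sight: curvature model, profile sampling,
# blocking rules, and the engine invariants.

test_that("curvature drop follows the spherical closed form d^2/(2R)", {
  cfg <- sight_config(curved = TRUE)
  expect_identical(curvature_drop(0, cfg), 0)
  expect_equal(curvature_drop(1000, cfg), 1000^2 / (2 * 6371000))
  expect_equal(curvature_drop(10000, cfg), 7.848, tolerance = 1e-4)
  # quadratic scaling: 10x the distance = 100x the drop
  expect_equal(curvature_drop(10000, cfg), 100 * curvature_drop(1000, cfg))
  # flat model switches the drop off entirely
  expect_identical(curvature_drop(c(10, 1e4), sight_config(curved = FALSE)),
                   c(0, 0))
  # the configurable radius reproduces alternative Earth radii exactly
  cfg2 <- sight_config(curved = TRUE, earth_radius_m = 6731000)
  expect_equal(curvature_drop(10000, cfg2), 1e8 / (2 * 6731000))
  expect_error(curvature_drop(-1, cfg), "non-negative")
})

test_that("profile sampling: fixed spacing, endpoints included, flagged nodata", {
  dem <- make_dem("flat", nrows = 5, ncols = 80, resolution = 30)
  p <- cell_center(dem, 3, 2)[1, ]
  q <- c(p[1] + 1000, p[2])
  prof <- sample_profile(dem, p, q, sight_config(sample_step_m = 15))
  expect_identical(nrow(prof), 68L)           # 66 interior + both endpoints
  expect_identical(prof$distance_m[1], 0)
  expect_equal(prof$distance_m[68], 1000)
  expect_true(all(diff(prof$distance_m) > 0))
  expect_true(all(prof$terrain_m == 0))
  expect_false(attr(prof, "any_nodata"))

  # curvature applied with p1 as the zero-drop origin
  profc <- sample_profile(dem, p, q, sight_config(curved = TRUE, sample_step_m = 15))
  expect_equal(profc$terrain_curved_m,
               profc$terrain_m - profc$distance_m^2 / (2 * 6371000))

  dem$values[3, 20] <- NA; dem$nodata_mask[3, 20] <- TRUE
  prof2 <- sample_profile(dem, p, q, sight_config(sample_step_m = 15))
  expect_true(attr(prof2, "any_nodata"))
  expect_error(sample_profile(dem, p, c(p[1] + 1e6, p[2])), "outside")
})

test_that("ridge fixture profile peaks at the crossing", {
  dem <- make_dem("ridge", nrows = 41, ncols = 41, height = 50)
  p <- cell_center(dem, 21, 2)[1, ]
  q <- cell_center(dem, 21, 40)[1, ]
  prof <- sample_profile(dem, p, q)
  D <- max(prof$distance_m)
  expect_equal(max(prof$terrain_m), 50)
  peak_d <- prof$distance_m[which(prof$terrain_m == 50)]
  expect_true(all(abs(peak_d - D / 2) < 0.1 * D))
})

test_that("flat terrain is visible; a mid-path ridge blocks near its crest", {
  flat <- make_dem("flat", nrows = 21, ncols = 41, resolution = 30)
  p <- cell_center(flat, 11, 3)[1, ]
  q <- cell_center(flat, 11, 37)[1, ]
  r <- line_of_sight(flat, p, q, from_height_m = 10, to_height_m = 0.3)
  expect_true(r$visible)
  expect_true(is.na(r$blocking_distance_m))

  ridge <- make_dem("ridge", nrows = 21, ncols = 41, height = 50)
  rb <- line_of_sight(ridge, p, q, from_height_m = 10, to_height_m = 0.3)
  expect_false(rb$visible)
  D <- rb$distance_m
  expect_gt(rb$blocking_distance_m, 0)
  expect_lt(abs(rb$blocking_distance_m - D / 2), 3 * 30)
})

test_that("the 11 km curved/flat worked pair matches the closed form", {
  dem <- make_dem("flat", nrows = 5, ncols = 400, resolution = 30)
  p <- cell_center(dem, 3, 4)[1, ]
  q <- c(p[1] + 11000, p[2])
  R <- 6371000
  cur <- line_of_sight(dem, p, q, from_height_m = 2, to_height_m = 0,
                       cfg = sight_config(curved = TRUE))
  flt <- line_of_sight(dem, p, q, from_height_m = 2, to_height_m = 0,
                       cfg = sight_config(curved = FALSE))
  expect_false(cur$visible)
  expect_true(flt$visible)

  # closed form: terrain e(d)=0, chord from (0, 2) to (11000, -D^2/2R);
  # exceedance f(d) = -d^2/2R - (2 + (B-2) d/D), maximal near D/2
  D <- 11000; B <- -D^2 / (2 * R)
  f <- function(d) -d^2 / (2 * R) - (2 + (B - 2) * d / D)
  expect_equal(f(5500), 1.3747, tolerance = 1e-3)
  prof <- cur$profile
  interior <- prof$distance_m >= 15 & (D - prof$distance_m) >= 15
  got <- max((prof$terrain_curved_m - prof$sightline_m)[interior])
  want <- max(f(prof$distance_m[interior]))
  expect_equal(got, want, tolerance = 1e-9)
  # first blocked sample brackets the analytic root of f
  root <- min(Re(polyroot(c(-2, -(B - 2) / D, -1 / (2 * R)))))
  expect_lt(abs(cur$blocking_distance_m - root), 20)
})

test_that("terrain exactly on the sight line does not block (strict rule)", {
  dem <- make_dem("flat", nrows = 5, ncols = 41, resolution = 30)
  p <- cell_center(dem, 3, 2)[1, ]
  q <- cell_center(dem, 3, 40)[1, ]
  # tower and target both at height 0 over flat ground: the line lies
  # exactly on the terrain everywhere
  r <- line_of_sight(dem, p, q, from_height_m = 0, to_height_m = 0)
  expect_true(r$visible)
})

test_that("LOS is symmetric for equal endpoint heights on a shared sample set", {
  fx <- standard_fixtures(31)
  set.seed(11)
  checked <- 0L
  for (dem in fx[c("hill", "stairs", "basin")]) {
    for (i in 1:34) {
      rc <- matrix(sample(5:27, 4, replace = TRUE), 2)
      p <- cell_center(dem, rc[1, 1], rc[1, 2])[1, ]
      q <- cell_center(dem, rc[2, 1], rc[2, 2])[1, ]
      D <- sqrt(sum((p - q)^2))
      if (D < 60) next
      # a step that divides D exactly, so both directions share samples
      step <- D / ceiling(D / 15)
      for (curved in c(FALSE, TRUE)) {
        cfg <- sight_config(curved = curved, sample_step_m = step)
        a <- line_of_sight(dem, p, q, from_height_m = 3, to_height_m = 3, cfg = cfg)
        b <- line_of_sight(dem, q, p, from_height_m = 3, to_height_m = 3, cfg = cfg)
        expect_identical(a$visible, b$visible)
        checked <- checked + 1L
      }
    }
  }
  expect_gte(checked, 100L)
})

test_that("raising either endpoint never converts visible to blocked", {
  fx <- standard_fixtures(31)
  for (dem in fx[c("hill", "ridge")]) {
    tw <- tower_at(dem, 16, 4, height_m = 0)
    q <- cell_center(dem, 16, 28)[1, ]
    vis_tower <- vapply(c(0, 1, 3, 10, 40, 150), function(h)
      line_of_sight(dem, c(tw$x, tw$y), q, from_height_m = h,
                    to_height_m = 0.3)$visible, logical(1))
    expect_true(all(diff(vis_tower) >= 0))   # once visible, stays visible
    expect_true(vis_tower[6])                # clears the 50 m relief at mid-path
    vis_target <- vapply(c(0, 0.3, 2, 10, 120), function(th)
      line_of_sight(dem, c(tw$x, tw$y), q, from_height_m = 5,
                    to_height_m = th)$visible, logical(1))
    expect_true(all(diff(vis_target) >= 0))
    expect_true(vis_target[5])
  }
})

test_that("single-pair LOS agrees with the dense brute-force oracle", {
  fx <- standard_fixtures(31)
  set.seed(23)
  for (dem in fx) {
    cfg <- dense_cfg(dem)
    cfgc <- dense_cfg(dem, curved = TRUE)
    for (i in 1:20) {
      rc <- matrix(sample(2:30, 4, replace = TRUE), 2)
      p <- cell_center(dem, rc[1, 1], rc[1, 2])[1, ]
      q <- cell_center(dem, rc[2, 1], rc[2, 2])[1, ]
      if (all(p == q)) next
      te <- dem$values[rc[2, 1], rc[2, 2]] + 0.3
      expect_identical(line_of_sight(dem, p, q, 5, 0.3, cfg = cfg)$visible,
                       oracle_los_visible(dem, p, 5, q, te, FALSE,
                                          step = cfg$sample_step_m))
      expect_identical(line_of_sight(dem, p, q, 5, 0.3, cfg = cfgc)$visible,
                       oracle_los_visible(dem, p, 5, q, te, TRUE,
                                          step = cfgc$sample_step_m))
    }
  }
})

test_that("target on a missing-data cell is invalid, not merely hidden", {
  dem <- make_dem("flat", nrows = 11, ncols = 11, resolution = 30)
  dem$values[6, 9] <- NA; dem$nodata_mask[6, 9] <- TRUE
  p <- cell_center(dem, 6, 2)[1, ]
  q <- cell_center(dem, 6, 9)[1, ]
  r <- line_of_sight(dem, p, q, from_height_m = 5, to_height_m = 1)
  expect_false(r$visible)
  expect_false(r$valid)
  # nodata strictly between the endpoints does not block
  dem2 <- make_dem("flat", nrows = 11, ncols = 11, resolution = 30)
  dem2$values[6, 5] <- NA; dem2$nodata_mask[6, 5] <- TRUE
  r2 <- line_of_sight(dem2, p, cell_center(dem2, 6, 10)[1, ],
                      from_height_m = 5, to_height_m = 1)
  expect_true(r2$visible)
  expect_true(r2$valid)
})

test_that("profile CSV export mirrors the profile columns", {
  dem <- make_dem("ridge", nrows = 21, ncols = 41)
  p <- cell_center(dem, 11, 3)[1, ]
  q <- cell_center(dem, 11, 39)[1, ]
  r <- line_of_sight(dem, p, q, from_height_m = 10, to_height_m = 0.3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(r, f)
  back <- utils::read.csv(f)
  expect_identical(names(back),
                   c("distance_m", "terrain_m", "terrain_curved_m", "sightline_m"))
  expect_equal(back$distance_m, r$profile$distance_m)
  expect_equal(back$sightline_m, r$profile$sightline_m)
})
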