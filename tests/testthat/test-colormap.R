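test_that("jet endpoints and clipping match the anchored encoding", {
  expect_equal(unname(encode_temperature(28)[1, ]), c(0L, 0L, 128L))
  expect_equal(unname(encode_temperature(37)[1, ]), c(128L, 0L, 0L))
  # saturation: anything below/above the anchors takes the anchor colour
  expect_equal(encode_temperature(20), encode_temperature(28))
  expect_equal(encode_temperature(40), encode_temperature(37))
  # closed-form jet oracle at a handful of positions
  jet_oracle <- function(x) {
    cl <- function(v) pmin(1, pmax(0, v))
    round(255 * c(cl(1.5 - abs(4 * x - 3)), cl(1.5 - abs(4 * x - 2)),
                  cl(1.5 - abs(4 * x - 1))))
  }
  for (x in c(0, 0.125, 0.25, 0.375, 0.5, 0.625, 0.875, 1))
    expect_equal(unname(jet_rgb(x)[1, ]), unname(jet_oracle(x)))
})

test_that("encode_frame produces the per-pixel palette image", {
  fr <- ramp_frame()
  img <- encode_frame(fr)
  expect_equal(dim(img), c(240L, 320L, 3L))
  expect_equal(img[1, 1, ], unname(encode_temperature(28)[1, ]))
  expect_equal(img[240, 320, ], unname(encode_temperature(37)[1, ]))
  # PNG round trip
  path <- withr::local_tempfile(fileext = ".png")
  write_encoded_png(img, path)
  expect_identical(read_encoded_png(path), img)
})

test_that("colour table deduplicates by averaging temperatures per colour", {
  # three temperatures, two of which share a colour level (and a
  # background level well away from both)
  spec <- colormap_spec()
  vals <- matrix(30, 240, 320)
  vals[1, 1:3] <- c(30.60, 30.61, 31.0)
  lev <- thermomap3d:::temperature_to_level(c(30, 30.60, 30.61, 31.0), spec)
  expect_equal(lev[2], lev[3])      # the construction premise
  expect_true(lev[1] != lev[2] && lev[4] != lev[2])
  tab <- build_color_table(list(thermal_frame(vals)), spec)
  r1 <- tab$temperature[abs(tab$temperature - 30.605) < 1e-9]
  expect_length(r1, 1)              # averaged row
  expect_true(any(abs(tab$temperature - 31.0) < 1e-9))
  # constant frame -> single row
  tab1 <- build_color_table(list(thermal_frame(matrix(30, 240, 320))))
  expect_equal(nrow(tab1), 1L)
  # dense ramp -> at most one row per producible colour
  expect_lte(nrow(ramp_color_table()), 256L)
  expect_error(build_color_table(list()), "at least one")
})

test_that("colour table is invariant to frame ordering and CSV round-trips", {
  set.seed(7)
  f1 <- thermal_frame(matrix(runif(240 * 320, 29, 33), 240, 320))
  f2 <- thermal_frame(matrix(runif(240 * 320, 31, 36), 240, 320))
  t12 <- build_color_table(list(f1, f2))
  t21 <- build_color_table(list(f2, f1))
  expect_equal(t12, t21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_color_table(t12, path)
  back <- read_color_table(path)
  expect_equal(back$temperature, t12$temperature)
  expect_equal(back$r, t12$r)
})

test_that("inverse model reaches the held-out MSE stopping criterion", {
  m <- train_inverse_model(ramp_color_table(), split_seed = 1L)
  expect_lte(m$test_mse, 1e-4)
  expect_gt(length(m$centers), 0)
  # training rows reproduce their tabulated temperature closely
  tab <- ramp_color_table()
  pred <- rgb_to_temperature(m, as.matrix(tab[, c("r", "g", "b")]))
  expect_lt(sqrt(mean((pred - tab$temperature)^2)), 0.02)
  expect_error(
    train_inverse_model(build_color_table(
      list(thermal_frame(matrix(30, 240, 320))))), "at least 4 rows")
  # JSON persistence round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_inverse_model(m, path)
  m2 <- read_inverse_model(path)
  rgbs <- jet_palette(colormap_spec())
  expect_equal(rgb_to_temperature(m2, rgbs), rgb_to_temperature(m, rgbs),
               tolerance = 1e-12)
})

test_that("round-trip decode stays within a palette step and is monotone", {
  spec <- colormap_spec()
  m <- train_inverse_model(ramp_color_table(), split_seed = 1L)
  pal <- jet_palette(spec)
  rec <- rgb_to_temperature(m, pal)
  truth <- palette_temperatures(spec)
  step <- (spec$t_high - spec$t_low) / spec$n_levels
  expect_lt(max(abs(rec - truth)), step)
  expect_true(all(diff(rec) >= -1e-9))   # monotone along the arc
})

test_that("blended and off-arc colours decode to finite in-range values", {
  spec <- colormap_spec()
  m <- train_inverse_model(ramp_color_table(), split_seed = 1L)
  pal <- jet_palette(spec)
  # 50/50 blends of adjacent colours land between the two levels
  # (compared against linear interpolation along the arc as oracle)
  for (i in c(10, 64, 128, 200)) {
    blend <- floor((pal[i, ] + pal[i + 1, ]) / 2)
    d <- rgb_to_temperature(m, blend)
    lo <- palette_temperatures(spec)[i] - 0.02
    hi <- palette_temperatures(spec)[i + 1] + 0.02
    expect_gte(d, lo); expect_lte(d, hi)
  }
  # arbitrary off-arc colours never fail and stay in the anchor range
  set.seed(3)
  rnd <- matrix(sample(0:255, 300, replace = TRUE), ncol = 3)
  d <- rgb_to_temperature(m, rnd)
  expect_true(all(is.finite(d)))
  expect_true(all(d >= spec$t_low & d <= spec$t_high))
  expect_error(rgb_to_temperature(structure(list(), class = "list"),
                                  c(1, 2, 3)), "not a trained")
})
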