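test_that("band integration follows the trapezoid rule", {
  s <- flat_spec(50)
  expect_equal(integrate_band(s, 400, 600), 10000)
  expect_equal(total_brightness(s), 50 * 400)
  expect_error(integrate_band(s, 500, 500), "lo < hi")
  expect_error(integrate_band(s, 600, 400), "lo < hi")

  r <- ifelse(grid301 >= 450 & grid301 <= 550, 100, 0)
  expect_equal(integrate_band(one_spec(r), 450, 550), 10000)
})

test_that("hue is the argmax wavelength with a low-wavelength tie rule", {
  expect_equal(hue_H1(one_spec(gaussian_refl(502, 30, 60))), 502)
  expect_equal(hue_H1(flat_spec(10)), 300)
  bimodal <- gaussian_refl(450, 5, 50) + gaussian_refl(650, 5, 50)
  expect_equal(hue_H1(one_spec(bimodal)), 450)
  expect_error(hue_H1(one_spec(rep(0, 401))), "no reflectance")
})

test_that("mean brightness averages the 401 grid points", {
  expect_equal(brightness_B2(flat_spec(40)), 40)
  r <- rep(0, 401)
  r[100] <- 100
  expect_equal(brightness_B2(one_spec(r)), 100 / 401)
  expect_equal(brightness_B2(one_spec((grid301 - 300) / 4)), 50)
})

test_that("fixed-band saturation matches bandwidth ratios and presets", {
  b <- band_presets()
  expect_equal(as.numeric(saturation_fixed(flat_spec(10), b$S1B)),
               110 / 400)
  r <- ifelse(grid301 >= 460 & grid301 <= 540, 30, 0)
  expect_equal(as.numeric(saturation_fixed(one_spec(r), b$S1Sc)), 1)
  full <- band_definition("full", "fixed", lo = 300, hi = 700)
  expect_equal(as.numeric(saturation_fixed(one_spec(random_spectrum()),
                                           full)), 1)
  expect_error(saturation_fixed(one_spec(rep(0, 401)), b$S1B),
               "zero total")
})

test_that("fixed-band saturation agrees with a fine-grid quadrature oracle", {
  f <- function(x) 5 + 60 * exp(-(x - 500)^2 / (2 * 30^2))
  s <- one_spec(f(grid301))
  got <- as.numeric(saturation_fixed(s, band_presets()$S1ScFull))
  oracle <- fine_grid_integral(f, 400, 600) / fine_grid_integral(f, 300, 700)
  expect_equal(got, oracle, tolerance = 1e-3)
})

test_that("peak-tracking saturation caps and truncates as specified", {
  s <- one_spec(gaussian_refl(502, 20, 50, bg = 1))
  expect_equal(as.numeric(saturation_S3(s)),
               as.numeric(saturation_S3(s, cap = 600)))

  # steeply rising spectrum peaks at 700; capping recentres the window
  # onto [550, 650], which holds far less area than the top of the rise
  mono <- one_spec(exp((grid301 - 300) / 40))
  capped <- saturation_S3(mono, cap = 600)
  expect_equal(attr(capped, "band_lo"), 550)
  expect_equal(attr(capped, "band_hi"), 650)
  uncapped <- saturation_S3(mono)
  expect_equal(attr(uncapped, "band_lo"), 650)
  expect_equal(attr(uncapped, "band_hi"), 700)
  expect_lt(as.numeric(capped), as.numeric(uncapped))

  # support strictly inside [452, 552] so the trapezoid rule sees zero
  # area outside the peak-tracking window
  r <- pmax(0, gaussian_refl(502, 25, 40) - gaussian_refl(502, 25, 40)[153])
  r[grid301 < 452 | grid301 > 552] <- 0
  expect_equal(as.numeric(saturation_S3(one_spec(r))), 1)
})

test_that("contrast saturation S8 implements the printed formula", {
  expect_equal(saturation_S8(flat_spec(25)), 0)
  # trapezoid edges of the step add half a step at each boundary
  r <- ifelse(grid301 >= 500 & grid301 <= 600, 100, 0)
  expect_equal(saturation_S8(one_spec(r)), (100 - 0) / 10100)

  # 5-segment toy spectrum against a direct max/min + trapezoid oracle
  seg <- c(rep(5, 80), rep(40, 80), rep(12, 80), rep(70, 80), rep(25, 81))
  s <- one_spec(seg)
  oracle <- (max(seg) - min(seg)) /
    (sum((seg[-1] + seg[-401])) / 2)
  expect_equal(saturation_S8(s), oracle)

  expect_equal(saturation_contrast_mean(s), (max(seg) - min(seg)) / mean(seg))
})

test_that("the metric panel is tidy, complete and deterministic", {
  s <- one_spec(gaussian_refl(500, 30, 50, bg = 2))
  p <- compute_metric_panel(s, c("H1", "S1B"))
  expect_equal(nrow(p), 2L)
  expect_equal(p$metric, c("H1", "S1B"))

  expect_equal(nrow(compute_metric_panel(s, character())), 0L)

  meta <- data.frame(individual_id = "a", sex = "M", treatment = "cold",
                     body_temperature = 23,
                     replicate = c("r1", "r2", "r3"),
                     stringsAsFactors = FALSE)
  refl <- sapply(1:3, function(i) gaussian_refl(500, 30, 40 + i, bg = 2))
  set3 <- spectrum_set(grid301, refl, meta)
  p7 <- compute_metric_panel(set3, c("S1B", "S1Sc", "S1ScFull", "S3",
                                     "S3Sc", "S8", "B2"))
  expect_equal(nrow(p7), 21L)
  expect_equal(length(unique(p7$value[p7$metric == "S1B"])), 3L)

  expect_error(compute_metric_panel(s, "nope"), "valid names")
})

test_that("custom bands load from YAML and override presets", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("green:", "  lo: 500", "  hi: 570",
               "S3Sc:", "  mode: peak_tracking", "  cap: 580"), yml)
  bands <- read_band_config(yml)
  expect_equal(bands$green$lo, 500)
  expect_equal(bands$S3Sc$cap, 580)
  s <- one_spec(rep(10, 401))
  expect_equal(as.numeric(saturation_fixed(s, bands$green)), 70 / 400)
})

test_that("saturation metrics are scale invariant and bounded", {
  set.seed(42)
  bands <- band_presets()
  for (i in 1:50) {
    r <- random_spectrum()
    s <- one_spec(r)
    s2 <- one_spec(3.7 * r)
    for (nm in c("S1B", "S1Sc", "S1ScFull")) {
      v <- as.numeric(saturation_fixed(s, bands[[nm]]))
      expect_gte(v, 0)
      expect_lte(v, 1)
      expect_equal(v, as.numeric(saturation_fixed(s2, bands[[nm]])),
                   tolerance = 1e-9)
    }
    expect_equal(as.numeric(saturation_S3(s)),
                 as.numeric(saturation_S3(s2)), tolerance = 1e-9)
    expect_equal(saturation_S8(s), saturation_S8(s2), tolerance = 1e-9)
    if (hue_H1(s) <= 600) {
      expect_identical(as.numeric(saturation_S3(s, cap = 600)),
                       as.numeric(saturation_S3(s)))
    }
  }
})

test_that("adding in-band reflectance raises a fixed metric, out-of-band lowers it", {
  set.seed(7)
  b <- band_presets()$S1Sc
  r <- random_spectrum()
  base <- as.numeric(saturation_fixed(one_spec(r), b))
  inband <- r + gaussian_refl(500, 10, 20)
  outband <- r + gaussian_refl(660, 8, 20)
  expect_gt(as.numeric(saturation_fixed(one_spec(inband), b)), base)
  expect_lt(as.numeric(saturation_fixed(one_spec(outband), b)), base)
})
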