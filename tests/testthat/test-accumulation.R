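# Ratio imaging, segmentation, size histograms and spectra.

px <- 141 / 512  # default pixel edge, um

test_that("ratio_image divides by the buffer mean and validates inputs", {
  f <- matrix(200, 8, 8)
  buf <- matrix(FALSE, 8, 8); buf[1:2, ] <- TRUE
  f[buf] <- 100
  r <- ratio_image(f, buf)
  expect_equal(unique(r[!buf]), 2.0)
  expect_equal(mean(r[buf]), 1.0)  # self-normalisation
  blob <- matrix(400, 6, 6); blob[3, 3] <- 1000
  b2 <- matrix(FALSE, 6, 6); b2[1, ] <- TRUE
  expect_equal(ratio_image(blob, b2)[3, 3], 2.5)
  expect_error(ratio_image(f, matrix(FALSE, 8, 8)), "empty")
  expect_error(ratio_image(matrix(0, 8, 8), buf), "positive")
})

test_that("region_contrast is the mean-ratio of region to buffer", {
  f <- matrix(0, 2, 2)
  f[1, 1] <- 4; f[1, 2] <- 6   # region pixels {4, 6}
  f[2, 1] <- 2; f[2, 2] <- 3   # buffer pixels {2, 3}
  region <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  buffer <- !region
  expect_equal(region_contrast(f, region, buffer), 2.0)
  expect_equal(region_contrast(f, buffer, buffer), 1.0)
  expect_error(region_contrast(f, matrix(FALSE, 2, 2), buffer), "empty")
})

test_that("segmentation thresholds, labels and filters by minimum area", {
  elig <- matrix(TRUE, 64, 64)
  # all below threshold: nothing
  expect_equal(nrow(segment_accumulations(matrix(1, 64, 64), elig,
                                          pixel_size = px)), 0L)
  # 5x5 block at ratio 2: 25 px * 0.0758 um^2 = 1.90 um^2 < 10 -> filtered
  r <- matrix(1, 64, 64); r[10:14, 10:14] <- 2
  expect_equal(nrow(segment_accumulations(r, elig, pixel_size = px)), 0L)
  # 12x12 block: 144 px -> 10.92 um^2, one record
  r2 <- matrix(1, 64, 64); r2[10:21, 10:21] <- 2
  rec <- segment_accumulations(r2, elig, pixel_size = px, worm_id = "w1")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$area, 144 * px^2, tolerance = 1e-12)
  expect_equal(rec$area, 10.92, tolerance = 1e-3)
  expect_equal(rec$mean_ratio, 2)
  expect_equal(rec$worm_id, "w1")
  # the eligible mask gates pixels
  rec2 <- segment_accumulations(r2, matrix(FALSE, 64, 64), pixel_size = px)
  expect_equal(nrow(rec2), 0L)
})

test_that("8- vs 4-connectivity controls diagonal merging", {
  r <- matrix(1, 40, 40)
  r[2:14, 2:14] <- 2      # block A
  r[15:27, 15:27] <- 2    # block B, touching A only diagonally
  elig <- matrix(TRUE, 40, 40)
  p8 <- analysis_params(min_area = 1, connectivity = 8L)
  p4 <- analysis_params(min_area = 1, connectivity = 4L)
  expect_equal(nrow(segment_accumulations(r, elig, p8, px)), 1L)
  expect_equal(nrow(segment_accumulations(r, elig, p4, px)), 2L)
})

test_that("total_area sums records and is 0 when empty", {
  expect_equal(total_area(NULL), 0)
  expect_equal(total_area(data.frame(area = numeric())), 0)
  expect_equal(total_area(data.frame(area = c(10.92, 30))), 40.92)
})

test_that("raising min_area or narrowing the band never raises total area", {
  for (s in 1:5) {
    set.seed(100 + s)
    r <- matrix(stats::runif(48 * 48, 0.8, 3.5), 48, 48)
    elig <- matrix(stats::runif(48 * 48) > 0.1, 48, 48)
    totals <- vapply(c(0.1, 0.5, 1, 2), function(ma) {
      total_area(segment_accumulations(
        r, elig, analysis_params(min_area = ma), px))
    }, 0)
    expect_true(all(diff(totals) <= 1e-12))
    narrow <- total_area(segment_accumulations(
      r, elig, analysis_params(ratio_low = 1.8, ratio_high = 2.8,
                               min_area = 0.1), px))
    wide <- total_area(segment_accumulations(
      r, elig, analysis_params(ratio_low = 1.47, ratio_high = 3.12,
                               min_area = 0.1), px))
    expect_gte(wide, narrow)
  }
})

test_that("area-contribution curve: frequency, contribution, conservation", {
  # hand fixture: areas on midpoints -> exact conservation
  prm <- analysis_params()
  cv <- area_contribution(c(30, 50, 50), n_worms = 2, prm)
  b2 <- cv[cv$bin_low == 20, ]; b3 <- cv[cv$bin_low == 40, ]
  expect_equal(b2$freq_per_worm, 0.5)
  expect_equal(b3$freq_per_worm, 1.0)
  expect_equal(b2$contribution_per_worm, 15)
  expect_equal(b3$contribution_per_worm, 50)
  expect_equal(sum(cv$contribution_per_worm), 65)  # = mean total area / worm
  # empty input -> all-zero curve
  cv0 <- area_contribution(numeric(), 3, prm)
  expect_true(all(cv0$freq_per_worm == 0))
  # contribution = freq x midpoint, everywhere
  expect_equal(cv$contribution_per_worm, cv$freq_per_worm * cv$bin_mid)
  # fraction below a cutoff
  expect_equal(contribution_fraction_below(cv, 40), 15 / 65)
  expect_equal(contribution_fraction_below(cv, 1000), 1)
})

test_that("midpoint-binning error stays within the analytic bound", {
  for (s in 1:8) {
    set.seed(200 + s)
    areas <- stats::runif(60, 10, 180)
    n_worms <- 7
    prm <- analysis_params()
    cv <- area_contribution(areas, n_worms, prm)
    integral <- sum(cv$contribution_per_worm)
    exact <- sum(areas) / n_worms
    bound <- nrow(cv) * (prm$bin_width / 2) * max(cv$freq_per_worm)
    expect_lte(abs(integral - exact), bound + 1e-9)
  }
})

test_that("normalized spectrum peaks at 1 and validates the stack", {
  mk <- function(v, w) {
    f <- matrix(v, 4, 4); attr(f, "wavenumber") <- w; f
  }
  region <- matrix(TRUE, 4, 4)
  sp <- normalized_spectrum(list(mk(2, 2800), mk(4, 2900), mk(8, 3000)),
                            region)
  expect_equal(sp$intensity, c(0.25, 0.5, 1.0))
  sp2 <- normalized_spectrum(list(mk(5, 2800), mk(5, 2900)), region)
  expect_equal(sp2$intensity, c(1, 1))
  expect_error(normalized_spectrum(list(mk(1, 2900), mk(2, 2800)), region),
               "increasing")
  expect_error(normalized_spectrum(list(mk(1, 2800), mk(2, 2800)), region),
               "duplicate|increasing")
  # synthetic CH-stretch stack peaks at the lipid band
  st <- render_band_stack(strain_preset("N2"), seed = 3)
  spec <- normalized_spectrum(st$frames, st$region)
  expect_equal(spec$wavenumber[which.max(spec$intensity)], 2845)
  expect_equal(max(spec$intensity), 1)
})

test_that("N2 synthetic cohort puts the dominant size class in 20-60 um^2", {
  p <- strain_preset("N2")
  prm <- analysis_params()
  areas <- c(); n_worms <- 10
  for (i in seq_len(n_worms)) {
    ws <- render_worm(p, seed = 500 + i, components = "accumulations",
                      gfp = FALSE)
    q <- quantify_accumulations(ws, prm)
    areas <- c(areas, q$records$area)
  }
  cv <- area_contribution(areas, n_worms, prm)
  dom <- cv$bin_low[which.max(cv$freq_per_worm)]
  expect_true(dom >= 20 && dom < 60)
})
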