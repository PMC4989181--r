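# Integrated per-oocyte signals, carrier-lipid regression, geometry.

test_that("integrated CARS follows the sqrt-of-subtracted formula", {
  f <- matrix(1, 4, 4)
  oo <- matrix(FALSE, 4, 4); oo[1, 1:4] <- TRUE
  nuc <- matrix(FALSE, 4, 4); nuc[1, 4] <- TRUE  # single pixel, value 1
  f[1, 1:4] <- c(5, 5, 10, 1)
  # B = 1; sqrt(4) + sqrt(4) + sqrt(9) + sqrt(0) = 7
  expect_equal(integrated_cars(f, oo, nuc), 7)
  # uniform oocyte at the background level gives 0
  expect_equal(integrated_cars(matrix(3, 4, 4), oo, nuc), 0)
  # doubling the pixel count at fixed contrast doubles the statistic
  f2 <- matrix(1, 4, 8)
  oo2 <- matrix(FALSE, 4, 8); oo2[1:2, 1:4] <- TRUE
  nuc2 <- matrix(FALSE, 4, 8); nuc2[2, 4] <- TRUE
  f2[oo2] <- 5; f2[nuc2] <- 1
  oo1 <- oo2 & rbind(matrix(TRUE, 1, 8), matrix(FALSE, 3, 8))
  base <- sum(sqrt(pmax(f2[oo1] - 1, 0)))
  expect_equal(integrated_cars(f2, oo2, nuc2),
               2 * base - 2)  # nucleus pixel swaps a sqrt(4) for sqrt(0)
  expect_error(integrated_cars(f, oo, matrix(FALSE, 4, 4)), "empty")
  badnuc <- matrix(FALSE, 4, 4); badnuc[3, 3] <- TRUE
  expect_error(integrated_cars(f, oo, badnuc), "inside")
})

test_that("increasing a cytoplasmic pixel never decreases integrated CARS", {
  set.seed(42)
  f <- matrix(stats::runif(64, 0, 100), 8, 8)
  oo <- matrix(FALSE, 8, 8); oo[2:7, 2:7] <- TRUE
  nuc <- matrix(FALSE, 8, 8); nuc[4:5, 4:5] <- TRUE
  base <- integrated_cars(f, oo, nuc)
  for (i in 1:10) {
    idx <- which(oo & !nuc)[sample.int(sum(oo & !nuc), 1)]
    f2 <- f; f2[idx] <- f2[idx] + stats::runif(1, 0, 50)
    expect_gte(integrated_cars(f2, oo, nuc), base)
  }
})

test_that("integrated GFP is the clamped background-subtracted sum", {
  g <- matrix(2, 3, 3)
  oo <- matrix(FALSE, 3, 3); oo[1, 1:2] <- TRUE
  neg <- matrix(FALSE, 3, 3); neg[3, ] <- TRUE
  g[1, 1:2] <- c(3, 7)
  expect_equal(integrated_gfp(g, oo, neg), 6)   # (3-2) + (7-2)
  expect_equal(integrated_gfp(matrix(2, 3, 3), oo, neg), 0)
  g0 <- g; g0[neg] <- 0
  expect_equal(integrated_gfp(g0, oo, neg), 10)  # zero background: plain sum
})

test_that("delta signals are offsets against the -5 oocyte", {
  m <- data.frame(position = c(-5L, -3L, -1L),
                  integrated_cars = c(10, 18, 25),
                  integrated_gfp = c(2, 4, 9))
  d <- delta_signals(m)
  expect_equal(d$delta_cars, c(0, 8, 15))
  expect_equal(d$delta_gfp, c(0, 2, 7))
  same <- data.frame(position = -5:-1, integrated_cars = rep(7, 5))
  expect_true(all(delta_signals(same)$delta_cars == 0))
  expect_error(delta_signals(data.frame(position = -4:-1,
                                        integrated_cars = 1:4)), "-5")
})

test_that("carrier-lipid fit matches the closed-form OLS oracle", {
  # exact line
  fit <- carrier_lipid_fit(0:3, 2 * (0:3) + 5)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 5)
  expect_equal(fit$r_squared, 1)
  # zero-covariance points
  fit0 <- carrier_lipid_fit(c(0, 1, 2), c(0, 1, 0))
  expect_equal(fit0$r_squared, 0, tolerance = 1e-12)
  # random small designs against the oracle
  for (s in 1:20) {
    set.seed(300 + s)
    n <- sample(3:10, 1)
    x <- stats::rnorm(n); y <- 1.5 * x + stats::rnorm(n, sd = 0.3)
    fit <- carrier_lipid_fit(x, y)
    orc <- ols_oracle(x, y)
    expect_equal(fit$slope, orc$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-9)
    expect_equal(fit$r_squared, orc$r_squared, tolerance = 1e-9)
  }
  expect_error(carrier_lipid_fit(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("cylinder volume formula and its degree-3 homogeneity", {
  expect_equal(oocyte_volume(50.9, 22.4), pi * 50.9 * 11.2^2)
  expect_equal(oocyte_volume(50.9, 22.4), 2.006e4, tolerance = 1e-3)
  expect_equal(oocyte_volume(1, 2), pi)
  expect_equal(oocyte_volume(3 * 50.9, 3 * 22.4),
               27 * oocyte_volume(50.9, 22.4))
  expect_error(oocyte_volume(0, 5), "positive")
})

test_that("mask axes: rectangles and disks are exact, rotation-invariant", {
  m <- matrix(FALSE, 60, 60); m[21:40, 11:50] <- TRUE  # 40 x 20 px
  ax <- axes_from_mask(m, 1)
  expect_equal(unname(ax["length"]), 40, tolerance = 0.1)
  expect_equal(unname(ax["width"]), 20, tolerance = 0.1)
  # disk of radius r -> length = width = 2r
  d <- matrix(FALSE, 61, 61)
  ctr <- 31; r <- 14
  for (i in 1:61) for (j in 1:61)
    if ((i - ctr)^2 + (j - ctr)^2 <= r^2) d[i, j] <- TRUE
  axd <- axes_from_mask(d, 1)
  expect_equal(unname(axd["length"]), 2 * r, tolerance = 0.06)
  expect_equal(unname(axd["width"]), 2 * r, tolerance = 0.06)
  # rotated rectangle: same axes within pixelation error
  th <- 30 * pi / 180
  rot <- matrix(FALSE, 80, 80)
  for (i in 1:80) for (j in 1:80) {
    x <- (j - 40.5) * cos(th) + (i - 40.5) * sin(th)
    y <- -(j - 40.5) * sin(th) + (i - 40.5) * cos(th)
    if (abs(x) <= 20 && abs(y) <= 10) rot[i, j] <- TRUE
  }
  axr <- axes_from_mask(rot, 1)
  expect_equal(unname(axr["length"]), 40, tolerance = 0.05 * 40)
  expect_equal(unname(axr["width"]), 20, tolerance = 0.05 * 20)
  expect_error(axes_from_mask(matrix(FALSE, 3, 3), 1), "empty")
})

test_that("lipid table normalisation scales means and SEMs by the reference", {
  tab <- data.frame(strain = c("N2", "N2", "fat-2"),
                    position = c(-1L, -2L, -1L),
                    mean = c(200, 120, 150), sem = c(10, 8, 9))
  out <- normalize_lipid(tab)
  expect_equal(out$mean[1], 1)
  expect_equal(out$mean[3], 0.75)
  expect_equal(out$sem, c(10, 8, 9) / 200)
  allsame <- data.frame(strain = "N2", position = -1L, mean = 5)
  expect_equal(normalize_lipid(allsame)$mean, 1)
  expect_error(normalize_lipid(tab, "fat-3"), "not present")
})

test_that("noiseless renders recover the planted integrated-CARS target
           exactly and the planted contrast to machine precision", {
  p <- strain_preset("N2")
  ws <- render_worm(p, seed = 77, noise_cv = 0, texture_amp = 0)
  f <- ws$bands[["2845"]]
  for (k in -5:-1) {
    oo <- region_mask(ws, "oocyte", k)
    nuc <- region_mask(ws, "nucleus", k)
    tr <- ws$truth$oocytes[ws$truth$oocytes$position == k, ]
    expect_equal(integrated_cars(f, oo, nuc), tr$cars_target,
                 tolerance = 1e-12)
  }
  buf <- region_mask(ws, "buffer_roi")
  tr <- ws$truth$accumulations
  for (i in seq_len(nrow(tr)))
    expect_equal(region_contrast(f, ws$truth$accumulation_masks[[i]], buf),
                 tr$contrast_realized[i], tolerance = 1e-12)
})
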