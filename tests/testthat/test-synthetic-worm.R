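# Generator: presets, deterministic rendering, ground-truth consistency.

test_that("presets store the strain parameters and reject unknown names", {
  n2 <- strain_preset("N2")
  expect_equal(n2$ovulation_rate_true, 2.5)
  expect_equal(unname(n2$ld_contrast["mean"]), 4.39)
  expect_equal(unname(n2$acc_contrast_large["mean"]), 2.53)
  expect_equal(unname(n2$acc_contrast_small["mean"]), 1.69)
  f2 <- strain_preset("fat-2")
  expect_equal(f2$ovulation_rate_true, 0.5)
  # fat-2 carries 75% of the N2 lipid content in the -1/-2 oocytes
  expect_equal(unname(f2$oocyte_lipid_profile[c("-2", "-1")] /
                        n2$oocyte_lipid_profile[c("-2", "-1")]),
               c(0.75, 0.75))
  # every preset satisfies the 50% step into the -1 oocyte and is monotone
  for (s in strain_names()) {
    lp <- strain_preset(s)$oocyte_lipid_profile
    expect_equal(unname(lp["-1"] / lp["-2"]), 1.5, tolerance = 1e-12)
    expect_true(all(diff(lp) >= 0))
  }
  expect_error(strain_preset("fat-9"), "unknown strain")
})

test_that("rendering is bit-identical for a fixed seed and leaves RNG alone", {
  p <- strain_preset("N2")
  set.seed(123); before <- runif(1)
  a <- render_worm(p, seed = 5)
  b <- render_worm(p, seed = 5)
  expect_identical(a$bands, b$bands)
  expect_identical(a$gfp, b$gfp)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth$accumulations, b$truth$accumulations)
  set.seed(123); expect_identical(runif(1), before)
})

test_that("rendered frames respect the 12-bit range and mask invariants", {
  p <- strain_preset("fat-1")
  ws <- render_worm(p, seed = 9)
  for (bnd in ws$bands) {
    expect_true(all(bnd >= 0 & bnd <= 4095))
    expect_true(all(bnd == round(bnd)))
  }
  expect_true(all(ws$gfp >= 0 & ws$gfp <= 4095))
  expect_true(any(region_mask(ws, "buffer_roi")))
  # nucleus inside its oocyte, oocytes mutually exclusive
  for (k in -5:-1) {
    oo <- region_mask(ws, "oocyte", k)
    nuc <- region_mask(ws, "nucleus", k)
    expect_true(all(oo[nuc]))
  }
  oo_all <- sapply(-5:-1, function(k) sum(region_mask(ws, "oocyte", k)))
  tot <- sum(sapply(-5:-1, function(k) region_mask(ws, "oocyte", k)))
  expect_equal(tot, sum(oo_all))  # no overlap between oocytes
})

test_that("a saturating profile is rejected", {
  p <- strain_preset("N2")
  p$buffer_level <- 1500  # 4.39 * 1500 > 4095
  expect_error(render_worm(p, seed = 1), "saturate")
})

test_that("noiseless uniform blobs render at exactly contrast x buffer", {
  fld <- render_blob_field(30, contrast_mean = 2.0, contrast_sd = 0,
                           shape = "disk", seed = 2, buffer_level = 500,
                           noise_cv = 0)
  expect_true(all(fld$frame[fld$masks[[1]]] == 1000))
  expect_true(all(fld$frame[fld$buffer_roi] == 500))
})

test_that("measured blob contrast matches the planted statistics (MC)", {
  # 50 blobs at the large-accumulation preset, noise CV 0.05
  fld <- render_blob_field(rep(60, 50), 2.53, 0.59, "polygon", seed = 31,
                           noise_cv = 0.05, dim = 760)
  cr <- vapply(fld$masks,
               function(m) region_contrast(fld$frame, m, fld$buffer_roi), 0)
  se <- sd(cr) / sqrt(length(cr))
  expect_lt(abs(mean(cr) - 2.53), 2 * se + 0.02)
})

test_that("noiseless render round-trips: planted areas recoverable by
           thresholding at the planted contrast", {
  p <- strain_preset("N2")
  ws <- render_worm(p, seed = 21, noise_cv = 0, texture_amp = 0,
                    components = "accumulations", gfp = FALSE)
  ratio <- ratio_image(ws$bands[["2845"]], region_mask(ws, "buffer_roi"))
  tr <- ws$truth$accumulations
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    cc <- tr$contrast_realized[i]
    recov <- sum(ratio >= cc - 1e-9 & ratio <= cc + 1e-9 &
                   ws$truth$accumulation_masks[[i]])
    expect_equal(recov * ws$pixel_size^2, tr$area_um2[i], tolerance = 1e-12)
  }
})

test_that("reproduction assay simulation is seeded and internally consistent", {
  p <- strain_preset("N2")
  a <- simulate_reproduction(p, 50, 6, seed = 4)
  b <- simulate_reproduction(p, 50, 6, seed = 4)
  expect_identical(a, b)
  expect_true(all(a$eggs_laid >= 0 & a$final_retained >= 0))
  # zero ovulation rate: nothing new appears
  p0 <- p; p0$ovulation_rate_true <- 0
  z <- simulate_reproduction(p0, 30, 6, seed = 8)
  expect_true(all(z$eggs_laid + z$final_retained - z$initial_retained == 0))
})

test_that("assay cohort recovers the planted ovulation rate within 2 SE", {
  p <- strain_preset("N2")
  a <- simulate_reproduction(p, 200, 6, seed = 14)
  r <- ovulation_rate(a$eggs_laid, a$final_retained, a$initial_retained,
                      a$elapsed, a$gonad_arms)
  # Poisson-based SE of the mean rate estimate
  se <- sqrt(2.5 / (200 * 2 * 6))
  expect_lt(abs(mean(r) - 2.5), 2 * se)
})
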