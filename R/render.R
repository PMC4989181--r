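# Synthetic worm-scene renderer.
#
# Scenes are 12-bit multi-band rasters (stored as numeric matrices of integer
# counts in [0, 4095]) emulating CARS frames at the protein (~1665 cm^-1),
# non-resonant (~2200 cm^-1) and lipid (~2845 cm^-1) Raman bands, plus an
# optional two-photon GFP channel.  A single 8-bit label raster carries the
# region classes; ground truth (per-blob contrasts and areas, per-oocyte
# lipid targets and geometry) is returned alongside.

#' Region label codes used in synthetic label rasters
#'
#' Oocytes at positions -5..-1 carry codes 10..14 and their nuclei 20..24
#' (the nucleus code overwrites the oocyte code in the raster; accessors
#' reassemble the full oocyte mask).
#'
#' @return Named integer vector of label codes.
#' @export
label_codes <- function() {
  c(background = 0L, intestine = 1L, embryo = 2L, body_wall = 3L,
    hypodermis = 4L, pseudocoelom_eligible = 5L, buffer_roi = 6L,
    gfp_negative_roi = 7L,
    stats::setNames(10:14, paste0("oocyte_", -5:-1)),
    stats::setNames(20:24, paste0("nucleus_", -5:-1)))
}

# Evaluate `code` with the RNG seeded at `seed`, restoring prior RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Multiplicative speckle: I * (1 + cv Z), then integer quantisation and
# clipping to the 12-bit range.
apply_noise <- function(frame, noise_cv) {
  if (noise_cv > 0)
    frame <- frame * (1 + noise_cv * stats::rnorm(length(frame)))
  m <- round(frame)
  m[m < 0] <- 0
  m[m > 4095] <- 4095
  matrix(m, nrow(frame))
}

dilate8 <- function(mask) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  out[-1, ] <- out[-1, ] | mask[-nr, ]
  out[-nr, ] <- out[-nr, ] | mask[-1, ]
  out[, -1] <- out[, -1] | mask[, -nc]
  out[, -nc] <- out[, -nc] | mask[, -1]
  out[-1, -1] <- out[-1, -1] | mask[-nr, -nc]
  out[-nr, -nc] <- out[-nr, -nc] | mask[-1, -1]
  out[-1, -nc] <- out[-1, -nc] | mask[-nr, -1]
  out[-nr, -1] <- out[-nr, -1] | mask[-1, -nc]
  out
}

new_worm_image_set <- function(bands, gfp, labels, pixel_size, truth,
                               strain, seed) {
  structure(list(bands = bands, gfp = gfp, labels = labels,
                 pixel_size = pixel_size, truth = truth,
                 strain = strain, seed = seed),
            class = "worm_image_set")
}

#' @export
print.worm_image_set <- function(x, ...) {
  cat("<worm_image_set> strain ", x$strain, ", seed ", x$seed, "\n", sep = "")
  cat("  ", nrow(x$labels), " x ", ncol(x$labels), " px, ",
      signif(x$pixel_size, 4), " um/px; bands: ",
      paste(names(x$bands), collapse = ", "),
      if (!is.null(x$gfp)) " + GFP", "\n", sep = "")
  cat("  planted accumulations: ", nrow(x$truth$accumulations),
      ", lipid droplets: ", nrow(x$truth$lipid_droplets), "\n", sep = "")
  invisible(x)
}

#' Extract a region mask from a worm image set
#'
#' @param ws A `worm_image_set`.
#' @param class Region class name (see [label_codes()]), e.g. `"buffer_roi"`,
#'   `"oocyte"`, `"nucleus"`, `"pseudocoelom_eligible"`.
#' @param position Oocyte position in -5..-1, required for `"oocyte"` /
#'   `"nucleus"`.
#' @param include_nucleus For `"oocyte"`, whether the nucleus sub-region is
#'   part of the mask (default `TRUE`, as the nucleus is inside the oocyte).
#' @return Logical matrix.
#' @export
region_mask <- function(ws, class, position = NULL, include_nucleus = TRUE) {
  lc <- label_codes()
  if (class %in% c("oocyte", "nucleus")) {
    if (is.null(position) || !position %in% -5:-1)
      stop("position in -5..-1 required for oocyte/nucleus masks")
    if (class == "nucleus")
      return(ws$labels == lc[[paste0("nucleus_", position)]])
    m <- ws$labels == lc[[paste0("oocyte_", position)]]
    if (include_nucleus)
      m <- m | (ws$labels == lc[[paste0("nucleus_", position)]])
    return(m)
  }
  if (!class %in% names(lc)) stop("unknown region class: ", class)
  ws$labels == lc[[class]]
}

# Place a mask generator on free space: sample candidate centres within
# `eligible`, reject overlaps with `occupied` (dilated, so 8-connected
# components stay distinct).  Returns the mask or NULL after `tries`.
place_component <- function(dim, eligible_idx, occupied, make_mask,
                            tries = 40L) {
  blocked <- dilate8(occupied)
  for (i in seq_len(tries)) {
    ctr <- eligible_idx[sample.int(nrow(eligible_idx), 1L), ]
    m <- make_mask(ctr[1], ctr[2])
    if (!any(m & blocked)) return(m)
  }
  NULL
}

#' Render a synthetic worm image set
#'
#' Draws a full scene for one worm of the given strain: polygonal yolk
#' accumulations in the pseudocoelomic space with per-blob contrast sampled
#' from the strain's large/small statistics, hypodermal lipid droplets, a
#' bright intestine and embryos (excluded regions), a body-wall rim, staged
#' oocytes -5..-1 with nuclei, a uniform surrounding-buffer ROI, and an
#' optional GFP channel in which the yolk-carrier signal is linearly coupled
#' to oocyte lipid content.
#'
#' The lipid-band intensity of oocyte `k` is chosen so that the integrated
#' CARS statistic (sum of square roots of nucleus-background-subtracted
#' counts over the oocyte) equals `cars_gain` times the worm's lipid content
#' at `k`; the ground truth stores the realised (post-quantisation) target.
#' Noise is multiplicative Gaussian with the profile's CV, followed by
#' integer quantisation and clipping to [0, 4095].  Output is deterministic
#' for a fixed seed.
#'
#' @param profile A `strain_profile` from [strain_preset()].
#' @param seed Integer seed.
#' @param dim Raster edge in pixels (square frame).
#' @param fov_um Field of view edge in micrometres.
#' @param components Scene parts to draw, any of `"accumulations"`, `"lds"`,
#'   `"oocytes"`, `"organs"`.
#' @param gfp Render the GFP (TPEF) channel?
#' @param noise_cv Override the profile's noise CV (e.g. 0 for noiseless
#'   reference renders).
#' @param texture_amp Amplitude of the shared within-blob texture (0 gives
#'   perfectly uniform blobs).
#' @return A `worm_image_set`: band matrices (names `"1665"`, `"2200"`,
#'   `"2845"`), optional `gfp` matrix, `labels` raster, `pixel_size`, and a
#'   `truth` list with `accumulations`, `lipid_droplets` and `oocytes`
#'   data frames.
#' @export
render_worm <- function(profile, seed,
                        dim = 512L, fov_um = 141,
                        components = c("accumulations", "lds", "oocytes",
                                       "organs"),
                        gfp = TRUE,
                        noise_cv = NULL, texture_amp = NULL) {
  stopifnot(dim >= 512L)  # scene layout is designed for >= 512 px frames
  validate_strain_profile(profile)
  im <- imaging_constants()
  if (is.null(noise_cv)) noise_cv <- profile$noise_cv
  if (is.null(texture_amp)) texture_amp <- im$texture_amp
  if (max(profile$acc_contrast_large["mean"] + 3 * profile$acc_contrast_large["sd"],
          profile$ld_contrast["mean"] + 3 * profile$ld_contrast["sd"]) *
      profile$buffer_level > 4095)
    stop("profile contrast x buffer_level would saturate the 12-bit range")

  px <- fov_um / dim
  lc <- label_codes()
  with_seed(seed, {
    d <- c(dim, dim)
    clean <- matrix(profile$buffer_level, dim, dim)  # lipid band, pre-noise
    labels <- matrix(0L, dim, dim)

    # --- fixed anatomy -------------------------------------------------
    wall <- matrix(FALSE, dim, dim)
    wall[c(1:6, (dim - 5):dim), ] <- TRUE
    wall[, c(1:6, (dim - 5):dim)] <- TRUE
    labels[wall] <- lc[["body_wall"]]
    clean[wall] <- 1.2 * profile$buffer_level

    buf <- matrix(FALSE, dim, dim)
    buf[10:60, 10:130] <- TRUE
    labels[buf] <- lc[["buffer_roi"]]

    gfpneg <- matrix(FALSE, dim, dim)
    gfpneg[10:60, 380:500] <- TRUE
    labels[gfpneg] <- lc[["gfp_negative_roi"]]

    occupied <- wall | buf | gfpneg
    truth <- list()

    if ("organs" %in% components) {
      intest <- matrix(FALSE, dim, dim)
      intest[75:125, 150:470] <- TRUE
      labels[intest] <- lc[["intestine"]]
      tx <- smooth_texture(intest)
      clean[intest] <- 3.0 * profile$buffer_level * (1 + 0.2 * tx)
      emb <- ellipse_mask(d, 100, 60, 28, 16) & !occupied & !intest
      labels[emb] <- lc[["embryo"]]
      clean[emb] <- 2.2 * profile$buffer_level
      occupied <- occupied | intest | emb
    }

    # --- oocytes ---------------------------------------------------------
    oo_truth <- NULL
    if ("oocytes" %in% components) {
      worm_scale <- max(0.5, stats::rnorm(1, 1, 0.10))
      len1 <- max(10, stats::rnorm(1, profile$oocyte_length_dist["mean"],
                                   profile$oocyte_length_dist["sd"]))
      wid1 <- max(5, stats::rnorm(1, profile$oocyte_width_dist["mean"],
                                  profile$oocyte_width_dist["sd"]))
      scale_by_pos <- c(`-5` = 0.60, `-4` = 0.70, `-3` = 0.80,
                        `-2` = 0.90, `-1` = 1.00)
      centers <- list(`-5` = c(200, 80), `-4` = c(200, 225), `-3` = c(200, 390),
                      `-2` = c(345, 120), `-1` = c(345, 350))
      rows <- lapply(as.character(-5:-1), function(pk) {
        k <- as.integer(pk)
        sc <- scale_by_pos[[pk]]
        a <- (len1 * sc / 2) / px   # semi-major, cols
        b <- (wid1 * sc / 2) / px   # semi-minor, rows
        ctr <- centers[[pk]]
        oo <- ellipse_mask(d, ctr[1], ctr[2], a, b)
        nuc <- disk_mask(d, ctr[1], ctr[2], 0.3 * b)
        nuc <- nuc & oo
        content <- unname(profile$oocyte_lipid_profile[pk]) * worm_scale
        n_cyto <- sum(oo & !nuc)
        delta <- (content * im$cars_gain / n_cyto)^2
        i_cyto <- im$nucleus_level + delta
        if (i_cyto > 4095)
          stop("oocyte lipid rendering would saturate the 12-bit range")
        clean[oo & !nuc] <<- i_cyto
        clean[nuc] <<- im$nucleus_level
        labels[oo] <<- lc[[paste0("oocyte_", k)]]
        labels[nuc] <<- lc[[paste0("nucleus_", k)]]
        occupied <<- occupied | oo
        # realised integrated-CARS target after quantisation
        delta_q <- round(i_cyto) - im$nucleus_level
        data.frame(position = k, lipid_content = content,
                   cars_target = n_cyto * sqrt(max(delta_q, 0)),
                   carrier = max(0, (content - profile$carrier_offset *
                                       worm_scale) / profile$carrier_slope),
                   length_um = len1 * sc, width_um = wid1 * sc,
                   n_pixels = sum(oo), n_cyto = n_cyto)
      })
      oo_truth <- do.call(rbind, rows)
    }
    truth$oocytes <- oo_truth

    # --- hypodermis + lipid droplets ------------------------------------
    hyp <- matrix(FALSE, dim, dim)
    hyp[440:(dim - 6), 7:(dim - 6)] <- TRUE
    hyp <- hyp & !occupied
    labels[hyp] <- lc[["hypodermis"]]
    clean[hyp] <- 1.1 * profile$buffer_level
    ld_truth <- data.frame()
    if ("lds" %in% components) {
      n_ld <- stats::rpois(1, 10)
      hyp_idx <- which(hyp & !dilate8(!hyp), arr.ind = TRUE)
      occ_ld <- !hyp
      ld_rows <- list()
      for (i in seq_len(n_ld)) {
        r_um <- stats::runif(1, 0.8, 1.6)
        m <- place_component(d, hyp_idx, occ_ld,
                             function(r, c) disk_mask(d, r, c, r_um / px))
        if (is.null(m)) next
        cc <- stats::rnorm(1, profile$ld_contrast["mean"],
                           profile$ld_contrast["sd"])
        cc <- min(max(cc, 1), 4095 / profile$buffer_level)
        vals <- cc * profile$buffer_level
        if (texture_amp > 0 && sum(m) > 4)
          vals <- vals * (1 + texture_amp * smooth_texture(m, 3L))
        clean[m] <- vals
        occ_ld <- occ_ld | m
        ld_rows[[length(ld_rows) + 1L]] <- data.frame(
          id = length(ld_rows) + 1L, contrast = cc,
          area_um2 = sum(m) * px^2,
          contrast_realized = mean(round(clean[m])) / profile$buffer_level)
      }
      if (length(ld_rows)) ld_truth <- do.call(rbind, ld_rows)
    }
    occupied <- occupied | hyp
    truth$lipid_droplets <- ld_truth

    # --- pseudocoelomic accumulations -----------------------------------
    interior <- matrix(FALSE, dim, dim)
    interior[8:(dim - 7), 8:(dim - 7)] <- TRUE
    eligible <- interior & !dilate8(dilate8(occupied)) & !hyp
    labels[eligible & labels == 0L] <- lc[["pseudocoelom_eligible"]]
    acc_truth <- data.frame()
    acc_masks <- list()
    if ("accumulations" %in% components) {
      n_acc <- stats::rpois(1, profile$acc_count_lambda)
      el_idx <- which(eligible, arr.ind = TRUE)
      occ_acc <- !eligible
      acc_rows <- list()
      for (i in seq_len(n_acc)) {
        repeat {
          area_um2 <- stats::rlnorm(1, profile$acc_size_dist["meanlog"],
                                    profile$acc_size_dist["sdlog"])
          if (area_um2 >= profile$acc_size_dist["min"] &&
              area_um2 <= profile$acc_size_dist["max"]) break
        }
        poly <- random_convex_polygon(area_um2 / px^2)
        m <- place_component(d, el_idx, occ_acc,
                             function(r, c) rasterize_polygon(d, r, c, poly))
        if (is.null(m)) next
        big <- area_um2 >= 40
        cs <- if (big) profile$acc_contrast_large else profile$acc_contrast_small
        cc <- max(1, stats::rnorm(1, cs["mean"], cs["sd"]))
        vals <- cc * profile$buffer_level
        if (texture_amp > 0 && sum(m) > 4)
          vals <- vals * (1 + texture_amp * smooth_texture(m))
        clean[m] <- vals
        occ_acc <- occ_acc | m
        idx <- which(m, arr.ind = TRUE)
        acc_masks[[length(acc_rows) + 1L]] <- m
        acc_rows[[length(acc_rows) + 1L]] <- data.frame(
          id = length(acc_rows) + 1L,
          class = if (big) "large" else "small",
          contrast = cc,
          contrast_realized = mean(round(clean[m])) / profile$buffer_level,
          area_um2 = sum(m) * px^2,
          centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]))
      }
      if (length(acc_rows)) acc_truth <- do.call(rbind, acc_rows)
    }
    truth$accumulations <- acc_truth
    truth$accumulation_masks <- acc_masks

    # --- band synthesis, noise, quantisation ----------------------------
    base <- matrix(profile$buffer_level, dim, dim)
    bands <- list(
      "1665" = base + im$protein_band_fraction * (clean - base),
      "2200" = base + 0.05 * (clean - base),
      "2845" = clean
    )
    bands <- lapply(bands, apply_noise, noise_cv = noise_cv)
    for (w in names(bands)) attr(bands[[w]], "wavenumber") <- as.numeric(w)

    gfp_frame <- NULL
    if (gfp) {
      g <- matrix(im$gfp_background, dim, dim)
      if (!is.null(oo_truth)) {
        for (k in -5:-1) {
          oo <- labels == lc[[paste0("oocyte_", k)]] |
            labels == lc[[paste0("nucleus_", k)]]
          row <- oo_truth[oo_truth$position == k, ]
          g[oo] <- g[oo] + row$carrier * im$gfp_gain / row$n_pixels
        }
      }
      gfp_frame <- apply_noise(g, noise_cv)
    }

    new_worm_image_set(bands, gfp_frame, labels, px, truth,
                       profile$strain_name, seed)
  })
}

#' Render a grid of isolated blobs on a uniform buffer
#'
#' A calibration scene: convex polygonal blobs (or disks) of stated areas are
#' laid out on a non-overlapping grid over a uniform buffer, with a buffer
#' ROI strip at the top.  Used for contrast-recovery and detection-limit
#' experiments where full worm anatomy is unnecessary.
#'
#' @param areas_um2 Vector of target blob areas. The planted area recorded in
#'   the truth table is the realised rasterised mask area.
#' @param contrast_mean,contrast_sd Per-blob contrast distribution
#'   (`contrast_sd = 0` fixes the contrast).
#' @param shape `"polygon"` or `"disk"`.
#' @param seed Integer seed.
#' @param dim,fov_um Raster geometry as in [render_worm()].
#' @param buffer_level Buffer plateau in counts.
#' @param noise_cv Multiplicative noise CV.
#' @param texture_amp Within-blob texture amplitude.
#' @return List with `frame` (lipid-band matrix), `buffer_roi` mask,
#'   `masks` (list of per-blob truth masks), `truth` data frame and
#'   `pixel_size`.
#' @export
render_blob_field <- function(areas_um2, contrast_mean, contrast_sd = 0,
                              shape = c("polygon", "disk"), seed,
                              dim = 512L, fov_um = 141, buffer_level = 400,
                              noise_cv = 0.05, texture_amp = 0) {
  shape <- match.arg(shape)
  px <- fov_um / dim
  max_r <- 0.95 * sqrt(max(areas_um2) / px^2) + 2
  cell <- ceiling(2 * max_r + 4)
  top <- 34L
  ncols <- (dim - 8L) %/% cell
  nrows <- (dim - top - 4L) %/% cell
  if (length(areas_um2) > nrows * ncols)
    stop("too many blobs for one frame: capacity ", nrows * ncols)
  with_seed(seed, {
    d <- c(dim, dim)
    frame <- matrix(buffer_level, dim, dim)
    buf <- matrix(FALSE, dim, dim)
    buf[4:28, 4:(dim - 4)] <- TRUE
    masks <- vector("list", length(areas_um2))
    rows <- vector("list", length(areas_um2))
    for (i in seq_along(areas_um2)) {
      gi <- (i - 1L) %/% ncols
      gj <- (i - 1L) %% ncols
      crow <- top + gi * cell + cell / 2
      ccol <- 4 + gj * cell + cell / 2
      a_px <- areas_um2[i] / px^2
      m <- if (shape == "disk")
        disk_mask(d, crow, ccol, sqrt(a_px / pi))
      else
        rasterize_polygon(d, crow, ccol, random_convex_polygon(a_px))
      cc <- max(1, stats::rnorm(1, contrast_mean, contrast_sd))
      if (cc * buffer_level > 4095)
        stop("contrast x buffer_level would saturate the 12-bit range")
      vals <- cc * buffer_level
      if (texture_amp > 0 && sum(m) > 4)
        vals <- vals * (1 + texture_amp * smooth_texture(m))
      frame[m] <- vals
      masks[[i]] <- m
      rows[[i]] <- data.frame(
        id = i, target_area_um2 = areas_um2[i],
        planted_area_um2 = sum(m) * px^2, contrast = cc,
        contrast_realized = mean(round(frame[m])) / buffer_level)
    }
    frame <- apply_noise(frame, noise_cv)
    attr(frame, "wavenumber") <- 2845
    list(frame = frame, buffer_roi = buf, masks = masks,
         truth = do.call(rbind, rows), pixel_size = px)
  })
}

#' Render a CARS band stack across the CH-stretch region
#'
#' Produces one frame per wavenumber for a single lipid-rich blob on uniform
#' buffer.  The blob's contrast follows a Lorentzian CH2-stretch line shape
#' peaked at 2845 cm^-1 with a weaker CH3 shoulder near 2930 cm^-1, so the
#' normalised spectrum of the blob region peaks at the lipid band.
#'
#' @param profile A `strain_profile` (supplies the peak contrast and noise).
#' @param wavenumbers Increasing wavenumbers (cm^-1), typically in
#'   2800-3050.
#' @param seed Integer seed.
#' @param dim Frame edge in pixels (small frames suffice).
#' @return List with `frames` (list of matrices, wavenumber attribute set),
#'   `wavenumbers`, and `region` (blob mask).
#' @export
render_band_stack <- function(profile, wavenumbers = seq(2800, 3050, by = 5),
                              seed = 1L, dim = 96L) {
  stopifnot(length(wavenumbers) >= 2, !is.unsorted(wavenumbers, strictly = TRUE))
  with_seed(seed, {
    d <- c(dim, dim)
    m <- disk_mask(d, dim / 2, dim / 2, dim / 5)
    lorentz <- function(w, w0, g) g^2 / ((w - w0)^2 + g^2)
    shape <- lorentz(wavenumbers, 2845, 35) + 0.35 * lorentz(wavenumbers, 2930, 30)
    shape <- shape / max(shape)
    peak_c <- profile$ld_contrast[["mean"]]
    frames <- lapply(seq_along(wavenumbers), function(i) {
      f <- matrix(profile$buffer_level, dim, dim)
      f[m] <- (1 + (peak_c - 1) * shape[i]) * profile$buffer_level
      f <- apply_noise(f, profile$noise_cv)
      attr(f, "wavenumber") <- wavenumbers[i]
      f
    })
    names(frames) <- as.character(wavenumbers)
    list(frames = frames, wavenumbers = wavenumbers, region = m)
  })
}
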