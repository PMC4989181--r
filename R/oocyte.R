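# Per-oocyte quantification: integrated CARS (lipid) and GFP (yolk carrier)
# signals over staged oocytes -5..-1, signal offsets relative to the -5
# oocyte, the carrier-lipid linear fit, and cylinder-model volumes.

#' Integrated CARS signal of one oocyte
#'
#' The non-resonant background is estimated as the mean intensity over the
#' oocyte's nucleus; the statistic is the sum over all oocyte pixels of the
#' square root of the background-subtracted intensity.  The square root
#' linearises the quadratic concentration dependence of the coherent signal,
#' so the statistic scales with the oocyte's lipid content.  Background-
#' subtracted values below zero (pixels dimmer than the nucleus) are clamped
#' to zero before the square root.
#'
#' @param frame Lipid-band intensity matrix (counts).
#' @param oocyte Logical oocyte mask (includes the nucleus).
#' @param nucleus Logical nucleus mask, a subset of `oocyte`.
#' @return Scalar integrated signal (sqrt-counts).
#' @export
integrated_cars <- function(frame, oocyte, nucleus) {
  stopifnot(identical(dim(frame), dim(oocyte)),
            identical(dim(frame), dim(nucleus)))
  if (!any(oocyte) || !any(nucleus)) stop("empty oocyte or nucleus mask")
  if (any(nucleus & !oocyte)) stop("nucleus mask must lie inside the oocyte")
  b <- mean(frame[nucleus])
  sum(sqrt(pmax(frame[oocyte] - b, 0)))
}

#' Integrated GFP signal of one oocyte
#'
#' Fluorescence is linear in fluorophore concentration, so no square root is
#' taken: the statistic is the sum of background-subtracted GFP intensities
#' over the oocyte, with the background estimated as the mean over a
#' GFP-negative reference region.  Negative differences are clamped to zero.
#'
#' @param gfp GFP intensity matrix (counts).
#' @param oocyte Logical oocyte mask.
#' @param gfp_negative Logical mask of the GFP-negative reference region.
#' @return Scalar integrated signal (counts).
#' @export
integrated_gfp <- function(gfp, oocyte, gfp_negative) {
  stopifnot(identical(dim(gfp), dim(oocyte)),
            identical(dim(gfp), dim(gfp_negative)))
  if (!any(oocyte) || !any(gfp_negative)) stop("empty mask")
  b <- mean(gfp[gfp_negative])
  sum(pmax(gfp[oocyte] - b, 0))
}

#' Per-worm signal offsets relative to the -5 oocyte
#'
#' The -5 oocyte carries essentially no detectable yolk-carrier signal, so it
#' serves as the per-worm offset: `delta(k) = value(k) - value(-5)` for both
#' channels, with `delta(-5) = 0` by construction.
#'
#' @param measurements Data frame for one worm with columns `position`
#'   (-5..-1), `integrated_cars` and optionally `integrated_gfp`.
#' @return The input with `delta_cars` (and `delta_gfp` if present) added.
#' @export
delta_signals <- function(measurements) {
  if (!-5L %in% measurements$position)
    stop("a -5 oocyte measurement is required as the offset")
  ref <- measurements[measurements$position == -5L, , drop = FALSE]
  measurements$delta_cars <- measurements$integrated_cars - ref$integrated_cars
  if ("integrated_gfp" %in% names(measurements) &&
      !all(is.na(measurements$integrated_gfp)))
    measurements$delta_gfp <- measurements$integrated_gfp - ref$integrated_gfp
  measurements
}

#' Linear fit of lipid signal on carrier signal
#'
#' Ordinary least squares of mean delta-integrated-CARS on mean
#' delta-integrated-GFP across oocyte positions.  A slope significantly
#' above zero with high R^2 indicates that the GFP-tagged carrier tracks
#' lipid delivery; a non-zero intercept carries the lipid delivered by
#' carrier pathways invisible to the GFP tag.
#'
#' @param delta_gfp,delta_cars Numeric vectors of position-mean offsets
#'   (length >= 3).
#' @return A `carrier_lipid_fit` list: `slope`, `intercept`, `r_squared`.
#' @export
carrier_lipid_fit <- function(delta_gfp, delta_cars) {
  stopifnot(length(delta_gfp) == length(delta_cars), length(delta_gfp) >= 3)
  if (stats::var(delta_gfp) == 0)
    stop("zero variance in the carrier signal")
  fit <- stats::lm(delta_cars ~ delta_gfp)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((delta_cars - mean(delta_cars))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot),
            class = "carrier_lipid_fit")
}

#' @export
print.carrier_lipid_fit <- function(x, ...) {
  cat(sprintf("<carrier_lipid_fit> slope %.4g, intercept %.4g, R^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Cylinder-model oocyte volume
#'
#' The oocyte is modelled as a cylinder of the measured length and width:
#' `volume = pi * length * (width / 2)^2`.
#'
#' @param length,width Oocyte axes in um (positive).
#' @return Volume in um^3 (vectorised).
#' @export
oocyte_volume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0))
    stop("length and width must be positive")
  pi * length * (width / 2)^2
}

#' Length and width of an oocyte mask
#'
#' Estimates the mask's principal axes from its second moments (the
#' orientation of the best-fit ellipse) and reports the pixel extents along
#' those axes.  Extents are exact for rectangles, disks and ellipse masks and
#' invariant under rotation, which makes them a reproducible stand-in for
#' manual caliper measurements.
#'
#' @param oocyte Logical mask.
#' @param pixel_size Pixel edge in um.
#' @return Named numeric vector `c(length = , width = )` in um.
#' @export
axes_from_mask <- function(oocyte, pixel_size) {
  if (!any(oocyte)) stop("empty mask")
  idx <- which(oocyte, arr.ind = TRUE)
  x <- idx[, 2] - mean(idx[, 2])
  y <- idx[, 1] - mean(idx[, 1])
  cv <- stats::cov(cbind(x, y)) * (nrow(idx) - 1) / nrow(idx)
  eg <- eigen(cv, symmetric = TRUE)
  u <- eg$vectors[, 1]  # major axis direction
  proj_major <- x * u[1] + y * u[2]
  proj_minor <- -x * u[2] + y * u[1]
  len <- (max(proj_major) - min(proj_major) + 1) * pixel_size
  wid <- (max(proj_minor) - min(proj_minor) + 1) * pixel_size
  c(length = len, width = wid)
}

#' Normalise a strain lipid table to a reference cell
#'
#' Divides every mean (and SEM) by the mean of the reference strain/position
#' cell, so the reference cell reads exactly 1.
#'
#' @param tab Data frame with columns `strain`, `position`, `mean` and
#'   optionally `sem`.
#' @param ref_strain,ref_position Reference cell (defaults: `"N2"`, -1).
#' @return The table with `mean` and `sem` rescaled.
#' @export
normalize_lipid <- function(tab, ref_strain = "N2", ref_position = -1L) {
  hit <- tab$strain == ref_strain & tab$position == ref_position
  if (!any(hit)) stop("reference cell ", ref_strain, " / ", ref_position,
                      " not present")
  ref <- tab$mean[hit][1]
  if (ref == 0) stop("reference mean is zero")
  tab$mean <- tab$mean / ref
  if ("sem" %in% names(tab)) tab$sem <- tab$sem / ref
  tab
}

#' Quantify all oocytes of one rendered worm
#'
#' Convenience wrapper running [integrated_cars()], [integrated_gfp()] and
#' [axes_from_mask()] over the five staged oocyte masks of a
#' `worm_image_set`.
#'
#' @param ws A `worm_image_set` from [render_worm()].
#' @param band Band name used for the CARS statistic (default `"2845"`).
#' @return Data frame with one row per position: `worm_id`, `position`,
#'   `integrated_cars`, `integrated_gfp`, `length`, `width`, `volume`.
#' @export
quantify_oocytes <- function(ws, band = "2845") {
  frame <- ws$bands[[band]]
  gfpneg <- region_mask(ws, "gfp_negative_roi")
  rows <- lapply(-5:-1, function(k) {
    oo <- region_mask(ws, "oocyte", k)
    nuc <- region_mask(ws, "nucleus", k)
    ax <- axes_from_mask(oo, ws$pixel_size)
    data.frame(worm_id = paste0(ws$strain, "_s", ws$seed),
               position = k,
               integrated_cars = integrated_cars(frame, oo, nuc),
               integrated_gfp = if (is.null(ws$gfp)) NA_real_
                                else integrated_gfp(ws$gfp, oo, gfpneg),
               length = ax[["length"]], width = ax[["width"]],
               volume = oocyte_volume(ax[["length"]], ax[["width"]]))
  })
  do.call(rbind, rows)
}
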