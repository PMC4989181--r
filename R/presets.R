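# Strain preset registry.
#
# Every literature-derived constant used by the synthetic generator lives in
# this one table so provenance is auditable in a single place.  Two kinds of
# entries coexist:
#
#   * measured values reported for the real strains (contrast ratios of
#     accumulations and hypodermal lipid droplets, ovulation rates, the
#     -2 -> -1 lipid step, relative lipid deficits, oocyte volumes, egg
#     numbers) -- these are stored verbatim;
#   * calibration values the literature does not report numerically
#     (per-strain blob-count and blob-size distributions, noise CV, buffer
#     counts, oocyte length/width spreads) -- chosen once to give realistic
#     scenes and marked "calibrated" below.
#
# Lipid profiles are in arbitrary relative units; every strain satisfies the
# observed 50% lipid increase across the -2 -> -1 transition, and the ratios
# between strains reproduce the reported delivery-rate and content deficits
# (e.g. fat-2 carries 75% of the N2 content in its -1/-2 oocytes).

.positions <- c(-5L, -4L, -3L, -2L, -1L)

# shared imaging constants (calibrated; 12-bit detector)
.imaging <- list(
  buffer_level   = 400,    # counts, surrounding-buffer plateau
  noise_cv       = 0.05,   # multiplicative speckle CV
  nucleus_level  = 300,    # counts, oocyte-nucleus (non-resonant) plateau
  gfp_background = 100,    # counts, TPEF background plateau
  cars_gain      = 6e4,    # integrated-CARS counts^(1/2) per lipid unit
  gfp_gain       = 2e5,    # integrated-GFP counts per carrier unit
  protein_band_fraction = 0.6,  # accumulation contrast carry-over to 1665 cm^-1
  texture_amp    = 0.15    # within-blob multiplicative texture amplitude
)

.lipid_profile <- function(p) {
  names(p) <- as.character(.positions)
  p
}

# N2 reference profile: monotone, 50% step into -1.
.n2_profile <- .lipid_profile(c(1.0, 1.3, 1.7, 2.2, 3.3))

.preset_registry <- list(
  N2 = list(
    oocyte_lipid_profile = .n2_profile,
    ovulation_rate_true = 2.5,            # oocytes / arm / h
    egg_number_mean = 250,                # calibrated total brood
    acc_count_lambda = 5,                 # calibrated (Poisson)
    acc_size_meanlog = log(40), acc_size_sdlog = 0.6,   # calibrated, um^2
    oocyte_length_mean = 50.9, oocyte_width_mean = 22.4 # um; pi*L*(W/2)^2 ~ 2.0e4 um^3
  ),
  `fat-1` = list(
    oocyte_lipid_profile = .n2_profile,   # content similar to N2
    ovulation_rate_true = 2.0,
    egg_number_mean = 230,
    acc_count_lambda = 9,
    acc_size_meanlog = log(60), acc_size_sdlog = 0.7,
    oocyte_length_mean = 50.9, oocyte_width_mean = 22.4
  ),
  `fat-2` = list(
    oocyte_lipid_profile = .lipid_profile(0.75 * .n2_profile),  # 25% deficit
    ovulation_rate_true = 0.5,
    egg_number_mean = 48,                 # ~19% of wild type
    acc_count_lambda = 9,
    acc_size_meanlog = log(60), acc_size_sdlog = 0.7,
    oocyte_length_mean = 47.2, oocyte_width_mean = 20.8  # ~20% smaller volume
  ),
  `fat-3` = list(
    oocyte_lipid_profile = .lipid_profile(c(0.344, 0.65, 1.05,
                                            2.2 / 1.4, 3.3 / 1.4)),
    ovulation_rate_true = 1.4,
    egg_number_mean = 120,
    acc_count_lambda = 9,
    acc_size_meanlog = log(60), acc_size_sdlog = 0.7,
    oocyte_length_mean = 47.2, oocyte_width_mean = 20.8
  ),
  `fat-4` = list(
    oocyte_lipid_profile = .lipid_profile(c(0.816, 1.2, 1.65, 2.2, 3.3)),
    ovulation_rate_true = 1.25,
    egg_number_mean = 130,
    acc_count_lambda = 9,
    acc_size_meanlog = log(60), acc_size_sdlog = 0.7,
    oocyte_length_mean = 50.9, oocyte_width_mean = 22.4
  ),
  `fat-2+18:1n9` = list(                  # MUFA control: no rescue
    oocyte_lipid_profile = .lipid_profile(0.75 * .n2_profile),
    ovulation_rate_true = 0.5,
    egg_number_mean = 55,
    acc_count_lambda = 9,
    acc_size_meanlog = log(60), acc_size_sdlog = 0.7,
    oocyte_length_mean = 47.2, oocyte_width_mean = 20.8
  ),
  `fat-2+18:2n6` = list(                  # omega-6: near-complete rescue
    oocyte_lipid_profile = .lipid_profile(0.95 * .n2_profile),
    ovulation_rate_true = 1.5,
    egg_number_mean = 188,                # 75% of wild type
    acc_count_lambda = 5,
    acc_size_meanlog = log(35), acc_size_sdlog = 0.7,
    oocyte_length_mean = 50.0, oocyte_width_mean = 22.0
  ),
  `fat-2+18:3n6` = list(                  # omega-6: partial rescue
    oocyte_lipid_profile = .lipid_profile(0.90 * .n2_profile),
    ovulation_rate_true = 1.5,
    egg_number_mean = 150,
    acc_count_lambda = 6,
    acc_size_meanlog = log(45), acc_size_sdlog = 0.7,
    oocyte_length_mean = 49.5, oocyte_width_mean = 21.8
  ),
  `fat-2+18:3n3` = list(                  # omega-3: no rescue
    oocyte_lipid_profile = .lipid_profile(0.75 * .n2_profile),
    ovulation_rate_true = 0.5,
    egg_number_mean = 55,
    acc_count_lambda = 9,
    acc_size_meanlog = log(60), acc_size_sdlog = 0.7,
    oocyte_length_mean = 47.2, oocyte_width_mean = 20.8
  )
)

#' Names of the built-in strain presets
#'
#' @return Character vector of strain names accepted by [strain_preset()].
#' @export
strain_names <- function() names(.preset_registry)

#' Build a ground-truth profile for one worm strain
#'
#' Returns the generator parameters for a named strain: contrast statistics of
#' pseudocoelomic yolk accumulations and hypodermal lipid droplets, the staged
#' oocyte lipid profile (positions -5 to -1, relative units), the linear
#' coupling between lipid content and the GFP-tagged yolk carrier, oocyte
#' geometry, the true ovulation rate and mean egg number, and the imaging
#' noise model.  Contrast ratios (2.53 +/- 0.59 large, 1.69 +/- 0.22 small
#' accumulations; 4.39 +/- 0.21 lipid droplets) and ovulation rates are the
#' measured strain values; blob-count and blob-size distributions are
#' calibrated, as the source measurements report only total accumulation
#' areas per strain.
#'
#' The carrier offset is tied to the -5 oocyte's lipid content: the GFP-tagged
#' carrier is essentially undetectable at position -5, so the -5 content
#' defines the carrier-independent baseline.
#'
#' @param name Strain name; one of [strain_names()].
#' @return An object of class `strain_profile` (a named list).
#' @examples
#' p <- strain_preset("N2")
#' p$ovulation_rate_true  # 2.5 oocytes per gonad arm per hour
#' @export
strain_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.preset_registry))
    stop("unknown strain name: ", paste(name, collapse = ", "),
         "; see strain_names()")
  s <- .preset_registry[[name]]
  prof <- structure(c(
    list(
      strain_name = name,
      # accumulation / LD contrast statistics (mean, sd), dimensionless
      acc_contrast_large = c(mean = 2.53, sd = 0.59),
      acc_contrast_small = c(mean = 1.69, sd = 0.22),
      ld_contrast        = c(mean = 4.39, sd = 0.21),
      acc_count_lambda   = s$acc_count_lambda,
      acc_size_dist      = c(meanlog = s$acc_size_meanlog,
                             sdlog   = s$acc_size_sdlog,
                             min = 10, max = 200),
      oocyte_lipid_profile = s$oocyte_lipid_profile,
      carrier_slope  = 2.0,                        # lipid units per GFP unit
      carrier_offset = unname(s$oocyte_lipid_profile["-5"]),
      oocyte_length_dist = c(mean = s$oocyte_length_mean,
                             sd = 0.05 * s$oocyte_length_mean),
      oocyte_width_dist  = c(mean = s$oocyte_width_mean,
                             sd = 0.05 * s$oocyte_width_mean),
      ovulation_rate_true = s$ovulation_rate_true,
      egg_number_mean = s$egg_number_mean
    ),
    .imaging[c("buffer_level", "noise_cv")]
  ), class = "strain_profile")
  validate_strain_profile(prof)
}

#' Validate a strain profile
#'
#' Checks the invariants every generator profile must satisfy: contrasts at
#' least 1, a nondecreasing lipid profile from -5 to -1, a nonnegative
#' ovulation rate, noise CV in `[0, 0.5]`, and a buffer level strictly inside
#' the 12-bit range.
#'
#' @param profile A `strain_profile`.
#' @return The profile, invisibly unchanged, or an error.
#' @export
validate_strain_profile <- function(profile) {
  stopifnot(inherits(profile, "strain_profile"))
  if (profile$acc_contrast_large["mean"] < 1 ||
      profile$acc_contrast_small["mean"] < 1 ||
      profile$ld_contrast["mean"] < 1)
    stop("all contrast means must be >= 1")
  lp <- profile$oocyte_lipid_profile
  if (length(lp) != 5L || any(diff(lp) < 0))
    stop("oocyte lipid profile must be nondecreasing from -5 to -1")
  if (profile$ovulation_rate_true < 0) stop("ovulation rate must be >= 0")
  if (profile$noise_cv < 0 || profile$noise_cv > 0.5)
    stop("noise_cv must lie in [0, 0.5]")
  if (profile$buffer_level <= 0 || profile$buffer_level >= 4095)
    stop("buffer_level must lie strictly inside (0, 4095)")
  invisible(profile)
}

#' @export
print.strain_profile <- function(x, ...) {
  cat("<strain_profile> ", x$strain_name, "\n", sep = "")
  cat("  contrasts (large/small acc, LD): ",
      sprintf("%.2f / %.2f / %.2f", x$acc_contrast_large["mean"],
              x$acc_contrast_small["mean"], x$ld_contrast["mean"]), "\n")
  cat("  lipid profile (-5..-1): ",
      paste(sprintf("%.3g", x$oocyte_lipid_profile), collapse = ", "), "\n")
  cat("  ovulation rate: ", x$ovulation_rate_true, " / arm / h;  eggs: ",
      x$egg_number_mean, "\n", sep = "")
  cat("  noise CV ", x$noise_cv, ", buffer ", x$buffer_level, " counts\n",
      sep = "")
  invisible(x)
}

# internal accessor for shared imaging constants
imaging_constants <- function() .imaging
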