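# End-to-end orchestration: per-worm quantification, cohort surveys over
# strains, and the detection-limit experiment.

#' Segment and total the accumulations of one rendered worm
#'
#' Runs [ratio_image()] on the lipid band against the worm's buffer ROI,
#' restricts to the pseudocoelom-eligible region, and segments with the
#' given parameters.
#'
#' @param ws A `worm_image_set`.
#' @param params An [analysis_params()].
#' @param band Band used for segmentation (default `"2845"`, the lipid
#'   band, which offers the best signal-to-noise).
#' @return List with `records` (accumulation table) and `total_area` (um^2).
#' @export
quantify_accumulations <- function(ws, params = analysis_params(),
                                   band = "2845") {
  frame <- ws$bands[[band]]
  ratio <- ratio_image(frame, region_mask(ws, "buffer_roi"))
  eligible <- region_mask(ws, "pseudocoelom_eligible")
  rec <- segment_accumulations(ratio, eligible, params, ws$pixel_size,
                               frame = frame,
                               worm_id = paste0(ws$strain, "_s", ws$seed))
  list(records = rec, total_area = total_area(rec))
}

#' Render and quantify a cohort of one strain
#'
#' @param profile A `strain_profile`.
#' @param n_worms Number of worms to render.
#' @param seed Base seed; worm `i` uses `seed + i`.
#' @param params An [analysis_params()].
#' @param components Scene parts passed to [render_worm()].
#' @return List with `oocytes` (stacked [quantify_oocytes()] tables),
#'   `accumulations` (stacked records), `total_areas` (per-worm vector).
#' @export
quantify_cohort <- function(profile, n_worms, seed,
                            params = analysis_params(),
                            components = c("accumulations", "lds", "oocytes",
                                           "organs")) {
  oo <- list(); rec <- list(); tot <- numeric(n_worms)
  for (i in seq_len(n_worms)) {
    ws <- render_worm(profile, seed + i, components = components)
    if ("oocytes" %in% components) oo[[i]] <- quantify_oocytes(ws)
    if ("accumulations" %in% components) {
      q <- quantify_accumulations(ws, params)
      rec[[i]] <- q$records
      tot[i] <- q$total_area
    }
  }
  list(oocytes = if (length(oo)) do.call(rbind, oo),
       accumulations = if (length(rec)) do.call(rbind, rec),
       total_areas = tot)
}

#' Detection-limit experiment for the ratio-threshold segmentation
#'
#' Plants blobs of known areas at the small-accumulation mean contrast on
#' replicate noisy frames, segments each frame with the given parameters,
#' and reports, for each planted area, the fraction of instances in which
#' the blob is recovered (a surviving component overlapping the planted
#' mask).  The detection limit is the smallest area detected in at least
#' `min_rate` of instances.
#'
#' The contrast is fixed at the small-accumulation mean: the experiment
#' probes size sensitivity at the representative contrast rather than
#' contrast-class spread (a blob whose whole contrast lies outside the ratio
#' band is undetectable at any size, which is a property of the band, not of
#' the size threshold under test).
#'
#' @param profile A `strain_profile` (supplies contrast, buffer, noise).
#' @param areas_um2 Ladder of planted areas.
#' @param n_seeds Replicates per area.
#' @param params An [analysis_params()].
#' @param seed Base seed.
#' @param noise_cv Noise CV for the frames (default: profile's).
#' @param min_rate Required detection fraction (default 0.95).
#' @return List with `limit_um2` (smallest reliably detected planted area),
#'   `curve` (data frame `area`, `detected`, `rate`).
#' @export
detection_limit <- function(profile, areas_um2 = seq(2, 40, by = 0.25),
                            n_seeds = 20L, params = analysis_params(),
                            seed = 1L, noise_cv = NULL, min_rate = 0.95) {
  if (is.null(noise_cv)) noise_cv <- profile$noise_cv
  contrast <- profile$acc_contrast_small[["mean"]]
  hits <- matrix(0L, length(areas_um2), n_seeds)
  planted <- matrix(NA_real_, length(areas_um2), n_seeds)
  chunks <- split(seq_along(areas_um2),
                  ceiling(seq_along(areas_um2) / 60))
  for (s in seq_len(n_seeds)) {
    for (ch in seq_along(chunks)) {
      sel <- chunks[[ch]]
      fld <- render_blob_field(areas_um2[sel], contrast, 0, "polygon",
                               seed = seed + 1000L * s + ch,
                               buffer_level = profile$buffer_level,
                               noise_cv = noise_cv)
      ratio <- ratio_image(fld$frame, fld$buffer_roi)
      eligible <- !fld$buffer_roi
      rec <- segment_accumulations(ratio, eligible, params, fld$pixel_size)
      seg_lab <- NULL
      if (nrow(rec)) {
        fg <- eligible & ratio >= params$ratio_low & ratio <= params$ratio_high
        seg_lab <- label_components(fg, params$connectivity)
        npx <- tabulate(seg_lab[seg_lab > 0L])
        ok_comp <- which(npx * fld$pixel_size^2 >= params$min_area)
        seg_ok <- matrix(seg_lab %in% ok_comp, nrow(seg_lab))
      } else seg_ok <- matrix(FALSE, nrow(ratio), ncol(ratio))
      for (j in seq_along(sel)) {
        planted[sel[j], s] <- fld$truth$planted_area_um2[j]
        if (any(seg_ok & fld$masks[[j]])) hits[sel[j], s] <- 1L
      }
    }
  }
  rate <- rowMeans(hits)
  mean_planted <- rowMeans(planted)
  ok <- which(rate >= min_rate)
  list(limit_um2 = if (length(ok)) mean_planted[min(ok)] else NA_real_,
       curve = data.frame(area = areas_um2, planted_area = mean_planted,
                          detected = rowSums(hits), rate = rate))
}

#' Strain survey: per-strain means of the headline metrics
#'
#' Renders and quantifies a small cohort per strain plus a simulated
#' reproduction assay, and assembles the wide summary table consumed by
#' [correlation_report()]: mean -1/-2 lipid content, -1 oocyte volume,
#' -2 -> -1 delivery rate, ovulation rate, total accumulation area and egg
#' number per strain.
#'
#' @param strains Strain names (default: all presets).
#' @param n_worms Rendered worms per strain.
#' @param n_assay Simulated assay worms per strain.
#' @param seed Base seed.
#' @return Data frame, one row per strain.
#' @export
survey_strains <- function(strains = strain_names(), n_worms = 6L,
                           n_assay = 50L, seed = 1L) {
  rows <- lapply(seq_along(strains), function(i) {
    p <- strain_preset(strains[i])
    coh <- quantify_cohort(p, n_worms, seed + 10000L * i)
    oo <- coh$oocytes
    lipid_mat <- tapply(oo$integrated_cars, oo$position, mean)
    assay <- simulate_reproduction(p, n_assay, 6, seed + 10000L * i + 5000L)
    ovr <- mean(ovulation_rate(assay$eggs_laid, assay$final_retained,
                               assay$initial_retained, assay$elapsed,
                               assay$gonad_arms))
    dr <- delivery_rates(lipid_mat[as.character(-5:-1)], ovr)
    data.frame(
      strain = strains[i],
      lipid_content = mean(oo$integrated_cars[oo$position %in% c(-1L, -2L)]),
      oocyte_size = mean(oo$volume[oo$position == -1L]),
      delivery_rate = dr$rate[dr$from == -2L],
      ovulation_rate = ovr,
      total_accumulation_area = mean(coh$total_areas),
      egg_number = p$egg_number_mean)
  })
  do.call(rbind, rows)
}
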