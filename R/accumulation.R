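# Segmentation and size-distribution analysis of secreted yolk-lipoprotein
# accumulations in the pseudocoelomic cavity.
#
# The measured quantity is the per-pixel intensity ratio to the mean of a
# user-drawn surrounding-buffer ROI.  Accumulations are pixels whose ratio
# falls inside a fixed band (default 1.47-3.12), grouped into connected
# components and filtered by a minimum area (default 10 um^2, the method's
# detection limit).

#' Analysis parameters for accumulation segmentation
#'
#' @param ratio_low,ratio_high Intensity-ratio band defining accumulation
#'   pixels (defaults 1.47 and 3.12).
#' @param min_area Minimum component area in um^2 retained (default 10, the
#'   detection limit of the ratio-threshold method).
#' @param bin_width Histogram bin width in um^2 for size-distribution curves
#'   (default 20, i.e. bins 0-20, 20-40, 40-60, ...).
#' @param connectivity Pixel adjacency for components: 8 (default; diagonal
#'   neighbours connect) or 4.
#' @return An `analysis_params` list.
#' @export
analysis_params <- function(ratio_low = 1.47, ratio_high = 3.12,
                            min_area = 10, bin_width = 20,
                            connectivity = 8L) {
  stopifnot(ratio_low > 1, ratio_high > ratio_low,
            min_area > 0, bin_width > 0, connectivity %in% c(4L, 8L))
  structure(list(ratio_low = ratio_low, ratio_high = ratio_high,
                 min_area = min_area, bin_width = bin_width,
                 connectivity = as.integer(connectivity)),
            class = "analysis_params")
}

#' Intensity-ratio image against a buffer ROI
#'
#' Divides every pixel by the mean intensity of the surrounding-buffer ROI,
#' yielding the dimensionless contrast raster on which thresholding operates.
#'
#' @param frame Numeric intensity matrix (counts).
#' @param buffer_roi Logical mask of the buffer ROI (same dimensions).
#' @return Numeric matrix of intensity ratios.
#' @export
ratio_image <- function(frame, buffer_roi) {
  stopifnot(is.matrix(frame), identical(dim(frame), dim(buffer_roi)))
  if (!any(buffer_roi)) stop("buffer ROI is empty")
  b <- mean(frame[buffer_roi])
  if (b <= 0) stop("buffer mean must be positive")
  frame / b
}

#' Mean region-to-buffer contrast
#'
#' Ratio of the mean intensity over a region mask to the mean over the buffer
#' ROI; evaluated per Raman band, this reproduces the band-panel contrast
#' comparisons (protein / non-resonant / lipid).
#'
#' @param frame Numeric intensity matrix.
#' @param region Logical mask of the region of interest.
#' @param buffer_roi Logical mask of the buffer ROI.
#' @return Dimensionless scalar contrast.
#' @export
region_contrast <- function(frame, region, buffer_roi) {
  stopifnot(identical(dim(frame), dim(region)),
            identical(dim(frame), dim(buffer_roi)))
  if (!any(region)) stop("region mask is empty")
  if (!any(buffer_roi)) stop("buffer ROI is empty")
  mean(frame[region]) / mean(frame[buffer_roi])
}

# 8- (or 4-) connected component labelling of a logical mask via a pixel
# adjacency graph.  Returns an integer matrix of component labels (0 =
# background).
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  if (!length(fg)) return(matrix(0L, nr, nc))
  id <- integer(nr * nc)
  id[fg] <- seq_along(fg)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  r <- (fg - 1L) %% nr + 1L
  cc <- (fg - 1L) %/% nr + 1L
  edges <- integer(0)
  for (o in offs) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- id[nb] > 0L
    if (any(hit))
      edges <- c(edges, rbind(id[fg[ok]][hit], id[nb][hit]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  out <- matrix(0L, nr, nc)
  out[fg] <- as.integer(comp)
  out
}

#' Segment yolk-lipoprotein accumulations from a ratio image
#'
#' Applies the per-pixel ratio band inside the eligible region (internal
#' organs, embryos and body wall already excluded), labels connected
#' components, discards components smaller than `min_area`, and reports one
#' record per surviving component.
#'
#' @param ratio Dimensionless ratio raster from [ratio_image()].
#' @param eligible Logical mask of the pseudocoelom-eligible region.
#' @param params An [analysis_params()] object.
#' @param pixel_size Pixel edge in um.
#' @param frame Optional intensity matrix (counts) used for the component
#'   `mean_intensity`; if `NULL` the column is `NA`.
#' @param worm_id Identifier stored on each record.
#' @return Data frame with one row per accumulation: `worm_id`,
#'   `component_id`, `area` (um^2), `n_pixels`, `mean_ratio`,
#'   `mean_intensity`, `centroid_x`, `centroid_y` (um, x along columns).
#' @export
segment_accumulations <- function(ratio, eligible, params = analysis_params(),
                                  pixel_size, frame = NULL, worm_id = "worm") {
  stopifnot(is.matrix(ratio), identical(dim(ratio), dim(eligible)))
  if (!is.null(frame)) stopifnot(identical(dim(frame), dim(ratio)))
  fg <- eligible & ratio >= params$ratio_low & ratio <= params$ratio_high
  lab <- label_components(fg, params$connectivity)
  empty <- data.frame(worm_id = character(), component_id = integer(),
                      area = numeric(), n_pixels = integer(),
                      mean_ratio = numeric(), mean_intensity = numeric(),
                      centroid_x = numeric(), centroid_y = numeric())
  if (!any(lab > 0L)) return(empty)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  npx <- tabulate(comp)
  keep <- which(npx * pixel_size^2 >= params$min_area)
  if (!length(keep)) return(empty)
  nr <- nrow(ratio)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  rows <- lapply(seq_along(keep), function(j) {
    k <- keep[j]
    sel <- comp == k
    data.frame(worm_id = worm_id, component_id = j,
               area = npx[k] * pixel_size^2, n_pixels = npx[k],
               mean_ratio = mean(ratio[idx[sel]]),
               mean_intensity = if (is.null(frame)) NA_real_
                                else mean(frame[idx[sel]]),
               centroid_x = (mean(cc[sel]) - 0.5) * pixel_size,
               centroid_y = (mean(r[sel]) - 0.5) * pixel_size)
  })
  do.call(rbind, rows)
}

#' Total accumulation area for one worm
#'
#' @param records Data frame from [segment_accumulations()] (one worm).
#' @return Sum of component areas in um^2 (0 for an empty record set).
#' @export
total_area <- function(records) {
  if (is.null(records) || nrow(records) == 0L) return(0)
  sum(records$area)
}

#' Area-contribution curve of pooled accumulation sizes
#'
#' Pools accumulation areas from a cohort, histograms them in uniform bins,
#' divides occurrences by the number of worms (per-worm frequency), and
#' multiplies each frequency by the bin's representative area (the bin
#' midpoint) to obtain the per-worm area contribution of each size class.
#' The sum of contributions approximates the mean total accumulation area
#' per worm (exactly, when all areas sit on bin midpoints).
#'
#' @param areas Numeric vector of pooled accumulation areas (um^2).
#' @param n_worms Number of worms pooled (>= 1).
#' @param params An [analysis_params()]; only `bin_width` is used.
#' @return An `area_contribution_curve`: data frame with `bin_low`,
#'   `bin_high`, `bin_mid`, `freq_per_worm`, `contribution_per_worm`, plus
#'   attributes `n_worms` and `bin_width`.
#' @seealso [contribution_fraction_below()]
#' @export
area_contribution <- function(areas, n_worms, params = analysis_params()) {
  if (n_worms < 1) stop("n_worms must be >= 1")
  bw <- params$bin_width
  n_bins <- if (length(areas)) max(1L, ceiling(max(areas) / bw)) else 1L
  edges <- seq(0, n_bins * bw, by = bw)
  cnt <- if (length(areas))
    tabulate(pmin(pmax(ceiling(areas / bw), 1L), n_bins), nbins = n_bins)
  else rep(0L, n_bins)
  mid <- edges[-length(edges)] + bw / 2
  curve <- data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
                      bin_mid = mid, freq_per_worm = cnt / n_worms,
                      contribution_per_worm = cnt / n_worms * mid)
  structure(curve, class = c("area_contribution_curve", "data.frame"),
            n_worms = n_worms, bin_width = bw)
}

#' Fraction of total area contribution below a size cutoff
#'
#' Integrates the area-contribution curve up to `cutoff` and divides by the
#' whole integral, answering questions of the form "what fraction of the
#' total accumulated area comes from accumulations smaller than 80 um^2?".
#' Bins straddling the cutoff contribute pro-rata.
#'
#' @param curve An `area_contribution_curve` from [area_contribution()].
#' @param cutoff Area cutoff in um^2.
#' @return Fraction in `[0, 1]` (`NA` if the curve is all zero).
#' @export
contribution_fraction_below <- function(curve, cutoff) {
  tot <- sum(curve$contribution_per_worm)
  if (tot == 0) return(NA_real_)
  w <- pmin(pmax((cutoff - curve$bin_low) /
                   (curve$bin_high - curve$bin_low), 0), 1)
  sum(w * curve$contribution_per_worm) / tot
}

#' Normalised CARS spectrum over a region
#'
#' Computes the mean region intensity of each frame in a wavenumber-ordered
#' stack and normalises by the maximum across frames, giving a unitless
#' spectrum with peak value 1.
#'
#' @param stack List of intensity matrices, each with a `wavenumber`
#'   attribute (cm^-1), strictly increasing.
#' @param region Logical mask applied to every frame.
#' @return Data frame with `wavenumber` and `intensity` (max-normalised).
#' @export
normalized_spectrum <- function(stack, region) {
  stopifnot(length(stack) >= 2)
  if (!any(region)) stop("region mask is empty")
  w <- vapply(stack, function(f) as.numeric(attr(f, "wavenumber")), 0)
  if (anyNA(w)) stop("every frame needs a wavenumber attribute")
  if (any(duplicated(w))) stop("duplicate wavenumbers in stack")
  if (is.unsorted(w, strictly = TRUE))
    stop("wavenumbers must be strictly increasing")
  m <- vapply(stack, function(f) mean(f[region]), 0)
  data.frame(wavenumber = w, intensity = m / max(m))
}
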