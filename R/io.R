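# File interfaces: multi-page 16-bit TIFF for band stacks, 8-bit TIFF for
# label rasters, CSV tables, and a plain key-value manifest.

#' Write a worm image set to disk
#'
#' Bands are written as one multi-page 16-bit grayscale TIFF (pages in
#' increasing wavenumber order, recorded in the manifest), the GFP channel
#' (if any) as a separate 16-bit TIFF, the label raster as a single-page
#' 8-bit TIFF, and a `manifest.txt` key-value file (TOML dialect) recording
#' strain, seed, pixel size and page order.
#'
#' @param ws A `worm_image_set`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_worm_tiff <- function(ws, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ord <- order(as.numeric(names(ws$bands)))
  pages <- lapply(ws$bands[ord], function(m) unclass(m) / 65535)
  tiff::writeTIFF(pages, file.path(dir, "bands.tif"), bits.per.sample = 16L)
  if (!is.null(ws$gfp))
    tiff::writeTIFF(unclass(ws$gfp) / 65535, file.path(dir, "gfp.tif"),
                    bits.per.sample = 16L)
  tiff::writeTIFF(ws$labels / 255, file.path(dir, "labels.tif"),
                  bits.per.sample = 8L)
  write_manifest(list(strain = ws$strain, seed = ws$seed,
                      pixel_size_um = ws$pixel_size,
                      band_pages = paste(names(ws$bands)[ord], collapse = ",")),
                 file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a worm image set written by [write_worm_tiff()]
#'
#' Ground truth is not serialised; the returned set carries bands, GFP,
#' labels and pixel size only.
#'
#' @param dir Directory produced by [write_worm_tiff()].
#' @return A `worm_image_set` (with `truth = NULL`).
#' @export
read_worm_tiff <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.txt"))
  pages <- tiff::readTIFF(file.path(dir, "bands.tif"), all = TRUE)
  wns <- strsplit(man$band_pages, ",")[[1]]
  bands <- lapply(pages, function(p) round(p * 65535))
  names(bands) <- wns
  for (w in wns) attr(bands[[w]], "wavenumber") <- as.numeric(w)
  gfp <- NULL
  if (file.exists(file.path(dir, "gfp.tif")))
    gfp <- round(tiff::readTIFF(file.path(dir, "gfp.tif")) * 65535)
  labels <- matrix(as.integer(round(
    tiff::readTIFF(file.path(dir, "labels.tif")) * 255)),
    nrow = nrow(bands[[1]]))
  new_worm_image_set(bands, gfp, labels,
                     as.numeric(man$pixel_size_um), NULL,
                     man$strain, as.integer(man$seed))
}

#' Write a key-value manifest (TOML dialect)
#'
#' @param x Named list of scalar values.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  fmt <- vapply(names(x), function(k) {
    v <- x[[k]]
    if (is.character(v)) sprintf('%s = "%s"', k, v)
    else sprintf("%s = %.17g", k, as.numeric(v))
  }, "")
  writeLines(fmt, path)
  invisible(path)
}

#' Read a manifest written by [write_manifest()]
#'
#' @param path Manifest file.
#' @return Named list; quoted values as character, others numeric.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    out[[key]] <- if (grepl('^".*"$', val)) gsub('^"|"$', "", val)
                  else as.numeric(val)
  }
  out
}
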