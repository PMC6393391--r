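#' 3-D image volume with physical voxel size
#'
#' A `volume_image` wraps a 3-D numeric array of non-negative intensities
#' indexed `[x, y, z]`, together with the physical size of a voxel along
#' each axis (micrometres) and an optional physical origin. All skeleton
#' coordinates in this package are continuous physical micrometre
#' coordinates; a point maps to the 0-based voxel index
#' `floor((coord - origin) / voxel_size)`, and the physical centre of voxel
#' `i` is `origin + (i + 0.5) * voxel_size`.
#'
#' @param intensities 3-D numeric array of non-negative intensities,
#'   indexed `[x, y, z]`.
#' @param voxel_size positive numeric length-3, micrometres per voxel along
#'   x, y, z.
#' @param origin numeric length-3, physical coordinate (micrometres) of the
#'   low corner of voxel `(0, 0, 0)`. Defaults to the world origin; template
#'   images built around a local bounding box use a non-zero origin.
#' @return A `volume_image` object.
#' @examples
#' vol <- volume_image(array(0, c(4, 4, 2)))
#' dim(vol)
#' @export
volume_image <- function(intensities, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  assert_that(is.array(intensities) && length(dim(intensities)) == 3,
              "intensities must be a 3-D array")
  assert_that(all(dim(intensities) >= 1), "all dimensions must be >= 1")
  voxel_size <- as.numeric(voxel_size)
  origin <- as.numeric(origin)
  assert_that(length(voxel_size) == 3 && all(is.finite(voxel_size)) && all(voxel_size > 0),
              "voxel_size must be 3 positive finite numbers")
  assert_that(length(origin) == 3 && all(is.finite(origin)),
              "origin must be 3 finite numbers")
  assert_that(all(is.finite(intensities)) && all(intensities >= 0),
              "intensities must be finite and non-negative")
  structure(intensities,
            voxel_size = voxel_size,
            origin = origin,
            class = c("volume_image", "array"))
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x)
  vs <- attr(x, "voxel_size")
  cat(sprintf("<volume_image> %d x %d x %d voxels, voxel size %.4g x %.4g x %.4g um\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Voxel size of a volume
#' @param vol a [volume_image()].
#' @return Numeric length-3 (micrometres per voxel).
#' @export
voxel_size <- function(vol) attr(vol, "voxel_size")

#' Physical origin of a volume
#' @param vol a [volume_image()].
#' @return Numeric length-3 (micrometres).
#' @export
volume_origin <- function(vol) attr(vol, "origin")

# Continuous um coordinates -> 0-based voxel indices (matrix n x 3).
voxel_index <- function(vol, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  vs <- voxel_size(vol)
  org <- volume_origin(vol)
  floor(sweep(sweep(pts, 2, org, "-"), 2, vs, "/"))
}

# 0-based voxel indices -> physical um centre coordinates.
voxel_center <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  vs <- voxel_size(vol)
  org <- volume_origin(vol)
  sweep(sweep(idx + 0.5, 2, vs, "*"), 2, org, "+")
}

#' Sample the voxel neighbourhood of a point
#'
#' Returns every voxel whose 0-based index lies within `halfwidth` of the
#' voxel containing `center` along each axis, clipped to the volume bounds.
#' This is the neighbourhood over which the local intensity score of a
#' skeleton point is accumulated. A centre further than `halfwidth` voxels
#' outside the volume yields an empty result (callers treat the score as
#' zero rather than failing near stack borders).
#'
#' @param image a [volume_image()].
#' @param center numeric length-3, physical micrometre coordinates.
#' @param halfwidth positive integer, neighbourhood half-width in voxels.
#' @return A tibble with columns `x`, `y`, `z` (voxel centre, micrometres)
#'   and `intensity`; zero rows when the centre is out of reach.
#' @examples
#' vol <- volume_image(array(1, c(5, 5, 5)))
#' nrow(sample_neighborhood(vol, c(2.5, 2.5, 2.5), 1)) # 27
#' @export
sample_neighborhood <- function(image, center, halfwidth) {
  assert_that(length(center) == 3 && all(is.finite(center)), "center must be 3 finite numbers")
  halfwidth <- as.integer(halfwidth)
  assert_that(halfwidth >= 1, "halfwidth must be >= 1")
  d <- dim(image)
  c0 <- as.integer(voxel_index(image, center))
  lo <- pmax(c0 - halfwidth, 0L)
  hi <- pmin(c0 + halfwidth, d - 1L)
  if (any(lo > hi)) {
    return(tibble::tibble(x = double(), y = double(), z = double(), intensity = double()))
  }
  xr <- lo[1]:hi[1]; yr <- lo[2]:hi[2]; zr <- lo[3]:hi[3]
  idx <- as.matrix(expand.grid(x = xr, y = yr, z = zr))
  ctr <- voxel_center(image, idx)
  vals <- as.vector(image[xr + 1L, yr + 1L, zr + 1L])
  tibble::tibble(x = ctr[, 1], y = ctr[, 2], z = ctr[, 3], intensity = vals)
}

#' Read a 3-D image stack
#'
#' Accepts a single multi-page grayscale TIFF, a directory of single-page
#' TIFFs (pages sorted by file name), or a raw binary file accompanied by a
#' plain-text YAML sidecar (`<path>.yaml` or `<path>.txt`) declaring
#' `shape`, `dtype` (`uint8`, `uint16`, `float32`, `float64`) and
#' optionally `voxel_size`. TIFF pages are z slices with matrix rows
#' running along y and columns along x; integer TIFF samples are read
#' as-is (no rescaling to `[0, 1]`).
#'
#' @param path file or directory path.
#' @param voxel_size numeric length-3, micrometres per voxel; overrides any
#'   sidecar value. Default `c(1, 1, 1)`.
#' @return A [volume_image()].
#' @export
read_stack <- function(path, voxel_size = NULL) {
  assert_that(file.exists(path), sprintf("no such file or directory: %s", path),
              class = "skelasso_io_error")
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    assert_that(length(files) >= 1, sprintf("no TIFF files in directory %s", path),
                class = "skelasso_format_error")
    pages <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
    return(stack_from_pages(pages, voxel_size %||% c(1, 1, 1)))
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    return(stack_from_pages(pages, voxel_size %||% c(1, 1, 1)))
  }
  read_raw_stack(path, voxel_size)
}

stack_from_pages <- function(pages, voxel_size) {
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_skelasso("TIFF pages have inconsistent sizes", "skelasso_format_error")
  }
  ny <- dims[1, 1]; nx <- dims[2, 1]; nz <- length(pages)
  arr <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]  # grayscale from first channel
    arr[, , k] <- t(pg)
  }
  volume_image(pmax(arr, 0), voxel_size)
}

read_raw_stack <- function(path, voxel_size) {
  sidecar <- paste0(path, c(".yaml", ".yml", ".txt"))
  sidecar <- sidecar[file.exists(sidecar)][1]
  if (is.na(sidecar)) {
    stop_skelasso(sprintf("raw stack %s has no sidecar (%s.yaml or .txt)", path, path),
                  "skelasso_config_error")
  }
  meta <- yaml::read_yaml(sidecar)
  assert_that(!is.null(meta$shape) && length(meta$shape) == 3,
              "sidecar must declare a length-3 'shape'", class = "skelasso_config_error")
  shape <- as.integer(meta$shape)
  dtype <- meta$dtype %||% "float64"
  n <- prod(shape)
  spec <- switch(dtype,
    uint8   = list(what = "integer", size = 1, signed = FALSE),
    uint16  = list(what = "integer", size = 2, signed = FALSE),
    float32 = list(what = "double",  size = 4, signed = TRUE),
    float64 = list(what = "double",  size = 8, signed = TRUE),
    stop_skelasso(sprintf("unsupported dtype '%s'", dtype), "skelasso_config_error")
  )
  raw_n <- file.info(path)$size
  if (raw_n < n * spec$size) {
    stop_skelasso(sprintf("raw file %s holds %d bytes but shape %s needs %d",
                          path, raw_n, paste(shape, collapse = "x"), n * spec$size),
                  "skelasso_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, spec$what, n = n, size = spec$size, signed = spec$signed,
                  endian = "little")
  vs <- voxel_size %||% meta$voxel_size %||% c(1, 1, 1)
  volume_image(array(pmax(as.numeric(vals), 0), shape), as.numeric(vs))
}

#' Write a 3-D image stack
#'
#' `format = "tiff"` writes a multi-page 16-bit grayscale TIFF (intensities
#' are rounded to integers; values must fit in `[0, 65535]`).
#' `format = "raw"` writes little-endian float64 samples plus a YAML sidecar
#' (`<path>.yaml`) recording shape, dtype and voxel size, and round-trips
#' continuous intensities exactly.
#'
#' @param vol a [volume_image()].
#' @param path output file path.
#' @param format `"tiff"` or `"raw"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path, format = NULL) {
  format <- format %||% if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "raw"
  if (format == "tiff") {
    assert_that(max(vol) <= 65535, "TIFF output requires intensities <= 65535",
                class = "skelasso_io_error")
    nz <- dim(vol)[3]
    pages <- lapply(seq_len(nz), function(k) t(vol[, , k]) / 65535)
    ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L), silent = TRUE)
    if (inherits(ok, "try-error")) {
      stop_skelasso(sprintf("cannot write TIFF to %s", path), "skelasso_io_error")
    }
  } else {
    con <- try(file(path, "wb"), silent = TRUE)
    if (inherits(con, "try-error")) {
      stop_skelasso(sprintf("cannot write raw stack to %s", path), "skelasso_io_error")
    }
    writeBin(as.vector(unclass(vol)), con, size = 8, endian = "little")
    close(con)
    yaml::write_yaml(list(shape = as.integer(dim(vol)),
                          dtype = "float64",
                          voxel_size = as.numeric(voxel_size(vol))),
                     paste0(path, ".yaml"))
  }
  invisible(path)
}
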