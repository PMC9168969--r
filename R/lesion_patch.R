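# Lightweight 2-D surrogate for the imaging chain: the parallel projection
# of a spherical mass onto a textured background patch at mammographic pixel
# pitch, plus an automatic size measurement.  This module deliberately does
# NOT model x-ray physics, anatomy simulation, or vendor image processing;
# it exists so the render -> measure -> doubling-time loop can be exercised
# end to end without the full virtual-trial imaging pipeline.

#' Specification of a lesion patch
#'
#' @param lesion_diameter Lesion diameter in mm.
#' @param pixel_pitch Detector pixel pitch in mm (default 0.07, i.e. the
#'   70-micron mammographic sampling this surrogate mimics).
#' @param patch_px Patch side length in pixels; `NULL` (default) chooses the
#'   smallest even size leaving at least a 20% margin around the lesion.
#' @param contrast Peak lesion amplitude added at the lesion center
#'   (dimensionless intensity units).
#' @param background List describing the background texture:
#'   `model` (`"flat"` or `"powerlaw"`), `mean` (flat offset),
#'   `amplitude` (texture standard deviation; 0 gives a noiseless patch) and
#'   `beta` (power-law exponent of the isotropic 1/f^beta spectrum,
#'   default 3, a standard mammographic-texture surrogate).
#' @param seed Optional seed for the background texture.
#' @return A list of class `patch_spec`.
#' @export
patch_spec <- function(lesion_diameter, pixel_pitch = 0.07, patch_px = NULL,
                       contrast = 1,
                       background = list(model = "powerlaw", mean = 0,
                                         amplitude = 0, beta = 3),
                       seed = NULL) {
  check_scalar_number(lesion_diameter, "lesion_diameter", 0, strict = TRUE)
  check_scalar_number(pixel_pitch, "pixel_pitch", 0, strict = TRUE)
  check_scalar_number(contrast, "contrast")
  bg <- utils::modifyList(
    list(model = "powerlaw", mean = 0, amplitude = 0, beta = 3), background
  )
  need_px <- ceiling(1.4 * lesion_diameter / pixel_pitch)
  if (is.null(patch_px)) {
    patch_px <- need_px + need_px %% 2
  } else if (patch_px < need_px) {
    stop(sprintf(
      "lesion (%.1f mm) too large for a %d-px patch at %.3f mm/px; need >= %d px",
      lesion_diameter, patch_px, pixel_pitch, need_px), call. = FALSE)
  }
  structure(
    list(lesion_diameter = lesion_diameter, pixel_pitch = pixel_pitch,
         patch_px = as.integer(patch_px), contrast = contrast,
         background = bg, seed = seed),
    class = "patch_spec"
  )
}

# Isotropic 1/f^beta Gaussian texture, standardized to unit sd.
powerlaw_texture <- function(n, beta, seed = NULL) {
  white <- with_seed_if(seed, matrix(stats::rnorm(n * n), n, n))
  f <- stats::fft(white)
  freq <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) / n
  rho <- sqrt(outer(freq^2, freq^2, `+`))
  filt <- rho^(-beta / 2)
  filt[1, 1] <- 0  # zero the DC term: the mean is set separately
  tex <- Re(stats::fft(f * filt, inverse = TRUE)) / (n * n)
  tex / stats::sd(tex)
}

#' Render a spherical lesion on a textured patch
#'
#' The lesion signal at in-plane distance `rho` from the lesion center is
#' the normalized chord length through the sphere,
#' `contrast * sqrt(r^2 - rho^2) / r` for `rho <= r`, i.e. the parallel
#' projection of a homogeneous sphere scaled to peak `contrast`.  The signal
#' is added to the background texture.  Pixel values are sampled at pixel
#' centers with the origin at the patch center (row-major storage).
#'
#' @param spec A [patch_spec()].
#' @return A `patch_px` x `patch_px` numeric matrix of intensities with the
#'   spec attached as attribute `"spec"`.
#' @export
render_patch <- function(spec) {
  stopifnot(inherits(spec, "patch_spec"))
  n <- spec$patch_px
  bg <- spec$background
  img <- matrix(bg$mean, n, n)
  if (bg$amplitude > 0) {
    if (bg$model == "powerlaw") {
      img <- img + bg$amplitude * powerlaw_texture(n, bg$beta, spec$seed)
    } else if (bg$model == "flat") {
      # flat background: amplitude ignored beyond the mean level
    } else {
      stop("unknown background model: ", bg$model, call. = FALSE)
    }
  }
  ax <- (seq_len(n) - (n + 1) / 2) * spec$pixel_pitch  # mm from patch center
  r <- spec$lesion_diameter / 2
  rho2 <- outer(ax^2, ax^2, `+`)
  chord <- matrix(0, n, n)
  inside <- rho2 <= r^2
  chord[inside] <- sqrt(r^2 - rho2[inside]) / r
  structure(img + spec$contrast * chord, spec = spec)
}

#' Automatically measure the lesion size in a patch
#'
#' Subtracts a robust background level (the median of the patch border),
#' locates the peak near `center_hint` (patch center by default), and
#' measures the extent of the contiguous above-threshold run along the row
#' and the column through the peak — two orthogonal sizes, converted to mm
#' via the pixel pitch and rounded to the 0.1-mm recording precision.
#'
#' @param image Matrix from [render_patch()] (or any image matrix).
#' @param pixel_pitch Pixel pitch in mm; taken from the attached spec when
#'   present.
#' @param center_hint Optional `c(row, col)` pixel location near the lesion;
#'   the peak is searched within `search_px` of it.
#' @param threshold Fraction of the background-subtracted peak defining the
#'   lesion extent (default 0.1).
#' @param search_px Half-width of the peak search window around the hint.
#' @return Named numeric vector `c(size_a = , size_b = )` in mm (row and
#'   column extents).
#' @export
auto_measure <- function(image, pixel_pitch = NULL, center_hint = NULL,
                         threshold = 0.1, search_px = 10) {
  spec <- attr(image, "spec")
  if (is.null(pixel_pitch)) {
    if (is.null(spec)) stop("supply `pixel_pitch`", call. = FALSE)
    pixel_pitch <- spec$pixel_pitch
  }
  n_r <- nrow(image); n_c <- ncol(image)
  bg_level <- stats::median(c(image[1, ], image[n_r, ], image[, 1],
                              image[, n_c]))
  img <- image - bg_level
  if (is.null(center_hint)) {
    center_hint <- c((n_r + 1) / 2, (n_c + 1) / 2)
  }
  rows <- max(1, round(center_hint[1]) - search_px):
    min(n_r, round(center_hint[1]) + search_px)
  cols <- max(1, round(center_hint[2]) - search_px):
    min(n_c, round(center_hint[2]) + search_px)
  win <- img[rows, cols, drop = FALSE]
  pk <- which(win == max(win), arr.ind = TRUE)[1, ]
  peak_r <- rows[pk[1]]; peak_c <- cols[pk[2]]
  peak <- img[peak_r, peak_c]
  if (!is.finite(peak) || peak <= 0) {
    stop("lesion not found: no signal above background", call. = FALSE)
  }
  run_length <- function(profile, at) {
    above <- profile > threshold * peak
    if (!above[at]) {
      stop("lesion not found: peak below measurement threshold",
           call. = FALSE)
    }
    lo <- at; while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- at; while (hi < length(above) && above[hi + 1]) hi <- hi + 1
    hi - lo + 1
  }
  ext_col <- run_length(img[peak_r, ], peak_c)  # along the row
  ext_row <- run_length(img[, peak_c], peak_r)  # along the column
  c(size_a = round_size(ext_col * pixel_pitch),
    size_b = round_size(ext_row * pixel_pitch))
}

#' Write a patch to disk as a 16-bit image with a JSON sidecar
#'
#' Intensities are linearly rescaled to the 16-bit range; the sidecar JSON
#' records the rendering spec (including the ground-truth diameter) and the
#' rescaling so the image is interpretable on its own.
#'
#' @param image Matrix from [render_patch()].
#' @param path Output path ending in `.tiff`/`.tif` or `.png`.
#' @return The image path, invisibly.
#' @export
write_patch <- function(image, path) {
  spec <- attr(image, "spec")
  lo <- min(image); hi <- max(image)
  scaled <- if (hi > lo) (image - lo) / (hi - lo) else image * 0
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("writing TIFF requires the `tiff` package", call. = FALSE)
    }
    tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("writing PNG requires the `png` package", call. = FALSE)
    }
    png::writePNG(scaled, path)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  sidecar <- sub(sprintf("\\.%s$", ext), ".json", path)
  meta <- list(intensity_min = lo, intensity_max = hi)
  if (!is.null(spec)) {
    meta <- c(meta, spec[c("lesion_diameter", "pixel_pitch", "patch_px",
                           "contrast", "background")])
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
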