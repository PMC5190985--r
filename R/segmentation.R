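#' Below-canopy image container
#'
#' Wraps an H x W x 3 array of 8-bit RGB values together with the
#' acquisition metadata of the below-canopy protocol: view zenith angle
#' (57.5 degrees by protocol), row side, offset along the row from the
#' vineyard pole, and vine / sampling-area identifiers.
#'
#' @param pixels numeric H x W x 3 array, channel values in `[0, 255]`.
#' @param view_angle_deg view zenith angle in degrees; the protocol value is
#'   57.5, where the leaf projection function is close to 0.5 for any leaf
#'   angle distribution.
#' @param side which side of the row the shot was taken from
#'   (`"left"`/`"right"`), or `NA`.
#' @param offset_cm distance along the row from the pole in cm (protocol
#'   values 20 and 40), or `NA`.
#' @param vine_id,area_id identifiers, or `NA`.
#' @return An object of class `canopy_image`.
#' @export
canopy_image <- function(pixels, view_angle_deg = 57.5, side = NA,
                         offset_cm = NA, vine_id = NA, area_id = NA) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    vinelai_input_error("'pixels' must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    vinelai_input_error("image must have at least one pixel")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    vinelai_input_error("channel values must lie in [0, 255]")
  if (!is.na(side)) side <- match.arg(as.character(side), c("left", "right"))
  structure(
    list(pixels = pixels, view_angle_deg = view_angle_deg, side = side,
         offset_cm = offset_cm, vine_id = vine_id, area_id = area_id),
    class = "canopy_image"
  )
}

#' @export
print.canopy_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<canopy_image> %d x %d px, view angle %.1f deg", d[1], d[2],
              x$view_angle_deg))
  if (!is.na(x$vine_id)) cat(", vine", x$vine_id)
  if (!is.na(x$side)) cat(",", x$side, "side")
  if (!is.na(x$offset_cm)) cat(sprintf(", offset %g cm", x$offset_cm))
  cat("\n")
  invisible(x)
}

#' Read a below-canopy image from PNG or JPEG
#'
#' @param path file path; format is chosen by extension (`.png`, `.jpg`,
#'   `.jpeg`, case-insensitive).
#' @param ... metadata passed on to [canopy_image()].
#' @return A [canopy_image()].
#' @export
read_canopy_image <- function(path, ...) {
  if (!file.exists(path))
    vinelai_input_error(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    vinelai_input_error(sprintf("unsupported image format '.%s': %s", ext, path))
  )
  if (length(dim(raw)) == 2L)                      # greyscale -> replicate
    raw <- array(raw, c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
  canopy_image(round(raw * 255), ...)
}

#' Convert an RGB canopy image to Hue-Saturation-Brightness
#'
#' Pure channel mapping to HSB (identical to HSV): hue in degrees
#' `[0, 360)`, saturation and brightness as fractions in `[0, 1]`. No
#' thresholding is applied. Achromatic pixels (R = G = B) get hue 0 by
#' convention.
#'
#' @param image a [canopy_image()] or a bare H x W x 3 array in `[0, 255]`.
#' @return An object of class `hsb_image` with matrices `hue`, `saturation`
#'   and `brightness` of the source shape.
#' @export
rgb_to_hsb <- function(image) {
  if (!inherits(image, "canopy_image")) image <- canopy_image(image)
  px <- image$pixels
  d <- dim(px)
  rgbm <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 255)
  shape <- d[1:2]
  structure(
    list(hue        = matrix(hsv[1, ] * 360, shape[1], shape[2]),
         saturation = matrix(hsv[2, ], shape[1], shape[2]),
         brightness = matrix(hsv[3, ], shape[1], shape[2])),
    class = "hsb_image"
  )
}

#' Segmentation thresholds
#'
#' Parameters of the unsupervised sky/vegetation rule. The default rule is
#' two-stage: (a) an Otsu threshold on the brightness channel marks bright
#' pixels as sky candidates; (b) candidates that are both strongly saturated
#' (`saturation > sat_max`) and green-hued (hue inside `green_hue_deg`) are
#' reassigned to vegetation, so bright sunlit leaves are not mistaken for
#' sky. When the brightness histogram is effectively unimodal - Otsu's
#' between/total variance ratio below `separability_min`, as on pure-sky or
#' fully closed frames - a fixed brightness cut `fallback_cut` is used
#' instead, keeping the behaviour deterministic.
#'
#' @param brightness_cut fixed brightness threshold in `[0, 1]`; `NULL`
#'   (default) selects the threshold automatically by Otsu's method.
#' @param sat_max saturation above which a bright pixel may be a sunlit
#'   leaf rather than sky.
#' @param green_hue_deg two-element hue band (degrees) treated as foliage.
#' @param separability_min minimum Otsu between/total variance ratio for
#'   the automatic threshold to be trusted.
#' @param fallback_cut fixed brightness cut used for unimodal images.
#' @param median_filter apply a 3 x 3 median pre-filter to the brightness
#'   channel before thresholding (mitigates JPEG chroma artifacts; off by
#'   default so the default pipeline is bit-reproducible).
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(brightness_cut = NULL, sat_max = 0.5,
                       green_hue_deg = c(60, 180), separability_min = 0.8,
                       fallback_cut = 0.75, median_filter = FALSE) {
  if (!is.null(brightness_cut) &&
      (brightness_cut < 0 || brightness_cut > 1))
    vinelai_config_error("'brightness_cut' must lie in [0, 1]")
  if (length(green_hue_deg) != 2L || green_hue_deg[1] >= green_hue_deg[2])
    vinelai_config_error("'green_hue_deg' must be an increasing pair")
  structure(
    list(brightness_cut = brightness_cut, sat_max = sat_max,
         green_hue_deg = green_hue_deg, separability_min = separability_min,
         fallback_cut = fallback_cut, median_filter = median_filter),
    class = "seg_params"
  )
}

# Otsu effectiveness: between-class / total variance at threshold `thr`.
# 0 when one class is empty or the channel is constant.
otsu_separability <- function(b, thr) {
  tot <- mean((b - mean(b))^2)
  if (tot < 1e-12) return(0)
  lo <- b <= thr
  w0 <- mean(lo)
  if (w0 == 0 || w0 == 1) return(0)
  w0 * (1 - w0) * (mean(b[lo]) - mean(b[!lo]))^2 / tot
}

#' Segment sky from vegetation in HSB space
#'
#' Labels every pixel sky or vegetation, fully unsupervised under the
#' default [seg_params()]. Deterministic given the image and parameters.
#'
#' @param hsb an `hsb_image` from [rgb_to_hsb()], or a [canopy_image()]
#'   (converted on the fly).
#' @param params a [seg_params()] object.
#' @return An object of class `segmentation_mask`: logical matrix `mask`
#'   (`TRUE` = sky), pixel counts `n_sky` and `n_total`, and the brightness
#'   threshold used.
#' @export
segment_sky <- function(hsb, params = seg_params()) {
  if (inherits(hsb, "canopy_image")) hsb <- rgb_to_hsb(hsb)
  if (!inherits(hsb, "hsb_image"))
    vinelai_input_error("'hsb' must be an hsb_image or canopy_image")
  b <- hsb$brightness
  if (isTRUE(params$median_filter) && length(b) > 9L)
    b <- EBImage::medianFilter(b, size = 1L)

  if (!is.null(params$brightness_cut)) {
    thr <- params$brightness_cut
  } else {
    thr <- EBImage::otsu(b, range = c(0, 1), levels = 256L)
    if (!is.finite(thr) ||
        otsu_separability(b, thr) < params$separability_min)
      thr <- params$fallback_cut
  }

  sky <- b > thr
  sunlit <- sky & hsb$saturation > params$sat_max &
    hsb$hue >= params$green_hue_deg[1] & hsb$hue <= params$green_hue_deg[2]
  sky[sunlit] <- FALSE

  structure(
    list(mask = sky, n_sky = sum(sky), n_total = length(sky),
         brightness_threshold = thr),
    class = "segmentation_mask"
  )
}

#' Gap fraction from a segmentation mask
#'
#' The gap fraction P0 at the acquisition view angle is the sky pixel share
#' of the frame, `n_sky / n_total`. A frame with no sky pixel at all is
#' flagged `saturated`: the canopy is locally closed and P0 = 0 carries no
#' invertible information (see [clamp_saturated()]).
#'
#' @param mask a `segmentation_mask` from [segment_sky()].
#' @return An object of class `gap_fraction` with fields `p0`, `saturated`
#'   and `mask`.
#' @export
gap_fraction <- function(mask) {
  if (!inherits(mask, "segmentation_mask"))
    vinelai_input_error("'mask' must be a segmentation_mask")
  if (mask$n_total == 0L)
    vinelai_input_error("mask has zero pixels")
  structure(
    list(p0 = mask$n_sky / mask$n_total,
         saturated = mask$n_sky == 0L,
         mask = mask),
    class = "gap_fraction"
  )
}

#' @export
print.gap_fraction <- function(x, ...) {
  cat(sprintf("<gap_fraction> P0 = %.4f (%d / %d sky pixels)%s\n",
              x$p0, x$mask$n_sky, x$mask$n_total,
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Write a segmentation mask as a PNG image
#'
#' Sky pixels are written as white (255), vegetation as black (0).
#'
#' @param mask a `segmentation_mask`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (!inherits(mask, "segmentation_mask"))
    vinelai_input_error("'mask' must be a segmentation_mask")
  png::writePNG(mask$mask * 1, path)
  invisible(path)
}
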