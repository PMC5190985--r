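#' Synthetic canopy scene specification
#'
#' Describes a below-canopy scene rendered by the Boolean leaf-disk model:
#' opaque leaf disks of radius `leaf_disk_radius_px` placed by a Poisson
#' process over a sky background. With disk-center intensity
#' `lambda = k * lai_true / (pi * r^2)` per pixel^2, the probability that
#' any pixel stays uncovered is exactly `exp(-k * lai_true)` - the same
#' exponential law the transmittance inversion assumes - so the generator
#' is an honest oracle for parameter recovery: segment the render, invert
#' the measured gap fraction, and the estimate should come back to
#' `lai_true` up to binomial sampling noise.
#'
#' The clumped variant replaces the Poisson process with a Matern cluster
#' process (disk centers scattered around Poisson parent points, mimicking
#' leaves bunched along shoots) at the same expected disk count. Clustering
#' raises the expected gap fraction above `exp(-k * lai_true)` (Jensen's
#' inequality on the random local density), so inversion underestimates the
#' true LAI - the saturation/clumping bias reported for dense row canopies.
#'
#' @param lai_true target true LAI (>= 0).
#' @param k extinction coefficient used for rendering; default the
#'   57.5-degree protocol value from [inversion_model()].
#' @param width,height image size in pixels.
#' @param leaf_disk_radius_px leaf disk radius in pixels.
#' @param clumped use the Matern cluster variant.
#' @param cluster_size mean disks per cluster (clumped variant).
#' @param cluster_radius_px cluster scatter radius (clumped variant).
#' @param jitter apply per-pixel chromatic jitter around the sky and leaf
#'   reference colors; `FALSE` renders exact two-tone images.
#' @param seed integer seed; every random draw in the render is governed
#'   by it and global RNG state is left untouched.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(lai_true, k = inversion_model()$k,
                       width = 512, height = 512, leaf_disk_radius_px = 6,
                       clumped = FALSE, cluster_size = 25,
                       cluster_radius_px = 20, jitter = TRUE, seed = 1L) {
  if (lai_true < 0) vinelai_input_error("'lai_true' must be >= 0")
  if (k <= 0) vinelai_input_error("'k' must be positive")
  r <- leaf_disk_radius_px
  if (r <= 0 || r >= min(width, height))
    vinelai_input_error("'leaf_disk_radius_px' must be in (0, min(width, height))")
  structure(
    list(lai_true = lai_true, k = k, width = as.integer(width),
         height = as.integer(height), leaf_disk_radius_px = r,
         clumped = clumped, cluster_size = cluster_size,
         cluster_radius_px = cluster_radius_px, jitter = jitter,
         seed = as.integer(seed),
         # reference palettes: HSB center and half-width of uniform jitter
         sky_hsb  = c(h = 210, s = 0.15, b = 0.95),
         sky_jit  = c(h = 15,  s = 0.08, b = 0.04),
         leaf_hsb = c(h = 120, s = 0.75, b = 0.33),
         leaf_jit = c(h = 25,  s = 0.12, b = 0.10)),
    class = "scene_spec"
  )
}

# disk centers of the (possibly clustered) point process, on a window
# extended by r beyond the pixel-center lattice so coverage is edge-free
draw_disk_centers <- function(spec) {
  r <- spec$leaf_disk_radius_px
  x0 <- 1 - r; x1 <- spec$width + r
  y0 <- 1 - r; y1 <- spec$height + r
  area <- (x1 - x0) * (y1 - y0)
  lambda <- spec$k * spec$lai_true / (pi * r^2)
  if (!spec$clumped) {
    n <- rpois(1L, lambda * area)
    cbind(x = runif(n, x0, x1), y = runif(n, y0, y1))
  } else {
    n_par <- rpois(1L, lambda * area / spec$cluster_size)
    if (n_par == 0L) return(cbind(x = numeric(0), y = numeric(0)))
    px <- runif(n_par, x0, x1)
    py <- runif(n_par, y0, y1)
    kids <- rpois(n_par, spec$cluster_size)
    idx <- rep.int(seq_len(n_par), kids)
    m <- length(idx)
    rho <- spec$cluster_radius_px * sqrt(runif(m))   # uniform on the disc
    phi <- runif(m, 0, 2 * pi)
    cbind(x = px[idx] + rho * cos(phi), y = py[idx] + rho * sin(phi))
  }
}

# TRUE where a leaf disk covers the pixel center
rasterize_disks <- function(centers, width, height, r) {
  covered <- matrix(FALSE, height, width)
  if (nrow(centers) == 0L) return(covered)
  r2 <- r^2
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    ix <- max(1L, ceiling(cx - r)):min(width,  floor(cx + r))
    iy <- max(1L, ceiling(cy - r)):min(height, floor(cy + r))
    if (ix[1] > ix[length(ix)] || iy[1] > iy[length(iy)]) next
    dx2 <- (ix - cx)^2
    dy2 <- (iy - cy)^2
    covered[iy, ix] <- covered[iy, ix] | outer(dy2, dx2, `+`) <= r2
  }
  covered
}

hsb_field <- function(n, center, jit, jitter) {
  if (!jitter) jit <- c(h = 0, s = 0, b = 0)
  h <- (center["h"] + runif(n, -jit["h"], jit["h"])) %% 360
  s <- pmin(1, pmax(0, center["s"] + runif(n, -jit["s"], jit["s"])))
  b <- pmin(1, pmax(0, center["b"] + runif(n, -jit["b"], jit["b"])))
  list(h = h, s = s, b = b)
}

#' Render a synthetic below-canopy image
#'
#' Draws the leaf-disk point process of a [scene_spec()], rasterizes the
#' disks over a sky background, and colors every pixel from the sky or
#' leaf HSB palette (with seeded chromatic jitter unless disabled).
#' Deterministic for a given seed; two renders of the same spec are
#' pixel-identical.
#'
#' @param spec a [scene_spec()], or a number taken as `lai_true` (with
#'   `...` passed to [scene_spec()]).
#' @param ... additional [scene_spec()] arguments when `spec` is numeric.
#' @return A [canopy_image()]. The true vegetation mask and the realised
#'   sky share are attached as attributes `leaf_mask` and
#'   `gap_fraction_true`; `lai_true` carries the target.
#' @export
render_canopy <- function(spec, ...) {
  if (is.numeric(spec)) spec <- scene_spec(spec, ...)
  if (!inherits(spec, "scene_spec"))
    vinelai_input_error("'spec' must be a scene_spec or a numeric lai_true")
  W <- spec$width; H <- spec$height
  img <- withr::with_seed(spec$seed, {
    covered <- rasterize_disks(draw_disk_centers(spec), W, H,
                               spec$leaf_disk_radius_px)
    n <- H * W
    sky <- hsb_field(n, spec$sky_hsb, spec$sky_jit, spec$jitter)
    leaf <- hsb_field(n, spec$leaf_hsb, spec$leaf_jit, spec$jitter)
    is_leaf <- as.vector(covered)
    h <- ifelse(is_leaf, leaf$h, sky$h)
    s <- ifelse(is_leaf, leaf$s, sky$s)
    b <- ifelse(is_leaf, leaf$b, sky$b)
    rgb <- grDevices::col2rgb(grDevices::hsv(h / 360, s, b))
    px <- array(0, c(H, W, 3L))
    px[, , 1] <- rgb[1, ]; px[, , 2] <- rgb[2, ]; px[, , 3] <- rgb[3, ]
    out <- canopy_image(px)
    attr(out, "leaf_mask") <- covered
    attr(out, "gap_fraction_true") <- 1 - mean(covered)
    attr(out, "lai_true") <- spec$lai_true
    out
  })
  img
}

#' Write a canopy image to PNG
#'
#' @param image a [canopy_image()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_canopy_png <- function(image, path) {
  if (!inherits(image, "canopy_image"))
    vinelai_input_error("'image' must be a canopy_image")
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Synthetic NDVI raster with a known linear LAI relationship
#'
#' Builds the NDVI field whose calibrated back-transform recovers a given
#' true LAI grid: `ndvi = (lai - b) / a` plus optional seeded Gaussian
#' noise, clipped to the NDVI domain `[-1, 1]`. No-data cells are
#' preserved.
#'
#' @param lai_field matrix (or [lai_grid()]) of true LAI values.
#' @param a,b slope and intercept of the forward relation
#'   `lai = a * ndvi + b`; `a` must be nonzero.
#' @param noise_sd standard deviation of additive NDVI noise (default 0).
#' @param seed integer seed for the noise.
#' @param cellsize,xll,yll grid geometry for the result.
#' @return A [lai_grid()] of NDVI values.
#' @export
make_ndvi_field <- function(lai_field, a, b, noise_sd = 0, seed = 1L,
                            cellsize = 1, xll = 0, yll = 0) {
  if (a == 0) vinelai_input_error("'a' must be nonzero")
  if (inherits(lai_field, "lai_grid")) {
    cellsize <- lai_field$cellsize; xll <- lai_field$xll; yll <- lai_field$yll
    lai_field <- lai_field$grid
  }
  lai_field <- as.matrix(lai_field)
  ndvi <- (lai_field - b) / a
  if (noise_sd > 0)
    ndvi <- ndvi + withr::with_seed(seed,
      matrix(rnorm(length(ndvi), sd = noise_sd), nrow(ndvi)))
  ndvi <- pmin(pmax(ndvi, -1), 1)
  lai_grid(ndvi, cellsize = cellsize, xll = xll, yll = yll, range = c(-1, 1))
}

#' Generate a synthetic vineyard fixture set on disk
#'
#' Renders a full protocol-compatible campaign: for each sampling area
#' (one true LAI per area) and each vine, four replicate below-canopy
#' images (two sides times two pole offsets), written as PNG files next to
#' a manifest CSV with columns `image_path`, `vine_id`, `area_id`, `side`,
#' `offset_cm` - the input format of [estimate_manifest()].
#'
#' @param dir output directory (created if missing).
#' @param lai_by_area named numeric vector: true LAI per sampling area.
#' @param n_vines vines per area.
#' @param seed integer master seed; per-image seeds are derived from it.
#' @param ... rendering options forwarded to [scene_spec()]
#'   (e.g. `width`, `height`, `clumped`).
#' @return Path of the manifest CSV, invisibly; the manifest gains a
#'   `lai_true` column for validation.
#' @export
make_synthetic_vineyard <- function(dir, lai_by_area = c(A1 = 0.5, A2 = 1.0),
                                    n_vines = 2, seed = 1L, ...) {
  if (is.null(names(lai_by_area)))
    names(lai_by_area) <- paste0("A", seq_along(lai_by_area))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sides <- c("left", "left", "right", "right")
  offsets <- c(20, 40, 20, 40)
  rows <- list()
  img_seed <- seed
  for (a in names(lai_by_area)) {
    for (v in seq_len(n_vines)) {
      vine <- sprintf("%s_v%d", a, v)
      for (rpl in 1:4) {
        img_seed <- img_seed + 1L
        spec <- scene_spec(lai_by_area[[a]], seed = img_seed, ...)
        fn <- sprintf("%s_r%d.png", vine, rpl)
        write_canopy_png(render_canopy(spec), file.path(dir, fn))
        rows[[length(rows) + 1L]] <- data.frame(
          image_path = fn, vine_id = vine, area_id = a,
          side = sides[rpl], offset_cm = offsets[rpl],
          lai_true = lai_by_area[[a]], stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
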