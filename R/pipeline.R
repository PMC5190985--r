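#' Estimate LAI from a single below-canopy image
#'
#' Runs the full per-image chain: HSB conversion, sky segmentation, gap
#' fraction, saturation clamp, transmittance inversion.
#'
#' @param image a [canopy_image()] or an image file path.
#' @param model an [inversion_model()].
#' @param params segmentation [seg_params()].
#' @return A one-row data frame: `n_sky`, `n_total`, `p0` (clamped),
#'   `saturated`, `lai` (plant scale).
#' @export
estimate_image <- function(image, model = inversion_model(),
                           params = seg_params()) {
  if (is.character(image)) image <- read_canopy_image(image)
  gf <- gap_fraction(segment_sky(rgb_to_hsb(image), params))
  cl <- clamp_saturated(gf$p0, gf$mask$n_total)
  data.frame(
    n_sky = gf$mask$n_sky, n_total = gf$mask$n_total,
    p0 = cl$p0, saturated = gf$saturated | cl$saturated,
    lai = lai_from_gap_fraction(cl$p0, model)
  )
}

#' Batch LAI estimation from a manifest
#'
#' Processes a campaign manifest (CSV or data frame with columns
#' `image_path`, `vine_id`, `area_id` and optionally `side`, `offset_cm`),
#' producing the three protocol reporting levels: per-replicate (one row
#' per image), per-vine (replicates averaged) and per-sampling-area
#' (vines averaged, plus the vineyard-scale LAI under the geometry).
#' Unreadable images are recorded as per-row errors and the run continues.
#'
#' @param manifest data frame or CSV path.
#' @param geom a [protocol_geometry()].
#' @param model an [inversion_model()].
#' @param params segmentation [seg_params()].
#' @param image_dir directory against which relative `image_path` entries
#'   are resolved; defaults to the manifest's own directory when `manifest`
#'   is a path.
#' @return A list of class `lai_run` with data frames `replicates`,
#'   `vines` and `areas`.
#' @export
estimate_manifest <- function(manifest, geom = geometry_preset("field"),
                              model = inversion_model(),
                              params = seg_params(), image_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(image_dir)) image_dir <- dirname(manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("image_path", "vine_id", "area_id")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    vinelai_input_error(paste("manifest is missing columns:",
                              paste(miss, collapse = ", ")))
  if (nrow(manifest) == 0L)
    vinelai_input_error("manifest is empty")
  check_geom(geom)

  one <- function(i) {
    path <- manifest$image_path[i]
    if (!is.null(image_dir) && !file.exists(path))
      path <- file.path(image_dir, manifest$image_path[i])
    res <- tryCatch(estimate_image(path, model, params), error = function(e)
      data.frame(n_sky = NA_integer_, n_total = NA_integer_, p0 = NA_real_,
                 saturated = NA, lai = NA_real_, error = conditionMessage(e)))
    if (is.null(res$error)) res$error <- NA_character_
    cbind(manifest[i, need, drop = FALSE], res, row.names = NULL)
  }
  replicates <- do.call(rbind, lapply(seq_len(nrow(manifest)), one))

  vines <- do.call(rbind, lapply(split(replicates, replicates$vine_id),
    function(d) {
      ok <- !is.na(d$lai)
      laip <- NA_real_
      if (any(ok))
        laip <- aggregate_vine(d$lai[ok], vine_id = d$vine_id[1])$laip
      data.frame(vine_id = d$vine_id[1], area_id = d$area_id[1],
                 n_replicates = sum(ok), laip = laip, n_errors = sum(!ok))
    }))
  vines <- vines[order(vines$area_id, vines$vine_id), , drop = FALSE]
  row.names(vines) <- NULL

  areas <- do.call(rbind, lapply(split(vines, vines$area_id), function(d) {
    laip <- d$laip[!is.na(d$laip)]
    if (length(laip) == 0L)
      return(data.frame(area_id = d$area_id[1], n_vines = 0L,
                        laip = NA_real_, laiv = NA_real_))
    est <- aggregate_area(laip, geom, area_id = d$area_id[1])
    data.frame(area_id = d$area_id[1], n_vines = est$n_vines,
               laip = est$laip_mean, laiv = est$laiv)
  }))
  areas <- areas[order(areas$area_id), , drop = FALSE]
  row.names(areas) <- NULL

  structure(list(replicates = replicates, vines = vines, areas = areas,
                 geom = geom, model = model),
            class = "lai_run")
}

#' @export
print.lai_run <- function(x, ...) {
  cat(sprintf("<lai_run> %d replicate(s), %d vine(s), %d area(s)\n",
              nrow(x$replicates), nrow(x$vines), nrow(x$areas)))
  print(x$areas)
  invisible(x)
}

#' Write the three reporting levels of a run to CSV
#'
#' Writes `replicates.csv`, `vines.csv` and `areas.csv` at full double
#' precision (rounding is for display only, never for stored output).
#'
#' @param run an `lai_run` from [estimate_manifest()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_csv <- function(run, dir) {
  if (!inherits(run, "lai_run"))
    vinelai_input_error("'run' must be an lai_run")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (level in c("replicates", "vines", "areas"))
    write.csv(run[[level]], file.path(dir, paste0(level, ".csv")),
              row.names = FALSE)
  invisible(dir)
}
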