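#' Specific leaf area from leaf discs
#'
#' The destructive reference uses discs of known area punched from a leaf
#' subsample (the protocol takes 40 discs of 0.01 m^2, one per leaf of a
#' mixed-age 40-leaf subsample) and weighed jointly while fresh:
#' `SLA = (n_discs * disc_area) / discs_total_weight`, in m^2 per gram of
#' fresh weight. The pooled-weight form matches weighing all discs
#' together rather than averaging per-disc ratios.
#'
#' @param discs_total_weight_g total fresh weight of the discs, g.
#' @param n_discs number of discs (protocol value 40).
#' @param disc_area_m2 area of one disc, m^2 (protocol value 0.01).
#' @return Specific leaf area, m^2 g^-1 fresh weight.
#' @export
specific_leaf_area <- function(discs_total_weight_g, n_discs = 40,
                               disc_area_m2 = 0.01) {
  if (any(discs_total_weight_g <= 0))
    vinelai_input_error("disc weight must be positive")
  if (any(n_discs < 1) || any(disc_area_m2 <= 0))
    vinelai_input_error("'n_discs' must be >= 1 and 'disc_area_m2' positive")
  n_discs * disc_area_m2 / discs_total_weight_g
}

#' Destructive vineyard LAI from leaf fresh weight
#'
#' The plant's leaf area is its total leaf fresh weight times the specific
#' leaf area; referring it to the ground surface allotted to one vine
#' (row spacing times vine spacing) gives the reference vineyard LAI:
#' `LAIv = W * SLA / (R * V)`.
#'
#' @param W total leaf fresh weight of the vine, g.
#' @param sla specific leaf area, m^2 g^-1 fresh weight
#'   (see [specific_leaf_area()]).
#' @param geom a [protocol_geometry()]; only `R` and `V` are used.
#' @return Vineyard LAI (dimensionless).
#' @export
destructive_laiv <- function(W, sla, geom = geometry_preset("field")) {
  check_geom(geom)
  if (any(W <= 0)) vinelai_input_error("leaf fresh weight must be positive")
  if (any(sla <= 0)) vinelai_input_error("specific leaf area must be positive")
  W * sla / (geom$R * geom$V)
}

#' Theoretical leaf number vigor index
#'
#' TL = shoots per plant times the mean number of leaves per shoot
#' (counted on a 5-shoot subsample in the field protocol). A quick
#' non-destructive descriptor of plant vigor used as a cross-check against
#' LAI estimates.
#'
#' @param n_shoots shoot count per plant (>= 0).
#' @param leaves_per_shoot mean leaves per shoot (>= 0).
#' @return TL, dimensionless; vectorised.
#' @export
theoretical_leaf_number <- function(n_shoots, leaves_per_shoot) {
  if (any(n_shoots < 0) || any(leaves_per_shoot < 0))
    vinelai_input_error("counts must be non-negative")
  n_shoots * leaves_per_shoot
}

#' Destructive reference table from a measurement CSV
#'
#' Computes SLA, the destructive vineyard LAI and TL for every row of a
#' destructive-measurement table with columns `vine_id`,
#' `leaf_fresh_weight_g`, `n_discs`, `disc_area_m2`, `discs_weight_g` and
#' optionally `n_shoots`, `leaves_per_shoot`.
#'
#' @param x a data frame or CSV path.
#' @param geom a [protocol_geometry()].
#' @return The input table with `sla`, `laiv_destructive` and (when shoot
#'   counts are present) `tl` columns appended.
#' @export
destructive_table <- function(x, geom = geometry_preset("field")) {
  if (is.character(x)) x <- read.csv(x, stringsAsFactors = FALSE)
  need <- c("vine_id", "leaf_fresh_weight_g", "n_discs", "disc_area_m2",
            "discs_weight_g")
  miss <- setdiff(need, names(x))
  if (length(miss))
    vinelai_input_error(paste("missing columns:", paste(miss, collapse = ", ")))
  x$sla <- specific_leaf_area(x$discs_weight_g, x$n_discs, x$disc_area_m2)
  x$laiv_destructive <- destructive_laiv(x$leaf_fresh_weight_g, x$sla, geom)
  if (all(c("n_shoots", "leaves_per_shoot") %in% names(x)))
    x$tl <- theoretical_leaf_number(x$n_shoots, x$leaves_per_shoot)
  x
}
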