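ZONE_LABELS <- c(LESION_TYPES, "early_acute", "late_chronic", "total_lesion",
                 "perilesional", "structurally_normal")
EARLY_ACUTE_TYPES <- c("srf", "irf", "drusen_ped", "nv")
LATE_CHRONIC_TYPES <- c("fibrosis", "atrophy")

#' Union of all lesion masks of an eye
#'
#' @param lesions list of `lesion_mask` objects sharing a frame.
#' @param frame frame to use when `lesions` is empty.
#' @return a [binary_mask()] (the total lesion area).
#' @export
total_lesion_mask <- function(lesions, frame = NULL) {
  if (length(lesions) == 0L) {
    if (is.null(frame)) stop("frame required for an empty lesion list", call. = FALSE)
    return(binary_mask(frame))
  }
  out <- lesions[[1]]$mask
  for (l in lesions[-1]) out <- mask_union(out, l$mask)
  out
}

#' Peri-lesional zone mask
#'
#' The band of retina within `border_mm` (default 0.3 mm, i.e. 1 degree of
#' visual angle) of the lesion boundary, excluding the lesion itself:
#' morphological dilation of the lesion union by a Euclidean disc of radius
#' `border_mm`, minus the union. Computed via the exact Euclidean distance
#' transform, so the annulus is disjoint from the lesion by construction.
#'
#' @param union [binary_mask()] of the total lesion area.
#' @param border_mm border thickness in mm (> 0).
#' @return a [binary_mask()]; empty when `union` is empty.
#' @export
perilesional_mask <- function(union, border_mm = 0.3) {
  stopifnot(inherits(union, "binary_mask"))
  if (!is.numeric(border_mm) || length(border_mm) != 1L || border_mm <= 0)
    stop("border_mm must be positive", call. = FALSE)
  if (mask_is_empty(union)) return(binary_mask(union$frame))
  border_px <- border_mm / frame_scale_mm(union$frame)
  # distance of every non-lesion pixel center to the nearest lesion pixel center
  d <- EBImage::distmap(matrix(as.numeric(!union$pixels),
                               nrow = nrow(union$pixels)))
  d <- matrix(as.numeric(d), nrow = nrow(union$pixels))
  binary_mask(union$frame, !union$pixels & d <= border_px)
}

#' Structurally-normal zone mask
#'
#' Retina inside the analysis region with no apparent pathological lesion:
#' the analysis region minus the lesion union minus the peri-lesional band.
#' Together the three zones partition the analysis region exactly.
#'
#' @param analysis_region,union,peri [binary_mask()] objects on one frame.
#' @return a [binary_mask()].
#' @export
structurally_normal_mask <- function(analysis_region, union, peri) {
  check_same_frame(analysis_region, union)
  check_same_frame(analysis_region, peri)
  binary_mask(analysis_region$frame,
              analysis_region$pixels & !union$pixels & !peri$pixels)
}

#' Default analysis region: disc about the fovea
#'
#' The region over which structurally-normal retina is defined; the default
#' 1.5 mm (5 degree) radius matches the extent of the microperimetry grid.
#'
#' @param frame an [enface_frame()].
#' @param radius_mm region radius in mm.
#' @return a [binary_mask()].
#' @export
analysis_region <- function(frame, radius_mm = deg_to_mm(5)) {
  rasterize_disc(c(0, 0), 2 * radius_mm, frame)
}

#' Build the full zone set of an eye
#'
#' Assembles per-type lesion masks plus the composite zones: total lesion,
#' early/acute (SRF, IRF, drusen/PED, NV), late/chronic (fibrosis, atrophy),
#' peri-lesional band and structurally-normal retina. Composite zones are
#' unions of member-type masks computed before any point assignment.
#'
#' @param lesions list of `lesion_mask` objects.
#' @param frame an [enface_frame()].
#' @param border_mm peri-lesional border thickness (mm).
#' @param region analysis-region mask; default [analysis_region()].
#' @return named list of [binary_mask()] zones.
#' @export
build_zones <- function(lesions, frame, border_mm = 0.3, region = NULL) {
  if (is.null(region)) region <- analysis_region(frame)
  zones <- list()
  for (l in lesions) {
    zones[[l$lesion_type]] <- if (is.null(zones[[l$lesion_type]]))
      l$mask else mask_union(zones[[l$lesion_type]], l$mask)
  }
  union <- total_lesion_mask(lesions, frame)
  peri <- perilesional_mask(union, border_mm)
  union_of <- function(types) {
    types <- intersect(types, names(zones))
    if (!length(types)) return(NULL)
    out <- zones[[types[1]]]
    for (t in types[-1]) out <- mask_union(out, zones[[t]])
    out
  }
  ea <- union_of(EARLY_ACUTE_TYPES)
  lc <- union_of(LATE_CHRONIC_TYPES)
  if (!is.null(ea)) zones$early_acute <- ea
  if (!is.null(lc)) zones$late_chronic <- lc
  if (length(lesions)) zones$total_lesion <- union
  zones$perilesional <- peri
  zones$structurally_normal <- structurally_normal_mask(region, union, peri)
  zones
}
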