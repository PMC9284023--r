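#' Physical specification of a tissue cage
#'
#' A tissue cage is a length of silicone tubing, sealed at both ends and
#' perforated with a fixed number of biopsy-punch holes, implanted
#' subcutaneously so that its fluid can be sampled through the skin. The
#' punched holes form the diffusible surface through which drug exchanges with
#' the surrounding tissue; the tubing lumen holds the sampled fluid. Because
#' every cage carries the same number and size of holes, the diffusible area
#' is fixed by design and the surface-area-to-volume ratio is controlled
#' purely by cage length.
#'
#' @param length_cm Cage length in cm.
#' @param outer_diameter_mm Tubing outer diameter in mm (default 17).
#' @param wall_thickness_mm Tubing wall thickness in mm (default 1, giving a
#'   15 mm lumen with the default tubing).
#' @param n_holes Number of punched fenestrations (default 24).
#' @param punch_diameter_mm Biopsy punch diameter in mm (default 4).
#' @return An object of class `"cage_spec"`.
#' @examples
#' spec <- cage_spec(3)
#' fenestration_area(spec)   # 3.0159 cm^2
#' lumen_volume(spec)        # 5.3014 mL
#' surface_to_volume(spec)   # 0.5689 cm^-1
#' @export
cage_spec <- function(length_cm, outer_diameter_mm = 17, wall_thickness_mm = 1,
                      n_holes = 24L, punch_diameter_mm = 4) {
  stopifnot(is.numeric(length_cm), length(length_cm) == 1L)
  if (length_cm < 0) stop("cage length must be non-negative", call. = FALSE)
  if (outer_diameter_mm <= 0) stop("outer diameter must be positive", call. = FALSE)
  if (wall_thickness_mm <= 0) stop("wall thickness must be positive", call. = FALSE)
  if (punch_diameter_mm <= 0) stop("punch diameter must be positive", call. = FALSE)
  if (n_holes < 0 || n_holes != round(n_holes))
    stop("n_holes must be a non-negative integer", call. = FALSE)
  if (outer_diameter_mm - 2 * wall_thickness_mm <= 0)
    stop("wall thickness leaves no lumen (wall >= OD/2)", call. = FALSE)
  structure(
    list(length_cm = length_cm,
         outer_diameter_mm = outer_diameter_mm,
         wall_thickness_mm = wall_thickness_mm,
         n_holes = as.integer(n_holes),
         punch_diameter_mm = punch_diameter_mm),
    class = "cage_spec")
}

#' @export
print.cage_spec <- function(x, ...) {
  cat(sprintf("Tissue cage: %g cm x %g mm OD (%g mm lumen), %d x %g mm holes\n",
              x$length_cm, x$outer_diameter_mm,
              x$outer_diameter_mm - 2 * x$wall_thickness_mm,
              x$n_holes, x$punch_diameter_mm))
  cat(sprintf("  diffusible area %.4f cm^2, volume %.4f mL, SA/V %.4f cm^-1\n",
              fenestration_area(x), lumen_volume(x), surface_to_volume(x)))
  invisible(x)
}

#' Diffusible (fenestration) surface area of a cage
#'
#' The punched holes are treated as flat circles; tube-wall curvature is
#' ignored. The area is independent of cage length.
#'
#' @param spec A [cage_spec()].
#' @return Area in cm^2.
#' @export
fenestration_area <- function(spec) {
  stopifnot(inherits(spec, "cage_spec"))
  r_cm <- spec$punch_diameter_mm / 10 / 2
  spec$n_holes * pi * r_cm^2
}

#' Lumen volume of a cage
#'
#' Volume of the full nominal cylinder bounded by the tubing lumen
#' (the putty-sealed ends are not subtracted).
#'
#' @param spec A [cage_spec()].
#' @return Volume in mL.
#' @export
lumen_volume <- function(spec) {
  stopifnot(inherits(spec, "cage_spec"))
  lumen_r_cm <- (spec$outer_diameter_mm - 2 * spec$wall_thickness_mm) / 10 / 2
  pi * lumen_r_cm^2 * spec$length_cm
}

#' Surface-area-to-volume ratio of a cage
#'
#' With the diffusible area fixed by design, SA/V is proportional to 1/length,
#' so longer cages equilibrate more slowly with the surrounding tissue under
#' Fick's-law diffusion.
#'
#' @param spec A [cage_spec()].
#' @return Ratio in cm^-1.
#' @export
surface_to_volume <- function(spec) {
  v <- lumen_volume(spec)
  if (v <= 0) stop("cage has zero volume; SA/V undefined", call. = FALSE)
  fenestration_area(spec) / v
}

#' Geometry table for a set of cage lengths
#'
#' One row per length with diffusible area, lumen volume and SA/V. Values are
#' kept at full precision; the print method rounds to 4 decimals.
#'
#' @param lengths_cm Vector of cage lengths in cm.
#' @param ... Passed to [cage_spec()] (tubing and punch dimensions).
#' @return A data frame of class `"cage_table"` with columns `length_cm`,
#'   `area_cm2`, `volume_ml`, `sav_per_cm`.
#' @examples
#' cage_table(c(3, 6, 10, 14, 18))
#' @export
cage_table <- function(lengths_cm = c(3, 6, 10, 14, 18), ...) {
  if (length(lengths_cm) == 0) stop("lengths_cm must be non-empty", call. = FALSE)
  specs <- lapply(lengths_cm, cage_spec, ...)
  out <- data.frame(
    length_cm = lengths_cm,
    area_cm2 = vapply(specs, fenestration_area, numeric(1)),
    volume_ml = vapply(specs, lumen_volume, numeric(1)),
    sav_per_cm = vapply(specs, surface_to_volume, numeric(1)))
  class(out) <- c("cage_table", "data.frame")
  out
}

#' @export
print.cage_table <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Fick's-law transfer rate from permeability and SA/V
#'
#' Under Fick's law the first-order exchange rate constant of a cage scales
#' with its surface-area-to-volume ratio times a permeability constant of the
#' membrane/tissue interface, so cages of different absolute size but equal
#' SA/V share the same rate constant.
#'
#' @param permeability_cm_h Permeability constant (cm/h).
#' @param sav_per_cm Surface-area-to-volume ratio (cm^-1).
#' @return First-order rate constant (h^-1).
#' @export
fick_rate <- function(permeability_cm_h, sav_per_cm) {
  stopifnot(all(permeability_cm_h >= 0), all(sav_per_cm >= 0))
  permeability_cm_h * sav_per_cm
}
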