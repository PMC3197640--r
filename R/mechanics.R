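#' Silicone post geometry
#'
#' Geometry and material of one elastic silicone post holding the tissue.
#' The EHT bends the post like a cantilever loaded at its tip, so tissue
#' force follows from small-deflection beam theory. The posts used for any
#' given rack must be measured and supplied: there is no universal geometry.
#' `default_post_geometry()` returns a documented illustrative PDMS post
#' (E = 1 MPa, R = 0.5 mm, L = 10 mm, stiffness about 0.147 N/m) intended
#' for simulations and examples only.
#'
#' @param elastic_modulus_pa elastic (Young's) modulus E of the silicone, Pa.
#' @param post_radius_mm post radius R, mm.
#' @param post_length_mm post length L (insertion point to tissue plane), mm.
#' @return An object of class `post_geometry` storing SI values (Pa, m).
#' @export
post_geometry <- function(elastic_modulus_pa, post_radius_mm, post_length_mm) {
  vals <- c(elastic_modulus_pa, post_radius_mm, post_length_mm)
  if (!all(vapply(vals, is_scalar_num, logical(1))) || any(vals <= 0)) {
    stop_param("post geometry requires strictly positive E, R and L")
  }
  structure(
    list(
      elastic_modulus = elastic_modulus_pa,   # Pa
      post_radius = post_radius_mm / 1000,    # m
      post_length = post_length_mm / 1000     # m
    ),
    class = "post_geometry"
  )
}

#' @rdname post_geometry
#' @export
default_post_geometry <- function() {
  post_geometry(elastic_modulus_pa = 1e6, post_radius_mm = 0.5,
                post_length_mm = 10)
}

#' Cantilever stiffness of a post
#'
#' Bending stiffness k = 3 pi E R^4 / (4 L^3) of the post tip, N/m.
#' Force and tip deflection are then related by F = k * delta.
#'
#' @param geom a [post_geometry()].
#' @return stiffness in N/m.
#' @export
post_stiffness <- function(geom) {
  stopifnot(inherits(geom, "post_geometry"))
  3 * pi * geom$elastic_modulus * geom$post_radius^4 / (4 * geom$post_length^3)
}

#' Convert post deflection to force (beam equation)
#'
#' Applies F = 3 pi E R^4 delta / (4 L^3), the small-deflection formula for
#' a cylindrical cantilever loaded at its tip. Sign convention: positive
#' deflection means the posts are bent toward each other (contraction), so
#' force traces are non-negative at rest.
#'
#' @param delta_m tip deflection in metres (vectorised; sign carries
#'   direction).
#' @param geom a [post_geometry()].
#' @return force in newtons, same length as `delta_m`.
#' @seealso [deflection_from_force()] for the exact inverse,
#'   [force_from_deflection_um()] for micrometre/micronewton convenience.
#' @export
force_from_deflection <- function(delta_m, geom) {
  stopifnot(is.numeric(delta_m))
  post_stiffness(geom) * delta_m
}

#' Convert force to post deflection (inverse beam equation)
#'
#' Exact algebraic inverse of [force_from_deflection()]; used by the
#' synthetic-data module to turn ground-truth force into the deflection a
#' camera would observe.
#'
#' @param force_n force in newtons (vectorised).
#' @inheritParams force_from_deflection
#' @return deflection in metres.
#' @export
deflection_from_force <- function(force_n, geom) {
  stopifnot(is.numeric(force_n))
  force_n / post_stiffness(geom)
}

#' @rdname force_from_deflection
#' @param delta_um deflection in micrometres.
#' @return `force_from_deflection_um` returns force in micronewtons.
#' @export
force_from_deflection_um <- function(delta_um, geom) {
  force_from_deflection(delta_um * 1e-6, geom) * 1e6
}

#' @rdname deflection_from_force
#' @param force_un force in micronewtons.
#' @return `deflection_from_force_un` returns deflection in micrometres.
#' @export
deflection_from_force_un <- function(force_un, geom) {
  deflection_from_force(force_un * 1e-6, geom) * 1e6
}

#' Tissue geometry
#'
#' @param diameter_mm tissue diameter in mm, assuming the EHT is a circular
#'   cylinder. The measured population mean is 0.72 mm.
#' @return object of class `tissue_geometry`.
#' @export
tissue_geometry <- function(diameter_mm = 0.72) {
  if (!is_scalar_num(diameter_mm) || diameter_mm <= 0) {
    stop_param("tissue diameter must be a positive number (mm)")
  }
  structure(list(diameter = diameter_mm), class = "tissue_geometry")
}

#' Cross-sectional stress developed by the tissue
#'
#' Divides force by the cross-sectional area of the tissue under the
#' simplifying assumption that the EHT is a circular cylinder.
#'
#' @param force_mn force in millinewtons (vectorised).
#' @param tissue a [tissue_geometry()].
#' @return stress in mN/mm^2.
#' @export
cross_sectional_stress <- function(force_mn, tissue = tissue_geometry()) {
  stopifnot(is.numeric(force_mn), inherits(tissue, "tissue_geometry"))
  area_mm2 <- pi * (tissue$diameter / 2)^2
  force_mn / area_mm2
}

#' @export
print.post_geometry <- function(x, ...) {
  cat(sprintf(
    "Silicone post: E = %.3g Pa, R = %.3g mm, L = %.3g mm (k = %.4g N/m)\n",
    x$elastic_modulus, x$post_radius * 1000, x$post_length * 1000,
    post_stiffness(x)))
  invisible(x)
}
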