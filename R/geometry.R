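# Truncated-sphere geometry of an adhered droplet pair.
#
# Two monolayer-coated droplets adhering across a bilayer disc are each a
# sphere truncated by the (assumed planar) contact disc of radius rc.  All
# lengths are micrometres unless stated otherwise.

#' Droplet-pair state
#'
#' Instantaneous geometry of two adhered droplets: the sphere radii `R1`,
#' `R2`, the contact (bilayer) radius `rc`, and optionally the
#' centre-to-centre distance `d`.  When `d` is omitted and `rc > 0` it is
#' reconstructed from the sphere-sphere intersection geometry.
#'
#' @param R1,R2 Sphere radii (um), both > 0.
#' @param rc Contact radius (um), `0 <= rc < min(R1, R2)`.
#' @param d Optional centre distance (um); must satisfy
#'   `|R1 - R2| < d < R1 + R2` when `rc > 0` and be consistent with `rc`.
#' @return An object of class `droplet_pair_state`: a list with fields
#'   `R1`, `R2`, `rc`, `d`.
#' @examples
#' st <- droplet_pair_state(50, 50, 30)
#' st$d  # 80 for the 30-40-50 right-triangle geometry
#' @export
droplet_pair_state <- function(R1, R2, rc, d = NULL) {
  stopif_not_scalar(R1, "R1", positive = TRUE)
  stopif_not_scalar(R2, "R2", positive = TRUE)
  stopif_not_scalar(rc, "rc", nonneg = TRUE)
  if (rc >= min(R1, R2))
    stop("contact radius must satisfy rc < min(R1, R2)", call. = FALSE)
  if (is.null(d)) {
    d <- if (rc > 0) center_distance_from_contact(R1, R2, rc) else NA_real_
  } else {
    stopif_not_scalar(d, "d", positive = TRUE)
    if (rc > 0 && !(abs(R1 - R2) < d && d < R1 + R2))
      stop("centre distance d inconsistent with overlapping spheres",
           call. = FALSE)
  }
  structure(list(R1 = R1, R2 = R2, rc = rc, d = d),
            class = "droplet_pair_state")
}

#' @export
print.droplet_pair_state <- function(x, ...) {
  cat(sprintf("<droplet_pair_state> R1 = %.3f um, R2 = %.3f um, rc = %.3f um, d = %s um\n",
              x$R1, x$R2, x$rc,
              if (is.na(x$d)) "NA" else sprintf("%.3f", x$d)))
  invisible(x)
}

#' Volume of a truncated sphere
#'
#' Volume of a sphere of radius `R` with the spherical cap beyond the
#' bilayer plane removed.  The cap height is `h = R - sqrt(R^2 - rc^2)`,
#' and the cap volume `pi * h^2 * (3 R - h) / 3`.
#'
#' @param R Sphere radius (um). Vectorised.
#' @param rc Contact radius (um), `0 <= rc <= R`. Vectorised.
#' @return Volume (um^3).
#' @examples
#' truncated_sphere_volume(50, 0)   # full sphere, 4/3 pi 50^3
#' truncated_sphere_volume(50, 50)  # hemisphere
#' @export
truncated_sphere_volume <- function(R, rc) {
  if (any(!is.finite(R)) || any(!is.finite(rc)))
    stop("R and rc must be finite", call. = FALSE)
  if (any(R <= 0)) stop("R must be > 0", call. = FALSE)
  if (any(rc < 0)) stop("rc must be >= 0", call. = FALSE)
  if (any(rc > R)) stop("rc must be <= R", call. = FALSE)
  h <- R - sqrt(R^2 - rc^2)
  4 / 3 * pi * R^3 - pi * h^2 * (3 * R - h) / 3
}

#' Bilayer contact area
#'
#' Area of the circular bilayer disc, `pi * rc^2`.
#'
#' @param rc Contact radius (um), >= 0. Vectorised.
#' @return Area (um^2).
#' @export
contact_area <- function(rc) {
  if (any(!is.finite(rc)) || any(rc < 0))
    stop("rc must be finite and >= 0", call. = FALSE)
  pi * rc^2
}

#' Contact radius from sphere centres
#'
#' Radius of the intersection circle of two spheres with radii `R1`, `R2`
#' and centre distance `d`: `rc = sqrt(R1^2 - x^2)` with
#' `x = (d^2 + R1^2 - R2^2) / (2 d)`.
#'
#' @param R1,R2 Sphere radii (um).
#' @param d Centre distance (um); tangent spheres (`d = R1 + R2`) give 0.
#' @return Contact radius (um).
#' @export
contact_radius_from_centers <- function(R1, R2, d) {
  stopif_not_scalar(R1, "R1", positive = TRUE)
  stopif_not_scalar(R2, "R2", positive = TRUE)
  stopif_not_scalar(d, "d", positive = TRUE)
  if (d == R1 + R2) return(0)
  if (d > R1 + R2 || d <= abs(R1 - R2))
    stop("spheres do not intersect in a circle (d outside (|R1-R2|, R1+R2])",
         call. = FALSE)
  x <- (d^2 + R1^2 - R2^2) / (2 * d)
  sqrt(max(R1^2 - x^2, 0))
}

# Inverse of contact_radius_from_centers for a shared contact plane:
# d = sqrt(R1^2 - rc^2) + sqrt(R2^2 - rc^2).
center_distance_from_contact <- function(R1, R2, rc) {
  if (rc > min(R1, R2)) stop("rc must be <= min(R1, R2)", call. = FALSE)
  sqrt(R1^2 - rc^2) + sqrt(R2^2 - rc^2)
}

# Sphere radius of a truncated sphere of known volume V and contact radius
# rc (monotone in R on [rc, Inf); solved by safeguarded root bracketing).
radius_from_volume <- function(V, rc) {
  stopif_not_scalar(V, "V", positive = TRUE)
  stopif_not_scalar(rc, "rc", nonneg = TRUE)
  r_full <- (3 * V / (4 * pi))^(1 / 3)
  if (rc == 0) return(r_full)
  lo <- max(r_full, rc * (1 + 1e-12))
  if (truncated_sphere_volume(lo, min(rc, lo)) >= V)
    stop("no truncated sphere with rc = ", signif(rc, 6),
         " attains volume ", signif(V, 6), call. = FALSE)
  hi <- lo * 2
  while (truncated_sphere_volume(hi, rc) < V) hi <- hi * 2
  stats::uniroot(function(R) truncated_sphere_volume(R, rc) - V,
                 lower = lo, upper = hi, tol = 1e-12 * r_full)$root
}
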