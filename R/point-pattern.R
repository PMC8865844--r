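#' Planar point pattern of nuclei centroids
#'
#' Coordinates are in micrometres with the origin at the lower-left corner of
#' the rectangular observation domain; y increases toward the growth front
#' (fan). Optional per-object shape attributes (diameter, area, eccentricity)
#' travel with the points.
#'
#' @param x,y numeric coordinate vectors (um).
#' @param domain bounding rectangle `c(xmin, xmax, ymin, ymax)` in um.
#' @param diameter optional per-point diameters (um), must be positive.
#' @param area optional per-object areas (um^2).
#' @param eccentricity optional per-object eccentricities in [0, 1).
#' @param id optional point identifiers (defaults to 1..n).
#' @return An object of class `PointPattern`: a list with a `points`
#'   data.frame and the `domain`.
#' @export
point_pattern <- function(x, y, domain = NULL, diameter = NULL, area = NULL,
                          eccentricity = NULL, id = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (is.null(domain)) {
    domain <- if (n > 0) c(min(x), max(x), min(y), max(y)) else c(0, 1, 0, 1)
  }
  stopifnot(length(domain) == 4, domain[2] >= domain[1], domain[4] >= domain[3])
  if (n > 0) {
    eps <- 1e-9 * max(1, abs(domain))
    if (any(x < domain[1] - eps | x > domain[2] + eps |
            y < domain[3] - eps | y > domain[4] + eps))
      stop("points outside the stated domain")
  }
  pts <- data.frame(id = if (is.null(id)) seq_len(n) else id, x = x, y = y)
  if (!is.null(diameter)) {
    stopifnot(length(diameter) == n, all(diameter > 0))
    pts$diameter <- diameter
  }
  if (!is.null(area)) {
    stopifnot(length(area) == n)
    pts$area <- area
  }
  if (!is.null(eccentricity)) {
    stopifnot(length(eccentricity) == n,
              all(eccentricity >= 0 & eccentricity < 1))
    pts$eccentricity <- eccentricity
  }
  structure(list(points = pts, domain = as.numeric(domain)),
            class = "PointPattern")
}

#' @export
print.PointPattern <- function(x, ...) {
  d <- x$domain
  cat(sprintf("PointPattern: %d points in [%g, %g] x [%g, %g] um\n",
              nrow(x$points), d[1], d[2], d[3], d[4]))
  invisible(x)
}

n_points <- function(p) nrow(p$points)

domain_area <- function(p) {
  d <- p$domain
  (d[2] - d[1]) * (d[4] - d[3])
}
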