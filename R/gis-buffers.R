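#' Length of a road segment inside a circular buffer
#'
#' Computes the exact length of the intersection of one or more straight road
#' segments with the closed disc of radius `radius` around `center`, by
#' solving the quadratic \eqn{\|P(t) - c\|^2 = r^2} along the segment
#' parametrization \eqn{P(t) = A + t(B - A)} and clipping \eqn{t} to
#' \eqn{[0, 1]}. The boundary counts as inside (closed-disc convention).
#'
#' @param segments Data frame with columns `x1, y1, x2, y2` (meters); extra
#'   columns are ignored. Zero-length segments contribute 0.
#' @param center Numeric length-2 vector `c(x, y)`.
#' @param radius Buffer radius in meters, `> 0`.
#' @return Numeric vector of per-segment intersection lengths (meters), each
#'   in `[0, segment length]`.
#' @export
segment_length_in_disc <- function(segments, center, radius) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0)
  dx <- segments$x2 - segments$x1
  dy <- segments$y2 - segments$y1
  len2 <- dx * dx + dy * dy
  fx <- segments$x1 - center[1L]
  fy <- segments$y1 - center[2L]
  # ||A + t D - c||^2 = r^2  ->  len2 t^2 + 2 (f.D) t + (||f||^2 - r^2) = 0
  b <- fx * dx + fy * dy
  c0 <- fx * fx + fy * fy - radius * radius
  disc <- b * b - len2 * c0
  out <- numeric(nrow(segments))
  ok <- len2 > 0 & disc > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- pmax((-b[ok] - sq) / len2[ok], 0)
    t2 <- pmin((-b[ok] + sq) / len2[ok], 1)
    out[ok] <- pmax(t2 - t1, 0) * sqrt(len2[ok])
  }
  out
}

#' Buffer-summed road variables (road length and traffic load)
#'
#' Sums, over all road segments, the segment length inside the disc around a
#' site, optionally weighted by the segment's traffic intensity. Unit weight
#' yields road length (m); intensity weight yields traffic load
#' (vehicles x m / day).
#'
#' @param center Numeric `c(x, y)` of the site, meters.
#' @param roads Road-segment data frame with `x1, y1, x2, y2`, `intensity`
#'   (vehicles/day) and logical `is_major`.
#' @param radius Buffer radius in meters, `> 0`.
#' @param weight `"unit"` for road length, `"intensity"` for traffic load.
#' @param major_only If `TRUE`, restrict to segments flagged `is_major`.
#' @return Single numeric value; 0 for an empty road set or empty buffer.
#' @export
buffer_sum <- function(center, roads, radius, weight = c("unit", "intensity"),
                       major_only = FALSE) {
  weight <- match.arg(weight)
  if (major_only && nrow(roads)) roads <- roads[roads$is_major, , drop = FALSE]
  if (!nrow(roads)) return(0)
  len <- segment_length_in_disc(roads, center, radius)
  if (weight == "intensity") sum(len * roads$intensity) else sum(len)
}

#' Ring (annulus) road variables
#'
#' Computed as the disc difference `buffer_sum(outer) - buffer_sum(inner)`,
#' which makes the additivity identity ring + inner = outer exact.
#'
#' @inheritParams buffer_sum
#' @param inner,outer Inner and outer radii in meters, `outer > inner > 0`.
#' @return Single numeric value, `>= 0`.
#' @export
ring_sum <- function(center, roads, inner, outer,
                     weight = c("unit", "intensity"), major_only = FALSE) {
  if (!(outer > inner && inner > 0))
    stop_data("ring_sum: need outer > inner > 0 (got inner=%g, outer=%g)",
              inner, outer)
  buffer_sum(center, roads, outer, weight, major_only) -
    buffer_sum(center, roads, inner, weight, major_only)
}

# point-to-segment Euclidean distances, vectorized over segments
point_segment_distance <- function(center, segments) {
  dx <- segments$x2 - segments$x1
  dy <- segments$y2 - segments$y1
  len2 <- dx * dx + dy * dy
  px <- center[1L] - segments$x1
  py <- center[2L] - segments$y1
  t <- ifelse(len2 > 0, pmin(pmax((px * dx + py * dy) / len2, 0), 1), 0)
  sqrt((px - t * dx)^2 + (py - t * dy)^2)
}

#' Traffic intensity on the nearest road
#'
#' Returns the intensity of the segment minimizing the point-to-segment
#' Euclidean distance to the site; exact ties are broken by the smallest
#' `segment_id`.
#'
#' @inheritParams buffer_sum
#' @return Intensity (vehicles/day) of the nearest segment.
#' @export
nearest_road_intensity <- function(center, roads, major_only = FALSE) {
  if (major_only && nrow(roads)) roads <- roads[roads$is_major, , drop = FALSE]
  if (!nrow(roads)) stop_data("nearest_road_intensity: empty road set")
  d <- point_segment_distance(center, roads)
  i <- which(d == min(d))
  if (length(i) > 1L) i <- i[order(roads$segment_id[i])][1L]
  roads$intensity[i]
}
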