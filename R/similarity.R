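#' Buffer a route geometry
#'
#' Planar buffer of a polyline with round joins and round end caps, the
#' construction under the shared-route overlap measure. For a straight
#' segment of length L the buffer area is \eqn{2 r L + \pi r^2}.
#'
#' @param geometry polyline matrix (n x 2, metres) or an `exposure_route`.
#' @param radius buffer radius in metres (default 5).
#' @param arctol arc-approximation tolerance passed to the clipper engine;
#'   the default `radius / 200` keeps area errors well below 0.1%.
#' @return a `route_buffer`: list of polygon rings (`list(x, y)`), with the
#'   radius kept as an attribute.
#' @export
buffer_route <- function(geometry, radius = 5, arctol = radius / 200) {
  if (inherits(geometry, "exposure_route")) geometry <- geometry$geometry
  geometry <- as.matrix(geometry)
  stopifnot(radius > 0)
  if (polyline_length(geometry) <= 0) stop("cannot buffer a zero-length geometry")
  rings <- polyclip::polylineoffset(
    list(x = geometry[, 1L], y = geometry[, 2L]), delta = radius,
    jointype = "round", endtype = "openround", arctol = arctol)
  structure(rings, class = "route_buffer", radius = radius)
}

#' Area of a route buffer (or any ring set)
#'
#' @param buf a `route_buffer` (holes, if any, carry opposite orientation).
#' @return area in square metres.
#' @export
buffer_area <- function(buf) polygon_area(buf)

#' Shared-route proportion of two buffered routes
#'
#' Overlap of the two buffer polygons. The default measure is the Jaccard
#' index, area(A intersect B) / area(A union B); `method = "mean"` divides
#' the intersection area by the mean of the two buffer areas instead. Both
#' are symmetric, lie in \[0, 1\] and equal 1 for identical routes; the
#' output is labelled with the method used so neither variant is silently
#' asserted.
#'
#' @param bufA,bufB `route_buffer` objects (see [buffer_route()]).
#' @param method `"jaccard"` (default) or `"mean"`.
#' @return the shared proportion (numeric scalar, attribute `method`).
#' @export
shared_route_proportion <- function(bufA, bufB,
                                    method = c("jaccard", "mean")) {
  method <- match.arg(method)
  if (!length(bufA) || !length(bufB)) stop("empty buffer polygon")
  inter <- polygon_area(polyclip::polyclip(bufA, bufB, op = "intersection"))
  denom <- if (method == "jaccard") {
    polygon_area(polyclip::polyclip(bufA, bufB, op = "union"))
  } else {
    (polygon_area(bufA) + polygon_area(bufB)) / 2
  }
  structure(min(1, inter / denom), method = method)
}

#' Pearson product-moment correlation with a zero-variance guard
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Pearson r, or `NA` (with a warning) when either input has zero
#'   variance.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; Pearson r is undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}

EXPOSURE_PAIRS <- list(c("aqi", "noise_db"), c("aqi", "gvi"),
                       c("noise_db", "gvi"))

#' Multi-exposure route similarity and correlation analysis
#'
#' For every OD pair, measures the spatial overlap (5 m buffers,
#' [shared_route_proportion()]) between each pair of exposure-optimal
#' routes (AQI-noise, AQI-GVI, noise-GVI). When an exposure type has no
#' improving route the shortest route stands in as its optimal, mirroring
#' the lack-of-alternatives situation. Overlaps are aggregated to departure
#' stations as trip-weighted means. Separately, the Pearson correlations
#' between route-mean exposure values are computed over OD pairs for each
#' route set (shortest and each optimal type).
#'
#' @param batch a [batch_route()] result.
#' @param trips trip table for the trip-weighted catchment aggregation.
#' @param radius buffer radius in metres (default 5).
#' @param method overlap denominator, see [shared_route_proportion()].
#' @return list with
#' \describe{
#'   \item{pairwise}{tibble: origin, dest, pair_type, shared_proportion.}
#'   \item{by_station}{tibble: station_id, pair_type, trip-weighted and
#'     unweighted mean shared proportion.}
#'   \item{correlations}{tibble: route_set, pair, r, n.}
#' }
#' @export
similarity_pipeline <- function(batch, trips = NULL, radius = 5,
                                method = c("jaccard", "mean")) {
  method <- match.arg(method)
  buf_cache <- new.env(parent = emptyenv())
  jac_cache <- new.env(parent = emptyenv())
  get_buf <- function(route) {
    key <- paste(route$edge_ids, collapse = "\r")
    if (is.null(buf_cache[[key]]))
      buf_cache[[key]] <- buffer_route(route$geometry, radius)
    list(key = key, buf = buf_cache[[key]])
  }
  overlap <- function(rA, rB) {
    a <- get_buf(rA); b <- get_buf(rB)
    if (a$key == b$key) return(1)
    jkey <- paste(sort(c(a$key, b$key)), collapse = "\n")
    if (is.null(jac_cache[[jkey]]))
      jac_cache[[jkey]] <- as.numeric(
        shared_route_proportion(a$buf, b$buf, method))
    jac_cache[[jkey]]
  }

  rows <- vector("list", length(batch$routes) * 3L)
  i <- 0L
  for (key in names(batch$routes)) {
    rt <- batch$routes[[key]]
    od <- strsplit(key, "->", fixed = TRUE)[[1L]]
    for (pr in EXPOSURE_PAIRS) {
      i <- i + 1L
      rows[[i]] <- data.frame(
        origin = od[1L], dest = od[2L],
        pair_type = paste(pr, collapse = "-"),
        shared_proportion = overlap(rt[[pr[1L]]], rt[[pr[2L]]]),
        stringsAsFactors = FALSE)
    }
  }
  pairwise <- tibble::as_tibble(dplyr::bind_rows(rows))

  wdf <- trip_weights(pairwise, trips, !is.null(trips))
  if (is.null(trips)) wdf$.w <- 1
  by_station <- dplyr::summarise(
    dplyr::group_by(wdf, station_id = .data$origin, .data$pair_type),
    mean_shared = mean(.data$shared_proportion),
    trip_weighted_mean_shared =
      if (sum(.data$.w) == 0) NA_real_
      else stats::weighted.mean(.data$shared_proportion, .data$.w),
    n_od_pairs = dplyr::n(), .groups = "drop")

  route_sets <- c("shortest", paste0(EXPOSURE_TYPES, "_optimal"))
  cors <- list()
  for (rs in route_sets) {
    sub <- dplyr::filter(batch$summary, .data$route_type == rs)
    for (pr in EXPOSURE_PAIRS) {
      x <- sub[[paste0("mean_", pr[1L])]]
      y <- sub[[paste0("mean_", pr[2L])]]
      nzv <- function(v) stats::sd(v) > 1e-12 * max(1, abs(mean(v)))
      r <- if (length(x) >= 3 && nzv(x) && nzv(y))
        stats::cor(x, y) else NA_real_
      cors[[length(cors) + 1L]] <- data.frame(
        route_set = rs, pair = paste(pr, collapse = "-"), r = r,
        n = length(x), stringsAsFactors = FALSE)
    }
  }
  list(pairwise = pairwise, by_station = by_station,
       correlations = tibble::as_tibble(dplyr::bind_rows(cors)))
}
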