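#' Read an ESRI ASCII grid
#'
#' Reads the classic `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' header followed by `nrows` whitespace-separated rows, north row first.
#'
#' @param path path to an `.asc` file.
#' @return a `raster_grid`: list with `origin_x`, `origin_y` (lower-left
#'   corner), `cell_size`, `nodata`, and `values`, an `nrows x ncols` matrix
#'   whose first row is the northernmost.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header incomplete; need ", paste(need, collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("ASCII grid has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  structure(list(origin_x = hdr$xllcorner, origin_y = hdr$yllcorner,
                 cell_size = hdr$cellsize, nodata = nodata, values = m),
            class = "raster_grid")
}

#' Write an ESRI ASCII grid
#'
#' @param grid a `raster_grid` (see [read_ascii_grid()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", format(grid$origin_x, scientific = FALSE)),
    paste("yllcorner", format(grid$origin_y, scientific = FALSE)),
    paste("cellsize", format(grid$cell_size, scientific = FALSE)),
    paste("NODATA_value", grid$nodata)
  ), con)
  apply(m, 1L, function(r) writeLines(paste(format(r, trim = TRUE), collapse = " "), con))
  invisible(path)
}

# Grid cell values at point coordinates; NA outside the extent or on nodata.
grid_value_at <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  xmax <- grid$origin_x + nc * grid$cell_size
  ymax <- grid$origin_y + nr * grid$cell_size
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  row <- nr - floor((y - grid$origin_y) / grid$cell_size)
  # points exactly on the top/right boundary belong to the outermost cell
  col[x == xmax] <- nc
  row[y == ymax] <- 1L
  out <- rep(NA_real_, length(x))
  ok <- col >= 1L & col <= nc & row >= 1L & row <= nr
  out[ok] <- grid$values[cbind(row[ok], col[ok])]
  out
}

#' Mean raster value along an edge geometry
#'
#' Samples the grid at points every `interval` metres along the polyline
#' (endpoints included) and returns the arithmetic mean of the non-nodata
#' samples. With `interval` well below the cell size this approximates the
#' length-weighted mean of the raster along the edge.
#'
#' @param grid a `raster_grid`.
#' @param geometry polyline matrix (n x 2, metres).
#' @param interval sampling step in metres (default 5, below the 13 m AQI
#'   cell size the layout emulates).
#' @return mean value, or `NA` (with a warning) when every sample falls on
#'   nodata or outside the grid.
#' @export
sample_raster_along_edge <- function(grid, geometry, interval = 5) {
  stopifnot(interval > 0)
  geometry <- as.matrix(geometry)
  total <- polyline_length(geometry)
  if (total <= 0) stop("geometry has zero length")
  at <- seq(0, total, by = interval)
  if (at[length(at)] < total) at <- c(at, total)
  pts <- points_along(geometry, at)
  v <- grid_value_at(grid, pts[, 1L], pts[, 2L])
  if (all(is.na(v))) {
    warning("all samples are nodata or outside the grid extent; returning NA")
    return(NA_real_)
  }
  mean(v, na.rm = TRUE)
}

#' Read noise polygons from GeoJSON
#'
#' Polygon features with a numeric `lden_db` property. Only the outer ring
#' of each polygon is used (the layer emulated is a dense tessellation of
#' simple band polygons).
#'
#' @param path path to a GeoJSON file.
#' @return a `noise_layer`: list of `list(x, y, lden_db, bbox)` entries.
#' @export
read_noise_polygons <- function(path) {
  gj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                 error = function(e) stop("malformed GeoJSON: ", conditionMessage(e)))
  if (is.null(gj$features)) stop("malformed GeoJSON: no features")
  polys <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("noise layer must contain Polygon features")
    db <- f$properties$lden_db
    if (is.null(db)) stop("noise polygon missing property lden_db")
    ring <- f$geometry$coordinates[[1L]]
    x <- vapply(ring, function(c2) as.numeric(c2[[1L]]), numeric(1))
    y <- vapply(ring, function(c2) as.numeric(c2[[2L]]), numeric(1))
    noise_polygon(x, y, as.numeric(db))
  })
  structure(polys, class = "noise_layer")
}

#' Build a noise polygon
#' @param x,y ring coordinates (closing vertex optional).
#' @param lden_db Lden value in dB, within \[0, 120\].
#' @return a polygon entry usable in a `noise_layer`.
#' @export
noise_polygon <- function(x, y, lden_db) {
  stopifnot(lden_db >= 0, lden_db <= 120, length(x) == length(y), length(x) >= 3)
  n <- length(x)
  if (x[1L] == x[n] && y[1L] == y[n]) { x <- x[-n]; y <- y[-n] }
  list(x = x, y = y, lden_db = lden_db,
       bbox = c(min(x), max(x), min(y), max(y)))
}

#' Write noise polygons to GeoJSON
#' @param layer a `noise_layer` (list of [noise_polygon()] entries).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_noise_polygons <- function(layer, path) {
  feats <- lapply(layer, function(p) {
    ring <- lapply(c(seq_along(p$x), 1L), function(i) c(p$x[i], p$y[i]))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(lden_db = p$lden_db))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Length-weighted noise level along an edge geometry
#'
#' The polyline is split into equal arc-length pieces represented by their
#' midpoints (step `interval` metres), so the result is invariant to
#' re-vertexing. At each midpoint the highest `lden_db` among covering
#' polygons applies (conservative, mirroring the worst-class principle of
#' composite air-quality indices); uncovered midpoints contribute the
#' `background_db` level. Averaging is arithmetic in dB by default; set
#' `energetic = TRUE` for energetic (sound-pressure) averaging
#' \eqn{10 \log_{10}(\mathrm{mean}(10^{L/10}))}.
#'
#' @param layer a `noise_layer`.
#' @param geometry polyline matrix (n x 2, metres).
#' @param background_db dB assigned outside all polygons (default 40).
#' @param interval sampling step in metres (default 1).
#' @param energetic logical; energetic instead of arithmetic averaging.
#' @return mean Lden in dB.
#' @export
assign_noise <- function(layer, geometry, background_db = 40, interval = 1,
                         energetic = FALSE) {
  geometry <- as.matrix(geometry)
  total <- polyline_length(geometry)
  if (total <= 0) stop("geometry has zero length")
  n <- max(1L, as.integer(ceiling(total / interval)))
  pts <- midpoints_along(geometry, n)
  db <- rep(background_db, n)
  gb <- coords_bbox(pts)
  for (p in layer) {
    if (!bbox_overlaps(p$bbox, gb)) next
    if (all(p$lden_db <= db)) next
    inside <- polyclip::pointinpolygon(list(x = pts[, 1L], y = pts[, 2L]),
                                       list(x = p$x, y = p$y))
    hit <- inside != 0  # boundary counts as covered
    db[hit] <- pmax(db[hit], p$lden_db)
  }
  if (energetic) 10 * log10(mean(10^(db / 10))) else mean(db)
}

#' Attach Green View Index values to network edges
#'
#' @param table a data frame with columns `edge_id` and `gvi` (values in
#'   \[0, 1\]).
#' @param net a [street_network()].
#' @return the network with its `gvi` column filled for matched edges;
#'   unmatched edges keep `NA`. Unknown edge ids in the table are ignored
#'   with a warning reporting their count.
#' @export
attach_gvi <- function(table, net) {
  stopifnot(all(c("edge_id", "gvi") %in% names(table)))
  if (nrow(table) > 0 && any(table$gvi < 0 | table$gvi > 1, na.rm = TRUE))
    stop("gvi values must lie in [0, 1]")
  unknown <- setdiff(as.character(table$edge_id), net$edges$id)
  if (length(unknown))
    warning(length(unknown), " gvi row(s) reference unknown edge id(s); ignored")
  m <- match(net$edges$id, as.character(table$edge_id))
  net$edges$gvi <- ifelse(is.na(m), NA_real_, table$gvi[m])
  net
}

#' Impute missing exposure values with the length-weighted network median
#'
#' Non-missing values are preserved exactly; missing values are replaced by
#' the length-weighted median over valued edges (the smallest value whose
#' cumulative edge length reaches half the valued total).
#'
#' @param net a [street_network()].
#' @param exposure_type one of `"aqi"`, `"noise_db"`, `"gvi"`.
#' @return the network with no missing values for `exposure_type`; the
#'   number of imputed edges is reported with a message.
#' @export
impute_missing <- function(net, exposure_type = c("aqi", "noise_db", "gvi")) {
  exposure_type <- match.arg(exposure_type)
  v <- net$edges[[exposure_type]]
  miss <- is.na(v)
  if (all(miss))
    stop("no edge carries a value for ", exposure_type, "; cannot impute")
  if (any(miss)) {
    med <- weighted_median(v[!miss], net$edges$length[!miss])
    net$edges[[exposure_type]][miss] <- med
    message("imputed ", sum(miss), " missing ", exposure_type,
            " value(s) with length-weighted median ", signif(med, 6))
  }
  net
}

#' Map a raw exposure value to an environmental cost coefficient
#'
#' The cost coefficient `ce` in the impedance function
#' \eqn{C_e = C_t + C_t \cdot ce \cdot s} is a unitless penalty in \[0, 1\].
#' Default mappings:
#' \describe{
#'   \item{aqi}{`(value - 1) / 4` - AQI 1 (good air) gives 0, AQI 5 gives 1.}
#'   \item{noise_db}{`clamp((value - ramp[1]) / (ramp[2] - ramp[1]), 0, 1)`
#'     with a 45-75 dB ramp, so the 55 dB high-daytime-noise threshold sits
#'     near ce = 1/3.}
#'   \item{gvi}{`1 - value` - greenery is a benefit, so greener edges get a
#'     lower penalty.}
#' }
#'
#' @param exposure_type one of `"aqi"`, `"noise_db"`, `"gvi"`.
#' @param value numeric vector of raw exposure values (AQI in \[1,5\],
#'   Lden dB in \[0,120\], GVI in \[0,1\]); out-of-range values are an error.
#' @param noise_ramp two dB values spanning the 0-to-1 noise penalty ramp.
#' @return numeric vector of coefficients in \[0, 1\].
#' @examples
#' cost_coefficient("aqi", c(1, 3, 5))
#' cost_coefficient("noise_db", 60) # 0.5 on the default 45-75 ramp
#' cost_coefficient("gvi", 0.3)     # 0.7
#' @export
cost_coefficient <- function(exposure_type = c("aqi", "noise_db", "gvi"),
                             value, noise_ramp = c(45, 75)) {
  exposure_type <- match.arg(exposure_type)
  lim <- switch(exposure_type, aqi = c(1, 5), noise_db = c(0, 120), gvi = c(0, 1))
  if (any(value < lim[1L] | value > lim[2L], na.rm = TRUE))
    stop(exposure_type, " value(s) outside valid range [",
         lim[1L], ", ", lim[2L], "]")
  switch(exposure_type,
    aqi = (value - 1) / 4,
    noise_db = pmin(pmax((value - noise_ramp[1L]) /
                           (noise_ramp[2L] - noise_ramp[1L]), 0), 1),
    gvi = 1 - value)
}

#' Attach exposure attributes to a network from external layers
#'
#' Convenience wrapper running [sample_raster_along_edge()] for AQI,
#' [assign_noise()] for noise and [attach_gvi()] for greenery, for whichever
#' layers are supplied.
#'
#' @param net a [street_network()].
#' @param aqi_grid optional `raster_grid` of AQI values.
#' @param noise_layer optional `noise_layer`.
#' @param gvi_table optional data frame (`edge_id`, `gvi`).
#' @param interval raster sampling step (metres).
#' @param background_db,noise_interval passed to [assign_noise()].
#' @return the network with exposure columns filled where layers cover it.
#' @export
assign_exposures <- function(net, aqi_grid = NULL, noise_layer = NULL,
                             gvi_table = NULL, interval = 5,
                             background_db = 40, noise_interval = 1) {
  if (!is.null(aqi_grid)) {
    net$edges$aqi <- vapply(net$edges$geometry, function(g)
      suppressWarnings(sample_raster_along_edge(aqi_grid, g, interval)),
      numeric(1))
  }
  if (!is.null(noise_layer)) {
    net$edges$noise_db <- vapply(net$edges$geometry, function(g)
      assign_noise(noise_layer, g, background_db, noise_interval), numeric(1))
  }
  if (!is.null(gvi_table)) net <- attach_gvi(gvi_table, net)
  net
}
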