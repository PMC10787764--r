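#' Multi-individual trajectory grid
#'
#' Positions of a fixed set of individuals on a shared, strictly increasing
#' 1 Hz integer time base, with explicit missingness. The grid is the
#' central container of the package: all dyadic computations index into it.
#'
#' @param ids character vector of individual identifiers.
#' @param times integer seconds (strictly increasing, unit step within a
#'   day segment).
#' @param x,y numeric matrices, `length(ids)` rows by `length(times)`
#'   columns, planar metres; `NA` where no fix.
#' @param interpolated logical matrix of the same shape flagging filled-in
#'   fixes; defaults to all `FALSE`.
#' @return an object of class `trajectory_grid`.
#' @export
trajectory_grid <- function(ids, times, x, y, interpolated = NULL) {
  ids <- as.character(ids)
  times <- as.integer(times)
  dimnames(x) <- dimnames(y) <- NULL
  stopifnot(nrow(x) == length(ids), ncol(x) == length(times),
            all(dim(x) == dim(y)), !is.unsorted(times, strictly = TRUE))
  if (is.null(interpolated)) {
    interpolated <- matrix(FALSE, nrow(x), ncol(x))
  }
  stopifnot(identical(is.na(x), is.na(y)))
  rownames(x) <- rownames(y) <- rownames(interpolated) <- ids
  structure(list(ids = ids, times = times, x = x, y = y,
                 interpolated = interpolated),
            class = "trajectory_grid")
}

#' @export
print.trajectory_grid <- function(x, ...) {
  tf <- tracked_fraction(x)
  cat(sprintf("trajectory_grid: %d individuals x %d s (%.1f%% of fixes present)\n",
              length(x$ids), length(x$times), 100 * mean(!is.na(x$x))))
  cat(sprintf("  time range [%d, %d], mean tracked fraction %.2f\n",
              min(x$times), max(x$times), mean(tf)))
  invisible(x)
}

#' Per-second fraction of individuals with a fix
#' @param grid a [trajectory_grid()].
#' @return numeric vector over `grid$times`, each in \[0, 1\].
#' @export
tracked_fraction <- function(grid) {
  colMeans(!is.na(grid$x))
}

#' Boolean per-time coverage mask
#'
#' True exactly where the tracked fraction reaches `min_fraction`
#' (boundary inclusive). Events overlapping masked-out seconds are dropped
#' downstream.
#'
#' @param grid a [trajectory_grid()].
#' @param min_fraction required fraction of individuals with a fix,
#'   in (0, 1\]; 0.5 by default, 0.8 for the stricter robustness setting.
#' @return logical vector over `grid$times`.
#' @export
coverage_mask <- function(grid, min_fraction = 0.5) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  tracked_fraction(grid) >= min_fraction
}

# --- projection ------------------------------------------------------------

.EARTH_RADIUS <- 6378137

#' Project geographic coordinates to a local planar frame
#'
#' Local equirectangular tangent-plane projection about `origin`
#' (lon0, lat0): x = R cos(lat0) (lon - lon0), y = R (lat - lat0), both in
#' metres. Exactly invertible, and accurate to well below GPS error at the
#' few-kilometre scale of a group's daily range.
#'
#' @param lon,lat degrees.
#' @param origin c(lon0, lat0) in degrees.
#' @return data.frame with planar `x`, `y` in metres.
#' @export
project_lonlat <- function(lon, lat, origin) {
  rad <- pi / 180
  data.frame(x = .EARTH_RADIUS * cos(origin[2] * rad) * (lon - origin[1]) * rad,
             y = .EARTH_RADIUS * (lat - origin[2]) * rad)
}

#' Inverse of [project_lonlat()]
#' @param x,y planar metres.
#' @param origin c(lon0, lat0) in degrees.
#' @return data.frame with `lon`, `lat` in degrees.
#' @export
unproject_xy <- function(x, y, origin) {
  rad <- pi / 180
  data.frame(lon = origin[1] + x / (.EARTH_RADIUS * cos(origin[2] * rad)) / rad,
             lat = origin[2] + y / .EARTH_RADIUS / rad)
}

# --- study area ------------------------------------------------------------

#' Define a study area in planar coordinates
#'
#' Either a rectangle (`xlim`, `ylim`) or an arbitrary polygon (two-column
#' matrix of vertices). Fixes outside the area are treated as gross GPS
#' outliers.
#'
#' @param xlim,ylim numeric length-2 ranges (rectangle form).
#' @param polygon optional two-column matrix of vertices (overrides the
#'   rectangle).
#' @return object of class `study_area`.
#' @export
study_area <- function(xlim = NULL, ylim = NULL, polygon = NULL) {
  if (is.null(polygon)) {
    stopifnot(length(xlim) == 2, length(ylim) == 2,
              diff(xlim) > 0, diff(ylim) > 0)
    polygon <- cbind(c(xlim[1], xlim[2], xlim[2], xlim[1]),
                     c(ylim[1], ylim[1], ylim[2], ylim[2]))
  }
  stopifnot(ncol(polygon) == 2, nrow(polygon) >= 3)
  # shoelace area must be non-degenerate
  xs <- polygon[, 1]; ys <- polygon[, 2]
  area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  stopifnot(area > 0)
  structure(list(polygon = polygon), class = "study_area")
}

# even-odd ray casting; boundary points count as inside
.point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

#' Remove fixes falling outside the study area
#'
#' Positions outside the area polygon are set to missing; the number of
#' removals is recorded in the `n_removed` attribute and reported.
#'
#' @param grid a [trajectory_grid()].
#' @param area a [study_area()] in the same planar frame.
#' @return the filtered grid.
#' @export
remove_outliers <- function(grid, area) {
  stopifnot(inherits(area, "study_area"))
  ok <- matrix(TRUE, nrow(grid$x), ncol(grid$x))
  present <- !is.na(grid$x)
  ok[present] <- .point_in_polygon(grid$x[present], grid$y[present], area$polygon)
  out <- present & !ok
  grid$x[out] <- NA_real_
  grid$y[out] <- NA_real_
  grid$interpolated[out] <- FALSE
  attr(grid, "n_removed") <- sum(out)
  if (sum(out) > 0) {
    message(sprintf("remove_outliers: %d fix(es) outside the study area set to missing",
                    sum(out)))
  }
  grid
}

#' Fill single-second gaps by linear interpolation
#'
#' A missing position at time t flanked by fixes at t - 1 and t + 1 is
#' replaced by the midpoint of the straight line connecting them, flagged
#' `interpolated`. Longer gaps are left missing; dyadic computations at
#' those times are skipped rather than imputed. Idempotent.
#'
#' @param grid a [trajectory_grid()].
#' @return grid with single gaps filled.
#' @export
interpolate_gaps <- function(grid) {
  nt <- length(grid$times)
  if (nt < 3) return(grid)
  unit <- c(FALSE, diff(grid$times) == 1L)            # times[t] - times[t-1] == 1
  for (i in seq_along(grid$ids)) {
    miss <- is.na(grid$x[i, ])
    t_mid <- which(miss[-c(1, nt)] ) + 1L             # candidate interior gaps
    if (!length(t_mid)) next
    ok <- !is.na(grid$x[i, t_mid - 1L]) & !is.na(grid$x[i, t_mid + 1L]) &
      unit[t_mid] & unit[t_mid + 1L]
    t_fill <- t_mid[ok]
    if (!length(t_fill)) next
    grid$x[i, t_fill] <- (grid$x[i, t_fill - 1L] + grid$x[i, t_fill + 1L]) / 2
    grid$y[i, t_fill] <- (grid$y[i, t_fill - 1L] + grid$y[i, t_fill + 1L]) / 2
    grid$interpolated[i, t_fill] <- TRUE
  }
  grid
}

# --- readers / writers -----------------------------------------------------

#' Default column mapping for Movebank-style CSV exports
#' @return named list of column names.
#' @export
movebank_cols <- function() {
  list(id = "individual-local-identifier",
       timestamp = "timestamp",
       lon = "location-long",
       lat = "location-lat",
       x = "x", y = "y")
}

#' Read a trajectory table into per-group, per-day grids
#'
#' Accepts a Movebank-style CSV with one row per fix. Coordinates may be
#' geographic (`lon`/`lat` columns; projected to planar metres about
#' `origin`) or already planar (`x`/`y` columns, metres). Timestamps are
#' parsed to integer seconds; sub-second jitter is rounded to the nearest
#' second with a warning. Rows whose id is absent from `metadata` are
#' skipped with a warning; unparsable timestamps are an error naming the
#' row. Trajectories are split per group and per UTC calendar day, so no
#' dyadic event can span days.
#'
#' @param path CSV file path.
#' @param metadata data.frame with columns `id`, `sex`, `group`.
#' @param col_map column mapping, see [movebank_cols()].
#' @param origin projection origin c(lon0, lat0); defaults to the centroid
#'   of the data when geographic coordinates are used.
#' @return named list of [trajectory_grid()] objects
#'   (`"<group>_<yyyy-mm-dd>"`), each carrying its ids' metadata rows in
#'   the `metadata` attribute.
#' @export
read_trajectories <- function(path, metadata, col_map = movebank_cols(),
                              origin = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  idc <- col_map$id
  stopifnot(idc %in% names(raw), col_map$timestamp %in% names(raw))
  ids_raw <- as.character(raw[[idc]])
  known <- ids_raw %in% as.character(metadata$id)
  if (any(!known)) {
    warning(sprintf("read_trajectories: skipping %d row(s) with unknown id(s): %s",
                    sum(!known), paste(unique(ids_raw[!known]), collapse = ", ")))
    raw <- raw[known, , drop = FALSE]
    ids_raw <- ids_raw[known]
  }
  ts_chr <- as.character(raw[[col_map$timestamp]])
  ts <- strptime(ts_chr, "%Y-%m-%d %H:%M:%OS", tz = "UTC")
  retry <- is.na(ts)
  if (any(retry)) {
    ts[retry] <- strptime(ts_chr[retry], "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  }
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop(sprintf("read_trajectories: unparsable timestamp '%s' at data row %d",
                 ts_chr[bad], bad))
  }
  secs <- as.numeric(ts)
  if (any(abs(secs - round(secs)) > 1e-6)) {
    warning("read_trajectories: sub-second timestamps rounded to the nearest second")
  }
  secs <- as.integer(round(secs))
  if (col_map$lon %in% names(raw) && col_map$lat %in% names(raw)) {
    lon <- raw[[col_map$lon]]; lat <- raw[[col_map$lat]]
    if (is.null(origin)) origin <- c(stats::median(lon), stats::median(lat))
    pl <- project_lonlat(lon, lat, origin)
    px <- pl$x; py <- pl$y
  } else {
    stopifnot(col_map$x %in% names(raw), col_map$y %in% names(raw))
    px <- raw[[col_map$x]]; py <- raw[[col_map$y]]
  }
  group <- as.character(metadata$group[match(ids_raw, as.character(metadata$id))])
  day <- format(as.POSIXct(secs, tz = "UTC", origin = "1970-01-01"), "%Y-%m-%d")
  key <- paste(group, day, sep = "_")
  out <- list()
  for (k in unique(key)) {
    sel <- key == k
    g_ids <- sort(unique(ids_raw[sel]))
    g_times <- seq(min(secs[sel]), max(secs[sel]))
    x <- matrix(NA_real_, length(g_ids), length(g_times))
    y <- matrix(NA_real_, length(g_ids), length(g_times))
    ri <- match(ids_raw[sel], g_ids)
    ci <- secs[sel] - g_times[1] + 1L
    # last fix wins on duplicate (id, second) rows
    x[cbind(ri, ci)] <- px[sel]
    y[cbind(ri, ci)] <- py[sel]
    g <- trajectory_grid(g_ids, g_times, x, y)
    attr(g, "metadata") <- metadata[match(g_ids, as.character(metadata$id)), ,
                                    drop = FALSE]
    attr(g, "origin") <- origin
    out[[k]] <- g
  }
  out[order(names(out))]
}

#' Write a grid as a normalized long-format table
#' @param grid a [trajectory_grid()].
#' @param path output CSV path.
#' @return the written data.frame, invisibly.
#' @export
write_trajectories <- function(grid, path) {
  present <- which(!is.na(grid$x), arr.ind = TRUE)
  df <- data.frame(id = grid$ids[present[, 1]],
                   t = grid$times[present[, 2]],
                   x = grid$x[present],
                   y = grid$y[present],
                   interpolated = grid$interpolated[present])
  df <- df[order(df$id, df$t), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
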