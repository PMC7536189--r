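#' Water-maze pool geometry
#'
#' All trajectory computations use a pool-centred frame in centimetres.
#' Defaults describe a 200-cm-diameter pool with a 10-cm hidden platform
#' placed at 60 cm radial distance in the north-east quadrant and a drop
#' point near the wall.
#'
#' @param pool_center numeric length-2, pool centre (cm); the origin by
#'   convention.
#' @param pool_radius pool radius in cm (default 100).
#' @param platform_center numeric length-2, platform centre (cm).
#' @param platform_radius platform radius in cm (default 5).
#' @param drop_point numeric length-2, release position (cm).
#' @return object of class `pool_geometry`.
#' @export
pool_geometry <- function(pool_center = c(0, 0), pool_radius = 100,
                          platform_center = c(60 / sqrt(2), 60 / sqrt(2)),
                          platform_radius = 5,
                          drop_point = c(-95 / sqrt(2), -95 / sqrt(2))) {
  stopifnot(length(pool_center) == 2, length(platform_center) == 2,
            length(drop_point) == 2, pool_radius > 0, platform_radius > 0)
  if (sqrt(sum((platform_center - pool_center)^2)) + platform_radius >
      pool_radius)
    stop("platform must lie inside the pool")
  structure(list(pool_center = as.numeric(pool_center),
                 pool_radius = as.numeric(pool_radius),
                 platform_center = as.numeric(platform_center),
                 platform_radius = as.numeric(platform_radius),
                 drop_point = as.numeric(drop_point)),
            class = "pool_geometry")
}

#' Swim trajectory with pool geometry
#'
#' @param t time in seconds from trial start, strictly increasing.
#' @param x,y position in cm, pool-centred frame.
#' @param geometry a [pool_geometry()].
#' @param dropped_rows count of input rows discarded during parsing
#'   (bookkeeping from [read_trajectory()]).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(t, x, y, geometry, dropped_rows = 0L) {
  stopifnot(inherits(geometry, "pool_geometry"))
  if (length(t) != length(x) || length(t) != length(y))
    stop("t, x, y must have equal length")
  if (length(t) < 2) stop("degenerate track")
  if (any(diff(t) <= 0)) stop("non-monotone time")
  r <- sqrt((x - geometry$pool_center[1])^2 + (y - geometry$pool_center[2])^2)
  if (any(r > geometry$pool_radius * 1.05))
    stop("trajectory leaves the pool")
  structure(list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 geometry = geometry, dropped_rows = as.integer(dropped_rows)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$t), " samples over ",
      round(x$t[length(x$t)] - x$t[1], 2), " s; path ",
      round(polyline_length(x$x, x$y), 1), " cm\n", sep = "")
  invisible(x)
}

polyline_length <- function(x, y) sum(sqrt(diff(x)^2 + diff(y)^2))

#' Read a swim trajectory from CSV
#'
#' Expects columns `time`, `x`, `y` (seconds / cm). Rows with missing
#' coordinates are dropped; the number of dropped rows is recorded in the
#' returned object (`$dropped_rows`) and reported with a message.
#'
#' @param path file path.
#' @param geometry a [pool_geometry()].
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, geometry) {
  tab <- utils::read.csv(path)
  need <- c("time", "x", "y")
  if (!all(need %in% names(tab)))
    stop("trajectory CSV needs columns time, x, y")
  ok <- stats::complete.cases(tab[, need])
  dropped <- sum(!ok)
  if (dropped > 0)
    message("read_trajectory: dropped ", dropped, " row(s) with missing coordinates")
  tab <- tab[ok, , drop = FALSE]
  if (nrow(tab) < 2) stop("degenerate track")
  if (any(diff(tab$time) <= 0)) stop("non-monotone time")
  trajectory(tab$time, tab$x, tab$y, geometry, dropped_rows = dropped)
}

#' Write a swim trajectory to CSV
#' @param trj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trj, path) {
  utils::write.csv(data.frame(time = trj$t, x = trj$x, y = trj$y),
                   path, row.names = FALSE)
  invisible(path)
}
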