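#' Route efficiency of a swim path
#'
#' Route efficiency is the straight drop-to-platform distance divided by
#' the actual swim path length up to first platform contact (or trial
#' end), expressed in percent and capped at 100. A perfectly straight
#' swim scores 100%; a path twice as long as the direct line scores 50%.
#'
#' @param trj a [trajectory()].
#' @return route efficiency in percent, in (0, 100\].
#' @export
route_efficiency <- function(trj) {
  stopifnot(inherits(trj, "trajectory"))
  g <- trj$geometry
  i_end <- platform_contact_index(trj)
  idx <- seq_len(if (is.na(i_end)) length(trj$t) else i_end)
  path <- polyline_length(trj$x[idx], trj$y[idx])
  if (path <= 0) stop("degenerate path")
  direct <- sqrt(sum((g$platform_center - g$drop_point)^2))
  min(100, 100 * direct / path)
}

# first sample within platform_radius of the platform centre (NA if none)
platform_contact_index <- function(trj) {
  g <- trj$geometry
  d <- sqrt((trj$x - g$platform_center[1])^2 +
              (trj$y - g$platform_center[2])^2)
  hit <- which(d <= g$platform_radius)
  if (length(hit)) hit[1] else NA_integer_
}

#' Water-maze trial metrics
#'
#' Computes per-trial performance measures. Metric accumulation stops
#' at first platform contact; trials that never reach the platform are
#' censored at the trial cap. Quadrant occupancy uses pool-frame
#' quadrants rotated so the platform quadrant comes first, with each
#' path segment's dwell time assigned by its midpoint.
#'
#' @param trj a [trajectory()].
#' @param strategy_cfg a [strategy_config()] used for classification.
#' @param trial_cap trial duration cap in seconds (default 120).
#' @return object of class `trial_metrics`: `route_efficiency` (%),
#'   `time_to_target` (s), `censored` (logical), `path_length` (cm),
#'   `mean_speed` (cm/s), `quadrant_time` (named fractions summing
#'   to 1: target, adj_left, opposite, adj_right), `strategy`,
#'   `strategy_score`.
#' @export
trial_metrics <- function(trj, strategy_cfg = strategy_config(),
                          trial_cap = 120) {
  stopifnot(inherits(trj, "trajectory"))
  g <- trj$geometry
  i_end <- platform_contact_index(trj)
  censored <- is.na(i_end)
  idx <- seq_len(if (censored) length(trj$t) else i_end)
  path <- polyline_length(trj$x[idx], trj$y[idx])
  elapsed <- trj$t[idx[length(idx)]] - trj$t[1]
  tt <- if (censored) trial_cap else trj$t[i_end] - trj$t[1]

  # dwell-weighted quadrant occupancy, platform quadrant first
  mx <- (trj$x[idx[-length(idx)]] + trj$x[idx[-1]]) / 2 - g$pool_center[1]
  my <- (trj$y[idx[-length(idx)]] + trj$y[idx[-1]]) / 2 - g$pool_center[2]
  dtv <- diff(trj$t[idx])
  quad <- (floor(atan2(my, mx) / (pi / 2)) %% 4)      # 0..3 CCW from +x axis
  pq <- floor(atan2(g$platform_center[2] - g$pool_center[2],
                    g$platform_center[1] - g$pool_center[1]) / (pi / 2)) %% 4
  rel <- (quad - pq) %% 4
  qt <- vapply(0:3, function(q) sum(dtv[rel == q]), numeric(1))
  qt <- qt / sum(qt)
  names(qt) <- c("target", "adj_left", "opposite", "adj_right")

  cls <- classify_strategy(trj, strategy_cfg)
  structure(list(route_efficiency = route_efficiency(trj),
                 time_to_target = tt, censored = censored,
                 path_length = path,
                 mean_speed = if (elapsed > 0) path / elapsed else NA_real_,
                 quadrant_time = qt,
                 strategy = cls$strategy,
                 strategy_score = cls$strategy_score),
            class = "trial_metrics")
}

#' @export
print.trial_metrics <- function(x, ...) {
  cat(sprintf("<trial_metrics> %s (score %d); RE %.1f%%; time %.1f s%s; %.0f cm @ %.1f cm/s\n",
              x$strategy, x$strategy_score, x$route_efficiency,
              x$time_to_target, if (x$censored) " (censored)" else "",
              x$path_length, x$mean_speed))
  invisible(x)
}

#' Decision thresholds for search-strategy classification
#'
#' Zone definitions and cut-offs of the first-match classification
#' cascade. These defaults are stand-ins chosen to capture the
#' category semantics on synthetic archetypes; the exact parameters of
#' published classifiers vary between laboratories, so every threshold
#' is exposed here.
#'
#' @param thigmo_wall_width outer-annulus width as a fraction of the
#'   pool radius (default 0.15) for thigmotaxis.
#' @param thigmo_min_frac minimum fraction of samples in that annulus
#'   (default 0.75).
#' @param random_min_coverage minimum pool grid coverage for
#'   random search (default 0.5; 10 x 10 grid).
#' @param scanning_central_frac central-region radius as a fraction of
#'   the pool radius (default 0.6).
#' @param scanning_min_frac minimum fraction of samples in the central
#'   region (default 0.75).
#' @param scanning_min_coverage minimum grid coverage (default 0.15),
#'   keeps focal concentration from passing as scanning.
#' @param scanning_max_outer_frac maximum fraction beyond 0.8 pool
#'   radius (default 0.05), keeps cross-pool corridors from passing.
#' @param chaining_halfwidth half-width (cm) of the annulus at the
#'   platform's distance from the wall (default 12.5).
#' @param chaining_min_frac minimum fraction in the annulus (default 0.7).
#' @param near_platform_radius radius (cm) defining "near the platform"
#'   (default 20), shared by the chaining/directed exclusions and the
#'   focal rule.
#' @param max_platform_frac chaining and directed search require less
#'   than this fraction of samples near the platform (default 0.5),
#'   separating them from focal search.
#' @param directed_corridor_deg half-angle (degrees) of the
#'   drop-to-platform corridor for directed search (default 30).
#' @param directed_min_frac minimum corridor fraction (default 0.8).
#' @param directed_max_eff directed search requires route efficiency
#'   below this value (default 80%), separating it from direct swimming.
#' @param focal_min_frac minimum post-approach fraction within
#'   `near_platform_radius` (default 0.6).
#' @param focal_min_dwell minimum post-approach duration in seconds
#'   (default 5), separating focal search from a direct final approach.
#' @param direct_corridor_deg corridor half-angle for direct swimming
#'   (default 15).
#' @param direct_min_frac minimum corridor fraction (default 0.8).
#' @param direct_min_eff minimum route efficiency (default 80%).
#' @return object of class `strategy_config`.
#' @export
strategy_config <- function(thigmo_wall_width = 0.15,
                            thigmo_min_frac = 0.75,
                            random_min_coverage = 0.5,
                            scanning_central_frac = 0.6,
                            scanning_min_frac = 0.75,
                            scanning_min_coverage = 0.15,
                            scanning_max_outer_frac = 0.05,
                            chaining_halfwidth = 12.5,
                            chaining_min_frac = 0.7,
                            near_platform_radius = 20,
                            max_platform_frac = 0.5,
                            directed_corridor_deg = 30,
                            directed_min_frac = 0.8,
                            directed_max_eff = 80,
                            focal_min_frac = 0.6,
                            focal_min_dwell = 5,
                            direct_corridor_deg = 15,
                            direct_min_frac = 0.8,
                            direct_min_eff = 80) {
  fracs <- c(thigmo_wall_width, thigmo_min_frac, random_min_coverage,
             scanning_central_frac, scanning_min_frac,
             scanning_min_coverage, scanning_max_outer_frac,
             chaining_min_frac, max_platform_frac, directed_min_frac,
             focal_min_frac, direct_min_frac)
  if (any(fracs < 0) || any(fracs > 1)) stop("invalid strategy config")
  if (chaining_halfwidth < 0 || near_platform_radius < 0 ||
      focal_min_dwell < 0 || directed_corridor_deg < 0 ||
      direct_corridor_deg < 0 || directed_max_eff < 0 || direct_min_eff < 0)
    stop("invalid strategy config")
  structure(as.list(environment()), class = "strategy_config")
}

strategy_scores <- c(thigmotaxis = 0L, random_search = 0L, scanning = 0L,
                     chaining = 0L, directed_search = 1L, focal_search = 2L,
                     direct_swimming = 3L)

#' Classify the search strategy of a swim path
#'
#' First-match decision cascade over the seven categories, evaluated in
#' the order thigmotaxis, random search, scanning, chaining, directed
#' search, focal search, direct swimming, with random search as the
#' fallback. Undirected categories score 0 points; directed search,
#' focal search and direct swimming score 1, 2 and 3, reflecting
#' increasing reliance on an internal spatial representation.
#'
#' @param trj a [trajectory()].
#' @param config a [strategy_config()].
#' @return list with `strategy` (category name) and `strategy_score`
#'   (integer 0-3).
#' @export
classify_strategy <- function(trj, config = strategy_config()) {
  stopifnot(inherits(trj, "trajectory"), inherits(config, "strategy_config"))
  g <- trj$geometry
  x <- trj$x - g$pool_center[1]; y <- trj$y - g$pool_center[2]
  R <- g$pool_radius
  r <- sqrt(x^2 + y^2)
  n <- length(r)

  frac_outer <- mean(r >= (1 - config$thigmo_wall_width) * R)
  frac_central <- mean(r <= config$scanning_central_frac * R)
  frac_far_out <- mean(r > 0.8 * R)

  # grid coverage: 10x10 cells over the bounding square, cells whose
  # centre lies inside the pool
  ng <- 10L
  cell <- 2 * R / ng
  cx <- pmin(pmax(floor((x + R) / cell), 0), ng - 1)
  cy <- pmin(pmax(floor((y + R) / cell), 0), ng - 1)
  centers_x <- ((0:(ng - 1)) + 0.5) * cell - R
  inside <- outer(centers_x, centers_x,
                  function(a, b) sqrt(a^2 + b^2) < R)
  visited <- unique(cbind(cx, cy))
  visited <- visited[inside[cbind(visited[, 1] + 1L, visited[, 2] + 1L)], ,
                     drop = FALSE]
  coverage <- nrow(visited) / sum(inside)

  plat_d <- sqrt((trj$x - g$platform_center[1])^2 +
                   (trj$y - g$platform_center[2])^2)
  frac_near_plat <- mean(plat_d <= config$near_platform_radius)

  wall_d_plat <- R - sqrt(sum((g$platform_center - g$pool_center)^2))
  wall_d <- R - r
  frac_annulus <- mean(abs(wall_d - wall_d_plat) <= config$chaining_halfwidth)

  # corridor fractions: angle at the drop point between the sample and
  # the platform direction; samples within 5 cm of the drop are ignored
  v0 <- g$platform_center - g$drop_point
  dx <- trj$x - g$drop_point[1]; dy <- trj$y - g$drop_point[2]
  dd <- sqrt(dx^2 + dy^2)
  ang <- abs(atan2(dy * v0[1] - dx * v0[2], dx * v0[1] + dy * v0[2]))
  far <- dd > 5
  corridor_frac <- function(deg) {
    if (!any(far)) return(0)
    mean(ang[far] <= deg * pi / 180)
  }

  eff <- route_efficiency(trj)

  # focal features: approach = first entry into the near-platform zone
  app <- which(plat_d <= config$near_platform_radius)[1]
  post_dwell <- if (is.na(app)) 0 else trj$t[n] - trj$t[app]
  post_frac <- if (is.na(app)) 0 else
    mean(plat_d[app:n] <= config$near_platform_radius)

  strategy <-
    if (frac_outer >= config$thigmo_min_frac) "thigmotaxis"
    else if (coverage >= config$random_min_coverage) "random_search"
    else if (frac_central >= config$scanning_min_frac &&
             coverage >= config$scanning_min_coverage &&
             frac_far_out <= config$scanning_max_outer_frac &&
             frac_annulus < config$chaining_min_frac) "scanning"
    else if (frac_annulus >= config$chaining_min_frac &&
             frac_near_plat < config$max_platform_frac) "chaining"
    else if (corridor_frac(config$directed_corridor_deg) >=
               config$directed_min_frac &&
             eff < config$directed_max_eff &&
             frac_near_plat < config$max_platform_frac) "directed_search"
    else if (!is.na(app) && post_dwell >= config$focal_min_dwell &&
             post_frac >= config$focal_min_frac) "focal_search"
    else if (eff >= config$direct_min_eff &&
             corridor_frac(config$direct_corridor_deg) >=
               config$direct_min_frac) "direct_swimming"
    else "random_search"

  list(strategy = strategy,
       strategy_score = unname(strategy_scores[strategy]))
}

#' Mean strategy ranking per training day
#'
#' Averages the 0-3 strategy scores of all trials within each day
#' group, the standard summary of search-strategy progression over a
#' multi-day protocol (e.g. 6 trials per day).
#'
#' @param scores integer vector of per-trial strategy scores (0-3).
#' @param day integer/factor vector of day indices, same length.
#' @return data.frame with columns `day`, `mean_score`, `n_trials`;
#'   days with no trials are absent (missing), never reported as zero.
#' @export
strategy_ranking <- function(scores, day) {
  if (length(scores) != length(day)) stop("scores and day must align")
  if (length(scores) == 0) stop("no trials")
  if (!all(scores %in% 0:3)) stop("scores must be integers 0-3")
  agg <- stats::aggregate(list(mean_score = scores),
                          by = list(day = day), FUN = mean)
  agg$n_trials <- as.integer(table(day)[as.character(agg$day)])
  agg[order(agg$day), , drop = FALSE]
}
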