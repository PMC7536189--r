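#' Generate a synthetic swim trajectory for a search-strategy archetype
#'
#' Produces a 25-Hz swim path obeying the geometric signature of one of
#' the seven search strategies used to describe water-maze behaviour:
#'
#' * `thigmotaxis` — wall hugging: the mouse circles in the outer
#'   annulus (>= 85% of the pool radius).
#' * `random_search` — a persistent random walk covering the whole pool.
#' * `scanning` — a random walk confined to the central region.
#' * `chaining` — swimming in an annulus at the platform's distance from
#'   the wall, circling until the platform is crossed.
#' * `directed_search` — a weaving but goal-directed corridor from the
#'   drop point to the platform.
#' * `focal_search` — a direct approach followed by confined search
#'   within ~20 cm of the platform before contact.
#' * `direct_swimming` — a straight drop-to-platform segment with small
#'   heading jitter.
#'
#' The path terminates at platform contact (position within
#' `platform_radius` of the platform centre) or after 120 s.
#'
#' @param strategy archetype name (one of the seven above).
#' @param geometry a [pool_geometry()].
#' @param speed swim speed in cm/s (default 20).
#' @param seed integer seed; identical seeds give identical paths.
#' @param jitter multiplier on all stochastic components (default 1;
#'   `jitter = 0` makes `direct_swimming` a perfectly straight line).
#' @return a [trajectory()].
#' @export
generate_trajectory <- function(strategy, geometry = pool_geometry(),
                                speed = 20, seed = 1L, jitter = 1) {
  known <- c("thigmotaxis", "random_search", "scanning", "chaining",
             "directed_search", "focal_search", "direct_swimming")
  if (!(is.character(strategy) && length(strategy) == 1 &&
        strategy %in% known))
    stop("unknown strategy")
  stopifnot(inherits(geometry, "pool_geometry"), speed > 0, jitter >= 0)
  with_seed(substream_seed(seed, match(strategy, known)), {
    sim_archetype(strategy, geometry, speed, jitter)
  })
}

sim_archetype <- function(strategy, geom, speed, jitter) {
  dt <- 1 / 25
  max_n <- round(120 / dt)
  step <- speed * dt
  ctr <- geom$pool_center
  R <- geom$pool_radius
  plat <- geom$platform_center
  rp <- geom$platform_radius
  pos <- geom$drop_point
  xs <- numeric(max_n + 1); ys <- numeric(max_n + 1)
  xs[1] <- pos[1]; ys[1] <- pos[2]

  bearing <- function(from, to) atan2(to[2] - from[2], to[1] - from[1])
  dist2plat <- function(p) sqrt(sum((p - plat)^2))
  clamp_pool <- function(p) {
    d <- p - ctr; r <- sqrt(sum(d^2))
    if (r > 0.98 * R) ctr + d / r * 0.98 * R else p
  }

  # per-archetype persistent state
  phase <- switch(strategy,
    thigmotaxis = list(dir = sample(c(-1, 1), 1),
                       r = sqrt(sum((pos - ctr)^2))),
    chaining = list(stage = "transit", dir = sample(c(-1, 1), 1)),
    focal_search = list(stage = "approach", dwell = 0,
                        dir = sample(c(-1, 1), 1)),
    random_search = list(head = stats::runif(1, -pi, pi)),
    scanning = list(stage = "transit", head = NA_real_),
    directed_search = list(t0 = stats::runif(1, 0, 2 * pi)),
    direct_swimming = list())

  r_ring <- sqrt(sum((plat - ctr)^2))     # chaining radius
  weave_T <- 5                            # directed weave period (s)

  i <- 1L
  while (i <= max_n) {
    tnow <- (i - 1) * dt
    p <- c(xs[i], ys[i])
    head <- switch(strategy,
      thigmotaxis = {
        # follow the wall at ~0.92R with slight radial breathing
        phase$r <- max(0.87 * R, min(0.98 * R,
          phase$r + jitter * stats::rnorm(1, 0, 1.5)))
        ang <- atan2(p[2] - ctr[2], p[1] - ctr[1])
        target_ang <- ang + phase$dir * step / phase$r * 1.5
        target <- ctr + phase$r * c(cos(target_ang), sin(target_ang))
        bearing(p, target)
      },
      random_search = {
        phase$head <- phase$head + jitter * stats::rnorm(1, 0, 0.35)
        r <- sqrt(sum((p - ctr)^2))
        if (r > 0.95 * R) phase$head <- bearing(p, ctr) +
            jitter * stats::rnorm(1, 0, 0.4)
        phase$head
      },
      scanning = {
        r <- sqrt(sum((p - ctr)^2))
        if (identical(phase$stage, "transit")) {
          if (r < 0.40 * R) {
            phase$stage <- "scan"; phase$head <- stats::runif(1, -pi, pi)
          }
          bearing(p, ctr)
        } else {
          phase$head <- phase$head + jitter * stats::rnorm(1, 0, 0.45)
          if (r > 0.48 * R) phase$head <- bearing(p, ctr) +
              jitter * stats::rnorm(1, 0, 0.3)
          phase$head
        }
      },
      chaining = {
        r <- sqrt(sum((p - ctr)^2))
        if (identical(phase$stage, "transit")) {
          if (abs(r - r_ring) < 4) phase$stage <- "orbit"
          bearing(p, ctr)  # head inward from the wall
        } else {
          ang <- atan2(p[2] - ctr[2], p[1] - ctr[1])
          rr <- r_ring + jitter * stats::rnorm(1, 0, 2)
          target_ang <- ang + phase$dir * step / r_ring * 1.5
          target <- ctr + rr * c(cos(target_ang), sin(target_ang))
          bearing(p, target)
        }
      },
      directed_search = {
        b <- bearing(p, plat)
        # weave grows with distance from the drop so the early path does
        # not leave the goal corridor
        d0 <- sqrt(sum((p - geom$drop_point)^2))
        amp <- (70 * pi / 180) * min(1, d0 / 40)
        b + amp * sin(2 * pi * tnow / weave_T + phase$t0) *
          jitter + jitter * stats::rnorm(1, 0, 0.10)
      },
      focal_search = {
        d <- dist2plat(p)
        if (identical(phase$stage, "approach")) {
          if (d < 14) phase$stage <- "focal"
          bearing(p, plat) + jitter * stats::rnorm(1, 0, 0.05)
        } else if (phase$dwell * dt < 25) {
          phase$dwell <- phase$dwell + 1
          # orbit the platform at 8-17 cm without touching it
          ang <- atan2(p[2] - plat[2], p[1] - plat[1])
          rr <- max(8, min(17, d + jitter * stats::rnorm(1, 0, 2.5)))
          target_ang <- ang + phase$dir * step / 12
          target <- plat + rr * c(cos(target_ang), sin(target_ang))
          bearing(p, target)
        } else {
          bearing(p, plat)
        }
      },
      direct_swimming = bearing(p, plat) + jitter * stats::rnorm(1, 0, 0.05)
    )
    nxt <- clamp_pool(p + step * c(cos(head), sin(head)))
    i <- i + 1L
    xs[i] <- nxt[1]; ys[i] <- nxt[2]
    if (dist2plat(nxt) <= rp) break
  }
  idx <- seq_len(i)
  trajectory((idx - 1) * dt, xs[idx], ys[idx], geometry = geom)
}
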