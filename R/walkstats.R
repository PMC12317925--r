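#' Per-walk distance and deviation statistics
#'
#' Total distance is the accumulated centre-to-centre path length;
#' resultant distance the straight-line distance from start to finish.
#' Walk deviation — how far the walk departs from a straight line — is
#' their difference expressed as a percentage of the total distance,
#' `100 * (total - resultant) / total`, which makes runs of different
#' neighbourhood sizes (and hence different absolute walk lengths)
#' comparable. A walk of zero total length has deviation 0 by convention
#' (it deviates from nothing); a walk returning to its start has
#' deviation 100. The azimuth is the quadrant-method compass bearing of
#' the start-to-end resultant, undefined (`NA`) for zero displacement.
#'
#' @param walk A [run_walk()] result.
#' @return A list: `total_distance`, `resultant_distance`,
#'   `deviation_pct`, `azimuth_deg`.
#' @export
walk_distances <- function(walk) {
  stopifnot(inherits(walk, "walk"))
  total <- sum(walk$step_lengths)
  a <- walk$centres[1L, ]
  b <- walk$centres[nrow(walk$centres), ]
  resultant <- sqrt(sum((b - a)^2))
  # clamped: rounding on a near-closed walk must not push past 100
  deviation <- if (total > 0) min(max(100 * (total - resultant) / total, 0), 100) else 0
  list(total_distance = total, resultant_distance = resultant,
       deviation_pct = deviation, azimuth_deg = azimuth(a, b))
}

#' Compass azimuth by the quadrant method
#'
#' Bearing in degrees clockwise from grid north. With easting difference
#' dE and northing difference dN, the base angle is
#' `atan(|dE| / |dN|)` and the quadrant correction is: NE `theta`,
#' SE `180 - theta`, SW `180 + theta`, NW `360 - theta`. Zero
#' displacement has no defined bearing and returns `NA`.
#'
#' @param start,end World `(x, y)` coordinates.
#' @return Degrees in `[0, 360)`, or `NA_real_`.
#' @examples
#' azimuth(c(0, 0), c(0, 1))    # 0 (due north)
#' azimuth(c(0, 0), c(1, 0))    # 90 (due east)
#' azimuth(c(0, 0), c(-1, -1))  # 225 (south-west)
#' @export
azimuth <- function(start, end) {
  dE <- end[1] - start[1]
  dN <- end[2] - start[2]
  if (dE == 0 && dN == 0) return(NA_real_)
  theta <- atan(abs(dE) / abs(dN)) * 180 / pi  # atan(Inf) = 90 when dN = 0
  az <- if (dE >= 0 && dN > 0) theta
        else if (dE > 0 && dN <= 0) 180 - theta
        else if (dE <= 0 && dN < 0) 180 + theta
        else 360 - theta
  az %% 360
}

#' Rayleigh test of circular uniformity
#'
#' Tests a sample of bearings against the uniform circular distribution,
#' with power against a unimodal alternative. The statistic is
#' `Z = n * Rbar^2` where `Rbar` is the mean resultant length, and the
#' p-value uses the standard small-sample series
#' `exp(-Z) * [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2)]`,
#' clipped to `[0, 1]`.
#'
#' @param azimuths Bearings in degrees (finite; `n >= 1`).
#' @return An object of class `htest` with `statistic` (Z), `p.value`,
#'   `estimate` (Rbar) and `parameter` (n).
#' @export
rayleigh_test <- function(azimuths) {
  if (length(azimuths) < 1L || !all(is.finite(azimuths)))
    stop("`azimuths` must be a non-empty vector of finite bearings")
  n <- length(azimuths)
  th <- azimuths * pi / 180
  rbar <- sqrt(sum(cos(th))^2 + sum(sin(th))^2) / n
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  structure(list(statistic = c(Z = z), p.value = p,
                 estimate = c(Rbar = rbar), parameter = c(n = n),
                 method = "Rayleigh test of circular uniformity",
                 data.name = deparse(substitute(azimuths))),
            class = "htest")
}

#' Kuiper's test of circular uniformity (Stephens modification)
#'
#' The rotation-invariant circular analogue of the Kolmogorov-Smirnov
#' test. The raw statistic `V = D+ + D-` is computed against the uniform
#' CDF of `azimuth / 360`; the reported statistic is the Stephens-
#' modified, sample-size-stable form
#' `V* = V * (sqrt(n) + 0.155 + 0.24 / sqrt(n))`, and the p-value is the
#' asymptotic series `sum_k 2 * (4 k^2 V*^2 - 1) * exp(-2 k^2 V*^2)`
#' (see [kuiper_pvalue()]). The statistic is invariant under rotation of
#' all bearings by any constant.
#'
#' @param azimuths Bearings in degrees; at least 5 (the asymptotic
#'   p-value is unreliable below that).
#' @return An object of class `htest` with `statistic` (the modified V*),
#'   `p.value` and `parameter` (n).
#' @export
kuiper_test <- function(azimuths) {
  if (length(azimuths) < 5L)
    stop("Kuiper's test needs at least 5 bearings")
  if (!all(is.finite(azimuths)))
    stop("`azimuths` must be finite")
  n <- length(azimuths)
  u <- sort((azimuths %% 360) / 360)
  i <- seq_len(n)
  dplus <- max(i / n - u)
  dminus <- max(u - (i - 1) / n)
  v <- dplus + dminus
  vstar <- v * (sqrt(n) + 0.155 + 0.24 / sqrt(n))
  structure(list(statistic = c(Vstar = vstar), p.value = kuiper_pvalue(vstar),
                 parameter = c(n = n),
                 method = "Kuiper's test of circular uniformity (Stephens-modified)",
                 data.name = deparse(substitute(azimuths))),
            class = "htest")
}

#' P-value of the Stephens-modified Kuiper statistic
#'
#' Evaluates the asymptotic null tail probability
#' `p = sum_{k>=1} 2 * (4 k^2 V*^2 - 1) * exp(-2 k^2 V*^2)` at a given
#' modified statistic, truncating the series when a term falls below
#' 1e-10 and clipping to `[0, 1]`.
#'
#' @param statistic The Stephens-modified Kuiper statistic V*.
#' @return P-value in `[0, 1]`.
#' @examples
#' kuiper_pvalue(1.834)  # ~0.03
#' @export
kuiper_pvalue <- function(statistic) {
  if (!is.numeric(statistic) || length(statistic) != 1L || !is.finite(statistic) ||
      statistic < 0)
    stop("`statistic` must be a single non-negative number")
  p <- 0
  for (k in 1:1000) {
    a <- 2 * k^2 * statistic^2
    term <- 2 * (2 * a - 1) * exp(-a)
    p <- p + term
    if (abs(term) < 1e-10) break
  }
  min(max(p, 0), 1)
}

#' Square-root-scaled rose-diagram bins
#'
#' Counts bearings into half-open sectors `[k * w, (k + 1) * w)` of width
#' `w` degrees (which must divide 360 exactly; 360 wraps into the first
#' sector) and reports square-root-scaled heights, the usual scaling for
#' orientation rose diagrams since sector *area* then reflects count.
#'
#' @param azimuths Bearings in degrees (may be empty).
#' @param bin_width Sector width in degrees, an exact divisor of 360.
#' @return Data frame with `bin_start`, `bin_end`, `count`, `height`
#'   (`sqrt(count)`); `sum(height^2)` reconstructs the sample size.
#' @export
rose_bins <- function(azimuths, bin_width = 15) {
  nb <- 360 / bin_width
  if (!is.finite(nb) || abs(nb - round(nb)) > 1e-9 || nb < 1)
    stop("`bin_width` must divide 360 exactly")
  nb <- as.integer(round(nb))
  az <- azimuths[is.finite(azimuths)] %% 360
  idx <- floor(az / bin_width) + 1L
  idx[idx > nb] <- 1L  # guard: floating wrap of values just under 360
  counts <- tabulate(idx, nbins = nb)
  data.frame(bin_start = (seq_len(nb) - 1L) * bin_width,
             bin_end = seq_len(nb) * bin_width,
             count = counts, height = sqrt(counts))
}

#' Per-walk statistics table
#'
#' One row per walk: run id, seed, termination status, number of steps,
#' fallback-event count, distances, deviation percentage and azimuth.
#' Walks with zero displacement have `NA` azimuth; downstream circular
#' analyses exclude (never zero-fill) them.
#'
#' @param walks List of [run_walk()] results.
#' @return A data frame.
#' @export
walk_stats_table <- function(walks) {
  if (!length(walks))
    return(data.frame(run = integer(), seed = integer(), status = character(),
                      n_steps = integer(), fallback_events = integer(),
                      total_distance = numeric(), resultant_distance = numeric(),
                      deviation_pct = numeric(), azimuth_deg = numeric()))
  rows <- lapply(seq_along(walks), function(k) {
    w <- walks[[k]]
    d <- walk_distances(w)
    data.frame(run = k, seed = w$seed, status = w$status,
               n_steps = length(w$step_lengths),
               fallback_events = sum(w$fallback),
               total_distance = d$total_distance,
               resultant_distance = d$resultant_distance,
               deviation_pct = d$deviation_pct,
               azimuth_deg = d$azimuth_deg)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
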