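#' Flight range from fuel load
#'
#' Potential flight distance for a bird departing with fuel load `f`
#' (proportion of lean body mass): `Y = c (1 - 1/sqrt(1 + f))`. The
#' relation is increasing and concave, with `Y(0) = 0` and asymptote `c`,
#' reflecting the rising cost of transporting fuel.
#'
#' @param f Fuel load(s), >= 0 (proportion of lean body mass).
#' @param c Composite flight-range coefficient, km (morphology and energy
#'   conversion efficiency; default 15000, reasonable for a shorebird).
#' @return Flight range(s), km.
#' @export
#' @examples
#' flight_range(1)  # 15000 * (1 - 1/sqrt(2)) ~ 4393 km
flight_range <- function(f, c = 15000) {
  if (any(f < 0)) stop("fuel load f must be >= 0")
  stopifnot(c > 0)
  c * (1 - 1 / sqrt(1 + f))
}

#' Optimal departure fuel load for an energy minimizer
#'
#' An energy minimizer departs with the fuel load maximizing the flight
#' distance per unit fuel, net of the search/settling energy cost `f0` paid
#' at each new stopover: `R(f) = (Y(f) - Y(f0)) / f`. Found by bounded
#' golden-section maximization (tolerance 1e-7 on f).
#'
#' @param f0 Search/settling energy cost, proportion of lean body mass
#'   (0 < f0 < 1).
#' @param c Flight-range coefficient, km.
#' @return The optimal departure fuel load `f*`.
#' @export
optimal_departure_fuel <- function(f0, c = 15000) {
  stopifnot(f0 > 0, f0 < 1, c > 0)
  obj <- function(f) (flight_range(f, c) - flight_range(f0, c)) / f
  opt <- stats::optimize(obj, interval = c(1e-8, 10), maximum = TRUE,
                         tol = 1e-7)
  if (!is.finite(opt$objective)) stop("objective not finite")
  opt$maximum
}

#' Number of flights for an energy-minimizing migrant
#'
#' Divides the migration distance by the flight range at the optimal
#' departure fuel load. A partial flight still requires a flight, so the
#' quotient is rounded up by default; the raw quotient is attached as
#' attribute `"quotient"` (and `rounding = "round"` gives
#' nearest-integer rounding).
#'
#' @param D Migration distance, km (> 0).
#' @param f0 Search/settling energy cost.
#' @param c Flight-range coefficient, km.
#' @param rounding `"ceiling"` (default) or `"round"` (minimum 1).
#' @return Positive integer number of flights, with attribute `"quotient"`.
#' @export
#' @examples
#' n_flights_energy(2000, f0 = 0.005)  # 3.25 -> 4 flights
n_flights_energy <- function(D, f0, c = 15000,
                             rounding = c("ceiling", "round")) {
  rounding <- match.arg(rounding)
  stopifnot(all(D > 0))
  y <- flight_range(optimal_departure_fuel(f0, c), c)
  q <- D / y
  n <- if (rounding == "ceiling") ceiling(q) else pmax(1, round(q))
  structure(as.integer(n), quotient = q)
}

#' Total migration time for a time-minimizing migrant
#'
#' Total time (fueling plus search/settling) of a migration of distance `D`
#' divided into `n` equal flights:
#' `T(n) = n ( (1/k) (c^2 / (c - D/n)^2 - 1) + te )`.
#'
#' @param n Number of flights (positive integer(s)).
#' @param D Total migration distance, km; must satisfy `D/n < c`.
#' @param k Fuel deposition rate, proportion of lean body mass per day.
#' @param te Search/settling time cost per stopover, days.
#' @param c Flight-range coefficient, km.
#' @return Total migration time, days.
#' @export
#' @examples
#' total_migration_time(1, D = 3000, k = 0.02, te = 1)  # 29.125 days
total_migration_time <- function(n, D, k, te, c = 15000) {
  stopifnot(all(n >= 1), k > 0, te >= 0, c > 0)
  if (any(D / n >= c)) stop("infeasible: flight step D/n must be below c")
  n * ((1 / k) * (c^2 / (c - D / n)^2 - 1) + te)
}

#' Optimal number of flights for a time minimizer
#'
#' Integer minimizer of [total_migration_time()] over `n = 1..n_max`
#' (exhaustive enumeration; ties broken toward fewer flights).
#'
#' @param D Migration distance, km (`D < c`).
#' @param k Fuel deposition rate, per day.
#' @param te Search/settling time cost, days.
#' @param c Flight-range coefficient, km.
#' @param n_max Upper bound of the search (default 50); hitting the bound
#'   raises a warning.
#' @return Optimal integer number of flights.
#' @export
#' @examples
#' optimal_n_time(3000, k = 0.02, te = 1)  # 3 flights
#' optimal_n_time(3000, k = 0.03, te = 1)  # 2 flights
optimal_n_time <- function(D, k, te, c = 15000, n_max = 50) {
  stopifnot(D > 0, D < c)
  n <- seq_len(n_max)
  tt <- total_migration_time(n, D, k, te, c)
  best <- which.min(tt)
  if (best == n_max) {
    warning("optimal n at the search boundary n_max = ", n_max)
  }
  as.integer(best)
}

#' Prediction grid for the energy-minimization model
#'
#' Optimal flight counts over a grid of migration distances and
#' search/settling energy costs.
#'
#' @param f0_grid Energy costs (default 0.005 to 0.1 by 0.005).
#' @param D_grid Distances, km (default 500 to 3500 by 100).
#' @param c Flight-range coefficient, km.
#' @return Object of class `migration_grid` (long-format data.frame with
#'   columns `D_km`, `f0`, `quotient`, `n_star`), model `"energy"`.
#' @export
sweep_energy <- function(f0_grid = seq(0.005, 0.1, by = 0.005),
                         D_grid = seq(500, 3500, by = 100), c = 15000) {
  y_star <- vapply(f0_grid,
                   function(f0) flight_range(optimal_departure_fuel(f0, c), c),
                   numeric(1))
  g <- expand.grid(D_km = D_grid, f0 = f0_grid)
  g$quotient <- g$D_km / y_star[match(g$f0, f0_grid)]
  g$n_star <- as.integer(ceiling(g$quotient))
  structure(g, class = c("migration_grid", "data.frame"), model = "energy",
            c = c)
}

#' Prediction grid for the time-minimization model
#'
#' Optimal flight counts over a grid of migration distances, fuel deposition
#' rates and search/settling time costs.
#'
#' @param k_grid Fuel deposition rates (default 40 values spanning
#'   0.01-0.04 per day).
#' @param te_grid Time costs, days (default 0.1 to 2 by 0.1).
#' @param D_grid Distances, km (default 500 to 3500 by 100).
#' @param c Flight-range coefficient, km.
#' @param n_max Upper bound of the integer search.
#' @return Object of class `migration_grid` (long-format data.frame with
#'   columns `D_km`, `k`, `te_d`, `n_star`), model `"time"`.
#' @export
sweep_time <- function(k_grid = seq(0.01, 0.04, length.out = 40),
                       te_grid = seq(0.1, 2, by = 0.1),
                       D_grid = seq(500, 3500, by = 100), c = 15000,
                       n_max = 50) {
  g <- expand.grid(D_km = D_grid, k = k_grid, te_d = te_grid)
  n <- seq_len(n_max)
  # T(n) factorises: n * ((1/k) * flight_term(D, n) + te)
  tt <- matrix(0, nrow(g), n_max)
  for (j in n) {
    flight_term <- c^2 / (c - g$D_km / j)^2 - 1
    tt[, j] <- j * (flight_term / g$k + g$te_d)
  }
  g$n_star <- as.integer(max.col(-tt, ties.method = "first"))
  if (any(g$n_star == n_max)) {
    warning("some cells reached the search boundary n_max = ", n_max)
  }
  structure(g, class = c("migration_grid", "data.frame"), model = "time",
            c = c)
}

#' @export
print.migration_grid <- function(x, ...) {
  cat(sprintf("%s-minimization prediction grid: %d cells, n* in %d..%d\n",
              attr(x, "model"), nrow(x), min(x$n_star), max(x$n_star)))
  utils::str(as.data.frame(x), give.attr = FALSE)
  invisible(x)
}

#' Heat-map of a prediction grid
#'
#' Optimal flight count against distance and cost parameter. For the time
#' model one `k` slice is shown (nearest grid value to `k`).
#'
#' @param x A `migration_grid`.
#' @param k Fuel deposition rate slice for the time model (default 0.02).
#' @param ... Passed to [graphics::image()].
#' @export
plot.migration_grid <- function(x, k = 0.02, ...) {
  if (attr(x, "model") == "energy") {
    xs <- sort(unique(x$D_km))
    ys <- sort(unique(x$f0))
    z <- matrix(x$n_star[order(x$f0, x$D_km)], length(xs), length(ys))
    graphics::image(xs, ys, z, xlab = "migration distance (km)",
                    ylab = "search/settling energy cost f0",
                    main = "energy minimizer: optimal number of flights", ...)
  } else {
    ks <- sort(unique(x$k))
    ksel <- ks[which.min(abs(ks - k))]
    s <- x[x$k == ksel, ]
    xs <- sort(unique(s$D_km))
    ys <- sort(unique(s$te_d))
    z <- matrix(s$n_star[order(s$te_d, s$D_km)], length(xs), length(ys))
    graphics::image(xs, ys, z, xlab = "migration distance (km)",
                    ylab = "search/settling time cost te (days)",
                    main = sprintf("time minimizer (k = %.3f)", ksel), ...)
  }
  invisible(x)
}
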