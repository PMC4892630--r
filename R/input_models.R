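#' Static Poisson input samples
#'
#' Draws one input value per cell from a Poisson law with mean `u_mean`,
#' emulating static cell-to-cell variability (e.g. plasmid copy number that
#' is constant over a cell's lifetime but differs between cells).
#'
#' @param u_mean Mean input level (> 0).
#' @param n_samples Number of cells (>= 1).
#' @param seed Integer seed; the draw is reproducible bit-for-bit.
#' @return Integer vector of input values.
#' @examples
#' u <- sample_static_poisson_u(10, 1000, seed = 1)
#' mean(u)
#' @export
sample_static_poisson_u <- function(u_mean, n_samples, seed = 1L) {
  stopifnot(u_mean > 0, n_samples >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  stats::rpois(n_samples, u_mean)
}

# save/restore the global RNG state so seeded generators do not perturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a birth-death input trajectory
#'
#' Exact event-driven simulation of a scalar birth-death process with
#' constant birth propensity `birth_rate` and death propensity
#' `death_rate * u`.  At stationarity `u` is Poisson with mean
#' `birth_rate/death_rate` and decorrelates on the timescale
#' `1/death_rate`; this is the dynamic-input regime.
#'
#' @param birth_rate Birth rate (per unit time, > 0).
#' @param death_rate Per-molecule death rate (per unit time, > 0).
#' @param t_final Final time (> 0).
#' @param seed Integer seed.
#' @param u0 Initial value; defaults to the rounded stationary mean.
#' @return An object of class `input_trajectory`: a list with increasing
#'   event times `t` and right-continuous piecewise-constant values `u`.
#' @examples
#' traj <- simulate_birth_death_u(10, 1, t_final = 50, seed = 1)
#' input_time_average(traj, t_min = 25)
#' @export
simulate_birth_death_u <- function(birth_rate, death_rate, t_final,
                                   seed = 1L, u0 = NULL) {
  stopifnot(birth_rate > 0, death_rate > 0, t_final > 0)
  if (is.null(u0)) u0 <- round(birth_rate / death_rate)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  path <- birth_death_path_cpp(u0, birth_rate, death_rate, t_final)
  structure(list(t = path$t, u = path$u, t_final = t_final,
                 birth_rate = birth_rate, death_rate = death_rate),
            class = "input_trajectory")
}

#' Evaluate an input trajectory at arbitrary times
#' @param traj An `input_trajectory`.
#' @param t Times (>= 0).
#' @return The piecewise-constant value of `u` at each `t`.
#' @export
input_at <- function(traj, t) {
  idx <- findInterval(t, traj$t)
  traj$u[pmax(idx, 1)]
}

#' Time average of an input trajectory
#' @param traj An `input_trajectory`.
#' @param t_min Discard times before this (default: second half only).
#' @return Time-averaged value of `u` over `[t_min, t_final]`.
#' @export
input_time_average <- function(traj, t_min = traj$t_final / 2) {
  tt <- c(traj$t[traj$t >= t_min], traj$t_final)
  uu <- traj$u[traj$t >= t_min]
  if (length(uu) == 0) {  # no event after t_min: constant value
    return(input_at(traj, t_min))
  }
  # include the segment straddling t_min
  first <- input_at(traj, t_min)
  tt <- c(t_min, tt)
  uu <- c(first, uu)
  sum(uu * diff(tt)) / (traj$t_final - t_min)
}

#' Export an input trajectory to CSV
#' @param traj An `input_trajectory`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(data.frame(t = traj$t, u = traj$u), path,
                   row.names = FALSE)
  invisible(path)
}
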