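#' Effective-population-size trajectory
#'
#' A piecewise-constant Ne history as produced by sequential coalescent
#' methods: ordered (time before present in years, Ne) points with strictly
#' increasing times; Ne holds from each point's time until the next.
#'
#' @param time_years numeric, strictly increasing, years before present
#' @param ne effective population sizes, > 0
#' @param population population id
#' @param generation_time_years generation time in years (> 0)
#' @return a `ne_trajectory` list
#' @export
ne_trajectory <- function(time_years, ne, population = "pop",
                          generation_time_years = 1) {
  stopifnot(length(time_years) == length(ne), length(ne) >= 2,
            all(diff(time_years) > 0), all(ne > 0),
            generation_time_years > 0)
  structure(list(population = population,
                 generation_time_years = generation_time_years,
                 time_years = as.numeric(time_years), ne = as.numeric(ne),
                 rescale_factor = 1),
            class = "ne_trajectory")
}

#' Read an Ne trajectory from a TSV file (columns time_years, ne)
#' @param path TSV path
#' @param population population id
#' @param generation_time_years generation time in years
#' @return an `ne_trajectory`
#' @export
read_ne_trajectory <- function(path, population = "pop",
                               generation_time_years = 1) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  ne_trajectory(d$time_years, d$ne, population, generation_time_years)
}

#' Write an Ne trajectory as TSV
#' @param traj an `ne_trajectory`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_ne_trajectory <- function(traj, path) {
  utils::write.table(data.frame(time_years = traj$time_years, ne = traj$ne),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rescale a trajectory's generation time
#'
#' Multiplies every time coordinate by `factor` (e.g. 3 to give one
#' population three times the other's generation time, the inbreeding
#' correction for a heavily selfing population); Ne values are unchanged
#' and the cumulative factor is recorded in the trajectory's provenance.
#' Rescaling composes multiplicatively: factors f then g equal one rescale
#' by f*g.
#'
#' @param traj an `ne_trajectory`
#' @param factor positive scale factor
#' @return the rescaled `ne_trajectory`
#' @export
rescale_generation_time <- function(traj, factor) {
  stopifnot(inherits(traj, "ne_trajectory"), factor > 0)
  traj$time_years <- traj$time_years * factor
  traj$generation_time_years <- traj$generation_time_years * factor
  traj$rescale_factor <- traj$rescale_factor * factor
  traj
}

# piecewise-constant evaluation: Ne at time t is the Ne of the most recent
# breakpoint at or before t
.traj_at <- function(traj, t) {
  idx <- findInterval(t, traj$time_years)
  idx[idx < 1] <- 1L
  traj$ne[idx]
}

#' Split time by trajectory matching
#'
#' Formalizes the "matched Ne trajectories" reading of a population split:
#' both trajectories are evaluated (piecewise-constant) on a common time
#' grid over their overlapping range — the union of both trajectories'
#' breakpoints, optionally augmented with log-spaced fill points — and the
#' split time is the most recent grid time tau such that
#' |ln Ne_A(t) - ln Ne_B(t)| <= tol_log for every grid time t >= tau
#' (the populations share one history into the past and diverge below tau).
#'
#' @param traj_a,traj_b `ne_trajectory` objects
#' @param tol_log tolerance on |log Ne_A - log Ne_B|
#' @param n_fill log-spaced grid points added to the breakpoint union
#' @return split time in years, or NA (undefined) when the trajectories
#'   never match into the past or their time ranges do not overlap (a
#'   diagnostic is attached as attribute `reason`)
#' @export
match_split_time <- function(traj_a, traj_b, tol_log = 0.1, n_fill = 0L) {
  lo <- max(min(traj_a$time_years), min(traj_b$time_years))
  hi <- min(max(traj_a$time_years), max(traj_b$time_years))
  if (lo > hi) {
    out <- NA_real_
    attr(out, "reason") <- "non-overlapping time ranges"
    return(out)
  }
  grid <- sort(unique(c(traj_a$time_years, traj_b$time_years)))
  grid <- grid[grid >= lo & grid <= hi]
  if (n_fill > 0)
    grid <- sort(unique(c(grid, exp(seq(log(lo), log(hi),
                                        length.out = n_fill)))))
  agree <- abs(log(.traj_at(traj_a, grid)) - log(.traj_at(traj_b, grid))) <=
    tol_log
  if (!agree[length(agree)]) {
    out <- NA_real_
    attr(out, "reason") <- "trajectories differ at the oldest grid time"
    return(out)
  }
  # smallest grid time from which agreement holds all the way into the past
  disagree <- which(!agree)
  if (!length(disagree)) return(grid[1])
  grid[max(disagree) + 1L]
}
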