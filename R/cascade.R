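# Closed-form and Monte Carlo solutions of the two-step serial cascade
# first -> middle -> last that generates the band-power template pattern.

#' Closed-form occupancy within one phase of the cascade
#'
#' Solves the linear serial-decay chain first -> middle -> last with rates
#' \code{pFirst} and \code{pSecond} from arbitrary initial occupancy. In a
#' towards phase the roles (first, middle, last) are (beta, sigma, delta); in
#' an away phase they are (delta, sigma, beta). The population is closed: the
#' three components always sum to the initial total.
#'
#' The middle-mode solution uses a difference of exponentials whose
#' denominator vanishes as the two rates coincide; the default rates sit very
#' close to that singularity, so the difference is evaluated with
#' \code{expm1} and the exact equal-rate limit
#' \eqn{N_2(t) = (N_2(0) + N_1(0) p t) e^{-pt}} is substituted when the rates
#' are numerically indistinguishable.
#'
#' @param occ0 Numeric length 3: initial occupancy in role order
#'   (first, middle, last); all non-negative.
#' @param pFirst Rate of the first -> middle transition (> 0), per unit time.
#' @param pSecond Rate of the middle -> last transition (> 0), per unit time.
#' @param t Non-negative time(s) since phase start, in the same unit (1\% of
#'   episode duration in this package's core).
#' @return A numeric matrix with one row per time point and columns
#'   \code{first}, \code{middle}, \code{last}.
#' @examples
#' phaseOccupancy(c(1, 0, 0), 0.13, 0.131, 10)
#' @export
phaseOccupancy <- function(occ0, pFirst, pSecond, t) {
  occ0 <- as.numeric(occ0)
  if (length(occ0) != 3L || any(!is.finite(occ0)) || any(occ0 < 0))
    stop("occ0 must be three non-negative finite values (first, middle, last)")
  if (!is.finite(pFirst) || !is.finite(pSecond) || pFirst <= 0 || pSecond <= 0)
    stop("rates must be positive")
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be non-negative")
  total <- sum(occ0)
  e1 <- exp(-pFirst * t)
  n1 <- occ0[1] * e1
  if (abs(pSecond - pFirst) < 1e-9 * pFirst) {
    # equal-rate limit of the serial chain
    n2 <- (occ0[2] + occ0[1] * pFirst * t) * exp(-pFirst * t)
  } else {
    # e^(-p1 t) - e^(-p2 t) = -e^(-p1 t) * expm1(-(p2 - p1) t), stable for
    # nearly equal rates
    dexp <- -e1 * expm1(-(pSecond - pFirst) * t)
    n2 <- occ0[2] * exp(-pSecond * t) + occ0[1] * pFirst / (pSecond - pFirst) * dexp
  }
  n3 <- total - n1 - n2
  cbind(first = n1, middle = n2, last = pmax(n3, 0))
}

#' Time of the middle-mode (sigma) maximum within a phase
#'
#' The middle mode is fed by the first mode and drained into the last, so it
#' passes through an interior maximum when inflow equals outflow — the sigma
#' peak occurring while delta is still rising in a towards phase. For a pure
#' first-mode start the maximum is at
#' \eqn{\ln(p_2/p_1)/(p_2 - p_1)}; for general initial occupancy the root of
#' \eqn{p_1 N_1(t) = p_2 N_2(t)} is located numerically.
#'
#' @inheritParams phaseOccupancy
#' @return The interior peak time, or \code{NA} when the middle mode is
#'   maximal at phase start (no source, or outflow already dominating).
#' @examples
#' sigmaPeakTime(c(1, 0, 0), 0.2, 0.6)   # log(3)/0.4
#' @export
sigmaPeakTime <- function(occ0, pFirst, pSecond) {
  occ0 <- as.numeric(occ0)
  if (length(occ0) != 3L || any(!is.finite(occ0)) || any(occ0 < 0))
    stop("occ0 must be three non-negative finite values")
  if (pFirst <= 0 || pSecond <= 0) stop("rates must be positive")
  # dN2/dt at time t, up to sign: inflow minus outflow
  g <- function(t) {
    occ <- phaseOccupancy(occ0, pFirst, pSecond, t)
    pFirst * occ[, "first"] - pSecond * occ[, "middle"]
  }
  if (g(0) <= 0) return(NA_real_)
  if (occ0[2] == 0 && occ0[3] == 0) {
    if (abs(pSecond - pFirst) < 1e-9 * pFirst) return(1 / pFirst)
    return(log(pSecond / pFirst) / (pSecond - pFirst))
  }
  hi <- 1 / min(pFirst, pSecond)
  while (g(hi) > 0) hi <- hi * 2
  stats::uniroot(g, c(0, hi), tol = 1e-12)$root
}

.phaseRates <- function(probs, phase) {
  p <- probVector(probs)
  if (phase == "towards") c(p[["betaSigma"]], p[["sigmaDelta"]])
  else c(p[["deltaSigma"]], p[["sigmaBeta"]])
}

# map band-named occupancy (beta, sigma, delta) to role order for the phase
.toRoles <- function(occ, phase) {
  if (phase == "towards") c(occ[["beta"]], occ[["sigma"]], occ[["delta"]])
  else c(occ[["delta"]], occ[["sigma"]], occ[["beta"]])
}

.fromRoles <- function(m, phase) {
  if (phase == "towards")
    cbind(beta = m[, "first"], sigma = m[, "middle"], delta = m[, "last"])
  else
    cbind(beta = m[, "last"], sigma = m[, "middle"], delta = m[, "first"])
}

#' Simulate the mode-occupancy trajectory of a whole episode
#'
#' Chains the closed-form phase solution across the towards/away phases of
#' the model's plan, taking the starting occupancy of each phase equal to the
#' end values of the preceding phase, so the trajectory is continuous at
#' every switchover.
#'
#' @param model An \linkS4class{EpisodeModel}.
#' @param grid Sorted time points in [0, 100] (percent of episode duration)
#'   at which to evaluate; default the centres of the 50 standard 2\% bins.
#' @return A \linkS4class{ModeOccupancy} over \code{grid}.
#' @examples
#' traj <- simulateEpisode(episodeModel(plan = phasePlan(c(40, 70))))
#' @export
simulateEpisode <- function(model, grid = seq(1, 99, by = 2)) {
  stopifnot(is(model, "EpisodeModel"))
  grid <- as.numeric(grid)
  if (any(grid < 0) || any(grid > 100)) stop("grid must lie within [0, 100]")
  if (is.unsorted(grid)) stop("grid must be sorted")
  iv <- phaseIntervals(model@plan)
  occ <- model@initialOccupancy  # named beta, sigma, delta
  out <- matrix(NA_real_, length(grid), 3,
                dimnames = list(NULL, c("beta", "sigma", "delta")))
  for (i in seq_len(nrow(iv))) {
    phase <- iv$phase[i]
    rates <- .phaseRates(model@probabilities, phase)
    roles0 <- .toRoles(occ, phase)
    # right-closed at episode end so grid point 100 is covered
    sel <- grid >= iv$start[i] & (grid < iv$end[i] | i == nrow(iv) & grid <= iv$end[i])
    if (any(sel)) {
      m <- phaseOccupancy(roles0, rates[1], rates[2], grid[sel] - iv$start[i])
      out[sel, ] <- .fromRoles(m, phase)
    }
    endm <- phaseOccupancy(roles0, rates[1], rates[2], iv$end[i] - iv$start[i])
    endocc <- .fromRoles(endm, phase)
    occ <- c(beta = endocc[1, "beta"], sigma = endocc[1, "sigma"],
             delta = endocc[1, "delta"])
  }
  modeOccupancy(beta = out[, "beta"], sigma = out[, "sigma"],
                delta = out[, "delta"], time = grid)
}

#' Map a mode-occupancy trajectory to EEG band power
#'
#' Each band's power is its mode occupancy times the band's normalisation
#' factor (uV^2 per unit occupancy); the constant background beta component
#' is added to the beta band only.
#'
#' @param traj A \linkS4class{ModeOccupancy} on an equally spaced grid.
#' @param bandScales Named numeric (delta, sigma, beta), all > 0.
#' @param betaBias Constant background beta power in uV^2 (>= 0).
#' @return A \linkS4class{PowerTimeCourse} on the trajectory's grid.
#' @export
occupancyToPower <- function(traj, bandScales = c(delta = 1, sigma = 1, beta = 1),
                             betaBias = 0) {
  stopifnot(is(traj, "ModeOccupancy"))
  bs <- as.numeric(bandScales); names(bs) <- names(bandScales)
  if (is.null(names(bandScales))) names(bs) <- BAND_ORDER
  if (any(bs <= 0)) stop("bandScales must be positive")
  if (betaBias < 0) stop("betaBias must be non-negative")
  powerTimeCourse(time = traj@time,
                  delta = bs[["delta"]] * traj@delta,
                  sigma = bs[["sigma"]] * traj@sigma,
                  beta = bs[["beta"]] * traj@beta + betaBias)
}

#' Evaluate an episode model as band power on a grid
#'
#' Convenience composition of [simulateEpisode()] and [occupancyToPower()]
#' using the model's own scales and beta bias.
#'
#' @inheritParams simulateEpisode
#' @return A \linkS4class{PowerTimeCourse}.
#' @export
predictPower <- function(model, grid = seq(1, 99, by = 2)) {
  occupancyToPower(simulateEpisode(model, grid), model@bandScales,
                   model@betaBias)
}

#' Monte Carlo simulation of one cascade phase
#'
#' Simulates the stochastic counterpart of [phaseOccupancy()]: a fixed
#' population of neurons, each independently subject at every time step of
#' length \code{dt} to a first -> middle transition with probability
#' \code{pFirst * dt} and a middle -> last transition with probability
#' \code{pSecond * dt}. Individual transitions are instantaneous on the time
#' scale of the phase; the total count is conserved exactly.
#'
#' @param counts0 Integer length 3: initial neuron counts in role order
#'   (first, middle, last).
#' @param pFirst,pSecond Transition rates per unit time (> 0).
#' @param dt Time step; \code{pFirst * dt} and \code{pSecond * dt} must be
#'   < 1 (default 0.01).
#' @param tEnd End time of the phase.
#' @param seed Integer seed; runs are bit-reproducible.
#' @return A data.frame with columns \code{time}, \code{first},
#'   \code{middle}, \code{last} (integer counts at each step).
#' @examples
#' mc <- monteCarloPhase(c(1000, 0, 0), 0.13, 0.131, tEnd = 20, seed = 1)
#' @export
monteCarloPhase <- function(counts0, pFirst, pSecond, dt = 0.01, tEnd, seed) {
  counts0 <- as.integer(round(counts0))
  if (length(counts0) != 3L || any(counts0 < 0))
    stop("counts0 must be three non-negative integers")
  if (pFirst < 0 || pSecond < 0) stop("rates must be non-negative")
  if (pFirst * dt >= 1 || pSecond * dt >= 1)
    stop("p * dt must be < 1; decrease dt")
  nstep <- as.integer(round(tEnd / dt))
  out <- matrix(0L, nstep + 1L, 3L,
                dimnames = list(NULL, c("first", "middle", "last")))
  out[1L, ] <- counts0
  n <- counts0
  withSeed(seed, {
    for (s in seq_len(nstep)) {
      move12 <- stats::rbinom(1L, n[1], pFirst * dt)
      move23 <- stats::rbinom(1L, n[2], pSecond * dt)
      n <- c(n[1] - move12, n[2] + move12 - move23, n[3] + move23)
      out[s + 1L, ] <- n
    }
  })
  data.frame(time = seq(0, by = dt, length.out = nstep + 1L),
             first = out[, 1], middle = out[, 2], last = out[, 3])
}

#' Export an occupancy or power trajectory as delimited text
#'
#' @param x A \linkS4class{ModeOccupancy} or \linkS4class{PowerTimeCourse}.
#' @param path Output file path (tab-separated, header line first).
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(x, path) {
  df <- if (is(x, "ModeOccupancy")) {
    stats::setNames(occupancyFrame(x), c("time_pct", "n_beta", "n_sigma", "n_delta"))
  } else if (is(x, "PowerTimeCourse")) {
    data.frame(time_pct = x@time, delta = x@power[, "delta"],
               sigma = x@power[, "sigma"], beta = x@power[, "beta"])
  } else stop("x must be a ModeOccupancy or PowerTimeCourse")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
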