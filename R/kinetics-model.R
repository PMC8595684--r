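# Phenomenological activity kinetics for the synthetic scene generator.
#
# Per-pixel activity A follows a receptor-driven production term opposed by
# basal decay plus two activity-driven feedback pools with fast and slow
# kinetics:
#
#   dA/dt  = k_in * u(t) * g(x) - (k_off + k1*F1 + k2*F2) * A
#   dFi/dt = ai * A - di * Fi                    (i = 1 fast, i = 2 slow)
#
# g(x) = exp(-dist(x, target)^2 / (2 * spread_length^2)) for focal stimuli
# and g = 1 for global stimuli. The receptor drive u(t) is a constant basal
# input plus, for each light pulse, a term power * exp(-(t - t_pulse)/tau_r)
# for t >= t_pulse: the bistable receptor stays active after a pulse and is
# progressively switched off by the longer-wavelength imaging light. This
# is a deliberately phenomenological stand-in for multi-level negative
# regulation; no mechanistic biochemistry is modeled.

#' Kinetics parameters for the synthetic activity model
#'
#' Defaults were tuned once, on the ODE alone, to reproduce the qualitative
#' response features of the assay class being emulated: a single-pulse
#' response peaking well under 20 s, a post-stimulus undershoot near 25 s,
#' and recovery to baseline on the order of 2 min.
#'
#' @param k_in activation gain per unit stimulus (1/s per stimulus unit).
#' @param k_off basal decay rate (1/s).
#' @param a1,d1,k1 fast feedback pool: production from A, decay, strength.
#' @param a2,d2,k2 slow feedback pool.
#' @param spread_length spatial response length scale for focal stimuli
#'   (micron).
#' @param receptor_tau receptor inactivation time constant under imaging
#'   light (s).
#' @param receptor_tau_on receptor activation/transmission rise time (s).
#' @param basal_input constant basal receptor drive (stimulus units);
#'   gives a nonzero resting activity so post-stimulus undershoot is
#'   expressible.
#' @return list of class `fret_kinetics`.
#' @export
kinetics_params <- function(k_in = 0.25, k_off = 0.10,
                            a1 = 0.20, d1 = 0.12, k1 = 3.0,
                            a2 = 0.03, d2 = 0.022, k2 = 6.0,
                            spread_length = 2.5,
                            receptor_tau = 6, receptor_tau_on = 2,
                            basal_input = 0.35) {
  p <- list(k_in = k_in, k_off = k_off, a1 = a1, d1 = d1, k1 = k1,
            a2 = a2, d2 = d2, k2 = k2, spread_length = spread_length,
            receptor_tau = receptor_tau, receptor_tau_on = receptor_tau_on,
            basal_input = basal_input)
  if (any(unlist(p) < 0)) stop("all kinetic rates must be >= 0")
  if (spread_length <= 0) stop("spread_length must be > 0")
  class(p) <- "fret_kinetics"
  p
}

#' A stimulus event
#'
#' @param time stimulus time (s), within the imaging interval.
#' @param kind "global" (whole field) or "focal" (targeted pulse).
#' @param power relative stimulus strength (arbitrary units; focal powers
#'   may be given in microwatt and scaled against a calibration power
#'   downstream).
#' @param target for focal events, 0-based pixel coordinate c(x, y).
#' @param duration pulse duration (s); kinetics treat pulses as brief
#'   relative to the frame interval.
#' @return list of class `fret_stimulus`.
#' @export
stimulus_event <- function(time, kind = c("global", "focal"), power = 1,
                           target = NULL, duration = 0.010) {
  kind <- match.arg(kind)
  if (kind == "focal" && (is.null(target) || length(target) != 2))
    stop("focal stimulus events require a target pixel c(x, y)")
  structure(list(time = time, kind = kind, power = power,
                 target = target, duration = duration),
            class = "fret_stimulus")
}

# Receptor drive u(t) at (vector) times for a list of stimuli affecting a
# given spatial weight; returns total drive per time (excluding g(x)).
# Each pulse contributes a difference-of-exponentials response (finite
# activation time receptor_tau_on, inactivation by the imaging light with
# time constant receptor_tau), normalized to peak at `power`.
.receptor_drive <- function(t, stimuli, kin) {
  u <- rep(kin$basal_input, length(t))
  tr <- kin$receptor_tau; ton <- kin$receptor_tau_on
  if (ton >= tr) ton <- 0.99 * tr
  tstar <- tr * ton / (tr - ton) * log(tr / ton)
  norm <- exp(-tstar / tr) - exp(-tstar / ton)
  for (s in stimuli) {
    on <- t >= s$time
    dt <- t[on] - s$time
    u[on] <- u[on] + s$power * (exp(-dt / tr) - exp(-dt / ton)) / norm
  }
  u
}

#' Resting steady state of the activity model
#'
#' Solves the fixed point under the basal drive alone (used to initialize
#' scenes at equilibrium).
#'
#' @param kin `fret_kinetics`.
#' @return list with `A`, `F1`, `F2`.
#' @export
kinetics_steady_state <- function(kin) {
  u0 <- kin$basal_input
  f <- function(A) {
    F1 <- kin$a1 * A / max(kin$d1, 1e-12)
    F2 <- kin$a2 * A / max(kin$d2, 1e-12)
    kin$k_in * u0 - (kin$k_off + kin$k1 * F1 + kin$k2 * F2) * A
  }
  if (u0 == 0 || kin$k_in == 0) return(list(A = 0, F1 = 0, F2 = 0))
  A <- stats::uniroot(f, c(0, 1e3), tol = 1e-14)$root
  list(A = A, F1 = kin$a1 * A / max(kin$d1, 1e-12),
       F2 = kin$a2 * A / max(kin$d2, 1e-12))
}

#' Integrate the activity model
#'
#' Fixed-step RK4 over a fine sub-grid of the frame interval, vectorized
#' over pixels (one spatial weight g per pixel). Substep boundaries are
#' aligned with the frame grid; stimulus onsets are snapped to the nearest
#' substep.
#'
#' @param kin `fret_kinetics`.
#' @param stimuli list of `fret_stimulus` (their spatial component must
#'   already be folded into `g`; pass the stimuli relevant to this cell).
#' @param times frame times (s), uniformly spaced from 0.
#' @param g spatial weight per pixel (vector, values in [0, 1]).
#' @param A0,F10,F20 initial state (scalars or per-pixel vectors); default
#'   is the basal steady state.
#' @param n_sub substeps per frame interval (default 30).
#' @return list with matrices `A`, `F1`, `F2` of dim (pixels, frames);
#'   `A` is clipped to [0, 1].
#' @export
integrate_activity <- function(kin, stimuli, times, g = 1,
                               A0 = NULL, F10 = NULL, F20 = NULL,
                               n_sub = 30L) {
  np <- length(g)
  ss <- kinetics_steady_state(kin)
  A <- rep(if (is.null(A0)) ss$A else A0, length.out = np)
  F1 <- rep(if (is.null(F10)) ss$F1 else F10, length.out = np)
  F2 <- rep(if (is.null(F20)) ss$F2 else F20, length.out = np)
  nt <- length(times)
  outA <- matrix(0, np, nt); outF1 <- matrix(0, np, nt); outF2 <- matrix(0, np, nt)
  outA[, 1] <- A; outF1[, 1] <- F1; outF2[, 1] <- F2
  if (nt == 1)
    return(list(A = pmin(pmax(outA, 0), 1), F1 = outF1, F2 = outF2))
  dt_frame <- times[2] - times[1]
  h <- dt_frame / n_sub
  # snap stimulus times to the substep grid
  stimuli <- lapply(stimuli, function(s) {
    s$time <- round(s$time / h) * h
    s
  })
  deriv <- function(t, A, F1, F2) {
    u <- .receptor_drive(t, stimuli, kin)
    dA <- kin$k_in * u * g - (kin$k_off + kin$k1 * F1 + kin$k2 * F2) * A
    list(dA = dA,
         dF1 = kin$a1 * A - kin$d1 * F1,
         dF2 = kin$a2 * A - kin$d2 * F2)
  }
  for (fr in 2:nt) {
    t0 <- times[fr - 1]
    for (k in seq_len(n_sub)) {
      t <- t0 + (k - 1) * h
      k1v <- deriv(t, A, F1, F2)
      k2v <- deriv(t + h / 2, A + h / 2 * k1v$dA, F1 + h / 2 * k1v$dF1,
                   F2 + h / 2 * k1v$dF2)
      k3v <- deriv(t + h / 2, A + h / 2 * k2v$dA, F1 + h / 2 * k2v$dF1,
                   F2 + h / 2 * k2v$dF2)
      k4v <- deriv(t + h, A + h * k3v$dA, F1 + h * k3v$dF1,
                   F2 + h * k3v$dF2)
      A <- A + h / 6 * (k1v$dA + 2 * k2v$dA + 2 * k3v$dA + k4v$dA)
      F1 <- F1 + h / 6 * (k1v$dF1 + 2 * k2v$dF1 + 2 * k3v$dF1 + k4v$dF1)
      F2 <- F2 + h / 6 * (k1v$dF2 + 2 * k2v$dF2 + 2 * k3v$dF2 + k4v$dF2)
      A <- pmax(A, 0)
    }
    outA[, fr] <- A; outF1[, fr] <- F1; outF2[, fr] <- F2
  }
  list(A = pmin(pmax(outA, 0), 1), F1 = outF1, F2 = outF2)
}
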