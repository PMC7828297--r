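# Linear Kalman filter over the 8-component bounding-box state
#   x = (u, v, s, r, du, dv, ds, dr)
# where (u, v) is the box center, s the area, r the width/height aspect
# ratio, and the last four components are per-frame rates of change. The
# transition model is discrete constant velocity with dt = 1 frame on all
# four measured components; the aspect ratio is a time-varying state, not a
# constant, so leaf motion that reshapes the box is tracked rather than
# fought. The measurement observes (u, v, s, r) only.

STATE_DIM <- 8L
MEAS_DIM <- 4L

kf_transition_matrix <- function() {
  F <- diag(STATE_DIM)
  F[cbind(1:4, 5:8)] <- 1
  F
}

kf_observation_matrix <- function() {
  H <- matrix(0, MEAS_DIM, STATE_DIM)
  H[cbind(1:4, 1:4)] <- 1
  H
}

#' Tracking and counting configuration
#'
#' The state-space model is fixed (constant velocity, dt = 1 frame); its
#' noise levels and the association/lifecycle parameters are tunable here.
#' Units: `u`, `v` in px, `s` in px^2, `r` dimensionless.
#'
#' @param iou_threshold Minimum IoU for a predicted track and a detection to
#'   remain associated after optimal assignment; pairs below the gate are
#'   demoted to unmatched on both sides. Default 0.3.
#' @param max_age Number of consecutive unmatched frames a track survives
#'   (coasting on prediction alone) before deletion. Default 2, the value
#'   found best for corn seedling counting.
#' @param process_noise_pos Per-frame process variance added to each of the
#'   four measured components (state units squared). Default 1.
#' @param process_noise_rate Per-frame process variance added to each rate
#'   component. Default 0.01.
#' @param meas_noise Length-4 measurement variance for `(u, v, s, r)`.
#'   Default `c(1, 1, 10, 0.01)`.
#' @param init_rate_var_mult Multiplier applied to the measured-component
#'   prior variances to initialize the (unobserved) rate variances of a new
#'   track; large so the first few updates determine the velocity. Default
#'   1000.
#' @return A list of class `stand_config`.
#' @export
stand_config <- function(iou_threshold = 0.3,
                         max_age = 2L,
                         process_noise_pos = 1.0,
                         process_noise_rate = 0.01,
                         meas_noise = c(1, 1, 10, 0.01),
                         init_rate_var_mult = 1000) {
  stopifnot(iou_threshold >= 0, iou_threshold <= 1,
            max_age >= 0, length(meas_noise) == 4L, all(meas_noise >= 0),
            process_noise_pos >= 0, process_noise_rate >= 0,
            init_rate_var_mult > 0)
  structure(list(
    iou_threshold = iou_threshold,
    max_age = as.integer(max_age),
    process_noise_pos = process_noise_pos,
    process_noise_rate = process_noise_rate,
    meas_noise = as.numeric(meas_noise),
    init_rate_var_mult = init_rate_var_mult
  ), class = "stand_config")
}

config_Q <- function(config) {
  diag(c(rep(config$process_noise_pos, 4L),
         rep(config$process_noise_rate, 4L)))
}

config_R <- function(config) diag(config$meas_noise, MEAS_DIM)

config_P0 <- function(config) {
  pos_var <- pmax(config$meas_noise, 1e-6) * 10
  diag(c(pos_var, pos_var * config$init_rate_var_mult))
}

symmetrize <- function(P) (P + t(P)) / 2

#' Kalman time update (predict)
#'
#' Projects state and covariance one frame forward under the
#' constant-velocity model: positions advance by their rates, rates stay,
#' covariance is propagated and inflated by the process noise.
#'
#' @param state Length-8 state vector.
#' @param cov 8x8 state covariance.
#' @param process_noise 8x8 process-noise covariance `Q`.
#' @return List with elements `state` and `cov` (symmetric PSD).
#' @export
kf_predict <- function(state, cov, process_noise) {
  F <- kf_transition_matrix()
  state_new <- as.numeric(F %*% state)
  cov_new <- symmetrize(F %*% cov %*% t(F) + process_noise)
  list(state = state_new, cov = cov_new)
}

#' Kalman measurement update
#'
#' Standard linear update with the Joseph-form covariance so the posterior
#' stays symmetric positive semidefinite even at extreme gains. The
#' posterior state is a gain-weighted combination of the prior prediction
#' and the new measurement.
#'
#' @param state Length-8 prior state.
#' @param cov 8x8 prior covariance.
#' @param z Length-4 measurement `(u, v, s, r)`.
#' @param measurement_noise 4x4 measurement-noise covariance `R`.
#' @return List with `state`, `cov`.
#' @export
kf_update <- function(state, cov, z, measurement_noise) {
  H <- kf_observation_matrix()
  innov <- as.numeric(z) - as.numeric(H %*% state)
  S <- H %*% cov %*% t(H) + measurement_noise
  S <- symmetrize(S)
  K <- tryCatch(t(solve(S, H %*% cov)),
                error = function(e)
                  stop("singular innovation covariance in Kalman update",
                       call. = FALSE))
  state_new <- as.numeric(state + K %*% innov)
  IKH <- diag(STATE_DIM) - K %*% H
  cov_new <- symmetrize(IKH %*% cov %*% t(IKH) +
                          K %*% measurement_noise %*% t(K))
  list(state = state_new, cov = cov_new)
}

# Predicted box from a state vector; s and r can transiently go
# non-positive when prediction overshoots, so clamp to a small epsilon for
# the geometry only (the filter state itself is left untouched).
state_to_box <- function(state) {
  s <- max(state[[3L]], 1e-6)
  r <- max(state[[4L]], 1e-6)
  measurement_to_box(c(state[[1L]], state[[2L]], s, r))
}
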