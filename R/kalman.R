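#' Class-augmented constant-velocity Kalman filter
#'
#' Each track carries a linear-Gaussian state over the 7-vector
#' `(u, v, s, r, du, dv, ds)`: box center, aspect ratio, height, and the
#' rates of change of the first three. The height `r` has no rate term and
#' is propagated as constant. The class label is the eighth, non-dynamical
#' state component: a categorical cannot participate in the Gaussian, so
#' it is carried as an immutable side label with no noise and no dynamics,
#' and is used upstream to gate association by category.
#'
#' Noise magnitudes follow the ByteTrack convention: standard deviations
#' proportional to the box height, with weights
#' `std_weight_position` and `std_weight_velocity` from
#' [tracker_config()]. The time step is fixed at one frame.
#'
#' @name kalman
NULL

.kf_F <- local({
  F <- diag(7)
  F[1, 5] <- 1; F[2, 6] <- 1; F[3, 7] <- 1
  F
})
.kf_H <- cbind(diag(4), matrix(0, 4, 3))

# Box height implied by the state mean, per convention.
.kf_height <- function(mean, convention) {
  if (convention == "paper") max(mean[4], 1e-6)
  else max(sqrt(max(mean[3], 1e-12) / max(mean[4], 1e-12)), 1e-6)
}

# Per-slot standard deviations. Slot "a" is the dimensionless aspect slot
# (s under the paper convention, r under sort); slot "d" the dimensional
# one (height, or area which scales as height squared).
.kf_stds <- function(h, cfg) {
  wp <- cfg$std_weight_position
  wv <- cfg$std_weight_velocity
  if (cfg$state_convention == "paper") {
    # slots: u v s(aspect) r(height) | du dv ds
    list(init = c(2 * wp * h, 2 * wp * h, 1e-2, 2 * wp * h,
                  10 * wv * h, 10 * wv * h, 1e-5),
         q = c(wp * h, wp * h, 1e-2, wp * h, wv * h, wv * h, 1e-5),
         r = c(wp * h, wp * h, 1e-1, wp * h))
  } else {
    # slots: u v s(area) r(aspect) | du dv ds
    list(init = c(2 * wp * h, 2 * wp * h, 2 * wp * h^2, 1e-2,
                  10 * wv * h, 10 * wv * h, 10 * wv * h^2),
         q = c(wp * h, wp * h, wp * h^2, 1e-2, wv * h, wv * h, wv * h^2),
         r = c(wp * h, wp * h, wp * h^2, 1e-1))
  }
}

.kf_check_psd <- function(P, tol = 1e-6) {
  if (any(abs(P - t(P)) > 1e-6 * (1 + max(abs(P))))) {
    stop("covariance is not symmetric", call. = FALSE)
  }
  # Cholesky of P + tol*I: cheap PSD certificate for the 7x7 hot path
  ridge <- tol * max(1, max(abs(P)))
  ok <- tryCatch({ chol(P + diag(ridge, nrow(P))); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("covariance is not positive semi-definite", call. = FALSE)
  invisible(P)
}

#' Initialise a Kalman state from a detection
#'
#' Positions come from the detection box's observation form; all velocity
#' components start at zero with inflated variance. The class label is
#' fixed for the lifetime of the state.
#'
#' @param det One-row data frame with box columns and `class`.
#' @param config A [tracker_config()].
#' @return A `kalman_state`: list with `mean` (7-vector), `cov` (7x7),
#'   `class`.
#' @export
kf_init <- function(det, config = tracker_config()) {
  obs <- box_to_observation(det, convention = config$state_convention)
  .kf_init_z(c(obs$u[1], obs$v[1], obs$s[1], obs$r[1]), det$class[1], config)
}

# z = (u, v, s, r) numeric; hot-path entry avoiding data-frame overhead
.kf_init_z <- function(z, class, config) {
  mean <- c(z, 0, 0, 0)
  h <- .kf_height(mean, config$state_convention)
  std <- .kf_stds(h, config)$init
  structure(list(mean = mean, cov = diag(std^2), class = class),
            class = "kalman_state")
}

#' Propagate a Kalman state one frame forward
#'
#' Constant-velocity transition: `u += du`, `v += dv`, `s += ds`, `r`
#' unchanged; covariance goes through `F P F' + Q`. The class label is
#' untouched.
#'
#' @param state A `kalman_state`.
#' @param config A [tracker_config()].
#' @return The predicted `kalman_state`.
#' @export
kf_predict <- function(state, config = tracker_config()) {
  .kf_check_psd(state$cov)
  h <- .kf_height(state$mean, config$state_convention)
  q <- .kf_stds(h, config)$q
  mean <- as.vector(.kf_F %*% state$mean)
  cov <- .kf_F %*% state$cov %*% t(.kf_F) + diag(q^2)
  structure(list(mean = mean, cov = (cov + t(cov)) / 2, class = state$class),
            class = "kalman_state")
}

#' Correct a Kalman state against an observed detection
#'
#' Standard Kalman update against the `(u, v, s, r)` observation of the
#' detection box, in Joseph form so the posterior covariance stays
#' symmetric positive semi-definite. Class gating happens upstream: a
#' class mismatch here is an internal-consistency error, not a data
#' condition.
#'
#' @param state A predicted `kalman_state`.
#' @param det One-row data frame with box columns and `class`.
#' @param config A [tracker_config()].
#' @return The corrected `kalman_state`.
#' @export
kf_correct <- function(state, det, config = tracker_config()) {
  obs <- box_to_observation(det, convention = config$state_convention)
  .kf_correct_z(state, c(obs$u[1], obs$v[1], obs$s[1], obs$r[1]),
                det$class[1], config)
}

.kf_correct_z <- function(state, z, class, config) {
  if (!identical(class, state$class)) {
    stop("internal error: class-gated association delivered a '",
         class, "' detection to a '", state$class, "' track",
         call. = FALSE)
  }
  h <- .kf_height(state$mean, config$state_convention)
  rstd <- .kf_stds(h, config)$r
  R <- diag(rstd^2)
  H <- .kf_H
  P <- state$cov
  S <- H %*% P %*% t(H) + R
  K <- t(solve(S, H %*% P))       # P H' S^-1
  mean <- state$mean + as.vector(K %*% (z - H %*% state$mean))
  IKH <- diag(7) - K %*% H
  cov <- IKH %*% P %*% t(IKH) + K %*% R %*% t(K)
  # scale slots must stay positive for the box to remain valid
  mean[3] <- max(mean[3], 1e-6)
  mean[4] <- max(mean[4], 1e-6)
  structure(list(mean = mean, cov = (cov + t(cov)) / 2, class = state$class),
            class = "kalman_state")
}

#' Box implied by a Kalman state mean
#'
#' @param state A `kalman_state`.
#' @param config A [tracker_config()] (sets the state convention).
#' @return One-row tibble in corner form.
#' @export
kf_box <- function(state, config = tracker_config()) {
  obs <- tibble::tibble(u = state$mean[1], v = state$mean[2],
                        s = max(state$mean[3], 1e-6),
                        r = max(state$mean[4], 1e-6))
  box_from_observation(obs, convention = config$state_convention)
}
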