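#' Leaky integrate-and-fire neuron parameters
#'
#' Bundles the three constants that define one population of leaky
#' integrate-and-fire (LIF) neurons: the membrane time constant `tau`, the
#' reset (and initial) potential `u_res`, and the spiking threshold `theta`.
#' The derived bias `b = u_res - theta` is stored alongside; it is the bias
#' term of the equivalent rectified-linear unit.
#'
#' @param tau Membrane time constant, in arbitrary time units; must be > 0.
#' @param u_res Reset potential, also the initial potential at `t = 0`.
#' @param theta Spiking threshold.
#'
#' @return An object of class `lif_params`: a list with elements `tau`,
#'   `u_res`, `theta`, and `b`.
#'
#' @examples
#' p <- lif_params(tau = 20, u_res = 0, theta = 1)
#' p$b # -1
#' @export
lif_params <- function(tau = 20, u_res = 0, theta = 1) {
  stop_if_not_scalar(tau, "tau", positive = TRUE)
  stop_if_not_scalar(u_res, "u_res")
  stop_if_not_scalar(theta, "theta")
  structure(
    list(tau = tau, u_res = u_res, theta = theta, b = u_res - theta),
    class = "lif_params"
  )
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf(
    "<lif_params> tau = %g, u_res = %g, theta = %g (b = %g)\n",
    x$tau, x$u_res, x$theta, x$b
  ))
  invisible(x)
}

#' Membrane potential of a LIF neuron under constant drive
#'
#' For a static input image the weighted input sum `v_in` is constant over
#' time, so the membrane equation
#' \deqn{\tau \, du/dt = -(u - u_{res}) + v_{in}, \qquad u(0) = u_{res}}
#' has the closed-form solution
#' \deqn{u(t) = -v_{in} e^{-t/\tau} + u_{res} + v_{in}.}
#'
#' @param v_in Constant total input drive (weighted sum of inputs). May be a
#'   vector.
#' @param t Time(s) at which to evaluate the potential; must be >= 0.
#' @param params A [lif_params()] object.
#'
#' @return Membrane potential value(s), vectorized over `v_in` and `t`.
#' @seealso [analytic_first_spike()], [simulate_first_spike()]
#' @export
membrane_potential <- function(v_in, t, params) {
  stopifnot(inherits(params, "lif_params"))
  if (any(!is.finite(v_in))) stop("`v_in` must be finite")
  if (any(t < 0)) stop("`t` must be >= 0")
  -v_in * exp(-t / params$tau) + params$u_res + v_in
}

#' Closed-form first spike time of a LIF neuron
#'
#' Solves `u(t) = theta` for the membrane trajectory of
#' [membrane_potential()]. A spike exists iff `b + v_in > 0` with
#' `b = u_res - theta`; in that case
#' \deqn{t_s = -\tau \log\left(1 + \frac{u_{res} - \theta}{v_{in}}\right),}
#' which decreases monotonically in `v_in`: a stronger drive spikes earlier.
#' This intensity-to-latency map is the basis of rank order coding.
#'
#' @param v_in Constant input drive(s).
#' @param params A [lif_params()] object.
#'
#' @return First spike time(s); `NA` where the neuron never spikes
#'   (`b + v_in <= 0`). A non-spiking drive is a valid outcome, not an error.
#' @export
analytic_first_spike <- function(v_in, params) {
  stopifnot(inherits(params, "lif_params"))
  if (any(!is.finite(v_in))) stop("`v_in` must be finite")
  ts <- rep(NA_real_, length(v_in))
  fires <- (params$b + v_in) > 0
  if (params$b >= 0) {
    # resting potential already at/above threshold: immediate spike
    ts[fires] <- 0
  } else {
    ts[fires] <- -params$tau * log1p(params$b / v_in[fires])
  }
  ts
}

#' Euler-simulated first spike time (time-stepped oracle)
#'
#' Integrates the membrane equation with explicit forward Euler steps from
#' `u(0) = u_res` and reports the first step time at which `u >= theta`.
#' This is the independent time-stepped check for the closed-form
#' [analytic_first_spike()]; the two agree to within `2 * dt` for any
#' spiking drive of moderate latency.
#'
#' @param v_in Constant input drive(s).
#' @param params A [lif_params()] object.
#' @param dt Euler step; default `1e-3 * tau`. A warning is issued when
#'   `dt >= tau` (unstable discretization) but the simulation still runs.
#' @param t_max Simulation horizon; default `50 * tau`, long enough that
#'   `exp(-t_max / tau)` is far below float precision.
#'
#' @return First spike time(s); `NA` where no spike occurs by `t_max`.
#' @export
simulate_first_spike <- function(v_in, params,
                                 dt = 1e-3 * params$tau,
                                 t_max = 50 * params$tau) {
  stopifnot(inherits(params, "lif_params"))
  stop_if_not_scalar(dt, "dt", positive = TRUE)
  stop_if_not_scalar(t_max, "t_max", positive = TRUE)
  if (any(!is.finite(v_in))) stop("`v_in` must be finite")
  if (dt >= params$tau) {
    warning("dt >= tau: Euler discretization is unstable at this step size")
  }
  n <- length(v_in)
  ts <- rep(NA_real_, n)
  u <- rep(params$u_res, n)
  alive <- rep(TRUE, n)
  if (params$u_res >= params$theta) {
    return(rep(0, n))
  }
  n_steps <- ceiling(t_max / dt)
  for (s in seq_len(n_steps)) {
    u[alive] <- u[alive] +
      (dt / params$tau) * (-(u[alive] - params$u_res) + v_in[alive])
    fired <- alive & u >= params$theta
    if (any(fired)) {
      ts[fired] <- s * dt
      alive[fired] <- FALSE
      if (!any(alive)) break
    }
  }
  ts
}

#' Rectified-linear drive of the equivalent artificial neuron
#'
#' The limit `t -> Inf` of the LIF membrane potential minus threshold is
#' `b + sum(w * x)` with `b = u_res - theta`: the weighted sum of a
#' perceptron with bias. Its positive part is therefore the ReLU activation
#' of the equivalent artificial neuron, and it is positive exactly when a
#' finite first spike time exists. Larger activation corresponds to an
#' earlier spike.
#'
#' @param weights Synaptic weight vector.
#' @param inputs Input vector, same length as `weights`.
#' @param params A [lif_params()] object.
#'
#' @return `max(0, b + sum(weights * inputs))`.
#' @export
relu_drive <- function(weights, inputs, params) {
  stopifnot(inherits(params, "lif_params"))
  if (length(weights) != length(inputs)) {
    stop("`weights` and `inputs` must have the same length")
  }
  max(0, params$b + sum(weights * inputs))
}
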