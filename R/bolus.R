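#' Gamma-variate arterial input (bolus) model
#'
#' Peak-normalized gamma-variate bolus commonly used to describe the arrival
#' of an injected tracer. The curve is zero before `arrival_time`, rises to
#' its maximum `amplitude` at `arrival_time + shape * scale`, and decays with
#' a gamma tail:
#' \deqn{b(t) = A \, (x/\alpha)^{\alpha} e^{\alpha - x}, \quad
#'       x = (t - t_0)/\beta \ge 0,}
#' with shape \eqn{\alpha}, scale \eqn{\beta} (seconds) and peak value
#' \eqn{A}. Peak normalization decouples the peak height from the shape and
#' scale parameters.
#'
#' The defaults place the bolus peak at 10 s post injection, i.e. shortly
#' before the first imaging frame of the default [acq_geometry()].
#'
#' @param arrival_time Bolus arrival in seconds after injection (>= 0).
#' @param shape Dimensionless shape parameter (> 0).
#' @param scale Time scale in seconds (> 0).
#' @param amplitude Peak signal amplitude (>= 0).
#' @return An object of class `bolus_model`.
#' @examples
#' b <- gamma_variate_bolus()
#' evaluate_bolus(b, b$arrival_time + b$shape * b$scale)  # == amplitude
#' @export
gamma_variate_bolus <- function(arrival_time = 4, shape = 3, scale = 2,
                                amplitude = 1) {
  vals <- c(arrival_time, shape, scale, amplitude)
  if (any(!is.finite(vals)))
    stop("bolus parameters must be finite")
  stopifnot(arrival_time >= 0, shape > 0, scale > 0, amplitude >= 0)
  structure(list(family = "gamma_variate", arrival_time = arrival_time,
                 shape = shape, scale = scale, amplitude = amplitude),
            class = "bolus_model")
}

#' Evaluate a bolus model
#'
#' @param model A [gamma_variate_bolus()] object.
#' @param t Numeric vector of times in seconds (finite).
#' @return Bolus signal values; zero for `t < arrival_time`, non-negative
#'   everywhere, maximum `amplitude` at `arrival_time + shape * scale`.
#' @export
evaluate_bolus <- function(model, t) {
  stopifnot(inherits(model, "bolus_model"))
  if (any(!is.finite(t))) stop("t must be finite")
  out <- numeric(length(t))
  ok <- t >= model$arrival_time
  if (any(ok)) {
    x <- (t[ok] - model$arrival_time) / model$scale
    out[ok] <- model$amplitude * (x / model$shape)^model$shape *
      exp(model$shape - x)
  }
  out
}
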