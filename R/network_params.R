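#' Parameters of the two-population VISp rate model
#'
#' Constructs the full parameter set of the pyramidal (P) / fast-spiking (F)
#' threshold-linear rate model with capped cross-modal input. The defaults
#' are the published basal parameterization of the model; every argument can
#' be overridden individually.
#'
#' Units: time constants in seconds, gains in Hz per input unit, synaptic
#' weights in input units per Hz, thresholds and drives in input units.
#' `alpha = J_PF / J_PP` is the weight-space analogue of the synaptic I/E
#' ratio and is derived, never set independently. The effective cap on the
#' cross-modal drive is `rho = delta * theta_P`.
#'
#' @param tau_P,tau_F population time constants (s); both > 0.
#' @param G_P,G_F input-output gains (Hz per input unit); both > 0.
#' @param J_PP,J_PF,J_FF,J_FP synaptic weights (> 0). `J_PF` defaults to
#'   `alpha * J_PP` when `alpha` is given, otherwise to its basal value 4.
#' @param theta_P,theta_F activation thresholds (>= 0).
#' @param I_v_P,I_v_F visual drives onto P and F.
#' @param I_cm cross-modal drive before capping (the same drive reaches both
#'   populations).
#' @param delta dimensionless cap factor; the cap is `rho = delta * theta_P`.
#'   `Inf` disables the cap.
#' @param alpha optional I/E weight ratio; when supplied, `J_PF` is set to
#'   `alpha * J_PP` and any explicit `J_PF` is ignored.
#'
#' @return An object of class `"network_params"`: a named list of the fields
#'   above plus the derived `alpha` and `rho`.
#' @examples
#' p <- network_params()
#' p$alpha # 2
#' p$rho   # 0.5
#' @export
network_params <- function(tau_P = 0.060, tau_F = 0.012,
                           G_P = 1, G_F = 5,
                           J_PP = 2, J_PF = NULL, J_FF = 0.8, J_FP = 0.4,
                           theta_P = 0.5, theta_F = 0.35,
                           I_v_P = 3.6, I_v_F = 0.6,
                           I_cm = 0.6, delta = 1, alpha = NULL) {
  if (!is.null(alpha)) {
    J_PF <- alpha * J_PP
  } else if (is.null(J_PF)) {
    J_PF <- 4
  }
  p <- list(tau_P = tau_P, tau_F = tau_F, G_P = G_P, G_F = G_F,
            J_PP = J_PP, J_PF = J_PF, J_FF = J_FF, J_FP = J_FP,
            theta_P = theta_P, theta_F = theta_F,
            I_v_P = I_v_P, I_v_F = I_v_F,
            I_cm = I_cm, delta = delta)
  p$alpha <- p$J_PF / p$J_PP
  p$rho <- p$delta * p$theta_P
  class(p) <- "network_params"
  validate_network_params(p)
  p
}

validate_network_params <- function(p) {
  pos <- c("tau_P", "tau_F", "G_P", "G_F", "J_PP", "J_PF", "J_FF", "J_FP")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("network_params: '", nm, "' must be finite and > 0", call. = FALSE)
  }
  if (p$theta_P < 0 || p$theta_F < 0)
    stop("network_params: thresholds must be >= 0", call. = FALSE)
  if (p$delta < 0)
    stop("network_params: 'delta' must be >= 0", call. = FALSE)
  if (p$rho < 0)
    stop("network_params: rho = delta * theta_P must be >= 0", call. = FALSE)
  invisible(p)
}

#' Modify a parameter set, keeping derived quantities consistent
#'
#' @param params a [network_params()] object.
#' @param ... named fields to replace. Setting `alpha` rescales `J_PF`;
#'   setting `J_PP` while keeping `alpha` fixed is done by passing both.
#' @return a new `network_params` object.
#' @export
update_params <- function(params, ...) {
  upd <- list(...)
  base <- unclass(params)
  base$alpha <- NULL
  base$rho <- NULL
  for (nm in names(upd)) {
    if (nm == "alpha") next
    base[[nm]] <- upd[[nm]]
  }
  if ("alpha" %in% names(upd)) {
    base$J_PF <- NULL
    return(do.call(network_params, c(base, list(alpha = upd$alpha))))
  }
  do.call(network_params, base)
}

#' @export
print.network_params <- function(x, ...) {
  cat("Two-population VISp rate model parameters\n")
  cat(sprintf("  tau_P=%.3g s  tau_F=%.3g s  G_P=%.3g  G_F=%.3g\n",
              x$tau_P, x$tau_F, x$G_P, x$G_F))
  cat(sprintf("  J_PP=%.3g J_PF=%.3g J_FF=%.3g J_FP=%.3g (alpha=%.3g)\n",
              x$J_PP, x$J_PF, x$J_FF, x$J_FP, x$alpha))
  cat(sprintf("  theta_P=%.3g theta_F=%.3g  I_v=(%.3g, %.3g)  I_cm=%.3g  rho=%.3g\n",
              x$theta_P, x$theta_F, x$I_v_P, x$I_v_F, x$I_cm, x$rho))
  invisible(x)
}

#' Stimulus timing protocol
#'
#' Default protocol: visual drive on for 10 s from t = 0; cross-modal drive
#' added after 5 s and maintained until visual offset; Euler step 0.0001 s.
#'
#' @param t_total total simulated time (s).
#' @param t_v_on,t_v_off visual-input window (s).
#' @param t_cm_on,t_cm_off cross-modal-input window (s).
#' @param dt integration step (s).
#' @return an object of class `"stimulus_protocol"`.
#' @export
stimulus_protocol <- function(t_total = 10, t_v_on = 0, t_v_off = 10,
                              t_cm_on = 5, t_cm_off = 10, dt = 1e-4) {
  if (!(dt > 0)) stop("stimulus_protocol: dt must be > 0", call. = FALSE)
  if (!(0 <= t_v_on && t_v_on < t_v_off && t_v_off <= t_total))
    stop("stimulus_protocol: need 0 <= t_v_on < t_v_off <= t_total", call. = FALSE)
  if (!(0 <= t_cm_on && t_cm_on < t_cm_off && t_cm_off <= t_total))
    stop("stimulus_protocol: need 0 <= t_cm_on < t_cm_off <= t_total", call. = FALSE)
  structure(list(t_total = t_total, t_v_on = t_v_on, t_v_off = t_v_off,
                 t_cm_on = t_cm_on, t_cm_off = t_cm_off, dt = dt),
            class = "stimulus_protocol")
}
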