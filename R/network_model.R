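#' Cap the cross-modal drive
#'
#' The cross-modal input is clipped to the band `[0, rho]` with
#' `rho = delta * theta_P`, modelling the intrinsic subthreshold effect of
#' the tactile drive on the pyramidal population: on its own it can
#' depolarize but never activate P.
#'
#' @param I_cm cross-modal drive before capping (input units).
#' @param delta dimensionless cap factor (>= 0); `Inf` disables the cap.
#' @param theta_P pyramidal activation threshold (>= 0).
#' @return the capped drive, in `[0, delta * theta_P]`.
#' @examples
#' cap_crossmodal(0.6, 1, 0.5) # 0.5
#' @export
cap_crossmodal <- function(I_cm, delta, theta_P) {
  if (any(!is.na(delta) & delta < 0) || any(!is.na(theta_P) & theta_P < 0))
    stop("cap_crossmodal: delta and theta_P must be >= 0", call. = FALSE)
  pmax(pmin(I_cm, delta * theta_P), 0)
}

#' Threshold-linear response function
#'
#' `f(h) = 0` for `h <= theta` and `G * (h - theta)` above threshold;
#' continuous at the threshold.
#'
#' @param h summed input (input units); vectorized.
#' @param G linear gain (> 0).
#' @param theta activation threshold.
#' @return firing rate (Hz), same length as `h`.
#' @export
response_function <- function(h, G, theta) {
  if (!is.finite(G) || G <= 0)
    stop("response_function: G must be finite and > 0", call. = FALSE)
  G * pmax(h - theta, 0)
}

#' Simulate the two-population rate model
#'
#' Forward-Euler integration of the population dynamics
#' `tau_i dA_i/dt = -A_i + f_i(h_i)` with the cross-modal drive capped and
#' the threshold-linear transfer. The cross-modal drive reaches both
#' populations with equal strength during its stimulus window.
#'
#' @param params a [network_params()] object.
#' @param protocol a [stimulus_protocol()] object.
#' @param initial initial rates `c(A_P, A_F)` (Hz, >= 0); default zero.
#' @param keep_every store every k-th step in the returned trajectory
#'   (the integration itself always runs at `protocol$dt`).
#' @param check_convergence warn if the relative rate change over the 0.1 s
#'   before each stimulus transition exceeds `1e-9`.
#' @return an object of class `"trajectory"`: list with `times`, `A_P`,
#'   `A_F` (all stored steps) and the protocol used.
#' @export
simulate_network <- function(params, protocol = stimulus_protocol(),
                             initial = c(0, 0), keep_every = 1L,
                             check_convergence = FALSE) {
  stopifnot(inherits(params, "network_params"),
            inherits(protocol, "stimulus_protocol"))
  if (any(initial < 0)) stop("initial rates must be >= 0", call. = FALSE)
  dt <- protocol$dt
  n <- as.integer(round(protocol$t_total / dt))
  times <- (0:n) * dt
  icm_cap <- cap_crossmodal(params$I_cm, params$delta, params$theta_P)

  v_on <- times >= protocol$t_v_on & times < protocol$t_v_off
  cm_on <- times >= protocol$t_cm_on & times < protocol$t_cm_off

  A_P <- numeric(n + 1L); A_F <- numeric(n + 1L)
  A_P[1] <- initial[1]; A_F[1] <- initial[2]
  aP <- initial[1]; aF <- initial[2]
  rP <- dt / params$tau_P; rF <- dt / params$tau_F
  # external drive per step, precomputed (transfer function inlined below
  # for speed: the loop is the hot path at dt = 1e-4)
  in_P <- v_on * params$I_v_P + cm_on * icm_cap
  in_F <- v_on * params$I_v_F + cm_on * icm_cap
  J_PP <- params$J_PP; J_PF <- params$J_PF
  J_FP <- params$J_FP; J_FF <- params$J_FF
  G_P <- params$G_P; G_F <- params$G_F
  th_P <- params$theta_P; th_F <- params$theta_F
  blow_up <- function() {
    bad <- which(!is.finite(A_P) | !is.finite(A_F))
    bad <- if (length(bad)) bad[1] else n + 1L
    stop(sprintf("integration instability: non-finite rate at step %d (t = %.4f s)",
                 bad - 1L, times[min(bad, n + 1L)]), call. = FALSE)
  }
  # NaN iterates (overflow via Inf - Inf) abort the branch test itself;
  # translate that into the instability diagnostic with the failing step
  tryCatch(
    for (k in seq_len(n)) {
      hP <- J_PP * aP - J_PF * aF + in_P[k] - th_P
      hF <- J_FP * aP - J_FF * aF + in_F[k] - th_F
      aP <- aP + rP * (if (hP > 0) G_P * hP - aP else -aP)
      aF <- aF + rF * (if (hF > 0) G_F * hF - aF else -aF)
      A_P[k + 1L] <- aP; A_F[k + 1L] <- aF
    },
    error = function(e) blow_up())
  if (!is.finite(aP) || !is.finite(aF)) blow_up()

  if (check_convergence) {
    w <- as.integer(round(0.1 / dt))
    for (tt in unique(c(protocol$t_cm_on, protocol$t_v_off))) {
      k1 <- as.integer(round(tt / dt))
      if (k1 > w) {
        for (A in list(A_P, A_F)) {
          a0 <- A[k1 + 1L - w]; a1 <- A[k1 + 1L]
          if (abs(a1 - a0) > 1e-9 * max(abs(a1), 1e-12))
            warning(sprintf("rates not converged before transition at t = %.3f s", tt),
                    call. = FALSE)
        }
      }
    }
  }

  keep <- seq(1L, n + 1L, by = as.integer(keep_every))
  if (keep[length(keep)] != n + 1L) keep <- c(keep, n + 1L)
  structure(list(times = times[keep], A_P = A_P[keep], A_F = A_F[keep],
                 protocol = protocol),
            class = "trajectory")
}

#' Steady-state rates read off a simulated trajectory
#'
#' Returns the rates at the last stored step before the cross-modal onset
#' (the visual-only state) and before the visual offset (the combined
#' visual + whisker state).
#'
#' @param traj a `"trajectory"` from [simulate_network()].
#' @return list with numeric pairs `v` and `vw` (`c(A_P, A_F)` each).
#' @export
steady_states_from_simulation <- function(traj) {
  pr <- traj$protocol
  i_v <- max(which(traj$times <= pr$t_cm_on))
  i_vw <- max(which(traj$times <= min(pr$t_cm_off, pr$t_v_off)))
  list(v = c(A_P = traj$A_P[i_v], A_F = traj$A_F[i_v]),
       vw = c(A_P = traj$A_P[i_vw], A_F = traj$A_F[i_vw]))
}

phi_of <- function(p) {
  wPP <- p$G_P * p$J_PP; wPF <- p$G_P * p$J_PF
  wFF <- p$G_F * p$J_FF; wFP <- p$G_F * p$J_FP
  wFP * wPF - (wPP - 1) * (wFF + 1)
}

#' Closed-form steady state of the active network
#'
#' Solves the combined active-branch linear system for the fixed point:
#' `A_P* = [(1 + w_FF) e_P - w_PF e_F] / phi`,
#' `A_F* = [w_FP e_P - (w_PP - 1) e_F] / phi`,
#' with effective weights `w_ij = G_i J_ij`, effective drives
#' `e_i = G_i (I_cm_capped + I_v_i - theta_i)` and
#' `phi = w_FP w_PF - (w_PP - 1)(w_FF + 1)`.
#' The closed form only holds when both populations are above threshold at
#' the fixed point; this is verified post hoc and reported in `valid`.
#'
#' @param params a [network_params()] object.
#' @param condition `"v"` (visual only; capped cross-modal drive set to 0)
#'   or `"v+w"` (visual plus capped cross-modal drive). `"cm-only"` returns
#'   the scalar F-only fixed point with P inactive.
#' @return an object of class `"steady_state"`: list with `A_P_star`,
#'   `A_F_star`, `condition`, `eps_P`, `eps_F`, `active_P`, `active_F`,
#'   `phi`, `valid`.
#' @export
steady_state_analytic <- function(params, condition = c("v", "v+w", "cm-only")) {
  stopifnot(inherits(params, "network_params"))
  condition <- match.arg(condition)
  icm <- cap_crossmodal(params$I_cm, params$delta, params$theta_P)
  phi <- phi_of(params)

  if (condition == "cm-only") {
    # P stays silent (icm < theta_P by construction of the cap when delta <= 1;
    # verified below); F solves A = G_F (icm - theta_F - J_FF A) on its own.
    aF <- max(params$G_F * (icm - params$theta_F), 0) /
      (1 + params$G_F * params$J_FF)
    hP <- icm - params$J_PF * aF
    out <- list(A_P_star = 0, A_F_star = aF, condition = condition,
                eps_P = params$G_P * (icm - params$theta_P),
                eps_F = params$G_F * (icm - params$theta_F),
                active_P = FALSE, active_F = aF > 0, phi = phi,
                valid = hP <= params$theta_P)
    class(out) <- "steady_state"
    return(out)
  }

  if (abs(phi) < .Machine$double.eps * 64)
    stop("degenerate network: phi = 0, no unique active fixed point", call. = FALSE)

  icm_c <- if (condition == "v") 0 else icm
  eP <- params$G_P * (icm_c + params$I_v_P - params$theta_P)
  eF <- params$G_F * (icm_c + params$I_v_F - params$theta_F)
  wPP <- params$G_P * params$J_PP; wPF <- params$G_P * params$J_PF
  wFF <- params$G_F * params$J_FF; wFP <- params$G_F * params$J_FP
  aP <- ((1 + wFF) * eP - wPF * eF) / phi
  aF <- (wFP * eP - (wPP - 1) * eF) / phi

  hP <- params$J_PP * aP - params$J_PF * aF + icm_c + params$I_v_P
  hF <- params$J_FP * aP - params$J_FF * aF + icm_c + params$I_v_F
  active_P <- aP > 0 && hP > params$theta_P
  active_F <- aF > 0 && hF > params$theta_F
  out <- list(A_P_star = aP, A_F_star = aF, condition = condition,
              eps_P = eP, eps_F = eF,
              active_P = active_P, active_F = active_F, phi = phi,
              valid = active_P && active_F)
  class(out) <- "steady_state"
  out
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady state (%s): A_P* = %.6g Hz, A_F* = %.6g Hz%s\n",
              x$condition, x$A_P_star, x$A_F_star,
              if (x$valid) "" else "  [invalid: active-branch assumption violated]"))
  invisible(x)
}

#' Closed-form suppression amplitudes
#'
#' The steady-state change caused by adding the capped cross-modal drive to
#' ongoing visual stimulation:
#' `dA_P* = Icm G_P [1 + G_F (J_FF - J_PF)] / phi`,
#' `dA_F* = Icm G_F [1 + G_P (J_FP - J_PP)] / phi`.
#' Both are proportional to the capped drive and independent of the visual
#' drive magnitudes (as long as both populations stay active in both
#' conditions; this validity is reported, not silently assumed).
#'
#' @param params a [network_params()] object.
#' @return numeric `c(dA_P = ..., dA_F = ...)` (Hz) with attribute `valid`
#'   (TRUE iff both populations are active at both fixed points).
#' @export
suppression_analytic <- function(params) {
  stopifnot(inherits(params, "network_params"))
  phi <- phi_of(params)
  if (abs(phi) < .Machine$double.eps * 64)
    stop("degenerate network: phi = 0", call. = FALSE)
  icm <- cap_crossmodal(params$I_cm, params$delta, params$theta_P)
  dP <- icm * params$G_P * (1 + params$G_F * (params$J_FF - params$J_PF)) / phi
  dF <- icm * params$G_F * (1 + params$G_P * (params$J_FP - params$J_PP)) / phi
  sv <- steady_state_analytic(params, "v")
  svw <- steady_state_analytic(params, "v+w")
  out <- c(dA_P = dP, dA_F = dF)
  attr(out, "valid") <- sv$valid && svw$valid
  out
}

#' Operating-regime classification
#'
#' Evaluates the three inhibition-stabilized-network (ISN) criteria and the
#' two suppression conditions:
#' I: `G_P J_PP > 1`; II: `G_F J_FF + 1 > k (G_P J_PP - 1)` with
#' `k = tau_F / tau_P`; III: `phi > 0` (recurrent-excitation instability is
#' stabilized by feedback inhibition). Suppression of P requires
#' `1 + G_F (J_FF - J_PF) < 0` together with `phi > 0`; suppression of F
#' requires `1 + G_P (J_FP - J_PP) < 0` together with `phi > 0`.
#'
#' @param params a [network_params()] object.
#' @return an object of class `"regime_report"`: list with `phi`, `k`,
#'   `isn_I`, `isn_II`, `isn_III`, `isn` (all three), `supp_P_condition`,
#'   `supp_F_condition`, `valid` (both populations active in both v and
#'   v+w, so the suppression closed form applies), and `label` in
#'   `{"non-ISN", "ISN without suppression", "ISN with suppression"}`.
#' @export
classify_regime <- function(params) {
  stopifnot(inherits(params, "network_params"))
  k <- params$tau_F / params$tau_P
  phi <- phi_of(params)
  isn_I <- params$G_P * params$J_PP > 1
  isn_II <- params$G_F * params$J_FF + 1 > k * (params$G_P * params$J_PP - 1)
  isn_III <- phi > 0
  bP <- 1 + params$G_F * (params$J_FF - params$J_PF)
  bF <- 1 + params$G_P * (params$J_FP - params$J_PP)
  supp_P <- bP < 0 && phi > 0
  supp_F <- bF < 0 && phi > 0
  valid <- tryCatch(
    steady_state_analytic(params, "v")$valid &&
      steady_state_analytic(params, "v+w")$valid,
    error = function(e) FALSE)
  isn <- isn_I && isn_II && isn_III
  label <- if (!isn) "non-ISN"
  else if (supp_P) "ISN with suppression" else "ISN without suppression"
  structure(list(phi = phi, k = k,
                 isn_I = isn_I, isn_II = isn_II, isn_III = isn_III, isn = isn,
                 supp_P_condition = supp_P, supp_F_condition = supp_F,
                 valid = valid, label = label),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("regime: %s (phi = %.4g, k = %.3g)\n", x$label, x$phi, x$k))
  cat(sprintf("  ISN criteria I/II/III: %s/%s/%s; suppression P/F: %s/%s\n",
              x$isn_I, x$isn_II, x$isn_III,
              x$supp_P_condition, x$supp_F_condition))
  invisible(x)
}

#' Cross-modal level abolishing visually evoked P firing (uncapped model)
#'
#' With the cap disabled, `A_P*` under combined stimulation decreases
#' linearly in the cross-modal drive whenever the P-suppression condition
#' holds; this returns the drive level at which it reaches zero:
#' `I_cm_0 = -A_P*(v) * phi / (G_P [1 + G_F (J_FF - J_PF)])`.
#'
#' @param params a [network_params()] object.
#' @return the cessation level (input units); `Inf` if P is not suppressed.
#' @export
crossmodal_cessation_level <- function(params) {
  stopifnot(inherits(params, "network_params"))
  bP <- 1 + params$G_F * (params$J_FF - params$J_PF)
  if (bP >= 0) return(Inf)
  sv <- steady_state_analytic(params, "v")
  -sv$A_P_star * phi_of(params) / (params$G_P * bP)
}

#' Response to a small extra drive onto the inhibitory population
#'
#' Probes the paradoxical effect: starting from the visual-only fixed point,
#' the visual drive onto F is increased by `frac` and the new analytic fixed
#' point computed. In the ISN regime both steady-state rates decrease;
#' outside it (instability criterion III violated, or recurrent excitation
#' subcritical) `A_F*` increases.
#'
#' @param params a [network_params()] object.
#' @param frac fractional increase of `I_v_F` (default 0.05).
#' @param simulate also integrate the perturbed network and report the
#'   simulated steady state (only meaningful for dynamically stable regimes).
#' @return list with `baseline` and `perturbed` steady states, the rate
#'   changes `dA_P`, `dA_F`, and optionally `simulated` changes.
#' @export
paradoxical_probe <- function(params, frac = 0.05, simulate = FALSE) {
  base <- steady_state_analytic(params, "v")
  pert_params <- update_params(params, I_v_F = params$I_v_F * (1 + frac))
  pert <- steady_state_analytic(pert_params, "v")
  out <- list(baseline = base, perturbed = pert,
              dA_P = pert$A_P_star - base$A_P_star,
              dA_F = pert$A_F_star - base$A_F_star)
  if (simulate) {
    pr <- stimulus_protocol(t_total = 6, t_v_off = 6, t_cm_on = 3, t_cm_off = 6)
    p0 <- update_params(params, I_cm = 0)
    tr0 <- simulate_network(p0, pr, keep_every = 100L)
    # reuse the cm window as the perturbation window: extra drive to F only
    trj <- simulate_extra_F_drive(params, pr, frac)
    s0 <- steady_states_from_simulation(tr0)
    out$simulated <- list(baseline = s0$v, perturbed = trj,
                          dA_P = trj[["A_P"]] - s0$v[["A_P"]],
                          dA_F = trj[["A_F"]] - s0$v[["A_F"]])
  }
  out
}

simulate_extra_F_drive <- function(params, protocol, frac) {
  pP <- update_params(params, I_cm = 0, I_v_F = params$I_v_F * (1 + frac))
  tr <- simulate_network(pP, protocol, keep_every = 100L)
  s <- steady_states_from_simulation(tr)
  s$vw
}
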