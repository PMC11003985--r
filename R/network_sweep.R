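#' Parameter sweeps of the suppression model
#'
#' Evaluates closed-form suppression amplitudes, the combined-condition
#' steady state and the operating-regime label over one or two named
#' parameter grids. Supported axes: `"I_cm"`, `"theta_P"`, `"alpha"`,
#' `"G_P"`, `"G_F"`, `"delta"`, and any raw `network_params` field. The
#' two-dimensional gain sweep (`G_P` x `G_F`) reproduces the
#' suppression-strength matrices with their regime boundaries.
#'
#' @param params baseline [network_params()].
#' @param axis name of the swept parameter.
#' @param grid numeric grid for `axis`.
#' @param axis2,grid2 optional second axis (full factorial).
#' @param simulate if `TRUE`, additionally integrate the network at each
#'   grid point and record the absolute analytic/numeric discrepancy
#'   (columns `sim_dA_P`, `sim_dA_F`, `max_abs_diff`).
#' @param protocol protocol used when `simulate = TRUE`.
#' @return a long-format `data.frame` with one row per grid point:
#'   the grid value(s), `dA_P`, `dA_F` (Hz), `A_P_vw`, `A_F_vw` (Hz),
#'   `phi`, `valid`, `regime`, and an `error` column (NA unless the grid
#'   point was degenerate, in which case the message is recorded and the
#'   numeric columns are NA).
#' @export
sweep_network <- function(params, axis, grid, axis2 = NULL, grid2 = NULL,
                          simulate = FALSE, protocol = stimulus_protocol()) {
  stopifnot(inherits(params, "network_params"))
  pts <- if (is.null(axis2)) data.frame(v1 = grid)
  else expand.grid(v1 = grid, v2 = grid2)
  names(pts) <- c(axis, axis2)[seq_len(ncol(pts))]

  one <- function(i) {
    upd <- as.list(pts[i, , drop = FALSE])
    p <- tryCatch(do.call(update_params, c(list(params), upd)),
                  error = function(e) e)
    if (inherits(p, "error"))
      return(data.frame(dA_P = NA_real_, dA_F = NA_real_,
                        A_P_vw = NA_real_, A_F_vw = NA_real_,
                        phi = NA_real_, valid = NA, regime = NA_character_,
                        error = conditionMessage(p)))
    res <- tryCatch({
      sup <- suppression_analytic(p)
      svw <- steady_state_analytic(p, "v+w")
      reg <- classify_regime(p)
      data.frame(dA_P = sup[["dA_P"]], dA_F = sup[["dA_F"]],
                 A_P_vw = svw$A_P_star, A_F_vw = svw$A_F_star,
                 phi = reg$phi, valid = attr(sup, "valid"),
                 regime = reg$label, error = NA_character_)
    }, error = function(e)
      data.frame(dA_P = NA_real_, dA_F = NA_real_,
                 A_P_vw = NA_real_, A_F_vw = NA_real_,
                 phi = NA_real_, valid = NA, regime = NA_character_,
                 error = conditionMessage(e)))
    if (simulate && is.na(res$error) && isTRUE(res$valid)) {
      tr <- simulate_network(p, protocol, keep_every = 200L)
      s <- steady_states_from_simulation(tr)
      res$sim_dA_P <- s$vw[["A_P"]] - s$v[["A_P"]]
      res$sim_dA_F <- s$vw[["A_F"]] - s$v[["A_F"]]
      res$max_abs_diff <- max(abs(res$sim_dA_P - res$dA_P),
                              abs(res$sim_dA_F - res$dA_F))
    } else if (simulate) {
      res$sim_dA_P <- NA_real_; res$sim_dA_F <- NA_real_
      res$max_abs_diff <- NA_real_
    }
    res
  }

  out <- do.call(rbind, lapply(seq_len(nrow(pts)), one))
  cbind(pts, out)
}
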