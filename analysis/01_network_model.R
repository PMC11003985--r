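#!/usr/bin/env Rscript

# Stage 1 -- the VISp rate model of cross-modal suppression.
#
# Simulates the basal two-population model (visual drive for 10 s, tactile
# cross-modal drive added after 5 s), confirms the simulated steady states
# against the closed form, classifies the operating regime, and runs the
# parameter sweeps (cross-modal drive, P threshold, I/E ratio, gain plane).
# Outputs land in results/network/.

suppressMessages(library(tactovis))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
out <- "results/network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

p <- network_params()
cat("Basal parameter set:\n"); print(p)

tr <- simulate_network(p, keep_every = 100L)
s <- steady_states_from_simulation(tr)
write.csv(data.frame(time = tr$times, A_P = tr$A_P, A_F = tr$A_F),
          file.path(out, "trajectory_basal.csv"), row.names = FALSE)

sv <- steady_state_analytic(p, "v"); svw <- steady_state_analytic(p, "v+w")
cat(sprintf("\nVisual-only steady state:    simulated (%.6f, %.6f) Hz, closed form (%.6f, %.6f) Hz\n",
            s$v[1], s$v[2], sv$A_P_star, sv$A_F_star))
cat(sprintf("Visual+whisker steady state: simulated (%.6f, %.6f) Hz, closed form (%.6f, %.6f) Hz\n",
            s$vw[1], s$vw[2], svw$A_P_star, svw$A_F_star))
sup <- suppression_analytic(p)
cat(sprintf("Suppression (dA_P, dA_F) = (%.3f, %.3f) Hz -- both populations are suppressed\n",
            sup[["dA_P"]], sup[["dA_F"]]))
print(classify_regime(p))

cat("\nCross-modal drive alone (no visual input):\n")
p_cm <- update_params(p, I_v_P = 0, I_v_F = 0)
cat(sprintf("  P stays silent; F settles at %.3f Hz (subthreshold capping at work)\n",
            steady_state_analytic(p_cm, "cm-only")$A_F_star))

cat("\nSweeps (closed form per grid point):\n")
sw_icm <- sweep_network(p, "I_cm", seq(0, 1.2, by = 0.02))
write.csv(sw_icm, file.path(out, "sweep_I_cm.csv"), row.names = FALSE)
cat(sprintf("  I_cm: suppression saturates at dA_P = %.2f Hz once I_cm >= rho = %.2f\n",
            min(sw_icm$dA_P), p$rho))
i0 <- crossmodal_cessation_level(update_params(p, delta = Inf))
cat(sprintf("  without the cap, visually evoked P firing ceases at I_cm = %.3f\n", i0))

sw_th <- sweep_network(p, "theta_P", seq(0.35, 0.75, by = 0.01))
write.csv(sw_th, file.path(out, "sweep_theta_P.csv"), row.names = FALSE)
cat("  theta_P: higher P threshold admits more capped drive -> stronger suppression\n")

sw_al <- sweep_network(p, "alpha", seq(1.2, 4, by = 0.05))
write.csv(sw_al, file.path(out, "sweep_alpha.csv"), row.names = FALSE)
cat("  alpha (I/E ratio): higher inhibitory weighting weakens suppression\n")

sw_g <- sweep_network(p, "G_P", seq(0.2, 2.5, by = 0.115),
                      "G_F", seq(0.25, 8, by = 0.25))
write.csv(sw_g, file.path(out, "sweep_gains.csv"), row.names = FALSE)
tab <- table(sw_g$regime)
cat("  gain plane operating regimes:\n")
print(tab)
cat(sprintf("\nWrote %d files to %s\n", 5L, out))
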