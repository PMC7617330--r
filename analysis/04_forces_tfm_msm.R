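#!/usr/bin/env Rscript
# Substrate forces and monolayer tension on synthetic islands: build a
# contractile scene on a 12.6 kPa finite-thickness gel, measure the
# bead-displacement field it produces, invert back to traction
# (GCV-regularized under noise), and recover the line-tension tensor by
# monolayer stress microscopy. Scores every stage against the generator
# ground truth.

library(epimech)
dir.create("results", showWarnings = FALSE)

gel <- gel_spec(E = 12600, nu = 0.49, thickness = 60)

# --- TFM round trip with measurement noise ------------------------------
sc <- generate_traction_scene("random_dipoles", 200, gel,
                              grid = list(n = 64, spacing = 5),
                              dipole_sigma = 40, seed = 401)
d <- forward_displacement(sc$scene$traction, gel)
dmax <- max(abs(c(d$u, d$v)))
set.seed(402)
d$u <- d$u + rnorm(length(d$u), 0, 0.01 * dmax)
d$v <- d$v + rnorm(length(d$v), 0, 0.01 * dmax)
lam <- gcv_lambda(d, gel)$lambda
rec <- invert_traction(d, gel, reg_lambda = lam)
tr <- sc$scene$traction
rel <- sqrt(sum((rec$u - tr$u)^2 + (rec$v - tr$v)^2) / sum(tr$u^2 + tr$v^2))
cat(sprintf("TFM: GCV lambda %.3g, traction recovery rel L2 error %.2f (1%% displacement noise)\n",
            lam, rel))
write_field(rec, "results/traction_recovered.csv")

# --- MSM on the strip oracle -------------------------------------------
strip <- generate_traction_scene("contractile_strip", 100, gel,
                                 grid = list(n = 128, spacing = 2),
                                 strip_frac = 200 / 256, strip_aspect = 0.05)
st <- recover_stress(strip$scene$traction, strip$scene$mask, nu_m = 0.5)
ts <- tension_summary(st)
cols <- which(apply(strip$scene$mask, 2, any))
rows <- which(apply(strip$scene$mask, 1, any))
prof <- colMeans(ts$tension_map[rows, cols])
write.csv(data.frame(x_um = (cols - min(cols) + 0.5) * 2, tension_mNm = prof),
          "results/strip_tension_profile.csv", row.names = FALSE)
cat(sprintf("MSM strip: peak tension %.3f mN/m (oracle 10), mask average %.3f mN/m, residual %.1e\n",
            max(prof), ts$average_normal_tension, st$residual))
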