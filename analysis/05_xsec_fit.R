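#!/usr/bin/env Rscript
# The chi-squared grid fit of the geometric cross-section parameters on a
# synthetic measurement set: point recovery on the default coarse grid, the
# degeneracy ridge on a fine grid, and a 100-seed recovery study. Writes
# results/chi2_surface.csv and results/chi2_best.json.

suppressPackageStartupMessages(library(hzesim))
dir.create("results", showWarnings = FALSE)

rec <- make_xsec_dataset(noise_fraction = 0.10, seed = 5)
write_xsec_csv(rec, "results/xsec_records.csv")

fit <- chi2_fit(rec)
cat(sprintf("coarse-grid best fit: r0 = %.2f fm, b = %.2f (truth 1.26, 0.2); chi2/record = %.2f\n",
            fit$best_fit$r0, fit$best_fit$transparency, fit$chi2_min / fit$n_records))

surf <- chi2_fit(rec, r0_grid = seq(1.10, 1.42, by = 0.02),
                 b_grid = seq(0, 0.6, by = 0.025))
write_chi2_surface(surf, "results/chi2_surface.csv", "results/chi2_best.json")
i130 <- which(abs(surf$r0_grid - 1.30) < 1e-9)
cat(sprintf("ridge: at r0 = 1.30 the best transparency is %.3f with chi2 only %.2fx the minimum\n",
            surf$b_grid[which.min(surf$chi2[i130, ])],
            min(surf$chi2[i130, ]) / surf$chi2_min))
cat("-> the radius and transparency are strongly correlated; the data constrain\n")
cat("   their combination far better than either parameter alone.\n")

hits <- 0
for (s in 1:100) {
  f <- chi2_fit(make_xsec_dataset(noise_fraction = 0.10, seed = s))
  hits <- hits + (abs(f$best_fit$r0 - 1.26) <= 0.08 + 1e-9 &&
                    abs(f$best_fit$transparency - 0.2) <= 0.2 + 1e-9)
}
cat(sprintf("recovery study: truth within one grid step in %d/100 seeded datasets\n", hits))
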