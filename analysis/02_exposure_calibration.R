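#!/usr/bin/env Rscript

# Step 2 — exposure-and-effects calibration table.
#
# Derives the constants the insecticide scenarios rest on: daily mortality
# probabilities per lethality class, toxic-unit treatment rates per
# half-life class (with the 7-day trigger-crossing check), and the drift
# deposition profile with and without drift-reducing technology. Writes
# results/exposure/.

suppressPackageStartupMessages(library(carabidscape))

outdir <- "results/exposure"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

## lethality classes -----------------------------------------------------
classes <- data.frame(lr_class = c("LR90", "LR50", "LR25"),
                      m = c(0.90, 0.50, 0.25))
classes$daily_p <- daily_mortality_prob(classes$m, 7)
cat("daily mortality probabilities (7-day classes):\n")
print(transform(classes, daily_p = round(daily_p, 4)), row.names = FALSE)

## treatment rates and trigger crossing ----------------------------------
rates <- data.frame(dt50 = c(1.3, 25))
rates$treatment_rate <- treatment_rate(rates$dt50, 7)
rates$conc_day7_20C <- rates$treatment_rate * 0.5^(7 / rates$dt50)
cat("\ntoxic-unit treatment rates (rate * 0.5^(7/DT50) must equal 1):\n")
print(transform(rates, treatment_rate = round(treatment_rate, 2)),
      row.names = FALSE)

## temperature dependence of the half-life -------------------------------
temps <- seq(0, 30, by = 5)
dt_tab <- expand.grid(temp_c = temps, dt50_20 = c(1.3, 25))
dt_tab$dt50_at_t <- temperature_adjusted_dt50(dt_tab$dt50_20, dt_tab$temp_c)

## drift profile ----------------------------------------------------------
dists <- c(0.5, 1, 2, 3, 5, 8, 12)
drift <- do.call(rbind, lapply(c(0, 0.5, 0.9), function(red) {
  data.frame(reduction = red, dist_m = dists,
             pct_of_rate = drift_fraction(dists, drift_curve(reduction = red)))
}))
cat("\ndrift deposition (% of application rate):\n")
print(reshape(drift, idvar = "dist_m", timevar = "reduction",
              direction = "wide"), row.names = FALSE, digits = 3)

write.csv(classes, file.path(outdir, "lethality_classes.csv"), row.names = FALSE)
write.csv(rates, file.path(outdir, "treatment_rates.csv"), row.names = FALSE)
write.csv(dt_tab, file.path(outdir, "dt50_temperature.csv"), row.names = FALSE)
write.csv(drift, file.path(outdir, "drift_profile.csv"), row.names = FALSE)

cat("\nFinding: the three classes map to daily kill probabilities of 0.28,\n",
    "0.09 and 0.04; calibrated deposits sit exactly on the trigger after\n",
    "7 days at 20 C (rates 41.78 and 1.21 toxic units).\n", sep = "")
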