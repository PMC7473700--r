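#!/usr/bin/env Rscript

# Stage 5: fiscal-space scenarios.
#
# Converts efficiency gaps into potential budget savings over the published
# hospital services expenditure levels: MUR 9,862 / 10,555 / 10,724 million
# for fiscal years 2020-21, 2021-22 and 2022-23.  Baselines are the two
# published mean-efficiency levels (0.89 full period, 0.81 for 2012-2017);
# targets raise efficiency to 0.90, 0.95 and full efficiency 1.0.

library(hospfrontier)

budgets <- c("FY2020-21" = 9862, "FY2021-22" = 10555, "FY2022-23" = 10724)
grid <- scenario_grid(baselines = c(0.89, 0.81),
                      targets = c(0.90, 0.95, 1.00),
                      budgets = budgets)
write_scenarios(grid, "results/fiscal_space.csv")

cat("Potential savings (MUR million), by fiscal year and scenario:\n\n")
print(as.data.frame(grid)[, c("fiscal_year", "eff_baseline", "eff_target",
                              "budget", "savings")], row.names = FALSE)

key_cells <- grid[grid$fiscal_year == "FY2021-22" & grid$eff_target >= 0.95, ]
cat("\nHeadline cells (FY2021-22):\n")
print(key_cells[, c("eff_baseline", "eff_target", "savings")], row.names = FALSE)
cat("\nWrote results/fiscal_space.csv\n")
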