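#!/usr/bin/env Rscript
# Summarize a metrics table into the study's headline comparisons:
# type I error and power by method, bias/relative bias, SD ratios
# against the complete-data fits, and SE calibration. Optionally draws
# the four panels as simple ggplots.
#
# Usage: Rscript analysis/04_report.R [metrics.csv] [--plots]

library(mlmisim)

args <- commandArgs(trailingOnly = TRUE)
path <- if (length(args) >= 1 && !startsWith(args[1], "--")) {
  args[1]
} else "results/metrics.csv"
m <- read.csv(path)
m$class <- ifelse(m$term %in% zero_terms(), "type I error",
                  ifelse(m$term %in% nonzero_terms(), "power", "other"))
m$level <- ifelse(grepl("^L", m$term), "level 2", "level 1")

cat("== Rejection rates (zero coefficients: type I error) ==\n")
t1 <- stats::aggregate(rejection_rate ~ method + level,
                       data = m[m$class == "type I error", ], FUN = max)
print(t1, digits = 3)

cat("\n== Power (nonzero coefficients, mean) ==\n")
t2 <- stats::aggregate(rejection_rate ~ method + level,
                       data = m[m$class == "power" &
                                  m$method != "complete", ],
                       FUN = mean)
print(t2, digits = 3)

cat("\n== SD ratio vs complete-data fits (max over coefficients) ==\n")
t3 <- stats::aggregate(sd_ratio ~ method + level,
                       data = m[m$method != "complete" &
                                  m$class != "other", ], FUN = max)
print(t3, digits = 3)

cat("\n== SE calibration (mean model SE / empirical SD; 1 = calibrated) ==\n")
t4 <- stats::aggregate(se_calibration ~ method + level,
                       data = m[m$class != "other", ], FUN = mean)
print(t4, digits = 3)

if ("--plots" %in% args && requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  g <- ggplot(m[m$class != "other", ],
              aes(term, rejection_rate, fill = method)) +
    geom_col(position = "dodge") +
    facet_wrap(~class, scales = "free_x") +
    geom_hline(yintercept = 0.05, linetype = 2) +
    labs(y = "rejection rate", x = NULL)
  ggsave("results/rejection_rates.pdf", g, width = 9, height = 4)
  cat("\nwrote results/rejection_rates.pdf\n")
}
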