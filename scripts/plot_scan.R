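#!/usr/bin/env Rscript
# Plot a 1-D potential-energy-surface scan written by scan_1d()/the CLI:
#   Rscript scripts/plot_scan.R <scan.csv> [out.pdf]
# Shows the extended-NEO curve, the conventional-HF curve when present, and
# the nuclear charge centroid at each grid point.

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: plot_scan.R <scan.csv> [out.pdf]")
out <- if (length(args) >= 2) args[2] else sub("\\.csv$", ".pdf", args[1])
sc <- read.csv(args[1])

suppressPackageStartupMessages(library(ggplot2))
long <- rbind(
  data.frame(displacement = sc$displacement, E = sc$E_neo, curve = "NEO"),
  if (!all(is.na(sc$E_rhf))) {
    data.frame(displacement = sc$displacement, E = sc$E_rhf, curve = "RHF")
  })
long <- long[is.finite(long$E), ]
long$E_rel <- (long$E - min(long$E)) * 627.509474  # kcal/mol above minimum

p <- ggplot(long, aes(displacement, E_rel, colour = curve)) +
  geom_line() + geom_point(size = 1.2) +
  labs(x = "displacement of the quantum center (Å)",
       y = "relative energy (kcal/mol)", colour = NULL) +
  theme_minimal()
ggsave(out, p, width = 5, height = 3.4)
cat("wrote", out, "\n")
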