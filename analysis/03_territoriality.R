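#!/usr/bin/env Rscript
# Full territoriality analysis of the synthetic study system: observed vs
# chance-expected nearest-neighbour distances, mixed-model evidence for
# territorial spacing, spatial regularity and exclusion ranges.

suppressPackageStartupMessages(library(nestspacing))
seed <- 20260923L

cfg <- run_config(mode = "synthetic", seed = seed,
                  out_dir = "results/synthetic_run")
rep <- run_pipeline(cfg)

cat("\n================ summary ================\n")
print(rep)
for (sp in names(rep$species)) {
  s <- rep$species[[sp]]
  if (isTRUE(s$skipped)) next
  mc <- s$annual$model_comparison
  cat(sprintf("\n%s\n", toupper(sp)))
  cat(sprintf("  annual mean NND %.0f m; multi-annual %.0f m\n",
              s$annual$mean_nnd_m, s$multiannual$nnd$mean_m))
  cat(sprintf("  AICc null-full: %.0f - %.0f = %.1f (%s backend) -> %s\n",
              mc$aicc_null, mc$aicc_full, mc$delta_i, mc$backend,
              if (mc$territorial) "territorial" else "no spacing evidence"))
  cat(sprintf("  beta (obs - sim) %.0f +/- %.0f m\n", mc$beta, mc$beta_se))
  cat(sprintf("  G annual %.2f, G territories %.2f\n",
              s$annual$g_mean, s$multiannual$g_index$g))
  if (length(s$histogram$exclusion_bins))
    cat(sprintf("  exclusion range: no observed NNDs below %.0f m where the null places them\n",
                s$histogram$bin_edges_m[max(s$histogram$exclusion_bins) + 1]))
  else
    cat("  no exclusion range detected\n")
}
cat("\nThe goshawk-like (strongest hard core) pattern shows the clearest",
    "spacing signal;\nthe buzzard-like (weakest hard core) pattern",
    "approaches spatial randomness,\nmirroring the ordering seen in the",
    "field system.\n")
cat("Report written to results/synthetic_run/report.json\n")
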