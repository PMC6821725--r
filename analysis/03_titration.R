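#!/usr/bin/env Rscript
# Stage 3: Boltzmann-sigmoid fits of the two protonation transitions:
# lambda_max vs pH on the acidic branch (proton acceptor) and A(514) vs
# pH on the alkaline branch (retinal Schiff base).
suppressPackageStartupMessages(library(pentarho))

dir.create("results", showWarnings = FALSE)
spa <- read_spectra_csv("results/data/titration_acidic.csv")
spb <- read_spectra_csv("results/data/titration_alkaline.csv")

fa <- titration_pka(spa, mode = "acceptor")
fb <- titration_pka(spb, mode = "rsb")
cat(sprintf("acceptor pKa = %.3f +/- %.3f (lambda_max %0.f -> %0.f nm)\n",
            fa$midpoint_pka, fa$se_pka, fa$y_low, fa$y_high))
cat(sprintf("Schiff-base pKa = %.3f +/- %.3f (A514 step %.3f)\n",
            fb$midpoint_pka, fb$se_pka, abs(fb$y_high - fb$y_low)))

write_report_json(list(
  acceptor = list(pka = fa$midpoint_pka, se = fa$se_pka,
                  dx = fa$dx, y_low = fa$y_low, y_high = fa$y_high),
  schiff_base = list(pka = fb$midpoint_pka, se = fb$se_pka,
                     dx = fb$dx, y_low = fb$y_low, y_high = fb$y_high)
), "results/titration_fit.json")
cat("wrote results/titration_fit.json\n")
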