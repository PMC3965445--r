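#!/usr/bin/env Rscript
# Step 1 — simulate the MRE acquisition.
#
# Builds the two-region viscoelastic phantom (parenchyma 5.234 + 1.447i kPa,
# hippocampus-like ROI 4.608 + 1.388i kPa, the control group means), solves
# the 900 Hz shear-wave problem and encodes the field into wrapped
# phase-image series for both MSG polarities with a polynomial static phase
# and 0.02 rad phase noise. The 128 px grid spans 12.5 mm -- the mouse
# brain's own scale -- so that the one-edge drive reaches the centred ROI
# with in-vivo-like wave amplitude (over 25 mm of lossy tissue the shear
# wave would decay ~40 dB, which no reconstruction survives; in vivo the
# skull excites the brain boundary from all sides instead).
#
# Large image intermediates (ground truth, wavefield, 16 phase images) go to
# scratch/simulation/ for step 2; a small summary lands in results/.

suppressPackageStartupMessages(library(mretools))
img_out <- "scratch/simulation"
dir.create(img_out, showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)
seed <- 20260918

protocol <- acquisition_protocol(fov = 0.0125)
phantom <- build_phantom(128, 0.0125, 5234 + 1447i, 4608 + 1388i, 1000)
field <- solve_forward(phantom, protocol, "left", drive_amplitude = 6e-6)
static <- static_phase_poly(128)
pos <- encode_phase(field, protocol, +1, static, noise_sd = 0.02, seed = seed)
neg <- encode_phase(field, protocol, -1, static, noise_sd = 0.02, seed = seed + 1)

write_field(phantom$gstar_map, file.path(img_out, "gstar_truth"))
write_field(phantom$region_labels, file.path(img_out, "region_labels.tsv"))
write_field(field$u, file.path(img_out, "wavefield"))
for (d in seq_len(protocol$n_dynamics)) {
  write_field(pos$phase[, , d], file.path(img_out, sprintf("phase_pos_d%02d.tsv", d)))
  write_field(neg$phase[, , d], file.path(img_out, sprintf("phase_neg_d%02d.tsv", d)))
}

summary <- data.frame(
  quantity = c("parenchyma_px", "hippocampus_px", "max_abs_u_m",
               "peak_encoded_phase_rad", "pixels_per_wavelength_hip"),
  value = c(sum(phantom$region_labels == 1), sum(phantom$region_labels == 2),
            max(Mod(field$u)), max(abs(pos$phase)),
            sqrt(Mod(4608 + 1388i) / 1000) / 900 / phantom$pixel_spacing))
write.csv(summary, "results/01_simulation_summary.csv", row.names = FALSE)

cat("Simulated acquisition written to", img_out, "\n")
print(summary, row.names = FALSE)
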