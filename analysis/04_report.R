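#!/usr/bin/env Rscript
# Step 4: report figures from the tidy result tables (no recomputation).
#
# Reads the TSVs written by steps 2-3 and renders summary figures with base
# graphics: per-band topography-style dot charts of the MTI-PRE z-score
# contrasts, boxplots of the per-recording HRV spectral features by period,
# and the EMG mean-frequency distribution by period.

res_dir <- "results/analysis"
if (!dir.exists(res_dir)) stop("run analysis/02_analyze.R first")
fig_dir <- "results/figures"
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

stats_eeg <- read.delim(file.path(res_dir, "stats_eeg.tsv"))
hrv <- read.delim(file.path(res_dir, "hrv.tsv"))
emg <- if (file.exists(file.path(res_dir, "emg.tsv"))) {
  read.delim(file.path(res_dir, "emg.tsv"))
} else NULL

pdf(file.path(fig_dir, "eeg_contrasts.pdf"), width = 8, height = 5)
mp <- stats_eeg[stats_eeg$contrast == "mti_pre", ]
bands <- unique(mp$band)
par(mfrow = c(1, length(bands)), mar = c(6, 3, 2, 0.5))
for (b in bands) {
  sub <- mp[mp$band == b, ]
  col <- ifelse(sub$significant, "red3", "grey40")
  plot(seq_len(nrow(sub)), sub$mean_change, pch = 19, col = col,
       xaxt = "n", xlab = "", ylab = "mean z change", main = b,
       ylim = range(mp$mean_change))
  abline(h = 0, lty = 3)
  axis(1, at = seq_len(nrow(sub)), labels = sub$channel, las = 2)
}
dev.off()

pdf(file.path(fig_dir, "hrv_spectral.pdf"), width = 8, height = 3.5)
par(mfrow = c(1, 3))
for (feat in c("LF", "HF", "LF_HF")) {
  sub <- hrv[hrv$feature == feat, ]
  boxplot(value ~ factor(period, c("pre", "mti", "post")), data = sub,
          xlab = "", ylab = feat, main = feat)
}
dev.off()

if (!is.null(emg)) {
  pdf(file.path(fig_dir, "emg_mnf.pdf"), width = 4, height = 3.5)
  sub <- emg[emg$feature == "mnf", ]
  boxplot(value ~ factor(period, c("pre", "mti", "post")), data = sub,
          xlab = "", ylab = "MNF (Hz)", main = "EMG mean frequency")
  dev.off()
}

cat("figures written to", fig_dir, "\n")
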