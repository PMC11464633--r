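#!/usr/bin/env Rscript
# Step 3: clinical scores.
#
# Recomputes the pain (VAS, one pre/post pair per recording session) and
# anxiety-depression (HADS, first vs last timepoint per patient) summaries
# from the study's per-patient score table shipped with the package, with
# permutation p-values and the minimal-clinically-important-difference flags
# (1.4 VAS points, 1.7 HADS points).

library(marphysio)

tab <- study_clinical_table()
demo <- summarize_demographics(tab)
vas <- summarize_vas(tab, seed = 1)
hads <- summarize_hads(tab, seed = 1)

cat(sprintf("patients: %d, mean age %.1f (range %d-%d), %.1f%% male\n",
            demo$n_patients, demo$mean_age, demo$age_range[1],
            demo$age_range[2], demo$sex_percent[["Male"]]))
cat(sprintf("VAS (n = %d sessions): PRE %.2f, POST %.2f, change %.3f (SD %.2f), p = %.2f, MCID reached: %s\n",
            vas$n_sessions, vas$pre$mean, vas$post$mean, vas$change$mean,
            vas$change$sd, vas$p, vas$mcid_reached))
for (scale in c("anxiety", "depression", "total")) {
  s <- hads[[scale]]
  cat(sprintf("HADS %-10s first %.3f, last %.3f, change %.3f (SD %.2f), p = %.3f, MCID reached: %s\n",
              scale, s$first_mean, s$last_mean, s$change_mean, s$change_sd,
              s$p, s$mcid_reached))
}
cat(sprintf("(%d patient(s) excluded from HADS: missing last timepoint)\n",
            hads$n_excluded))

summary_tab <- rbind(
  data.frame(scale = "vas", timepoint = c("pre", "post"),
             mean = c(vas$pre$mean, vas$post$mean),
             change_mean = vas$change$mean, change_sd = vas$change$sd,
             p = vas$p, n = vas$n_sessions),
  do.call(rbind, lapply(c("anxiety", "depression", "total"), function(sc) {
    s <- hads[[sc]]
    data.frame(scale = paste0("hads_", sc), timepoint = c("first", "last"),
               mean = c(s$first_mean, s$last_mean),
               change_mean = s$change_mean, change_sd = s$change_sd,
               p = s$p, n = hads$n_included)
  })))
write_results(list(clinical_summary = summary_tab), "results",
              overwrite = TRUE, seed = 1)
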