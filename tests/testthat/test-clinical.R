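test_that("demographic summaries reproduce the study's printed values", {
  tab <- study_clinical_table()
  d <- summarize_demographics(tab)
  expect_equal(d$mean_age, 33.6)
  expect_equal(d$age_range, c(18, 65))
  expect_equal(unname(d$sex_percent["Male"]), 88.9)
  expect_equal(d$n_patients, 9)
  # single patient: mean equals that age
  one <- tab; one$patients <- one$patients[3, ]; one$sessions <- one$sessions[5, ]
  expect_equal(summarize_demographics(one)$mean_age, 65)
})

test_that("VAS summaries reproduce the study's printed values", {
  tab <- study_clinical_table()
  v <- summarize_vas(tab, seed = 1)
  expect_equal(v$n_sessions, 17)
  expect_equal(v$pre$mean, 2.0)
  expect_equal(v$post$mean, 1.24, tolerance = 0.005)
  expect_equal(v$change$mean, -0.764, tolerance = 0.001)
  expect_equal(v$change$sd, 1.55, tolerance = 0.01)
  expect_false(v$mcid_reached)                     # |0.76| < 1.4
  expect_gt(v$p, 0.05)                             # no significant difference
  # constructed arithmetic example
  toy <- list(sessions = data.frame(patient = 1:2, session = 1,
                                    vas_pre = c(2, 4), vas_post = c(1, 1)),
              patients = study_clinical_table()$patients[1:2, ])
  expect_equal(summarize_vas(toy)$change$mean, -2)
  # all pre == post: zero change, p = 1
  same <- list(sessions = data.frame(patient = 1:3, session = 1,
                                     vas_pre = c(2, 3, 4),
                                     vas_post = c(2, 3, 4)),
               patients = study_clinical_table()$patients[1:3, ])
  vs <- summarize_vas(same)
  expect_equal(vs$change$mean, 0)
  expect_equal(vs$p, 1)
})

test_that("HADS summaries reproduce the study's printed values", {
  tab <- study_clinical_table()
  h <- summarize_hads(tab, seed = 1)
  expect_equal(h$n_included, 8)
  expect_equal(h$n_excluded, 1)
  expect_equal(h$anxiety$first_mean, 5.875)
  expect_equal(h$anxiety$last_mean, 4.0)
  expect_equal(h$anxiety$change_mean, -1.875)
  expect_equal(h$depression$first_mean, 3.75)
  expect_equal(h$depression$last_mean, 2.125)
  expect_equal(h$depression$change_mean, -1.625)
  expect_equal(h$total$first_mean, 9.625)
  expect_equal(h$total$last_mean, 6.125)
  expect_equal(h$total$change_mean, -3.5)
  expect_true(h$total$mcid_reached)                # 3.5 >= 1.7
  expect_gt(h$total$p, 0.05)
  # linearity: total summaries equal the sum of the subscales exactly
  expect_identical(h$total$first_mean,
                   h$anxiety$first_mean + h$depression$first_mean)
  expect_identical(h$total$change_mean,
                   h$anxiety$change_mean + h$depression$change_mean)
})

test_that("summaries are invariant to patient row order and flag MCID thresholds", {
  tab <- study_clinical_table()
  shuf <- tab
  set.seed(2)
  shuf$patients <- shuf$patients[sample(nrow(shuf$patients)), ]
  shuf$sessions <- shuf$sessions[sample(nrow(shuf$sessions)), ]
  expect_equal(summarize_hads(shuf, seed = 1)$total$change_mean,
               summarize_hads(tab, seed = 1)$total$change_mean)
  expect_equal(summarize_vas(shuf, seed = 1)$change$mean,
               summarize_vas(tab, seed = 1)$change$mean)
  # uniform +1 change per subscale -> total change 2 crosses the 1.7 MCID
  unif <- tab
  unif$patients$hads_anx_last <- unif$patients$hads_anx_first + 1
  unif$patients$hads_dep_last <- unif$patients$hads_dep_first + 1
  expect_true(summarize_hads(unif)$total$mcid_reached)    # 2 >= 1.7
  expect_false(summarize_hads(unif)$anxiety$mcid_reached) # 1 < 1.7
})

test_that("clinical tables validate their score ranges", {
  tab <- study_clinical_table()
  bad <- tab; bad$sessions$vas_pre[1] <- 11
  expect_error(summarize_vas(bad), "VAS")
  bad2 <- tab; bad2$patients$hads_anx_first[1] <- 25
  expect_error(summarize_hads(bad2), "HADS")
  bad3 <- tab; bad3$patients$severity[1] <- 4
  expect_error(summarize_demographics(bad3), "severity")
})

test_that("the synthetic clinical generator honours exact shifts and missingness", {
  # noiseless shift of -2 on every POST VAS, away from the clipping bounds
  g <- suppressWarnings(
    gen_clinical_table(n_patients = 6, vas_shift = -2, vas_noise_sd = 0,
                       vas_pre_mean = 6, seed = 7))
  ok <- g$sessions$vas_pre >= 2          # sessions untouched by clipping
  expect_gt(sum(ok), 6)
  expect_equal(mean(g$sessions$vas_post[ok] - g$sessions$vas_pre[ok]), -2)
  # one of nine patients missing the last HADS timepoint
  g9 <- suppressWarnings(
    gen_clinical_table(n_patients = 9, missing_last_frac = 1 / 9, seed = 4))
  h <- summarize_hads(g9)
  expect_equal(h$n_included, 8)
  expect_equal(h$n_excluded, 1)
  # determinism and range clipping
  expect_identical(suppressWarnings(gen_clinical_table(seed = 5)),
                   suppressWarnings(gen_clinical_table(seed = 5)))
  expect_warning(gen_clinical_table(n_patients = 8, vas_shift = -9,
                                    vas_noise_sd = 0, seed = 6), "clipped")
})
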