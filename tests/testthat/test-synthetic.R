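test_that("compound panels are reproducible and honor configured ranges", {
  p1 <- gen_compound_panel(34, seed = 7)
  p2 <- gen_compound_panel(34, seed = 7)
  expect_identical(attr(p1, "panel"), attr(p2, "panel"))
  expect_length(p1, 34)

  tab <- attr(p1, "panel")
  expect_true(all(tab$logp >= 1.4 & tab$logp <= 4.5))
  expect_true(all(tab$fup >= 0.05 & tab$fup <= 0.35))
  expect_true(all(tab$rbp >= 0.8 & tab$rbp <= 1.1))
  expect_true(all(tab$pka >= 7.5 & tab$pka <= 9.5))

  p3 <- gen_compound_panel(34, seed = 8)
  expect_false(identical(attr(p3, "panel")$logp, tab$logp))

  narrow <- attr(gen_compound_panel(20, seed = 1, logp_range = c(2, 2.5)),
                 "panel")
  expect_true(all(narrow$logp >= 2 & narrow$logp <= 2.5))
  expect_error(gen_compound_panel(0, seed = 1), ">= 1")
  expect_error(gen_compound_panel(5, seed = 1, fup_range = c(0.5, 0.1)),
               "invalid range")
})

test_that("default panel ranges cover the published analog property values", {
  # acetylfentanyl: logP 3.55, fup 16.8%, rbp 0.83
  expect_true(3.55 >= 1.4 && 3.55 <= 4.5)
  tab <- attr(gen_compound_panel(34, seed = 7), "panel")
  expect_true(min(tab$fup) < 0.168 && max(tab$fup) > 0.168)
  expect_true(min(tab$rbp) < 0.83 + 0.1)  # 0.83 sits inside [0.8, 1.1]
  cp <- acetylfentanyl_human
  expect_true(cp$logp >= 1.4 && cp$logp <= 4.5)
  expect_true(cp$fup >= 0.05 && cp$fup <= 0.35)
  expect_true(cp$rbp >= 0.8 - 1e-9 && cp$rbp <= 1.1)
})

test_that("zero assay noise reproduces the simulation at the schedule exactly", {
  m <- build_model(phys_rat, bht_rat, kp_bht, dose_regimen(per_kg = 7))
  study <- gen_observed_study(m, noise_cv = 0, n_subjects = 2, seed = 3)
  sim <- study$truth$sim
  truth <- stats::approx(sim$time, sim$conc["plasma", ],
                         xout = study$schedule)$y
  for (obs in study$observed) {
    expect_equal(obs$conc, truth, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("study generation is seed-deterministic", {
  m <- build_model(phys_rat, bht_rat, kp_bht, dose_regimen(per_kg = 7))
  s1 <- gen_observed_study(m, noise_cv = 0.2, n_subjects = 3, seed = 5)
  s2 <- gen_observed_study(m, noise_cv = 0.2, n_subjects = 3, seed = 5)
  s3 <- gen_observed_study(m, noise_cv = 0.2, n_subjects = 3, seed = 6)
  for (i in 1:3) {
    expect_identical(s1$observed[[i]]$conc, s2$observed[[i]]$conc)
  }
  expect_false(identical(s1$observed[[1]]$conc, s3$observed[[1]]$conc))
})

test_that("lognormal noise has median one: geometric mean ratio within 2% at n=500", {
  m <- build_model(phys_rat, bht_rat, kp_bht, dose_regimen(per_kg = 7))
  study <- gen_observed_study(m, noise_cv = 0.15, n_subjects = 500, seed = 42)
  sim <- study$truth$sim
  truth <- stats::approx(sim$time, sim$conc["plasma", ],
                         xout = study$schedule)$y
  post <- study$schedule > 0
  ratios <- sapply(study$observed, function(obs) obs$conc[post] / truth[post])
  geo <- exp(rowMeans(log(ratios)))
  expect_true(all(abs(geo - 1) < 0.02))
})

test_that("observations below the quantification limit are dropped, not zeroed", {
  m <- build_model(phys_rat, bht_rat, kp_bht, dose_regimen(per_kg = 7))
  study <- gen_observed_study(m, noise_cv = 0, n_subjects = 1, seed = 1,
                              lloq = 100)
  obs <- study$observed[[1]]
  expect_true(all(obs$conc >= 100))
  expect_lt(length(obs$time), length(study$schedule))
})

test_that("end-to-end recovery: most subjects' AUC within 2-fold of truth at CV 0.25", {
  m <- build_model(phys_rat, bht_rat, kp_bht, dose_regimen(per_kg = 7))
  study <- gen_observed_study(m, noise_cv = 0.25, n_subjects = 200, seed = 17)
  truth_auc <- study$truth$nca$auc_0_inf
  fe <- vapply(study$observed, function(obs) {
    fold_error(nca_iv(obs)$auc_0_inf, truth_auc)$fold_error
  }, numeric(1))
  expect_gte(mean(fe <= 2), 0.95)
  # and against the noise-free sparse-design AUC the median fold error
  # converges to 1 as the assay noise vanishes
  sparse_truth <- nca_iv(gen_observed_study(m, noise_cv = 0,
                                            n_subjects = 1,
                                            seed = 1)$observed[[1]])$auc_0_inf
  for (cv in c(0.1, 0.01)) {
    study_cv <- gen_observed_study(m, noise_cv = cv, n_subjects = 50, seed = 17)
    fe_cv <- vapply(study_cv$observed, function(obs) {
      fold_error(nca_iv(obs)$auc_0_inf, sparse_truth)$fold_error
    }, numeric(1))
    expect_lt(stats::median(fe_cv) - 1, 5 * cv)
  }
})
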