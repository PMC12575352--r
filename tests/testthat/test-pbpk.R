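test_that("build_model resolves doses and validates components", {
  m <- build_model(phys_rat, bht_rat, kp_bht, dose_regimen(per_kg = 7))
  expect_equal(m$regimen$amount_ug, 1.75)     # 7 ug/kg x 0.25 kg
  m2 <- build_model(phys_human, fentanyl_human, kp_fent_human_qsar,
                    dose_regimen(amount = 100))
  expect_equal(m2$regimen$amount_ug * 1e6, 1e8)  # 0.1 mg = 1e8 pg
  expect_error(build_model(phys_human, bht_rat, kp_fent_human_qsar,
                           dose_regimen(amount = 1)), "species mismatch")
  expect_error(dose_regimen(), "required")
  expect_error(dose_regimen(amount = -1), "positive")
})

test_that("with zero clearance mass is conserved and tissues equilibrate to Kp", {
  cmp0 <- with_clsys(bht_rat, 0)
  m <- build_model(phys_rat, cmp0, kp_bht, dose_regimen(amount = 1.75))
  sim <- simulate_pbpk(m, t_end = 48, n_points = 241)
  expect_lt(sim$mass_balance_error, 1e-3)
  c_blood <- sim$conc["venous_blood", ncol(sim$conc)]
  ratio <- sim$conc[kp_tissues(), ncol(sim$conc)] / c_blood
  expect_true(all(abs(ratio - kp_bht$kp) / kp_bht$kp < 0.005))
})

test_that("simulated exposure obeys AUC x CL = Dose within 1%", {
  m <- build_model(phys_human, fentanyl_human, kp_fent_human_qsar,
                   dose_regimen(amount = 100))
  sim <- simulate_pbpk(m, t_end = 72)
  nca <- nca_iv(sim_profile(sim))
  expect_equal(nca$cl, fentanyl_human$clsys, tolerance = 0.01)
  expect_equal(nca$auc_0_inf, auc_inf_iv(100, fentanyl_human$clsys),
               tolerance = 0.01)
})

test_that("the model is linear in dose", {
  m1 <- build_model(phys_rat, bht_rat, kp_bht, dose_regimen(amount = 1.75))
  m2 <- build_model(phys_rat, bht_rat, kp_bht, dose_regimen(amount = 3.5))
  s1 <- simulate_pbpk(m1, t_end = 4)
  s2 <- simulate_pbpk(m2, t_end = 4)
  sel <- s1$conc > 1e-6 * max(s1$conc)
  expect_equal(s2$conc[sel] / s1$conc[sel], rep(2, sum(sel)),
               tolerance = 1e-6)
})

test_that("NCA Vss from a noise-free simulation matches the algebraic value within 2%", {
  m <- build_model(phys_human, fentanyl_human, kp_fent_human_qsar,
                   dose_regimen(amount = 100))
  sim <- simulate_pbpk(m, t_end = 72)
  nca <- nca_iv(sim_profile(sim))
  v_alg <- vss_algebraic(kp_fent_human_qsar, phys_human, fentanyl_human$rbp)
  expect_equal(nca$vss, v_alg, tolerance = 0.02)
})

test_that("algebraic Vss definition and linearity", {
  expect_equal(vss_algebraic(uniform_kp(1), phys_rat, 1),
               sum(phys_rat$compartments$volume_L))
  v1 <- vss_algebraic(uniform_kp(2, species = "human"), phys_human, 1)
  v_blood <- sum(phys_volume(phys_human, c("arterial_blood", "venous_blood")))
  v2 <- vss_algebraic(uniform_kp(4, species = "human"), phys_human, 1)
  expect_equal(v2 - v_blood, 2 * (v1 - v_blood), tolerance = 1e-12)
})

test_that("uniform-Kp model matches the one-compartment closed form after mixing", {
  # clearance well below cardiac output, the regime where the
  # instantaneous-mixing approximation behind the closed form holds
  cmp <- compound_properties("onecpt", logp = 1, fup = 0.5, rbp = 1,
                             clsys = 0.02, species = "rat")
  m <- build_model(phys_rat, cmp, uniform_kp(1), dose_regimen(amount = 10))
  sim <- simulate_pbpk(m, t_end = 12, n_points = 961)
  v_tot <- sum(phys_rat$compartments$volume_L)
  keep <- sim$time > 0.5                      # past the distribution transient
  pred <- 1000 * 10 / v_tot * exp(-0.02 * sim$time[keep] / v_tot)
  expect_equal(sim$conc["plasma", keep], pred, tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("terminal half-life is invariant to the output grid within 1%", {
  m <- build_model(phys_rat, bht_rat, kp_bht, dose_regimen(amount = 1.75))
  th <- vapply(c(121, 241, 961), function(np) {
    nca_iv(sim_profile(simulate_pbpk(m, t_end = 4, n_points = np)))$t_half
  }, numeric(1))
  expect_lt(max(abs(th - th[2]) / th[2]), 0.01)
})

test_that("plasma is the venous series divided by the blood:plasma ratio", {
  m <- build_model(phys_human, acetylfentanyl_human,
                   predict_kp_composition(acetylfentanyl_human),
                   dose_regimen(amount = 100))
  sim <- simulate_pbpk(m)
  expect_equal(sim$conc["plasma", ],
               sim$conc["venous_blood", ] / acetylfentanyl_human$rbp)
})

test_that("hepatic clearance site eliminates via liver outflow", {
  cmp <- with_clsys(bht_rat, 0.9)
  m <- build_model(phys_rat, cmp, kp_bht, dose_regimen(amount = 1.75),
                   clearance_site = "liver")
  sim <- simulate_pbpk(m, t_end = 24)
  nca <- nca_iv(sim_profile(sim))
  expect_lt(sim$mass_balance_error, 1e-3)
  # well-stirred liver: the systemic plasma clearance that emerges is
  # rbp * Qh * CLb / (Qh + CLb), below the venous-site value
  clb <- 0.9 / bht_rat$rbp
  qh <- sum(phys_flow(phys_rat, c("liver", "spleen")))
  expect_equal(nca$cl, bht_rat$rbp * qh * clb / (qh + clb), tolerance = 0.02)
  expect_lt(nca$cl, 0.9)
})
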