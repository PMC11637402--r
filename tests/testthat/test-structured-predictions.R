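test_that("neutral F_ST predictions reproduce the three differentiation
           regimes and reduce to the standard island-model form", {
  expect_equal(predict_fst(island_params(10, 500, 0.00045), 1), 0.50,
               tolerance = 0.01)
  expect_equal(predict_fst(island_params(10, 500, 0.009), 1), 0.05,
               tolerance = 0.1)
  expect_equal(predict_fst(island_params(10, 500, 0.09), 1), 0.004,
               tolerance = 0.1)

  # m -> 0: the order-of-events corrections vanish
  isl <- island_params(10, 500, 1e-6)
  std <- 1 / (1 + 4 * 500 * 1e-6 * 10 / 9)
  expect_equal(predict_fst(isl, 1), std, tolerance = 1e-3)

  # smaller N_e,local (stronger background selection) inflates F_ST
  isl2 <- island_params(10, 500, 0.009)
  expect_gt(predict_fst(isl2, 0.5), predict_fst(isl2, 1))

  expect_error(predict_fst(island_params(1, 500, 0), 1), "d >= 2")
  expect_error(predict_fst(island_params(10, 500, 0), 1), "m > 0")
  expect_error(predict_fst(isl2, 1.5), "0, 1")
})

test_that("G_ST is bounded by Hudson F_ST and responds to B the same way", {
  isl <- island_params(10, 500, 0.00045)
  g <- predict_gst(isl, 1)
  expect_lt(g, predict_fst(isl, 1))
  expect_gt(g, 0.4)
  expect_lt(g, 0.5)
  expect_gt(predict_gst(isl, 0.5), g)
  for (m in c(0.001, 0.01, 0.09)) {
    i <- island_params(10, 500, m)
    expect_lt(predict_gst(i, 0.7), predict_fst(i, 0.7))
  }
  expect_error(predict_gst(island_params(10, 500, 0), 1), "m > 0")
})

test_that("two-island haploid approximation has its closed-form values and
           limits", {
  # 4 B N m = 1 -> 0.5
  expect_equal(predict_fst_two_island_haploid(500, 1, 5e-4), 0.5,
               tolerance = 1e-12)
  expect_equal(predict_fst_two_island_haploid(500, 0.5, 0.001), 0.5,
               tolerance = 1e-12)
  # B -> 0: complete differentiation
  expect_gt(predict_fst_two_island_haploid(500, 1e-9, 0.001), 0.999)
})

test_that("global effective size inflates with structure", {
  isl <- island_params(10, 500, 0.009)
  expect_identical(global_effective_size(isl, 0), 5000)
  expect_equal(global_effective_size(isl, 0.5), 10000, tolerance = 1e-12)
  g <- seq(0, 0.9, by = 0.1)
  ne <- vapply(g, global_effective_size, numeric(1), island = isl)
  expect_true(all(diff(ne) > 0))
  expect_error(global_effective_size(isl, 1), "0, 1")
})

test_that("diversity pipeline: panmictic neutral saturating value, diversity
           orderings, and structure inflating neutral total diversity", {
  seg0 <- selection_segment(t = 0.01, U = 0, L = 700, M = 0)
  neu <- neutral_region(1e-5, 1e4)

  # single panmictic deme of 5000, neutral: pi = 0.2/1.2
  p1 <- predict_pi(island_params(1, 5000, 0), seg0, neu)
  expect_equal(p1$pi_T_pred, 0.2 / 1.2, tolerance = 1e-10)
  expect_equal(p1$pi_T_pred, p1$pi_T_neutral, tolerance = 1e-10)

  # structured neutral metapopulation at the same N_global: G_ST > 0
  # inflates N_e,global and hence pi_T
  p10 <- predict_pi(island_params(10, 500, 0.00045), seg0, neu)
  expect_gt(p10$pi_T_neutral, p1$pi_T_neutral)

  # under selection: orderings pi_S <= pi_T <= pi_B, G <= F
  seg <- ref_segment(0.01)
  p <- predict_pi(island_params(10, 500, 0.00045), seg, neu)
  expect_lte(p$pi_S_pred, p$pi_T_pred)
  expect_lte(p$pi_T_pred, p$pi_B_pred)
  expect_lte(p$G_ST_pred, p$F_ST_pred)
  expect_gt(p$G_ST_pred, 0)
  expect_lt(p$F_ST_pred, 1)
  expect_gte(p$N_e_global, p$island$N_global)
  expect_lte(p$B_global, 1)
  # background selection reduces every diversity level
  expect_lt(p$pi_T_pred, p$pi_T_neutral)
  expect_lt(p$pi_S_pred, p$pi_S_neutral)
})

test_that("the migration effect drives the F_ST prediction toward the neutral
           curve as m grows", {
  gaps <- vapply(c(0.001, 0.01, 0.03, 0.09), function(m) {
    isl <- island_params(10, 500, m)
    fit <- solve_local_equilibrium(isl, ref_segment(0.015))
    predict_fst(isl, fit$B_local_het) - predict_fst(isl, 1)
  }, numeric(1))
  expect_true(all(gaps > 0))
  expect_true(all(diff(gaps) < 0))
})

test_that("the fitted model object exposes the standard methods", {
  # near-zero migration: the solver sits close to the classic
  # deterministic B, and never below it
  fit <- bgs_island_model(d = 10, N_local = 500, m = 0.00045,
                          t = 0.015, U = 7e-3, M = 0)
  co <- coef(fit)
  expect_named(co, c("B_local", "B_local_het", "N_f_local", "N_eH_local",
                     "R", "B_classic"))
  expect_equal(unname(co["B_local"] / co["B_classic"]), 1, tolerance = 0.1)
  expect_gte(co[["B_local"]], co[["B_classic"]])

  p <- predict(fit)
  expect_s3_class(p, "metapop_prediction")
  # the fitness-size variant predicts more differentiation than the
  # heterozygosity variant (smaller B)
  pf <- predict(fit, which_B = "fitness")
  expect_gt(pf$F_ST_pred, p$F_ST_pred)

  expect_output(print(fit), "B_local")
  expect_output(print(summary(fit)), "pi_T")

  # simulate method: scaled-down run preserving 4Nm and 4Nmu
  reps <- simulate(fit, nsim = 2, seed = 3, scale = 25,
                   generations = 100, L_neutral = 20)
  expect_identical(nrow(reps), 2L)
  expect_true(all(is.finite(reps$pi_T)))

  # plot method returns the plotted theory curve invisibly
  grDevices::pdf(NULL)
  df <- plot(fit, m_grid = c(0.005, 0.02, 0.09))
  grDevices::dev.off()
  expect_identical(nrow(df), 3L)
  expect_true(all(df$F_bgs >= df$F_neutral))
})
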