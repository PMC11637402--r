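test_that("classic deterministic B matches its closed forms, and the site sum
           agrees with the region form for unlinked sites", {
  # empty region: no selection, no reduction
  expect_identical(classic_B_site_sum(numeric(0), numeric(0), numeric(0)), 1)

  # single fully linked site
  expect_equal(classic_B_site_sum(1e-5, 0.015, 0), exp(-1e-5 / 0.015),
               tolerance = 1e-12)

  # 700 fully linked sites equal the region form with U = 7e-3, M = 0
  expect_equal(
    classic_B_site_sum(rep(1e-5, 700), 0.015, 0),
    classic_B_region(U = 7e-3, t = 0.015, M = 0),
    tolerance = 1e-12
  )
  expect_equal(classic_B_region(7e-3, 0.015, 0), exp(-0.014 / 0.03),
               tolerance = 1e-12)
  expect_equal(classic_B_region(7e-3, 0.015, 0.01), exp(-0.014 / 0.04),
               tolerance = 1e-12)

  expect_identical(classic_B_region(0, 0.015, 0), 1)
  expect_error(classic_B_site_sum(1e-5, 0, 0), "t > 0")
  expect_error(classic_B_region(7e-3, 0, 0), "2t \\+ M")
})

test_that("decay factor Z has the strong-selection limit and the drift clamp", {
  z0 <- decay_factor_Z(U = 7e-3, t = 0.015, R = 0)
  expect_equal(as.numeric(z0), 1 - 0.015, tolerance = 1e-12)
  expect_false(attr(z0, "drift_dominated"))

  # weak selection with appreciable fixation
  z <- decay_factor_Z(U = 7e-3, t = 5e-4, R = 3e-3)
  expect_equal(as.numeric(z), 1 - (7e-3 * 5e-4) / (7e-3 - 6e-3),
               tolerance = 1e-12)

  # fixation at half the mutation rate or more: association gone in one
  # generation, flagged as drift dominated
  zc <- decay_factor_Z(U = 7e-3, t = 5e-4, R = 3.5e-3)
  expect_identical(as.numeric(zc), 0)
  expect_true(attr(zc, "drift_dominated"))

  expect_error(decay_factor_Z(0, 0.01, 0), "'U' must be > 0")
})

test_that("point linkage inflation factor equals the squared geometric series
           and is shrunk by migration", {
  expect_identical(q_infinity_sq_point(r = 0.1, Z = 0, m = 0), 1)
  expect_equal(q_infinity_sq_point(0, 1 - 0.015, 0), (1 / 0.015)^2,
               tolerance = 1e-12)
  expect_equal(q_infinity_sq_point(0, 1 - 0.015, 0.09),
               (1 / (1 - 0.985 * 0.91))^2, tolerance = 1e-12)

  # independent oracle: truncated geometric sum of the autocorrelation
  for (prm in list(c(0, 0.985, 0), c(0.004, 0.97, 0.02), c(0.01, 0.9, 0.1))) {
    a <- prm[2] * (1 - prm[1]) * (1 - prm[3])
    direct <- sum(a^(0:20000))^2
    expect_equal(q_infinity_sq_point(prm[1], prm[2], prm[3]), direct,
                 tolerance = 1e-10)
  }

  # migration shrinks the association
  expect_lt(q_infinity_sq_point(0, 0.985, 0.09),
            q_infinity_sq_point(0, 0.985, 0))
  expect_error(q_infinity_sq_point(0, 1, 0), "must lie in")
})

test_that("region-averaged linkage inflation matches quadrature of the point
           form and reduces to the point value at M = 0", {
  expect_equal(q_infinity_sq_region(0, 0.985, 0),
               q_infinity_sq_point(0, 0.985, 0), tolerance = 1e-12)

  for (M in c(1e-4, 1e-3, 0.01, 0.1)) {
    for (Z in c(0.9, 0.99, 0.9999)) {
      for (m in c(0, 0.01, 0.1)) {
        closed <- q_infinity_sq_region(M, Z, m)
        quad <- stats::integrate(
          function(r) q_infinity_sq_point(r, Z, m),
          0, M / 2, rel.tol = 1e-10, abs.tol = 0
        )$value / (M / 2)
        expect_equal(closed, quad, tolerance = 1e-6)
      }
    }
  }
  expect_error(q_infinity_sq_region(0.01, 1, 0), "must lie in")
})

test_that("fixation rate interpolates from the neutral limit to zero and is
           continuous and monotone", {
  # t -> 0: all mutations eventually fix, at the gametic mutation rate
  expect_identical(fixation_rate(500, 7e-3, 0), 7e-3)
  expect_equal(fixation_rate(500, 7e-3, 1e-12), 7e-3, tolerance = 1e-8)

  expect_equal(fixation_rate(500, 7e-3, 0.015), 0.21 / (exp(30) - 1),
               tolerance = 1e-10)

  # effectively no fixation under strong selection
  expect_lt(fixation_rate(5000, 7e-3, 0.015), 1e-100)

  # strictly decreasing in N_f * t
  Nf <- c(5, 50, 500, 5000)
  r <- vapply(Nf, fixation_rate, numeric(1), U = 7e-3, t = 1e-3)
  expect_true(all(diff(r) < 0))
  expect_true(all(r >= 0 & r <= 7e-3))
})

test_that("local equilibrium: neutral limit exact, strong selection agrees with
           classic theory, migration raises B, mutation lowers B", {
  isl <- island_params(d = 10, N_local = 500, m = 0)

  # no selection: no reduction, neutral fixation rate
  neutral <- solve_local_equilibrium(
    isl, selection_segment(t = 0.015, U = 0, L = 700, M = 0)
  )
  expect_identical(neutral$B_local, 1)
  expect_identical(neutral$R, 0)
  expect_identical(neutral$B_local_het, 1)

  # strong selection (N_local t = 7.5): within 10% of the deterministic form
  fit <- solve_local_equilibrium(isl, ref_segment(0.015))
  expect_true(fit$converged)
  expect_equal(fit$B_local, classic_B_region(7e-3, 0.015, 0), tolerance = 0.1)

  # ordering N_f <= N_eH <= N
  expect_true(fit$B_local <= fit$B_local_het)
  expect_true(fit$B_local_het <= 1)
  expect_true(fit$R <= 7e-3)

  # migration effect: B_local non-decreasing in m
  B_m <- vapply(c(0, 0.001, 0.01, 0.09), function(m) {
    solve_local_equilibrium(island_params(10, 500, m), ref_segment(0.015),
                            heterozygosity = FALSE)$B_local
  }, numeric(1))
  expect_true(all(diff(B_m) > 0))

  # with the migration effect disabled, m has no influence on B
  B_off <- solve_local_equilibrium(island_params(10, 500, 0.09),
                                   ref_segment(0.015),
                                   apply_migration_effect = FALSE,
                                   heterozygosity = FALSE)$B_local
  expect_equal(B_off, B_m[1], tolerance = 1e-8)

  # B_local non-increasing in U
  B_u <- vapply(c(1e-3, 7e-3, 2e-2), function(U) {
    solve_local_equilibrium(
      isl, selection_segment(t = 0.015, U = U, L = 700, M = 0),
      heterozygosity = FALSE
    )$B_local
  }, numeric(1))
  expect_true(all(diff(B_u) < 0))

  # recombination weakens background selection
  B_M <- solve_local_equilibrium(isl, ref_segment(0.015, M = 0.01),
                                 heterozygosity = FALSE)$B_local
  expect_gt(B_M, B_m[1])
})

test_that("heterozygosity-effective size lies strictly between the fitness
           size and the census size in the weak-selection corner", {
  # weak selection, tight linkage, low migration: the regime where the
  # age-resolved correction matters most
  isl <- island_params(d = 10, N_local = 500, m = 0.00045)
  fit <- solve_local_equilibrium(isl, ref_segment(5e-4))
  expect_gt(fit$B_local_het, fit$B_local)
  expect_lt(fit$B_local_het, 1)
  expect_gt(fit$N_eH_local, fit$N_f_local)
  expect_lt(fit$N_eH_local, isl$N_local)

  # moderate selection too
  fit2 <- solve_local_equilibrium(isl, ref_segment(0.01))
  expect_gt(fit2$B_local_het, fit2$B_local)
})

test_that("nearly-neutral selection collapses to B ~ 1 without exceeding the
           physical bound", {
  # tiny deme, tiny t: fixation removes almost all additive variance
  isl <- island_params(d = 10, N_local = 5, m = 0)
  fit <- solve_local_equilibrium(isl, ref_segment(1e-4))
  expect_true(fit$converged)
  expect_lte(fit$B_local, 1)
  expect_gt(fit$B_local, 0.99)
  # fixation rate close to the neutral substitution rate
  expect_gt(fit$R, 0.9 * 7e-3)
})
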