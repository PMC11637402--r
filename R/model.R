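#' Fit the background-selection island model
#'
#' The package's central constructor: given the demography of a finite
#' island model and the architecture of a selected region linked to a
#' neutral block, solves the quantitative-genetic background-selection
#' equilibrium ([solve_local_equilibrium()]) for the local strength of
#' background selection, with the migration effect, interference
#' rescaling and the heterozygosity-effective size. The returned object
#' carries everything needed to predict metapopulation differentiation
#' and diversity ([predict()][predict.bgs_island]) and to validate the
#' predictions by forward simulation ([simulate()][simulate.bgs_island]).
#'
#' @param d Number of demes.
#' @param N_local Diploid individuals per deme.
#' @param m Total immigrant fraction per deme per generation.
#' @param t Heterozygous selection coefficient of deleterious alleles.
#' @param U Gametic deleterious mutation rate over the selected region.
#' @param M Map length of the selected region in Morgans.
#' @param L_selected Number of selected sites (two equal flanks).
#' @param mu_neutral Neutral per-site mutation rate per gamete.
#' @param L_neutral Number of neutral sites.
#' @param apply_migration_effect Include the `(1-m)` association-ending
#'   term (the migration effect) in the local solve.
#' @param interference_rescale Rescale the reference size by `B` to
#'   approximate selective interference.
#'
#' @return An object of class `"bgs_island"` with components `island`,
#'   `segment`, `neutral`, `layout`, `local` (the `"bgs_local"` fit) and
#'   `call`. Methods: `print`, `summary`, `coef`, `predict`, `simulate`,
#'   `plot`.
#' @examples
#' fit <- bgs_island_model(d = 10, N_local = 500, m = 0.009,
#'                         t = 0.015, U = 7e-3, M = 0)
#' coef(fit)
#' predict(fit)
#' @export
bgs_island_model <- function(d = 10, N_local = 500, m = 0.009,
                             t = 0.015, U = 7e-3, M = 0,
                             L_selected = 700L,
                             mu_neutral = 1e-5, L_neutral = 1e4,
                             apply_migration_effect = TRUE,
                             interference_rescale = TRUE) {
  island <- island_params(d = d, N_local = N_local, m = m)
  segment <- selection_segment(t = t, U = U, L = L_selected, M = M)
  neutral <- neutral_region(mu_neutral = mu_neutral, L_neutral = L_neutral)
  layout <- genome_layout(L_neutral = L_neutral, L_selected = L_selected,
                          M = M)
  local <- solve_local_equilibrium(
    island, segment,
    apply_migration_effect = apply_migration_effect,
    interference_rescale = interference_rescale,
    heterozygosity = TRUE
  )
  structure(
    list(island = island, segment = segment, neutral = neutral,
         layout = layout, local = local, call = match.call()),
    class = "bgs_island"
  )
}

#' @export
print.bgs_island <- function(x, digits = 4, ...) {
  cat("Background selection in an island model\n\n")
  print(x$island); print(x$segment); print(x$neutral)
  cat(sprintf("\n  B_local = %.*g   B_local (heterozygosity) = %.*g\n",
              digits, x$local$B_local, digits, x$local$B_local_het))
  invisible(x)
}

#' Model coefficients: solved background-selection quantities
#'
#' @param object A `"bgs_island"` fit.
#' @param ... Unused.
#' @return Named numeric vector with `B_local`, `B_local_het`,
#'   `N_f_local`, `N_eH_local`, `R` and the classic deterministic
#'   `B_classic` for comparison.
#' @export
coef.bgs_island <- function(object, ...) {
  c(
    B_local = object$local$B_local,
    B_local_het = object$local$B_local_het,
    N_f_local = object$local$N_f_local,
    N_eH_local = object$local$N_eH_local,
    R = object$local$R,
    B_classic = classic_B_region(object$segment$U, object$segment$t,
                                 object$segment$M)
  )
}

#' Metapopulation predictions from a fitted model
#'
#' Runs the full prediction pipeline ([predict_pi()]) on the fitted
#' local equilibrium: F_ST, G_ST, global effective size, global B and
#' the diversity set (`pi_T`, `pi_S`, `pi_B`) with neutral baselines.
#'
#' @param object A `"bgs_island"` fit.
#' @param which_B Which local B feeds the F_ST/G_ST formulas:
#'   `"het"` (heterozygosity-effective, default) or `"fitness"`.
#' @param ... Unused.
#' @return A `"metapop_prediction"` object.
#' @export
predict.bgs_island <- function(object, which_B = c("het", "fitness"), ...) {
  which_B <- match.arg(which_B)
  solved <- object$local
  if (which_B == "fitness") {
    solved$B_local_het <- solved$B_local
    solved$N_eH_local <- solved$N_f_local
  }
  predict_pi(object$island, object$segments %||% list(object$segment),
             object$neutral, solved = solved)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate from a fitted background-selection island model
#'
#' Forward-simulates the fitted model's exact conditions (demes, sizes,
#' migration, selection, genome layout) and returns per-replicate summary
#' statistics. The default scale is the full reference design
#' (`50 N_global` generations); pass `scale` to shrink deme size (and
#' rescale the neutral mutation rate and migration to preserve local
#' `4 N mu` and `4 N m d/(d-1)`) for desk-scale runs.
#'
#' @param object A `"bgs_island"` fit.
#' @param nsim Number of replicates.
#' @param seed Master seed (integer) for reproducibility.
#' @param scale Deme-size scale-down factor `s >= 1`: simulates
#'   `N_local / s` individuals per deme with `mu_neutral * s`, `m * s`
#'   and `generations` shrunk accordingly.
#' @param generations Override the burn-in length.
#' @param L_neutral Override the simulated neutral site count.
#' @param ... Unused.
#' @return A data frame from [run_replicates()].
#' @export
simulate.bgs_island <- function(object, nsim = 1, seed = NULL, scale = 1,
                                generations = NULL, L_neutral = NULL, ...) {
  stopifnot(scale >= 1)
  isl0 <- object$island
  N <- max(2L, as.integer(round(isl0$N_local / scale)))
  s_eff <- isl0$N_local / N
  m <- min(isl0$m * s_eff, 0.999)
  island <- island_params(isl0$d, N, if (isl0$d > 1L) m else 0)
  lay0 <- object$layout
  layout <- genome_layout(
    L_neutral = L_neutral %||% lay0$L_neutral,
    L_selected = lay0$L_selected, M = lay0$M
  )
  cfg <- sim_config(
    island, layout,
    t = object$segment$t, U = object$segment$U,
    mu_neutral = object$neutral$mu_neutral * s_eff,
    generations = generations %||% (50L * island$N_global),
    replicates = nsim,
    master_seed = seed %||% sample.int(.Machine$integer.max - 1L, 1L)
  )
  run_replicates(cfg)
}

#' @export
summary.bgs_island <- function(object, ...) {
  pred <- predict(object)
  structure(list(fit = object, pred = pred), class = "summary.bgs_island")
}

#' @export
print.summary.bgs_island <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\n")
  print(x$pred, digits = digits)
  invisible(x)
}

#' Plot theory curves for a fitted model
#'
#' Predicted F_ST (and local B) as a function of the migration rate at
#' the fitted selection parameters, against the neutral expectation —
#' the migration-effect picture: as `m` grows past `t`, the prediction
#' under background selection collapses onto the neutral curve.
#'
#' @param x A `"bgs_island"` fit.
#' @param m_grid Migration rates to sweep.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the data frame of plotted values.
#' @export
plot.bgs_island <- function(x, m_grid = 10^seq(-4, -1, length.out = 25),
                            ...) {
  rows <- lapply(m_grid, function(m) {
    isl <- island_params(x$island$d, x$island$N_local, m)
    fit <- solve_local_equilibrium(isl, x$segment)
    data.frame(
      m = m, B_het = fit$B_local_het,
      F_bgs = predict_fst(isl, fit$B_local_het),
      F_neutral = predict_fst(isl, 1)
    )
  })
  df <- do.call(rbind, rows)
  graphics::plot(df$m, df$F_bgs, log = "xy", type = "b", pch = 16,
                 xlab = "migration rate m", ylab = expression(F[ST]),
                 ...)
  graphics::lines(df$m, df$F_neutral, lty = 2)
  graphics::legend("topright", bty = "n", lty = c(1, 2), pch = c(16, NA),
                   legend = c("with background selection", "neutral"))
  invisible(df)
}
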