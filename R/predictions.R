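#' Predicted equilibrium F_ST in a finite island model
#'
#' Hudson-definition F_ST (`1 - pi_S/pi_B`) expected at migration-drift
#' equilibrium in a finite island model whose local drift is governed by
#' `N_local * B_local`, with offspring production (drift) occurring before
#' migration and measurement taken after migration, retaining terms of
#' order `m^2`:
#' \deqn{F_{ST} = \left[1 + \frac{d(d-1)(4-2m)\,N_{local} B_{local}\, m}
#'   {(d(1-m)-1)^2}\right]^{-1}.}
#' As `m -> 0` this reduces to the familiar
#' `1/(1 + 4 N_e m d/(d-1))` island-model form.
#'
#' @param island An [island_params()] object with `d >= 2` and `m > 0`.
#' @param B_local Local background-selection strength in (0, 1]
#'   (1 = neutral).
#' @return Predicted F_ST in (0, 1).
#' @examples
#' isl <- island_params(d = 10, N_local = 500, m = 0.009)
#' predict_fst(isl) # ~0.05, moderate differentiation
#' @export
predict_fst <- function(island, B_local = 1) {
  stopifnot(inherits(island, "island_params"), length(B_local) == 1L)
  if (island$d < 2L) stop("F_ST prediction requires d >= 2")
  if (island$m <= 0) stop("F_ST prediction requires m > 0")
  if (!is.finite(B_local) || B_local <= 0 || B_local > 1) {
    stop("'B_local' must lie in (0, 1]")
  }
  d <- island$d; m <- island$m
  x <- d * (d - 1) * (4 - 2 * m) * island$N_local * B_local * m /
    (d * (1 - m) - 1)^2
  1 / (1 + x)
}

#' Predicted equilibrium G_ST in a finite island model
#'
#' As [predict_fst()] but for `G_ST = 1 - pi_S/pi_T` (differentiation
#' standardised by total rather than between-deme diversity):
#' \deqn{G_{ST} = \left[1 + \frac{d^2(4-2m)\,N_{local} B_{local}\, m}
#'   {(d(1-m)-1)^2}\right]^{-1}.}
#' Always `<=` the Hudson F_ST for the same parameters, since
#' `pi_T <= pi_B`.
#'
#' @inheritParams predict_fst
#' @return Predicted G_ST in (0, 1).
#' @export
predict_gst <- function(island, B_local = 1) {
  stopifnot(inherits(island, "island_params"), length(B_local) == 1L)
  if (island$d < 2L) stop("G_ST prediction requires d >= 2")
  if (island$m <= 0) stop("G_ST prediction requires m > 0")
  if (!is.finite(B_local) || B_local <= 0 || B_local > 1) {
    stop("'B_local' must lie in (0, 1]")
  }
  d <- island$d; m <- island$m
  x <- d^2 * (4 - 2 * m) * island$N_local * B_local * m /
    (d * (1 - m) - 1)^2
  1 / (1 + x)
}

#' Two-island haploid F_ST approximation
#'
#' The earlier two-island haploid approximation
#' `F_ST ~ 1/(4 B N_local m + 1)`, kept for comparison with the finite-
#' island diploid prediction of [predict_fst()].
#'
#' @param N_local Local population size.
#' @param B Background-selection strength in (0, 1].
#' @param m Migration rate (> 0).
#' @return F_ST in (0, 1).
#' @examples
#' predict_fst_two_island_haploid(N_local = 500, B = 0.5, m = 0.001) # 0.5
#' @export
predict_fst_two_island_haploid <- function(N_local, B = 1, m) {
  stopifnot(N_local > 0, B > 0, B <= 1, m > 0)
  1 / (4 * B * N_local * m + 1)
}

#' Global effective size of a structured metapopulation
#'
#' Population structure inflates the metapopulation's effective size:
#' \deqn{N_{e,global} = \frac{N_{global}}{1 - G_{ST}}.}
#'
#' @param island An [island_params()] object.
#' @param G_ST Differentiation (`1 - pi_S/pi_T`) in [0, 1).
#' @return Global effective number of diploids, `>= N_global`.
#' @examples
#' global_effective_size(island_params(10, 500, 0.009), G_ST = 0.5) # 10000
#' @export
global_effective_size <- function(island, G_ST) {
  stopifnot(inherits(island, "island_params"), length(G_ST) == 1L)
  if (!is.finite(G_ST) || G_ST < 0 || G_ST >= 1) {
    stop("'G_ST' must lie in [0, 1)")
  }
  island$N_global / (1 - G_ST)
}

# Global background-selection strength: the metapopulation treated as one
# panmictic unit of size N_e,global (interference rescaling on,
# heterozygosity variant).
global_B <- function(N_e_global, segments) {
  pan <- island_params(d = 1L, N_local = N_e_global, m = 0)
  fit <- solve_local_equilibrium(
    pan, segments,
    apply_migration_effect = TRUE, # no-op at m = 0
    interference_rescale = TRUE, heterozygosity = TRUE
  )
  fit$B_local_het
}

#' Metapopulation diversity and differentiation predictions
#'
#' Full prediction pipeline for an island model under background
#' selection: solve the local equilibrium ([solve_local_equilibrium()],
#' migration effect and interference rescaling on, heterozygosity
#' variant), turn `B_local` into predicted `G_ST` and `F_ST`
#' ([predict_gst()], [predict_fst()]), inflate to the global effective
#' size ([global_effective_size()]), evaluate the global
#' background-selection strength `B_global` at that size, and predict
#' total diversity with the saturating infinite-alleles form
#' \deqn{\pi_T = \frac{4 N_{e,global} B_{global} \mu}
#'   {1 + 4 N_{e,global} B_{global} \mu},}
#' with `pi_S = pi_T (1 - G_ST)` and `pi_B = pi_S / (1 - F_ST)`. The same
#' pipeline with `U = 0` gives the neutral baselines.
#'
#' @param island An [island_params()] object.
#' @param segments A [selection_segment()] or list of them.
#' @param neutral A [neutral_region()] object (per-site rate `mu_neutral`).
#' @param solved Optionally, a pre-computed `"bgs_local"` fit (with
#'   heterozygosity variant) to reuse.
#' @return An object of class `"metapop_prediction"`: a list with
#'   `F_ST_pred`, `G_ST_pred`, `N_e_global`, `B_global`, `B_local`,
#'   `B_local_het`, `pi_T_pred`, `pi_S_pred`, `pi_B_pred`, and neutral
#'   baselines `pi_T_neutral`, `pi_S_neutral`, `pi_B_neutral`,
#'   `F_ST_neutral`, `G_ST_neutral`, `N_e_global_neutral`. For `d = 1` the
#'   F_ST/G_ST entries are `NA`/0 and the pipeline reduces to the
#'   panmictic saturating formula.
#' @examples
#' isl <- island_params(d = 10, N_local = 500, m = 0.00045)
#' seg <- selection_segment(t = 0.01, U = 7e-3, L = 700, M = 0)
#' neu <- neutral_region(mu_neutral = 1e-5, L_neutral = 1e4)
#' p <- predict_pi(isl, seg, neu)
#' 1 - p$pi_T_pred / p$pi_T_neutral # predicted fractional reduction of pi_T
#' @export
predict_pi <- function(island, segments, neutral, solved = NULL) {
  stopifnot(inherits(island, "island_params"), inherits(neutral, "neutral_region"))
  segments <- as_segment_list(segments)
  if (is.null(solved)) {
    solved <- solve_local_equilibrium(
      island, segments,
      apply_migration_effect = TRUE, interference_rescale = TRUE,
      heterozygosity = TRUE
    )
  }
  if (is.na(solved$B_local_het)) {
    stop("'solved' must carry the heterozygosity variant")
  }
  mu <- neutral$mu_neutral
  B_het <- solved$B_local_het

  sat_pi <- function(Ne, B) {
    x <- 4 * Ne * B * mu
    x / (1 + x)
  }

  if (island$d >= 2L) {
    G <- predict_gst(island, B_het)
    Fst <- predict_fst(island, B_het)
    G_n <- predict_gst(island, 1)
    F_n <- predict_fst(island, 1)
  } else {
    G <- 0; Fst <- NA_real_; G_n <- 0; F_n <- NA_real_
  }
  Ne_g <- global_effective_size(island, G)
  Ne_g_n <- global_effective_size(island, G_n)
  B_g <- global_B(Ne_g, segments)

  pi_T <- sat_pi(Ne_g, B_g)
  pi_T_n <- sat_pi(Ne_g_n, 1)
  pi_S <- pi_T * (1 - G)
  pi_S_n <- pi_T_n * (1 - G_n)
  pi_B <- if (is.na(Fst)) NA_real_ else pi_S / (1 - Fst)
  pi_B_n <- if (is.na(F_n)) NA_real_ else pi_S_n / (1 - F_n)

  structure(
    list(
      F_ST_pred = Fst, G_ST_pred = G,
      N_e_global = Ne_g, B_global = B_g,
      B_local = solved$B_local, B_local_het = B_het,
      pi_T_pred = pi_T, pi_S_pred = pi_S, pi_B_pred = pi_B,
      pi_T_neutral = pi_T_n, pi_S_neutral = pi_S_n, pi_B_neutral = pi_B_n,
      F_ST_neutral = F_n, G_ST_neutral = G_n, N_e_global_neutral = Ne_g_n,
      island = island, segments = segments, neutral = neutral
    ),
    class = "metapop_prediction"
  )
}

#' @export
print.metapop_prediction <- function(x, digits = 4, ...) {
  cat("Metapopulation predictions under background selection\n")
  print(x$island)
  fmt <- function(v) if (is.na(v)) "NA" else formatC(v, digits = digits, format = "g")
  cat(sprintf("  B_local = %s (het %s); B_global = %s\n",
              fmt(x$B_local), fmt(x$B_local_het), fmt(x$B_global)))
  cat(sprintf("  F_ST = %s (neutral %s); G_ST = %s (neutral %s)\n",
              fmt(x$F_ST_pred), fmt(x$F_ST_neutral),
              fmt(x$G_ST_pred), fmt(x$G_ST_neutral)))
  cat(sprintf("  N_e,global = %s (neutral %s)\n",
              fmt(x$N_e_global), fmt(x$N_e_global_neutral)))
  cat(sprintf("  pi_T = %s (neutral %s); pi_S = %s (neutral %s)\n",
              fmt(x$pi_T_pred), fmt(x$pi_T_neutral),
              fmt(x$pi_S_pred), fmt(x$pi_S_neutral)))
  invisible(x)
}
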