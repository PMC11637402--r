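#' Classic deterministic B from a per-site sum
#'
#' Strength of background selection at a focal neutral site under the
#' deterministic mutation-selection-balance approximation,
#' \deqn{B = \exp\left[-\sum_i \mu_i t_i / (r_i + t_i)^2\right],}
#' where site `i` mutates at rate `mu[i]`, is selected against with
#' heterozygous coefficient `t[i]`, and recombines with the neutral site at
#' frequency `r[i]`. Valid in the background selection regime (strong
#' selection, low mutation), where drift at selected sites can be ignored.
#'
#' @param mu Per-site deleterious mutation rates (per gamete).
#' @param t Heterozygous selection coefficients, all > 0.
#' @param r Recombination frequencies to the focal neutral site, all >= 0.
#' @return B in (0, 1]; 1 for an empty input.
#' @seealso [classic_B_region()] for the continuous-region form.
#' @examples
#' classic_B_site_sum(mu = 1e-5, t = 0.015, r = 0)
#' @export
classic_B_site_sum <- function(mu, t, r) {
  n <- length(mu)
  if (n == 0L) return(1)
  stopifnot(length(t) %in% c(1L, n), length(r) %in% c(1L, n))
  t <- rep_len(t, n); r <- rep_len(r, n)
  if (any(!is.finite(mu) | mu < 0)) stop("'mu' must be >= 0")
  if (any(!is.finite(t) | t <= 0)) {
    stop("deterministic B requires t > 0 at every site")
  }
  if (any(!is.finite(r) | r < 0)) stop("'r' must be >= 0")
  exp(-sum(mu * t / (r + t)^2))
}

#' Classic deterministic B for a selected region
#'
#' Continuous-region form of the deterministic background-selection
#' strength for a neutral site embedded in a selected region of total
#' gametic deleterious mutation rate `U` and map length `M` Morgans:
#' \deqn{B = \exp[-2U/(2t + M)].}
#'
#' @param U Gametic deleterious mutation rate of the region (>= 0).
#' @param t Heterozygous selection coefficient.
#' @param M Map length in Morgans.
#' @return B in (0, 1].
#' @examples
#' classic_B_region(U = 7e-3, t = 0.015, M = 0)    # ~0.627
#' classic_B_region(U = 7e-3, t = 0.015, M = 0.01) # ~0.705
#' @export
classic_B_region <- function(U, t, M = 0) {
  stopifnot(length(U) == 1L, length(t) == 1L, length(M) == 1L)
  if (!is.finite(U) || U < 0) stop("'U' must be >= 0")
  if (U == 0) return(1)
  if (2 * t + M <= 0) stop("'2t + M' must be > 0 when U > 0")
  exp(-2 * U / (2 * t + M))
}

#' Per-generation decay factor of the fitness-variance association
#'
#' The factor `Z = 1 - V_M/V_A` by which the association between a neutral
#' lineage and the fitness variance of a linked selected segment decays each
#' generation, expressed through the segment's mutation rate and fixation
#' rate as \deqn{Z = 1 - U t / (U - 2R).} With no fixation (`R = 0`, strong
#' selection) this is exactly `1 - t`; as fixation removes additive variance
#' the decay accelerates. Values that would fall at or below 0 are clamped
#' to 0 and flagged (`attr(, "drift_dominated")`): the segment's association
#' is then erased within a single generation.
#'
#' `U` here is the mutation-rate convention in which `V_A = (U - 2R) t`;
#' the package's solver passes the diploid region rate (twice the gametic
#' rate of a [selection_segment()]), paired with the gametic fixation rate
#' from [fixation_rate()].
#'
#' @param U Region deleterious mutation rate (> 0).
#' @param t Heterozygous selection coefficient.
#' @param R Per-generation fixation rate of deleterious alleles.
#' @return Z in [0, 1), with attribute `drift_dominated` (logical).
#' @examples
#' decay_factor_Z(U = 7e-3, t = 0.015, R = 0)      # 1 - t = 0.985
#' decay_factor_Z(U = 7e-3, t = 5e-4, R = 3e-3)    # 0.9965
#' @export
decay_factor_Z <- function(U, t, R = 0) {
  stopifnot(length(U) == 1L, length(t) == 1L, length(R) == 1L)
  if (!is.finite(U) || U <= 0) stop("'U' must be > 0")
  if (R == 0) {
    z <- 1 - t
    return(structure(max(0, min(z, 1 - 1e-15)), drift_dominated = z <= 0))
  }
  denom <- U - 2 * R
  z <- if (denom <= 0) 0 else 1 - U * t / denom
  drift <- z <= 0
  structure(max(0, min(z, 1 - 1e-15)), drift_dominated = drift)
}

#' Asymptotic linkage inflation factor at a point
#'
#' Squared summed autocorrelation of a neutral lineage's association with a
#' linked deleterious background, for recombination frequency `r` to the
#' selected site, per-generation decay `Z`, and emigration rate `m`:
#' \deqn{Q_\infty^2 = \left[\frac{1}{1 - Z(1-r)(1-m)}\right]^2,}
#' the square of the geometric series with ratio `Z(1-r)(1-m)`. The
#' `(1-m)` term is the migration effect: emigration, like recombination and
#' selection, ends the within-deme association.
#'
#' @param r Recombination frequency in [0, 0.5].
#' @param Z Decay factor in [0, 1); see [decay_factor_Z()].
#' @param m Migration rate in [0, 1).
#' @return Q-squared, >= 1.
#' @examples
#' q_infinity_sq_point(r = 0, Z = 1 - 0.015, m = 0)    # (1/0.015)^2
#' q_infinity_sq_point(r = 0, Z = 1 - 0.015, m = 0.09) # shrunk by migration
#' @export
q_infinity_sq_point <- function(r, Z, m = 0) {
  a <- Z * (1 - r) * (1 - m)
  if (any(a < 0) || any(a >= 1)) {
    stop("'Z(1-r)(1-m)' must lie in [0, 1)")
  }
  (1 / (1 - a))^2
}

#' Region-averaged asymptotic linkage inflation factor
#'
#' Average of [q_infinity_sq_point()] over a selected segment of map length
#' `M` Morgans with the focal neutral site at its centre (so recombination
#' frequencies run over `[0, M/2]`):
#' \deqn{\bar Q_\infty^2 = \frac{2}{M}\int_0^{M/2} Q_\infty^2(r)\,dr
#'   = \frac{1}{(1-a)\,(1 - a(1 - M/2))}, \quad a = Z(1-m).}
#' For `M = 0` this reduces to the point value at `r = 0`. Assumes `r` is
#' additive along the segment (small `M`).
#'
#' @param M Segment map length in Morgans (>= 0).
#' @param Z Decay factor in [0, 1).
#' @param m Migration rate in [0, 1).
#' @return Region-averaged Q-squared, >= 1.
#' @examples
#' q_infinity_sq_region(M = 0.01, Z = 0.985, m = 0)
#' @export
q_infinity_sq_region <- function(M, Z, m = 0) {
  stopifnot(length(M) == 1L, M >= 0)
  a <- Z * (1 - m)
  if (a < 0 || a >= 1) stop("'Z(1-m)' must lie in [0, 1)")
  if (M == 0) return(q_infinity_sq_point(0, Z, m))
  1 / ((1 - a) * (1 - a * (1 - M / 2)))
}

#' Fixation rate of deleterious alleles
#'
#' Per-generation rate at which deleterious alleles fix by drift in a
#' population of fitness-effective size `N_f`:
#' \deqn{R = \frac{4 N_f U t}{e^{4 N_f t} - 1},}
#' the product of the influx of new mutations and Kimura's fixation
#' probability for a semi-dominant deleterious allele. `U` is the gametic
#' deleterious mutation rate; `R` runs from `U` (neutral limit, `t -> 0`)
#' to 0 (strong selection). A series expansion is used for `4 N_f t`
#' below 1e-8 so the `t = 0` limit is exact.
#'
#' @param N_f Fitness-effective population size (> 0).
#' @param U Gametic deleterious mutation rate (>= 0).
#' @param t Heterozygous selection coefficient (>= 0).
#' @return R in [0, U].
#' @examples
#' fixation_rate(N_f = 500, U = 7e-3, t = 0.015) # ~1.96e-14
#' fixation_rate(N_f = 500, U = 7e-3, t = 0)     # U
#' @export
fixation_rate <- function(N_f, U, t) {
  stopifnot(length(N_f) == 1L, length(U) == 1L, length(t) == 1L)
  if (!is.finite(N_f) || N_f <= 0) stop("'N_f' must be > 0")
  if (!is.finite(U) || U < 0) stop("'U' must be >= 0")
  if (!is.finite(t) || t < 0) stop("'t' must be >= 0")
  x <- 4 * N_f * t
  if (x < 1e-8) return(U * (1 - x / 2))   # x/(e^x - 1) ~ 1 - x/2 + O(x^2)
  if (x > 700) return(4 * N_f * U * t * exp(-x))
  U * x / expm1(x)
}

# Per-segment additive variance, decay factor and region-averaged Q^2 at the
# current fixation rates. Diploid region rate 2U enters V_A and Z; see
# decay_factor_Z() for the convention.
segment_quantities <- function(segments, R_seg, m_eff) {
  n <- length(segments)
  VA <- Z <- Q2 <- VM <- numeric(n)
  clamped <- drift <- logical(n)
  for (i in seq_len(n)) {
    s <- segments[[i]]
    if (s$U == 0 || s$t == 0) {
      VA[i] <- 0; VM[i] <- 0; Z[i] <- 0; Q2[i] <- 1
      next
    }
    Udip <- 2 * s$U
    va <- (Udip - 2 * R_seg[i]) * s$t
    if (va < 0) { va <- 0; clamped[i] <- TRUE }
    VA[i] <- va
    VM[i] <- Udip * s$t^2
    z <- decay_factor_Z(Udip, s$t, R_seg[i])
    drift[i] <- isTRUE(attr(z, "drift_dominated"))
    Z[i] <- as.numeric(z)
    Q2[i] <- q_infinity_sq_region(s$M, Z[i], m_eff)
  }
  list(VA = VA, VM = VM, Z = Z, Q2 = Q2, clamped = clamped, drift = drift)
}

# Inner solver: self-consistent (N_f, R) at a fixed reference size N_ref.
# Damped fixed-point iteration; N_f enters the fixation rate (Eq for R) and
# the exponential (Eq for N_f) simultaneously.
solve_inner <- function(N_ref, segments, m_eff, damping = 0.5,
                        tol = 1e-12, max_iter = 10000L) {
  n <- length(segments)
  N_f <- N_ref
  R_seg <- numeric(n)
  for (iter in seq_len(max_iter)) {
    R_seg <- vapply(
      segments, function(s) fixation_rate(N_f, s$U, s$t), numeric(1)
    )
    sq <- segment_quantities(segments, R_seg, m_eff)
    expo <- sum(sq$VA * sq$Q2) / 2
    N_new <- N_ref * exp(-expo)
    if (abs(N_new - N_f) <= tol * max(N_f, 1)) {
      N_f <- N_new
      break
    }
    N_f <- damping * N_f + (1 - damping) * N_new
  }
  R_seg <- vapply(segments, function(s) fixation_rate(N_f, s$U, s$t), numeric(1))
  sq <- segment_quantities(segments, R_seg, m_eff)
  expo <- sum(sq$VA * sq$Q2) / 2
  resid <- abs(N_f - N_ref * exp(-expo)) / max(N_f, 1)
  list(
    N_f = N_f, B = exp(-expo), R_seg = R_seg, sq = sq,
    converged = resid < 1e-10, iterations = iter, residual = resid
  )
}

#' Solve the local background-selection equilibrium
#'
#' Solves the coupled quantitative-genetic system for the strength of
#' background selection experienced by one subpopulation of an island
#' model: the local fitness-effective size satisfies
#' \deqn{N_{f,local} = N_{local}\exp\left[-\sum_i V_{A,i} Q_i^2 / 2\right]}
#' with per-segment additive fitness variance `V_A = (2U - 2R) t` (gametic
#' segment rate `U`) and region-averaged linkage inflation `Q^2` carrying
#' the migration effect, while the per-segment fixation rate `R` is tied
#' back to `N_f` through [fixation_rate()]. The two equations are iterated
#' to a joint fixed point. With `interference_rescale = TRUE`, the
#' reference size fed into the fixation rate is itself rescaled by the
#' current `B` (selected sites experience background selection too), as an
#' outer fixed point on `B`.
#'
#' @param island An [island_params()] object.
#' @param segments A [selection_segment()] or list of them.
#' @param apply_migration_effect Include the `(1-m)` factor in `Q^2`
#'   (default `TRUE`). With `FALSE` the panmictic-style association is used
#'   even in a structured population.
#' @param interference_rescale Rescale the reference population size by `B`
#'   to approximate selective interference among deleterious sites
#'   (default `TRUE`).
#' @param heterozygosity Also compute the heterozygosity-effective size via
#'   [heterozygosity_B()] (default `TRUE`).
#' @param outer_tol Relative tolerance on `B` for the interference outer
#'   fixed point.
#' @param max_outer Maximum outer iterations.
#'
#' @return An object of class `"bgs_local"`: a list with `B_local`
#'   (`N_f,local / N_local`), `N_f_local`, `R` (total fixation rate summed
#'   over segments, per generation), `N_eH_local` and `B_local_het`
#'   (heterozygosity variants, `NA` unless `heterozygosity = TRUE`),
#'   per-segment `diagnostics` (`Z`, `V_A`, `V_M`, `Q2`, clamp flags),
#'   `converged` and `iterations`.
#' @examples
#' isl <- island_params(d = 10, N_local = 500, m = 0)
#' seg <- selection_segment(t = 0.015, U = 7e-3, L = 700, M = 0)
#' fit <- solve_local_equilibrium(isl, seg)
#' fit$B_local # close to classic_B_region(7e-3, 0.015, 0)
#' @export
solve_local_equilibrium <- function(island, segments,
                                    apply_migration_effect = TRUE,
                                    interference_rescale = TRUE,
                                    heterozygosity = TRUE,
                                    outer_tol = 1e-8, max_outer = 500L) {
  stopifnot(inherits(island, "island_params"))
  segments <- as_segment_list(segments)
  m_eff <- if (apply_migration_effect) island$m else 0
  N <- island$N_local

  if (all(vapply(segments, function(s) s$U == 0 || s$t == 0, logical(1)))) {
    # no selection anywhere: exact neutral answer
    n <- length(segments)
    R_tot <- sum(vapply(segments, function(s) if (s$t == 0) s$U else 0, numeric(1)))
    diag <- data.frame(
      Z = rep(0, n), V_A = rep(0, n), V_M = rep(0, n), Q2 = rep(1, n),
      VA_clamped = rep(FALSE, n), drift_dominated = rep(FALSE, n)
    )
    out <- structure(
      list(
        B_local = 1, N_f_local = N, R = R_tot,
        B_local_het = 1, N_eH_local = N,
        diagnostics = diag, converged = TRUE, iterations = 0L,
        island = island, segments = segments,
        apply_migration_effect = apply_migration_effect,
        interference_rescale = interference_rescale
      ),
      class = "bgs_local"
    )
    return(out)
  }

  B <- 1
  total_iter <- 0L
  inner <- NULL
  ok <- FALSE
  n_outer <- if (interference_rescale) max_outer else 1L
  for (k in seq_len(n_outer)) {
    N_ref <- if (interference_rescale) B * N else N
    inner <- solve_inner(N_ref, segments, m_eff)
    total_iter <- total_iter + inner$iterations
    if (!inner$converged) break
    if (!interference_rescale) { ok <- TRUE; break }
    if (abs(inner$B - B) <= outer_tol * max(B, 1e-12)) {
      B <- inner$B; ok <- TRUE; break
    }
    B <- inner$B
  }
  if (!ok || !inner$converged) {
    stop(sprintf(
      paste0("background-selection solver did not converge ",
             "(outer iterations = %d, last B = %.8g, residual = %.3g)"),
      k, inner$B, inner$residual
    ))
  }

  B_local <- inner$B
  sq <- inner$sq
  diag <- data.frame(
    Z = sq$Z, V_A = sq$VA, V_M = sq$VM, Q2 = sq$Q2,
    VA_clamped = sq$clamped, drift_dominated = sq$drift
  )
  res <- structure(
    list(
      B_local = B_local, N_f_local = B_local * N, R = sum(inner$R_seg),
      B_local_het = NA_real_, N_eH_local = NA_real_,
      diagnostics = diag, converged = TRUE, iterations = total_iter,
      island = island, segments = segments,
      apply_migration_effect = apply_migration_effect,
      interference_rescale = interference_rescale
    ),
    class = "bgs_local"
  )
  if (heterozygosity) {
    het <- heterozygosity_B(island, segments, res)
    res$N_eH_local <- het$N_eH_local
    res$B_local_het <- het$B_local_het
  }
  res
}

#' @export
print.bgs_local <- function(x, digits = 4, ...) {
  cat("Local background-selection equilibrium\n")
  print(x$island)
  cat(sprintf("  B_local      = %.*g  (N_f,local  = %.*g)\n",
              digits, x$B_local, digits, x$N_f_local))
  if (!is.na(x$B_local_het)) {
    cat(sprintf("  B_local,het  = %.*g  (N_eH,local = %.*g)\n",
                digits, x$B_local_het, digits, x$N_eH_local))
  }
  cat(sprintf("  R (fixations/generation) = %.*g\n", digits, x$R))
  cat(sprintf("  migration effect: %s; interference rescaling: %s\n",
              if (x$apply_migration_effect) "on" else "off",
              if (x$interference_rescale) "on" else "off"))
  invisible(x)
}

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch via symmetric
# tridiagonal eigendecomposition).
gauss_legendre01 <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1)] <- b
  A[cbind(i + 1, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(nodes = (x + 1) / 2, weights = w / 2)
}

#' Heterozygosity-effective size under background selection
#'
#' Equilibrium diversity reflects neutral mutations of all ages, and young
#' mutations have not yet accumulated the full (asymptotic) association
#' with deleterious backgrounds. This computes the age-resolved linkage
#' inflation \deqn{Q^2(\tau) = \left[\frac{1 - a^\tau}{1 - a}\right]^2,
#' \quad a = Z(1-r)(1-m),} the corresponding age-resolved effective size
#' `N_f(tau) = N_local exp[-sum V_A Q^2(tau)/2]`, and accumulates the
#' expected contribution of mutations of each age through the per-
#' generation lineage survival factor `1 - 1/(2 N_f(tau))`:
#' \deqn{B_{het} = \frac{1}{2N_{local}} \sum_{\tau\ge 0}
#'   \prod_{i=1}^{\tau} \left(1 - \frac{1}{2N_f(i)}\right).}
#' The sum is truncated at `10 N_local` generations and closed with the
#' analytic geometric tail at the asymptotic `N_f`, which makes the neutral
#' limit (`V_A = 0`) exactly 1. Segments with `M > 0` average `Q^2(tau)`
#' over recombination distances by Gauss-Legendre quadrature.
#'
#' @param island An [island_params()] object.
#' @param segments A [selection_segment()] or list of them.
#' @param solved A `"bgs_local"` fit from [solve_local_equilibrium()]
#'   providing the converged per-segment `Z` and `V_A` and asymptotic
#'   `N_f_local`.
#' @param horizon Truncation horizon in generations (default
#'   `10 * N_local`).
#' @param quad_nodes Gauss-Legendre node count for `M > 0` segments.
#' @return A list with `N_eH_local` and `B_local_het`
#'   (`= N_eH_local / N_local`), satisfying
#'   `B_local <= B_local_het <= 1`.
#' @export
heterozygosity_B <- function(island, segments, solved,
                             horizon = NULL, quad_nodes = 64L) {
  stopifnot(inherits(island, "island_params"), inherits(solved, "bgs_local"))
  segments <- as_segment_list(segments)
  N <- island$N_local
  m_eff <- if (solved$apply_migration_effect) island$m else 0
  Tmax <- if (is.null(horizon)) ceiling(10 * N) else as.integer(horizon)

  VA <- solved$diagnostics$V_A
  Z <- solved$diagnostics$Z
  active <- which(VA > 0 & Z > 0)
  if (length(active) == 0L) {
    return(list(N_eH_local = N, B_local_het = 1))
  }

  tau <- seq_len(Tmax)
  expo <- numeric(Tmax) # sum_i V_A,i Q_i^2(tau) / 2
  gl <- NULL
  for (i in active) {
    s <- segments[[i]]
    if (s$M == 0) {
      a <- Z[i] * (1 - m_eff)
      q2 <- ((1 - a^tau) / (1 - a))^2
    } else {
      if (is.null(gl)) gl <- gauss_legendre01(quad_nodes)
      r_nodes <- gl$nodes * (s$M / 2)
      a <- Z[i] * (1 - r_nodes) * (1 - m_eff)
      # average over r in [0, M/2]: rows tau, cols nodes
      pow <- exp(outer(tau, log(a)))
      q2 <- as.numeric(((1 - pow) / rep(1 - a, each = Tmax))^2 %*% gl$weights)
    }
    expo <- expo + VA[i] * q2 / 2
  }
  N_f_tau <- N * exp(-expo)
  N_f_tau <- pmax(N_f_tau, 0.5000001) # keep survival factor in (0, 1)
  surv <- 1 - 1 / (2 * N_f_tau)
  P <- cumprod(surv) # P[tau] = prod_{i=1}^{tau} surv(i)
  N_f_inf <- max(solved$N_f_local, 0.5000001)
  tail <- P[Tmax] * (2 * N_f_inf - 1)
  B_het <- (1 + sum(P) + tail) / (2 * N)
  B_het <- min(B_het, 1)
  B_het <- max(B_het, solved$B_local)
  list(N_eH_local = B_het * N, B_local_het = B_het)
}
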