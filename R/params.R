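#' Island-model demographic parameters
#'
#' Bundle of the demographic parameters of a finite island model: `d` demes
#' of `N_local` diploid individuals, exchanging a total fraction `m` of
#' immigrants per deme per generation (equally partitioned among the other
#' demes).
#'
#' @param d Number of demes (integer, >= 1).
#' @param N_local Diploid individuals per deme.
#' @param m Total immigrant fraction per deme per generation, in [0, 1).
#'   A single deme (`d = 1`) forces `m = 0`.
#'
#' @return An object of class `"island_params"`: a list with elements `d`,
#'   `N_local`, `N_global` (`= d * N_local`) and `m`.
#' @examples
#' island_params(d = 10, N_local = 500, m = 0.009)
#' @export
island_params <- function(d, N_local, m = 0) {
  stopifnot(length(d) == 1L, length(N_local) == 1L, length(m) == 1L)
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop("'d' must be an integer >= 1")
  if (!is.finite(N_local) || N_local < 1) stop("'N_local' must be >= 1")
  if (!is.finite(m) || m < 0 || m >= 1) stop("'m' must lie in [0, 1)")
  if (d == 1L && m > 0) stop("a single deme (d = 1) forces m = 0")
  structure(
    list(d = d, N_local = N_local, N_global = d * N_local, m = m),
    class = "island_params"
  )
}

#' @export
print.island_params <- function(x, ...) {
  cat(sprintf(
    "Island model: d = %d deme(s) x N_local = %g diploids (N_global = %g), m = %g\n",
    x$d, x$N_local, x$N_global, x$m
  ))
  invisible(x)
}

#' Selected-region architecture
#'
#' One contiguous genomic segment under purifying selection, linked to the
#' focal neutral region. Deleterious mutations arise at `L` sites with
#' per-site, per-gamete rate `mu_del`, each with heterozygous selection
#' coefficient `t`; the segment spans `M` Morgans of genetic map. The
#' gametic deleterious mutation rate of the segment is `U = mu_del * L`.
#'
#' @param t Heterozygous selection coefficient (>= 0, unitless).
#' @param M Map length of the segment in Morgans (>= 0).
#' @param L Number of selected sites (integer >= 1).
#' @param U Gametic deleterious mutation rate of the segment. Give either
#'   `U` or `mu_del`; the other is derived via `U = mu_del * L`.
#' @param mu_del Per-site deleterious mutation rate per gamete.
#'
#' @return An object of class `"selection_segment"`: a list with elements
#'   `t`, `mu_del`, `L`, `M`, `U`.
#' @examples
#' # the standard architecture used throughout: 700 selected sites, U = 7e-3
#' selection_segment(t = 0.015, U = 7e-3, L = 700, M = 0)
#' @export
selection_segment <- function(t, M = 0, L = 1L, U = NULL, mu_del = NULL) {
  stopifnot(length(t) == 1L, length(M) == 1L, length(L) == 1L)
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("'L' must be an integer >= 1")
  if (!is.finite(t) || t < 0) stop("'t' must be >= 0")
  if (t >= 1) stop("'t' must be < 1 (heterozygous selection coefficient)")
  if (!is.finite(M) || M < 0) stop("'M' must be >= 0")
  if (is.null(U) && is.null(mu_del)) stop("give one of 'U' or 'mu_del'")
  if (is.null(U)) U <- mu_del * L
  if (is.null(mu_del)) mu_del <- U / L
  if (abs(U - mu_del * L) > 1e-12 * max(U, 1e-300)) {
    stop("'U' must equal 'mu_del' * 'L'")
  }
  if (!is.finite(U) || U < 0) stop("'U' must be >= 0")
  structure(
    list(t = t, mu_del = mu_del, L = L, M = M, U = U),
    class = "selection_segment"
  )
}

#' @export
print.selection_segment <- function(x, ...) {
  cat(sprintf(
    "Selected segment: L = %d sites, t = %g, U = %g (mu_del = %g), M = %g Morgans\n",
    x$L, x$t, x$U, x$mu_del, x$M
  ))
  invisible(x)
}

#' Neutral-region architecture
#'
#' The focal neutral region: `L_neutral` sites mutating at per-site,
#' per-gamete rate `mu_neutral` under an infinite-alleles model. The block
#' is internally non-recombining.
#'
#' @param mu_neutral Neutral per-site mutation rate per gamete (>= 0).
#' @param L_neutral Number of neutral sites (integer >= 1).
#' @return An object of class `"neutral_region"`.
#' @examples
#' neutral_region(mu_neutral = 1e-5, L_neutral = 1e4)
#' @export
neutral_region <- function(mu_neutral, L_neutral = 1L) {
  stopifnot(length(mu_neutral) == 1L, length(L_neutral) == 1L)
  L_neutral <- as.integer(L_neutral)
  if (is.na(L_neutral) || L_neutral < 1L) stop("'L_neutral' must be >= 1")
  if (!is.finite(mu_neutral) || mu_neutral < 0) stop("'mu_neutral' must be >= 0")
  structure(
    list(mu_neutral = mu_neutral, L_neutral = L_neutral),
    class = "neutral_region"
  )
}

#' @export
print.neutral_region <- function(x, ...) {
  cat(sprintf(
    "Neutral region: L_neutral = %d sites, mu_neutral = %g per site per gamete\n",
    x$L_neutral, x$mu_neutral
  ))
  invisible(x)
}

# normalise a single segment or a list of segments into a list of segments
as_segment_list <- function(segments) {
  if (inherits(segments, "selection_segment")) return(list(segments))
  if (!is.list(segments) || !all(vapply(segments, inherits, TRUE, "selection_segment"))) {
    stop("'segments' must be a selection_segment or a list of them")
  }
  segments
}
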