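#' Genome layout for the forward simulator
#'
#' The simulated genome: a non-recombining block of `L_neutral` neutral
#' sites flanked on each side by `L_selected / 2` selected sites, with
#' total map length `M` Morgans spread uniformly across the selected
#' intervals.
#'
#' @param L_neutral Number of neutral sites (integer >= 1).
#' @param L_selected Number of selected sites (even integer >= 0).
#' @param M Total map length in Morgans (>= 0).
#' @return An object of class `"genome_layout"`.
#' @examples
#' genome_layout(L_neutral = 1e4, L_selected = 700, M = 0.01)
#' @export
genome_layout <- function(L_neutral = 1e4, L_selected = 700, M = 0) {
  L_neutral <- as.integer(L_neutral); L_selected <- as.integer(L_selected)
  if (is.na(L_neutral) || L_neutral < 1L) stop("'L_neutral' must be >= 1")
  if (is.na(L_selected) || L_selected < 0L || L_selected %% 2L != 0L) {
    stop("'L_selected' must be an even integer >= 0 (two equal flanks)")
  }
  if (!is.finite(M) || M < 0) stop("'M' must be >= 0")
  structure(
    list(L_neutral = L_neutral, L_selected = L_selected, M = M),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf(
    "Genome: [%d selected][%d neutral, non-recombining][%d selected], M = %g Morgans\n",
    x$L_selected %/% 2L, x$L_neutral, x$L_selected %/% 2L, x$M
  ))
  invisible(x)
}

#' Forward-simulation configuration
#'
#' Bundles everything one replicate of the forward Wright-Fisher
#' island-model simulation needs. Defaults reproduce the reference
#' experimental design: 10 demes of 500 diploids, 700 selected sites
#' (`U = 7e-3`) around 1e4 neutral sites (`mu = 1e-5`), burn-in of
#' `50 * N_global` generations, 750 replicates.
#'
#' @param island An [island_params()] object.
#' @param layout A [genome_layout()] object.
#' @param t Heterozygous selection coefficient.
#' @param U Gametic deleterious mutation rate over the selected sites
#'   (per-site rate is `U / L_selected`).
#' @param mu_neutral Neutral per-site mutation rate per gamete.
#' @param generations Burn-in length; default `50 * N_global`.
#' @param replicates Number of replicates (default 750).
#' @param master_seed Integer master seed; per-replicate child seeds are
#'   derived from it.
#' @return An object of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(island_params(10, 100, 0.045),
#'                   genome_layout(100, 700, 0), t = 0, U = 0,
#'                   mu_neutral = 5e-5, replicates = 10)
#' @export
sim_config <- function(island, layout = genome_layout(),
                       t = 0.015, U = 7e-3, mu_neutral = 1e-5,
                       generations = NULL, replicates = 750L,
                       master_seed = 1L) {
  stopifnot(inherits(island, "island_params"), inherits(layout, "genome_layout"))
  if (is.null(generations)) generations <- 50L * island$N_global
  generations <- as.integer(generations)
  replicates <- as.integer(replicates)
  if (is.na(generations) || generations < 1L) stop("'generations' must be >= 1")
  if (is.na(replicates) || replicates < 1L) stop("'replicates' must be >= 1")
  if (!is.finite(t) || t < 0 || t >= 1) stop("'t' must lie in [0, 1)")
  if (!is.finite(U) || U < 0) stop("'U' must be >= 0")
  if (U > 0 && layout$L_selected < 2L) stop("U > 0 requires selected sites")
  if (!is.finite(mu_neutral) || mu_neutral < 0) stop("'mu_neutral' must be >= 0")
  structure(
    list(
      island = island, layout = layout, t = t, U = U,
      mu_neutral = mu_neutral, generations = generations,
      replicates = replicates, master_seed = as.integer(master_seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  print(x$island); print(x$layout)
  cat(sprintf("  t = %g, U = %g, mu_neutral = %g\n", x$t, x$U, x$mu_neutral))
  cat(sprintf("  %d generation(s) burn-in, %d replicate(s), master seed %d\n",
              x$generations, x$replicates, x$master_seed))
  invisible(x)
}

#' Run one forward-simulation replicate
#'
#' Runs the burn-in for a single replicate and returns the raw final
#' state: per-deme neutral haplotype matrices (rows are haplotypes,
#' columns neutral sites, entries infinite-alleles labels with 0 the
#' ancestral allele), per-individual deleterious allele counts, and the
#' number of selected sites fixed across the metapopulation (`NA` on the
#' fully-linked `M = 0` fast path, where sites are not tracked
#' individually).
#'
#' @param config A [sim_config()] object.
#' @param seed Optional integer seed set before the run.
#' @return A list with elements `neutral` (list of `d` integer matrices),
#'   `k` (`N_local x d` matrix of deleterious counts per individual),
#'   `fixed_deleterious`, `n_block_nodes`.
#' @export
run_simulation <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  isl <- config$island; lay <- config$layout
  .run_forward_sim(
    d = isl$d, N_local = isl$N_local, m = isl$m,
    t = config$t, U = config$U, mu_neutral = config$mu_neutral,
    L_selected = max(lay$L_selected, 2L), L_neutral = lay$L_neutral,
    M_map = lay$M, generations = config$generations
  )
}

#' Run replicated forward simulations
#'
#' Runs `config$replicates` independent replicates (child seeds drawn
#' deterministically from `master_seed`) and summarises each with the
#' diversity and differentiation estimators: within-deme, between-deme
#' and total pairwise diversity (`pi_S`, `pi_B`, `pi_T`, per site,
#' averaged over sites), Hudson `F_ST` and `G_ST` (minor-allele-frequency
#' filter 0.05), and the fixed deleterious site count.
#'
#' @param config A [sim_config()] object.
#' @param maf_threshold Minor-allele-frequency filter for `F_ST`/`G_ST`.
#' @return A data frame with one row per replicate and columns
#'   `replicate`, `seed`, `pi_S`, `pi_B`, `pi_T`, `F_ST`, `G_ST`,
#'   `fixed_deleterious`.
#' @seealso [summarize_replicates()] for means and 95% CIs.
#' @examples
#' cfg <- sim_config(island_params(2, 20, 0.05), genome_layout(20, 2, 0),
#'                   t = 0, U = 0, mu_neutral = 1e-3,
#'                   generations = 400, replicates = 3, master_seed = 7)
#' run_replicates(cfg)
#' @export
run_replicates <- function(config, maf_threshold = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$replicates)
  out <- vector("list", config$replicates)
  for (i in seq_len(config$replicates)) {
    res <- run_simulation(config, seed = seeds[i])
    tab <- site_table(res$neutral)
    structured <- config$island$d >= 2L
    out[[i]] <- data.frame(
      replicate = i, seed = seeds[i],
      pi_S = pi_within(tab),
      pi_B = if (structured) pi_between(tab) else NA_real_,
      pi_T = pi_total(tab),
      F_ST = if (structured) hudson_fst(tab, maf_threshold = maf_threshold)
             else NA_real_,
      G_ST = if (structured) gst(tab, maf_threshold = maf_threshold)
             else NA_real_,
      fixed_deleterious = res$fixed_deleterious
    )
  }
  do.call(rbind, out)
}

#' Summarise replicate statistics
#'
#' Cross-replicate means with percentile 95% confidence intervals
#' (2.5 and 97.5 percentiles of the replicate values) and the standard
#' error of the mean, for each summary statistic.
#'
#' @param reps A data frame from [run_replicates()].
#' @param stats Character vector of columns to summarise.
#' @return A data frame with columns `stat`, `mean`, `se`, `lo`, `hi`,
#'   `n` (`lo`/`hi` are the percentile interval of the replicate
#'   distribution).
#' @export
summarize_replicates <- function(reps,
                                 stats = c("pi_S", "pi_B", "pi_T",
                                           "F_ST", "G_ST")) {
  stats <- intersect(stats, names(reps))
  rows <- lapply(stats, function(s) {
    v <- reps[[s]]
    v <- v[is.finite(v)]
    if (length(v) == 0L) {
      return(data.frame(stat = s, mean = NA_real_, se = NA_real_,
                        lo = NA_real_, hi = NA_real_, n = 0L))
    }
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(
      stat = s, mean = mean(v),
      se = stats::sd(v) / sqrt(length(v)),
      lo = q[1], hi = q[2], n = length(v)
    )
  })
  do.call(rbind, rows)
}

#' Multiplicative fitness
#'
#' Survival/selection weight of an individual carrying `k` deleterious
#' allele copies under multiplicative selection with heterozygous
#' coefficient `t`: `w = (1 - t)^k`.
#'
#' @param k Number of deleterious allele copies (non-negative integers).
#' @param t Heterozygous selection coefficient in [0, 1).
#' @return Fitness in (0, 1].
#' @examples
#' fitness_multiplicative(k = 2, t = 0.015) # 0.970225
#' @export
fitness_multiplicative <- function(k, t) {
  if (any(k < 0) || any(k != floor(k))) stop("'k' must be non-negative integers")
  if (t < 0 || t >= 1) stop("'t' must lie in [0, 1)")
  (1 - t)^k
}

#' Exchange migration between demes
#'
#' Applies one round of island-model migration to a metapopulation state:
#' for each pair of demes, a `Binomial(N_local, m/(d-1))` number of whole
#' individuals are swapped, so each individual emigrates with probability
#' `m` and immigrants are equally partitioned among source demes. Deme
#' sizes and metapopulation allele counts are conserved exactly.
#'
#' @param state A list of `d` integer matrices, one per deme, each with
#'   `2 * N_local` haplotype rows (rows `2i-1`, `2i` belong to individual
#'   `i`) and one column per site.
#' @param m Total immigrant fraction per deme per generation.
#' @return A list of matrices of the same shapes with individuals
#'   exchanged.
#' @examples
#' state <- list(matrix(1L, 4, 2), matrix(2L, 4, 2))
#' migrate(state, m = 0.5)
#' @export
migrate <- function(state, m) {
  stopifnot(is.list(state), length(state) >= 1L)
  .migrate_exchange(state, m)
}
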