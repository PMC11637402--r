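#' Site-by-deme allele count table
#'
#' Condenses per-deme haplotype matrices (rows haplotypes, columns sites,
#' entries allele labels) into per-site allele count matrices, the input
#' format of the diversity and differentiation estimators.
#'
#' @param haps A list of `d` matrices, one per deme, with equal column
#'   counts; each row is a haplotype, entries are arbitrary allele labels
#'   (multi-allelic sites supported).
#' @return An object of class `"site_table"`: a list of per-site
#'   `d x n_alleles` count matrices, with attributes `n_per_deme`
#'   (haplotypes per deme) and `d`.
#' @examples
#' haps <- list(matrix(c(1L, 1L, 2L, 2L), 4, 1), matrix(1L, 4, 1))
#' site_table(haps)
#' @export
site_table <- function(haps) {
  stopifnot(is.list(haps), length(haps) >= 1L)
  haps <- lapply(haps, as.matrix)
  L <- ncol(haps[[1]])
  if (any(vapply(haps, ncol, 0L) != L)) stop("demes must share the site count")
  n_hap <- vapply(haps, nrow, 0L)
  d <- length(haps)
  sites <- vector("list", L)
  for (s in seq_len(L)) {
    labs <- sort(unique(unlist(lapply(haps, function(h) h[, s]))))
    cnt <- matrix(0L, d, length(labs))
    for (k in seq_len(d)) {
      cnt[k, ] <- tabulate(match(haps[[k]][, s], labs), nbins = length(labs))
    }
    colnames(cnt) <- as.character(labs)
    sites[[s]] <- cnt
  }
  structure(sites, class = "site_table", n_per_deme = n_hap, d = d)
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("Site table: %d site(s), %d deme(s), %s haplotypes per deme\n",
              length(x), attr(x, "d"),
              paste(unique(attr(x, "n_per_deme")), collapse = "/")))
  invisible(x)
}

# per-site within-deme diversity, averaged over demes (unordered distinct
# pairs within each deme, sample-size corrected)
pi_within_sites <- function(table) {
  vapply(table, function(cnt) {
    n <- rowSums(cnt)
    p <- ifelse(n > 1, 1 - rowSums(cnt * (cnt - 1L)) / (n * (n - 1)), NA_real_)
    mean(p, na.rm = TRUE)
  }, numeric(1))
}

# per-site between-deme diversity, averaged over unordered deme pairs
pi_between_sites <- function(table) {
  d <- attr(table, "d")
  if (d < 2L) stop("pi_between requires at least 2 demes")
  vapply(table, function(cnt) {
    n <- rowSums(cnt)
    fr <- cnt / n
    # mean over unordered deme pairs of 1 - sum_a p_ak p_al
    G <- fr %*% t(fr)
    tot <- (sum(G) - sum(diag(G))) / (d * (d - 1))
    1 - tot
  }, numeric(1))
}

# per-site total (pooled) diversity, sample-size corrected
pi_total_sites <- function(table) {
  vapply(table, function(cnt) {
    tot <- colSums(cnt)
    n <- sum(tot)
    1 - sum(tot * (tot - 1)) / (n * (n - 1))
  }, numeric(1))
}

# pooled minor-allele frequency per site; for multi-allelic sites this is
# 1 - max allele frequency
maf_sites <- function(table) {
  vapply(table, function(cnt) {
    tot <- colSums(cnt)
    1 - max(tot) / sum(tot)
  }, numeric(1))
}

#' Within-deme pairwise diversity
#'
#' Average proportion of pairwise differences between haplotypes sampled
#' within a deme (unordered distinct pairs, so monomorphic demes score 0
#' without bias), averaged over demes and, by default, over sites.
#'
#' @param table A [site_table()].
#' @param per_site Return the per-site vector instead of the average.
#' @return Diversity in [0, 1].
#' @export
pi_within <- function(table, per_site = FALSE) {
  stopifnot(inherits(table, "site_table"))
  v <- pi_within_sites(table)
  if (per_site) v else mean(v)
}

#' Between-deme pairwise diversity
#'
#' Average proportion of pairwise differences between haplotypes sampled
#' from different demes, averaged over unordered deme pairs and, by
#' default, over sites.
#'
#' @inheritParams pi_within
#' @return Diversity in [0, 1].
#' @export
pi_between <- function(table, per_site = FALSE) {
  stopifnot(inherits(table, "site_table"))
  v <- pi_between_sites(table)
  if (per_site) v else mean(v)
}

#' Total (pooled) pairwise diversity
#'
#' Average proportion of pairwise differences between haplotypes pooled
#' across all demes (unordered distinct pairs), by default averaged over
#' sites. Satisfies `pi_S <= pi_T <= pi_B`.
#'
#' @inheritParams pi_within
#' @return Diversity in [0, 1].
#' @export
pi_total <- function(table, per_site = FALSE) {
  stopifnot(inherits(table, "site_table"))
  v <- pi_total_sites(table)
  if (per_site) v else mean(v)
}

#' Hudson's F_ST
#'
#' `F_ST = 1 - mean(pi_S) / mean(pi_B)` over sites passing the pooled
#' minor-allele-frequency filter (ratio of averages, the standard
#' recommendation for the Hudson estimator). Returns `NA` when no site
#' passes the filter.
#'
#' @param table A [site_table()].
#' @param maf_threshold Sites with pooled minor allele frequency below
#'   this are excluded (default 0.05).
#' @return F_ST estimate, or `NA_real_` if undefined.
#' @export
hudson_fst <- function(table, maf_threshold = 0.05) {
  stopifnot(inherits(table, "site_table"))
  keep <- maf_sites(table) >= maf_threshold
  if (!any(keep)) return(NA_real_)
  ps <- mean(pi_within_sites(table)[keep])
  pb <- mean(pi_between_sites(table)[keep])
  if (pb <= 0) return(NA_real_)
  1 - ps / pb
}

#' G_ST
#'
#' `G_ST = 1 - mean(pi_S) / mean(pi_T)` over sites passing the pooled
#' minor-allele-frequency filter; always `<=` [hudson_fst()] on the same
#' table since `pi_T <= pi_B`.
#'
#' @inheritParams hudson_fst
#' @return G_ST estimate, or `NA_real_` if undefined.
#' @export
gst <- function(table, maf_threshold = 0.05) {
  stopifnot(inherits(table, "site_table"))
  keep <- maf_sites(table) >= maf_threshold
  if (!any(keep)) return(NA_real_)
  ps <- mean(pi_within_sites(table)[keep])
  pt <- mean(pi_total_sites(table)[keep])
  if (pt <= 0) return(NA_real_)
  1 - ps / pt
}
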