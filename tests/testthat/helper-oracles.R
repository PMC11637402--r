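# Exhaustive pairwise-difference oracle for the diversity and
# differentiation estimators. Works directly on per-deme haplotype
# matrices (rows haplotypes, columns sites) by enumerating every
# haplotype pair; intentionally slow and independent of the package's
# count-based implementations.

oracle_pi_sites <- function(haps) {
  d <- length(haps)
  L <- ncol(haps[[1]])
  piS <- piB <- piT <- numeric(L)
  for (s in seq_len(L)) {
    # within demes: unordered distinct pairs, averaged over demes
    ws <- vapply(haps, function(h) {
      x <- h[, s]
      n <- length(x)
      diffs <- 0
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        diffs <- diffs + (x[i] != x[j])
      }
      diffs / choose(n, 2)
    }, numeric(1))
    piS[s] <- mean(ws)
    # between demes: all cross pairs, averaged over unordered deme pairs
    if (d >= 2) {
      bs <- c()
      for (a in seq_len(d - 1)) for (b in (a + 1):d) {
        xa <- haps[[a]][, s]; xb <- haps[[b]][, s]
        cnt <- 0
        for (i in seq_along(xa)) for (j in seq_along(xb)) {
          cnt <- cnt + (xa[i] != xb[j])
        }
        bs <- c(bs, cnt / (length(xa) * length(xb)))
      }
      piB[s] <- mean(bs)
    } else {
      piB[s] <- NA_real_
    }
    # total: pooled distinct pairs
    x <- unlist(lapply(haps, function(h) h[, s]))
    n <- length(x)
    diffs <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      diffs <- diffs + (x[i] != x[j])
    }
    piT[s] <- diffs / choose(n, 2)
  }
  list(pi_S = piS, pi_B = piB, pi_T = piT)
}

oracle_maf_sites <- function(haps) {
  L <- ncol(haps[[1]])
  vapply(seq_len(L), function(s) {
    x <- unlist(lapply(haps, function(h) h[, s]))
    1 - max(table(x)) / length(x)
  }, numeric(1))
}

oracle_stats <- function(haps, maf_threshold = 0.05) {
  ps <- oracle_pi_sites(haps)
  keep <- oracle_maf_sites(haps) >= maf_threshold
  fst <- if (any(keep)) 1 - mean(ps$pi_S[keep]) / mean(ps$pi_B[keep]) else NA_real_
  g <- if (any(keep)) 1 - mean(ps$pi_S[keep]) / mean(ps$pi_T[keep]) else NA_real_
  list(
    pi_S = mean(ps$pi_S), pi_B = mean(ps$pi_B), pi_T = mean(ps$pi_T),
    F_ST = fst, G_ST = g
  )
}

# random multi-allelic haplotype tables for property tests
random_haps <- function(d, n_hap, L, n_alleles = 3) {
  lapply(seq_len(d), function(k) {
    matrix(sample.int(n_alleles, n_hap * L, replace = TRUE), n_hap, L)
  })
}

# reference architecture used across tests: 700 selected sites, U = 7e-3
ref_segment <- function(t, M = 0) {
  selection_segment(t = t, U = 7e-3, L = 700, M = M)
}
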