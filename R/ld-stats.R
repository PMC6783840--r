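# Two-locus linkage disequilibrium from unphased genotypes: EM haplotype
# frequencies, Lewontin D'/r2, and profile-likelihood D' confidence bounds.

# 3x3 genotype count table from two dosage vectors (0/1/2/NA);
# pairwise-complete individuals only. n[i+1, j+1] = count of (gA=i, gB=j).
.pair_table <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  if (!all(ga %in% 0:2) || !all(gb %in% 0:2))
    stop_gshap("dosages must be 0, 1, 2 or missing")
  matrix(tabulate(ga * 3L + gb + 1L, nbins = 9L), 3, 3, byrow = TRUE)
}

# expected haplotype counts for frequencies p = (p11, p12, p21, p22)
# given the 3x3 genotype table; only the double heterozygote is ambiguous.
.expected_hap_counts <- function(n, p) {
  den <- p[1] * p[4] + p[2] * p[3]
  w <- if (den > 0) p[1] * p[4] / den else 0.5
  dh <- n[2, 2]
  c(
    2 * n[3, 3] + n[3, 2] + n[2, 3] + dh * w,        # A1B1
    2 * n[3, 1] + n[3, 2] + n[2, 1] + dh * (1 - w),  # A1B2
    2 * n[1, 3] + n[1, 2] + n[2, 3] + dh * (1 - w),  # A2B1
    2 * n[1, 1] + n[1, 2] + n[2, 1] + dh * w         # A2B2
  )
}

#' EM estimate of two-locus haplotype frequencies from unphased genotypes
#'
#' Maximizes the multinomial likelihood of the 3x3 genotype table over the
#' four haplotype frequencies (A1B1, A1B2, A2B1, A2B2), where allele 1 is
#' the allele counted by the dosage. Only double heterozygotes are
#' phase-ambiguous; all other cells contribute determinate haplotypes.
#'
#' @param ga,gb dosage vectors (0/1/2/`NA`) over the same individuals.
#' @param tol convergence tolerance on the max frequency change.
#' @param max_iter maximum EM iterations.
#' @return list of class `two_locus_table`: `p` (named haplotype
#'   frequencies), `pA1`, `pB1`, `n_informative`, `n_iter`, `table`.
#' @export
em_two_locus <- function(ga, gb, tol = 1e-8, max_iter = 1000) {
  n <- .pair_table(ga, gb)
  N <- sum(n)
  if (N < 1) stop_gshap("no individual with both markers observed")
  pA1 <- (2 * sum(n[3, ]) + sum(n[2, ])) / (2 * N)
  pB1 <- (2 * sum(n[, 3]) + sum(n[, 2])) / (2 * N)
  if (pA1 <= 0 || pA1 >= 1 || pB1 <= 0 || pB1 >= 1)
    stop_gshap("monomorphic locus: LD undefined")
  # initialize at linkage equilibrium
  p <- c(pA1 * pB1, pA1 * (1 - pB1), (1 - pA1) * pB1, (1 - pA1) * (1 - pB1))
  iter <- 0
  repeat {
    iter <- iter + 1
    cnt <- .expected_hap_counts(n, p)
    p_new <- cnt / (2 * N)
    if (max(abs(p_new - p)) < tol || iter >= max_iter) { p <- p_new; break }
    p <- p_new
  }
  structure(list(
    p = setNames(p, c("A1B1", "A1B2", "A2B1", "A2B2")),
    pA1 = pA1, pB1 = pB1, n_informative = N, n_iter = iter, table = n
  ), class = "two_locus_table")
}

# log-likelihood of a 3x3 genotype table under haplotype frequencies p
# (Hardy-Weinberg pairing of haplotypes)
.genotype_loglik <- function(n, p) {
  g <- matrix(0, 3, 3)
  g[3, 3] <- p[1]^2
  g[3, 2] <- 2 * p[1] * p[2]
  g[3, 1] <- p[2]^2
  g[2, 3] <- 2 * p[1] * p[3]
  g[2, 2] <- 2 * p[1] * p[4] + 2 * p[2] * p[3]
  g[2, 1] <- 2 * p[2] * p[4]
  g[1, 3] <- p[3]^2
  g[1, 2] <- 2 * p[3] * p[4]
  g[1, 1] <- p[4]^2
  used <- n > 0
  if (any(g[used] <= 0)) return(-Inf)
  sum(n[used] * log(g[used]))
}

#' Lewontin D, D', and r-squared from a two-locus table
#'
#' `D = pA1B1 pA2B2 - pA1B2 pA2B1`. `DMAX` follows the branch form
#' `min(pA1 pB2, pA2 pB1)` when `D >= 0` and `-min(pA1 pB1, pA2 pB2)` when
#' `D < 0`; `Dprime = |D / DMAX|` so it lies in \[0,1\].
#' `r2 = D^2 / (pA1 pA2 pB1 pB2)`.
#'
#' @param t a `two_locus_table` (from [em_two_locus()]) or a length-4
#'   numeric of haplotype frequencies (A1B1, A1B2, A2B1, A2B2).
#' @return list of class `ld_stats`: `D`, `DMAX`, `Dprime`, `r2`.
#' @export
ld_stats <- function(t) {
  p <- if (inherits(t, "two_locus_table")) t$p else {
    stopifnot(length(t) == 4, abs(sum(t) - 1) < 1e-6)
    t
  }
  pA1 <- p[1] + p[2]; pA2 <- 1 - pA1
  pB1 <- p[1] + p[3]; pB2 <- 1 - pB1
  if (min(pA1, pA2, pB1, pB2) <= 0)
    stop_gshap("zero marginal allele frequency: LD undefined")
  D <- unname(p[1] * p[4] - p[2] * p[3])
  DMAX <- if (D >= 0) min(pA1 * pB2, pA2 * pB1) else -min(pA1 * pB1, pA2 * pB2)
  Dprime <- if (DMAX == 0) 0 else min(1, abs(D / DMAX))
  r2 <- unname(D^2 / (pA1 * pA2 * pB1 * pB2))
  structure(list(D = D, DMAX = DMAX, Dprime = Dprime, r2 = min(1, r2)),
            class = "ld_stats")
}

#' Profile-likelihood confidence bounds on D'
#'
#' Profiles the likelihood of the observed 3x3 genotype table over a grid
#' of D' values in \[0,1\], with allele frequencies held at their MLEs and
#' the sign of D fixed at the EM estimate. The likelihood is normalized to
#' unit mass over the grid; `ci_low` is the smallest grid value whose
#' cumulative mass reaches `alpha_tail` and `ci_high` the smallest reaching
#' `1 - alpha_tail` (one-sided support bounds, Gabriel/Haploview scheme).
#'
#' @inheritParams em_two_locus
#' @param grid_step D' grid step (default 0.01).
#' @param alpha_tail tail mass (default 0.05 for 95% bounds).
#' @return list: `ci_low`, `ci_high`, plus the EM `Dprime` and `r2`.
#' @export
dprime_confidence_bounds <- function(ga, gb, grid_step = 0.01,
                                     alpha_tail = 0.05) {
  em <- em_two_locus(ga, gb)
  st <- ld_stats(em)
  n <- em$table
  pA <- em$pA1; pB <- em$pB1
  sgn <- if (st$D >= 0) 1 else -1
  dmax <- if (sgn > 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, by = grid_step)
  ll <- vapply(grid, function(d) {
    D <- sgn * d * dmax
    p <- c(pA * pB + D, pA * (1 - pB) - D, (1 - pA) * pB - D,
           (1 - pA) * (1 - pB) + D)
    p[p < 0 & p > -1e-12] <- 0
    if (any(p < 0)) return(-Inf)
    .genotype_loglik(n, p)
  }, numeric(1))
  if (all(!is.finite(ll))) stop_gshap("degenerate likelihood profile")
  w <- exp(ll - max(ll, na.rm = TRUE))
  w[!is.finite(w)] <- 0
  cum <- cumsum(w) / sum(w)
  ci_low <- grid[which(cum >= alpha_tail)[1]]
  ci_high <- grid[which(cum >= 1 - alpha_tail)[1]]
  list(ci_low = ci_low, ci_high = ci_high,
       Dprime = st$Dprime, r2 = st$r2, n_informative = em$n_informative)
}
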