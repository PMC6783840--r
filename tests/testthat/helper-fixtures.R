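# Shared fixtures and independent oracles, all generated in code.

# small breeding population with planted LD segments
tiny_population <- function(seed = 1, n_markers = 120, n_families = 20,
                            n_segments = 4, traits = list(t = list(n_qtl = 30, h2 = 0.4))) {
  simulate_population(
    n_chromosomes = 2, n_markers = n_markers, chromosome_length_bp = 2e6,
    n_families = n_families, progeny_per_family = 10,
    half_sib_fraction = 0.5, n_founders = 2 * n_families,
    n_segments = n_segments, traits = traits, seed = seed
  )
}

# unrelated panel with one planted perfect-LD segment on chromosome 1
planted_panel <- function(n = 400, n_markers = 40, seg = c(18, 22), seed = 13) {
  map <- make_marker_map(1, n_markers, 1e6, seed = seed)
  spec <- founder_spec(map, segments = data.frame(start = seg[1], end = seg[2]),
                       seed = seed + 1)
  phased <- sample_founder_genotypes(spec, map, n, seed = seed + 2)
  list(map = map, spec = spec, phased = phased, genotypes = dosages(phased))
}

# independent oracle: genotype-table log-likelihood under haplotype
# frequencies (HWE pairing), written without package internals
oracle_loglik <- function(tab, p11, p12, p21, p22) {
  gp <- matrix(0, 3, 3)
  gp[3, 3] <- p11^2;            gp[3, 2] <- 2 * p11 * p12;  gp[3, 1] <- p12^2
  gp[2, 3] <- 2 * p11 * p21
  gp[2, 2] <- 2 * p11 * p22 + 2 * p12 * p21
  gp[2, 1] <- 2 * p12 * p22
  gp[1, 3] <- p21^2;            gp[1, 2] <- 2 * p21 * p22;  gp[1, 1] <- p22^2
  if (any(gp[tab > 0] <= 0)) return(-Inf)
  sum(tab[tab > 0] * log(gp[tab > 0]))
}

# brute-force maximum of the same likelihood over D at the observed allele
# frequencies (EM fixed points always preserve the observed marginals)
oracle_grid_max <- function(ga, gb, n_grid = 4001) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  tab <- matrix(0, 3, 3)
  for (i in seq_along(ga)) tab[ga[i] + 1, gb[i] + 1] <- tab[ga[i] + 1, gb[i] + 1] + 1
  N <- sum(tab)
  pA <- (2 * sum(tab[3, ]) + sum(tab[2, ])) / (2 * N)
  pB <- (2 * sum(tab[, 3]) + sum(tab[, 2])) / (2 * N)
  d_lo <- -min(pA * pB, (1 - pA) * (1 - pB))
  d_hi <- min(pA * (1 - pB), (1 - pA) * pB)
  grid <- seq(d_lo, d_hi, length.out = n_grid)
  ll <- vapply(grid, function(D) {
    oracle_loglik(tab, pA * pB + D, pA * (1 - pB) - D,
                  (1 - pA) * pB - D, (1 - pA) * (1 - pB) + D)
  }, numeric(1))
  max(ll, na.rm = TRUE)
}

# independent tabular-method relationship matrix (recursive definition)
oracle_tabular_a <- function(sire, dam) {
  n <- length(sire)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      if (i == j) {
        A[i, i] <- 1 + if (sire[i] > 0 && dam[i] > 0) 0.5 * A[sire[i], dam[i]] else 0
      } else {
        v <- 0
        if (sire[i] > 0) v <- v + 0.5 * A[j, sire[i]]
        if (dam[i] > 0) v <- v + 0.5 * A[j, dam[i]]
        A[i, j] <- A[j, i] <- v
      }
    }
  }
  A
}

# random unphased genotype pair with given LD structure, for property tests
random_genotype_pair <- function(n, p11, p12, p21, p22) {
  hap <- sample.int(4, 2 * n, replace = TRUE, prob = c(p11, p12, p21, p22))
  a <- as.integer(hap %in% c(1, 2))  # allele A1
  b <- as.integer(hap %in% c(1, 3))  # allele B1
  ga <- a[seq_len(n)] + a[n + seq_len(n)]
  gb <- b[seq_len(n)] + b[n + seq_len(n)]
  list(ga = ga, gb = gb)
}
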