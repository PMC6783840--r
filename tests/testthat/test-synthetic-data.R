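test_that("marker maps are sorted, strictly increasing and evenly split", {
  map <- make_marker_map(1, 5, 1000, seed = 1)
  expect_equal(nrow(map), 5)
  expect_true(all(diff(map$position_bp) > 0))
  expect_true(all(map$position_bp >= 1 & map$position_bp <= 1000))

  map2 <- make_marker_map(11, 1100, 5e7, seed = 7)
  expect_equal(unname(table(map2$chromosome)), rep(100L, 11), ignore_attr = TRUE)
  expect_false(anyDuplicated(map2$marker_id) > 0)

  expect_error(make_marker_map(2, 10, 5, seed = 1), "too short")
  expect_error(make_marker_map(0, 10, 100), "n_markers")
})

test_that("pedigree simulation respects family structure and sire rules", {
  ped <- simulate_pedigree(1, 4, 0, 2, seed = 3)
  prog <- ped[ped$generation == 1, ]
  expect_equal(nrow(prog), 4)
  expect_equal(length(unique(prog$sire_id)), 1)
  expect_equal(length(unique(prog$dam_id)), 1)
  expect_false(anyNA(prog$sire_id))

  ped2 <- simulate_pedigree(65, 10, 0.5, 130, seed = 9)
  prog2 <- ped2[ped2$generation == 1, ]
  expect_equal(nrow(prog2), 650)
  hs_fams <- tapply(is.na(prog2$sire_id), prog2$family_id, all)
  expect_equal(sum(hs_fams), round(0.5 * 65))
  # each family has exactly one dam
  expect_true(all(tapply(prog2$dam_id, prog2$family_id,
                         function(d) length(unique(d))) == 1))

  ped3 <- simulate_pedigree(2, 3, 1, 4, seed = 1)
  expect_true(all(is.na(ped3$sire_id[ped3$generation == 1])))
  expect_error(simulate_pedigree(2, 3, 0, 1, seed = 1), "founders")
})

test_that("gene dropping is Mendelian and zero recombination copies a parent", {
  pop <- tiny_population(seed = 2, n_families = 6)
  geno <- dosages(pop$phased)
  ped <- pop$pedigree
  trios <- ped[!is.na(ped$sire_id) & !is.na(ped$dam_id), ]
  violations <- 0
  for (i in seq_len(nrow(trios))) {
    o <- geno[trios$individual_id[i], ]
    s <- geno[trios$sire_id[i], ]
    d <- geno[trios$dam_id[i], ]
    # each parent must be able to contribute the required allele
    lo <- (s == 2) + (d == 2)                    # forced 1-alleles
    hi <- 2 - ((s == 0) + (d == 0))              # forced 0-alleles
    violations <- violations + sum(o < lo | o > hi)
  }
  expect_equal(violations, 0)

  map <- make_marker_map(1, 30, 1e5, seed = 5)
  spec <- founder_spec(map, seed = 6)
  ped0 <- simulate_pedigree(2, 3, 0, 4, seed = 7)
  ph <- drop_genotypes(ped0, map, spec, recomb_rate_per_bp = 0, seed = 8)
  for (i in which(ped0$generation == 1)) {
    di <- match(ped0$dam_id[i], ped0$individual_id)
    expect_true(identical(ph$h1[i, ], ph$h1[di, ]) ||
                identical(ph$h1[i, ], ph$h2[di, ]))
  }
})

test_that("planted founder segments carry D' = 1 between member loci", {
  pan <- planted_panel(n = 200, seed = 11)
  seg <- pan$spec$segments
  idx <- seg$start[1]:seg$end[1]
  haps <- rbind(pan$phased$h1, pan$phased$h2)
  for (a in idx[-length(idx)]) for (b in idx[idx > a]) {
    p11 <- mean(haps[, a] == 1 & haps[, b] == 1)
    p10 <- mean(haps[, a] == 1 & haps[, b] == 0)
    p01 <- mean(haps[, a] == 0 & haps[, b] == 1)
    p00 <- mean(haps[, a] == 0 & haps[, b] == 0)
    st <- ld_stats(c(p11, p10, p01, p00))
    expect_equal(st$Dprime, 1, tolerance = 1e-12)
  }
})

test_that("frequency validation rejects out-of-range founder spec", {
  map <- make_marker_map(1, 10, 1e4, seed = 1)
  expect_error(founder_spec(map, freq = rep(0.02, 10)), "0.05")
})

test_that("phenotype simulation hits the target heritability and design", {
  pop <- tiny_population(seed = 4, n_families = 65)
  sim <- simulate_phenotypes(pop$phased, pop$pedigree, n_qtl = 30,
                             target_h2 = 0.4, seed = 9)
  phen <- sim$phenotypes
  tbv <- sim$truth$true_breeding_values
  # slope of phenotype on true BV ~ 1
  sl <- coef(lm(phen$t ~ tbv))[2]
  expect_gt(sl, 0.8); expect_lt(sl, 1.2)
  # single-tree plots: a family appears at most once per block
  expect_false(any(duplicated(phen[c("family_id", "design_block")])))
  # heritability targeting over replicates
  h2s <- vapply(1:20, function(r) {
    s <- simulate_phenotypes(pop$phased, pop$pedigree, 30, 0.4, seed = 100 + r)
    v_b <- var(s$truth$true_breeding_values)
    resid <- s$phenotypes$t - s$truth$trait_mean -
      s$truth$block_effects[s$phenotypes$design_block] -
      s$truth$true_breeding_values
    v_b / (v_b + var(resid))
  }, numeric(1))
  expect_lt(abs(mean(h2s) - 0.4), 0.05)

  expect_error(simulate_phenotypes(pop$phased, pop$pedigree, 30, 0),
               "target_h2")
})

test_that("ordinal traits use equal-probability thresholds", {
  pop <- tiny_population(seed = 6, n_families = 65)
  sim <- simulate_phenotypes(pop$phased, pop$pedigree, 30, 0.3,
                             ordinal_spec = list(levels = 7), seed = 12)
  freqs <- table(factor(sim$phenotypes$t, levels = 0:6)) / 650
  expect_true(all(abs(freqs - 1 / 7) < 0.05))
  expect_true(all(sim$phenotypes$t %in% 0:6))
})

test_that("identical seeds reproduce the simulation bit for bit", {
  a <- tiny_population(seed = 42, n_families = 4)
  b <- tiny_population(seed = 42, n_families = 4)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$t$qtl_effects, b$truth$t$qtl_effects)
})

test_that("inter-chromosomal founder LD vanishes with panel size", {
  map <- make_marker_map(2, 40, 1e6, seed = 21)
  spec <- founder_spec(map, seed = 22)
  g <- dosages(sample_founder_genotypes(spec, map, 400, seed = 23))
  chr <- map$chromosome
  r2 <- c()
  set.seed(24)
  for (k in 1:60) {
    i <- sample(which(chr == 1), 1); j <- sample(which(chr == 2), 1)
    r2 <- c(r2, ld_stats(em_two_locus(g[, i], g[, j]))$r2)
  }
  expect_lt(mean(r2), 0.02)
})
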