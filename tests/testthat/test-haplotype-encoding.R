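test_that("block EM equals direct counts when no phase ambiguity exists", {
  # 2-SNP block, no double heterozygotes: 40 x (11,11), 30 x (00,00),
  # 30 x (11,00) -> haplotypes 11 (0.55), 00 (0.45)
  g <- rbind(matrix(2, 40, 2),                 # 11 / 11
             matrix(0, 30, 2),                 # 00 / 00
             cbind(rep(2, 30), rep(0, 30)))    # 10 / 10
  set <- em_block_haplotypes(g)
  v <- set$variants
  expect_setequal(v$haplotype, c("11", "00", "10"))
  expect_equal(v$frequency[v$haplotype == "11"], 2 * 40 / 200, tolerance = 1e-9)
  expect_equal(v$frequency[v$haplotype == "10"], 2 * 30 / 200, tolerance = 1e-9)
  expect_equal(v$frequency[v$haplotype == "00"], 2 * 30 / 200, tolerance = 1e-9)
})

test_that("block EM recovers a known variant pool within 0.03", {
  set.seed(19)
  pool <- c("000", "011", "101", "110")
  pfreq <- c(0.4, 0.3, 0.2, 0.1)
  n <- 400
  pick <- function() pool[sample.int(4, 1, prob = pfreq)]
  g <- t(vapply(seq_len(n), function(i) {
    h1 <- as.integer(strsplit(pick(), "")[[1]])
    h2 <- as.integer(strsplit(pick(), "")[[1]])
    h1 + h2
  }, integer(3)))
  set <- em_block_haplotypes(g)
  est <- setNames(set$variants$frequency, set$variants$haplotype)
  for (k in seq_along(pool))
    expect_lt(abs(est[pool[k]] - pfreq[k]), 0.03)
})

test_that("diplotypes marginalize over missing sites but stay consistent", {
  g <- rbind(c(2, 2), c(0, 0), c(2, 0), c(2, NA), c(0, 0), c(2, 2))
  set <- em_block_haplotypes(g)
  cc <- assign_diplotypes(set)
  d4 <- set$diplotypes[4, ]
  expect_false(anyNA(d4))
  # observed site 1 has dosage 2: both assigned variants start with allele 1
  haps <- set$variants$haplotype[d4]
  expect_true(all(substr(haps, 1, 1) == "1"))
})

test_that("copy coding matches the 0/1/2 rule", {
  # construct a block set with three variants and known diplotypes
  g <- rbind(c(0, 0), c(1, 1), c(2, 2), c(1, 1), c(0, 0))
  set <- em_block_haplotypes(g)
  cc <- assign_diplotypes(set)
  expect_true(all(rowSums(cc, na.rm = TRUE) == 2))
  expect_true(all(cc %in% 0:2))
  # homozygous-at-all-SNPs rows have a forced single diplotype
  hom <- which(apply(g, 1, function(r) all(r %in% c(0, 2))))
  for (i in hom) {
    d <- set$diplotypes[i, ]
    expect_equal(d[1], d[2])
    expect_equal(unname(cc[i, d[1]]), 2L)
  }
})

test_that("phase round-trip succeeds on perfect-LD blocks", {
  pan <- planted_panel(n = 300, n_markers = 30, seg = c(10, 14), seed = 43)
  idx <- 10:14
  set <- em_block_haplotypes(pan$genotypes[, idx])
  cc <- assign_diplotypes(set)
  # truth: per-individual pair of haplotype strings
  truth_str <- function(h) apply(h[, idx, drop = FALSE], 1, paste, collapse = "")
  t1 <- truth_str(pan$phased$h1); t2 <- truth_str(pan$phased$h2)
  est1 <- set$variants$haplotype[set$diplotypes[, 1]]
  est2 <- set$variants$haplotype[set$diplotypes[, 2]]
  match_ok <- (est1 == t1 & est2 == t2) | (est1 == t2 & est2 == t1)
  expect_gte(mean(match_ok), 0.95)
  # copy-sum conservation with complete data and no filtered variants
  expect_true(all(rowSums(cc) == 2))
})

test_that("design matrices implement the three marker sets", {
  pop <- tiny_population(seed = 47, n_families = 30)
  blocks <- gabriel_blocks(pop$genotypes, pop$marker_map)
  expect_gt(nrow(blocks), 0)  # planted segments guarantee blocks here
  d_snp <- build_design(pop$genotypes, blocks, "SNP")
  d_hap <- build_design(pop$genotypes, blocks, "HAP")
  d_hs <- build_design(pop$genotypes, blocks, "HAP_SNP")

  m <- ncol(pop$genotypes)
  in_block <- sum(blocks$n_snps)
  expect_equal(ncol(d_snp$M), m)
  # HAP_SNP = retained variants + SNPs outside blocks, exactly
  expect_equal(ncol(d_hs$M), ncol(d_hap$M) + (m - in_block))
  # SNP coding: 2 is the common-allele homozygote, so column means >= 1
  expect_true(all(colMeans(d_snp$M) >= 1 - 1e-9))
  # per-column frequency is column mean / 2
  expect_equal(d_snp$freq, unname(colMeans(d_snp$M)) / 2, tolerance = 1e-12)
  # per block, retained-variant copies sum to at most 2
  hap_src <- d_hap$source
  for (b in unique(hap_src$block)) {
    cols <- which(hap_src$block == b)
    expect_true(all(rowSums(d_hap$M[, cols, drop = FALSE]) <= 2 + 1e-9))
  }
})

test_that("with no blocks the combined design collapses to the SNP design", {
  map <- make_marker_map(1, 20, 1e6, seed = 53)
  spec <- founder_spec(map, seed = 54)
  g <- dosages(sample_founder_genotypes(spec, map, 200, seed = 55))
  blocks <- gabriel_blocks(g, map)
  expect_equal(nrow(blocks), 0)
  d_snp <- build_design(g, blocks, "SNP")
  d_hs <- build_design(g, blocks, "HAP_SNP")
  expect_equal(d_hs$M, d_snp$M)
  expect_error(build_design(g, blocks, "HAP"), "no columns")
})

test_that("oversized blocks are rejected with advice to split", {
  g <- matrix(rbinom(100 * 16, 2, 0.5), 100, 16)
  expect_error(em_block_haplotypes(g), "cap")
})
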