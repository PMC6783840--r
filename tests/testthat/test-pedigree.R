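founder_row <- function(id) data.frame(individual_id = id,
                                       sire_id = NA_character_,
                                       dam_id = NA_character_,
                                       family_id = NA_character_,
                                       generation = 0L,
                                       stringsAsFactors = FALSE)
child_row <- function(id, s, d, gen = 1L) data.frame(individual_id = id,
                                                     sire_id = s, dam_id = d,
                                                     family_id = "f",
                                                     generation = gen,
                                                     stringsAsFactors = FALSE)
as_ped <- function(df) { class(df) <- c("pedigree", "data.frame"); df }

test_that("A is the identity for unrelated founders", {
  ped <- as_ped(rbind(founder_row("a"), founder_row("b"), founder_row("c")))
  Ainv <- build_a_inverse(ped)
  expect_equal(as.matrix(Ainv), diag(3), ignore_attr = TRUE)
  expect_equal(a_matrix(ped), diag(3), ignore_attr = TRUE)
})

test_that("trio relationships match the textbook values", {
  ped <- as_ped(rbind(founder_row("s"), founder_row("d"),
                      child_row("o", "s", "d")))
  A <- solve(as.matrix(build_a_inverse(ped)))
  expect_equal(diag(A), rep(1, 3), ignore_attr = TRUE)
  expect_equal(A["o", "s"], 0.5)
  expect_equal(A["o", "d"], 0.5)
  expect_equal(A["s", "d"], 0)
})

test_that("A-inverse inverts to the tabular-method A on toy pedigrees", {
  # full sibs, half sibs (shared dam, unknown sires), and a grandchild
  ped <- as_ped(rbind(founder_row("s1"), founder_row("d1"), founder_row("d2"),
                      child_row("fs1", "s1", "d1"),
                      child_row("fs2", "s1", "d1"),
                      child_row("hs1", NA_character_, "d2"),
                      child_row("hs2", NA_character_, "d2"),
                      child_row("gc", "fs1", "hs1", gen = 2L)))
  sire_ix <- match(ped$sire_id, ped$individual_id); sire_ix[is.na(sire_ix)] <- 0
  dam_ix <- match(ped$dam_id, ped$individual_id); dam_ix[is.na(dam_ix)] <- 0
  A_oracle <- oracle_tabular_a(sire_ix, dam_ix)
  A_pkg <- solve(as.matrix(build_a_inverse(ped)))
  expect_equal(unname(A_pkg), A_oracle, tolerance = 1e-8)
  expect_equal(A_pkg["fs1", "fs2"], 0.5)
  expect_equal(A_pkg["hs1", "hs2"], 0.25)
})

test_that("inbreeding from full-sib mating enters the recursion", {
  ped <- as_ped(rbind(founder_row("s"), founder_row("d"),
                      child_row("c1", "s", "d"),
                      child_row("c2", "s", "d"),
                      child_row("x", "c1", "c2", gen = 2L)))
  FF <- inbreeding_coefficients(ped)
  expect_equal(FF, c(0, 0, 0, 0, 0.25))
  sire_ix <- match(ped$sire_id, ped$individual_id); sire_ix[is.na(sire_ix)] <- 0
  dam_ix <- match(ped$dam_id, ped$individual_id); dam_ix[is.na(dam_ix)] <- 0
  A_pkg <- solve(as.matrix(build_a_inverse(ped)))
  expect_equal(unname(A_pkg), oracle_tabular_a(sire_ix, dam_ix),
               tolerance = 1e-8)
})

test_that("pedigree validation rejects broken structures", {
  bad <- as_ped(rbind(child_row("o", "s", "d"), founder_row("s"),
                      founder_row("d")))
  expect_error(build_a_inverse(bad), "precede")
  bad2 <- as_ped(rbind(founder_row("s"), child_row("o", "s", "ghost")))
  expect_error(build_a_inverse(bad2), "not in pedigree")
})

test_that("animal model is deterministic and h2 is the per-draw ratio", {
  pop <- tiny_population(seed = 57, n_families = 20)
  mc <- mcmc_settings(1500, 500, 5)
  f1 <- fit_animal_model(pop$phenotypes, "t", pop$pedigree, mcmc = mc, seed = 5)
  f2 <- fit_animal_model(pop$phenotypes, "t", pop$pedigree, mcmc = mc, seed = 5)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$a_samples, f2$a_samples)
  expect_equal(f1$samples$h2,
               f1$samples$sigma_a2 / (f1$samples$sigma_a2 + f1$samples$sigma_e2))
  expect_true(all(f1$samples$sigma_a2 > 0 & f1$samples$sigma_e2 > 0))
  expect_true(all(f1$samples$h2 > 0 & f1$samples$h2 < 1))
})

test_that("founders-only animal model agrees with an exchangeable ridge fit", {
  # with A = I the animal model collapses to y = Xb + u, u ~ N(0, I s2);
  # an identity-design whole-genome ridge with matched priors is the same
  # model sampled by a different code path
  set.seed(61)
  n <- 150
  ped <- as_ped(do.call(rbind, lapply(sprintf("f%03d", 1:n), founder_row)))
  u <- rnorm(n, 0, 2)
  y <- 10 + u + rnorm(n, 0, 2)
  phen <- data.frame(individual_id = ped$individual_id, design_block = 1L,
                     t = y, stringsAsFactors = FALSE)
  mc <- mcmc_settings(4000, 1000, 5)
  vy <- var(y)
  S <- 0.5 * vy * (5 + 2) / 5
  fa <- fit_animal_model(phen, "t", ped, mcmc = mc, seed = 7)
  spec <- model_spec("BRR", nu_m = 5, S_m = S, nu_e = 5, S_e = S, mcmc = mc)
  fg <- fit_whole_regression(y, matrix(1, n, 1), diag(n), spec, seed = 7)
  h_a <- mean(fa$samples$h2)
  h_g <- mean(fg$samples$sigma_m2 /
              (fg$samples$sigma_m2 + fg$samples$sigma_e2))
  expect_lt(abs(h_a - h_g), 0.05)
})

test_that("pedigree EBVs regressed on themselves give R2 = 1", {
  pop <- tiny_population(seed = 63, n_families = 10)
  fit <- fit_animal_model(pop$phenotypes, "t", pop$pedigree,
                          mcmc = mcmc_settings(800, 300, 5), seed = 3)
  r <- ebv_gebv_regression(fit$ebv, fit$ebv)
  expect_equal(r$slope, 1)
  expect_equal(r$r_squared, 1)
})
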