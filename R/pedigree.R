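# Pedigree machinery: additive-relationship inverse by Henderson's rules
# with Meuwissen-Luo inbreeding, and the Bayesian animal model
# y = X beta + Z a + e,  a ~ N(0, A sigma_a^2), fitted by Gibbs sampling.

# parent row indices (0 when unknown), pedigree assumed ordered
.parent_index <- function(ped) {
  norm <- function(p) {
    p[!is.na(p) & p == UNKNOWN_PARENT] <- NA
    ix <- match(p, ped$individual_id)
    ix[is.na(ix)] <- 0L
    ix
  }
  list(sire = norm(ped$sire_id), dam = norm(ped$dam_id))
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' @param pedigree a `pedigree` data frame, parents before offspring.
#' @return numeric vector of inbreeding coefficients F, one per individual.
#' @export
inbreeding_coefficients <- function(pedigree) {
  validate_pedigree(pedigree)
  pi <- .parent_index(pedigree)
  n <- nrow(pedigree)
  s <- pi$sire; d <- pi$dam
  FF <- numeric(n)
  L <- numeric(n)   # within-round scratch of the L vector
  DD <- numeric(n)  # Mendelian-sampling variances
  for (i in seq_len(n)) {
    DD[i] <- 0.5 - 0.25 * ((if (s[i] > 0) FF[s[i]] else -1) +
                           (if (d[i] > 0) FF[d[i]] else -1))
    if (s[i] == 0 || d[i] == 0) { FF[i] <- 0; next }
    # accumulate A[i,i] = sum_j L_j^2 D_j over ancestors j of i
    L[] <- 0
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * DD[j]
      if (s[j] > 0) L[s[j]] <- L[s[j]] + 0.5 * L[j]
      if (d[j] > 0) L[d[j]] <- L[d[j]] + 0.5 * L[j]
    }
    FF[i] <- aii - 1
  }
  FF
}

#' Inverse additive-relationship matrix (Henderson's rules)
#'
#' Builds the inverse of Wright's numerator relationship matrix A directly
#' from the pedigree using Henderson's recursive contributions, with
#' Mendelian-sampling variances adjusted for parental inbreeding
#' (Meuwissen-Luo). Unknown parents contribute nothing (open-pollination
#' treatment of half-sib sires).
#'
#' @param pedigree a `pedigree` data frame, parents before offspring.
#' @return sparse symmetric `Matrix::dsCMatrix`, rows/cols named by
#'   individual id.
#' @export
build_a_inverse <- function(pedigree) {
  validate_pedigree(pedigree)
  pi <- .parent_index(pedigree)
  s <- pi$sire; d <- pi$dam
  n <- nrow(pedigree)
  FF <- inbreeding_coefficients(pedigree)
  Fpar <- function(ix) if (ix > 0) FF[ix] else -1
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii[[length(ii) + 1]] <<- i; jj[[length(jj) + 1]] <<- j
    xx[[length(xx) + 1]] <<- v
  }
  for (k in seq_len(n)) {
    dk <- 0.5 - 0.25 * (Fpar(s[k]) + Fpar(d[k]))  # Mendelian variance
    ak <- 1 / dk
    add(k, k, ak)
    for (p in c(s[k], d[k])) if (p > 0) {
      add(k, p, -0.5 * ak); add(p, k, -0.5 * ak)
    }
    if (s[k] > 0 && d[k] > 0) {
      add(s[k], s[k], 0.25 * ak)
      add(d[k], d[k], 0.25 * ak)
      add(s[k], d[k], 0.25 * ak)
      add(d[k], s[k], 0.25 * ak)
    } else {
      for (p in c(s[k], d[k])) if (p > 0) add(p, p, 0.25 * ak)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(pedigree$individual_id,
                                               pedigree$individual_id))
  Matrix::forceSymmetric(Ainv)
}

#' Additive-relationship matrix by the tabular method
#'
#' Direct dense construction of Wright's A; intended for small pedigrees
#' (cross-checks, EBV summaries), not for model fitting.
#' @inheritParams build_a_inverse
#' @export
a_matrix <- function(pedigree) {
  validate_pedigree(pedigree)
  pi <- .parent_index(pedigree)
  s <- pi$sire; d <- pi$dam
  n <- nrow(pedigree)
  A <- matrix(0, n, n, dimnames = list(pedigree$individual_id,
                                       pedigree$individual_id))
  for (i in seq_len(n)) {
    A[i, i] <- 1 + (if (s[i] > 0 && d[i] > 0) 0.5 * A[s[i], d[i]] else 0)
    if (i == 1) next
    for (j in seq_len(i - 1)) {
      v <- 0
      if (s[i] > 0) v <- v + 0.5 * A[j, s[i]]
      if (d[i] > 0) v <- v + 0.5 * A[j, d[i]]
      A[i, j] <- A[j, i] <- v
    }
  }
  A
}

#' MCMC settings
#'
#' Desk-scale defaults; the long-chain settings used for production runs
#' (1e6 iterations, 1e5 burn-in, thin 50) are available by passing them
#' explicitly.
#'
#' @param iterations total Gibbs iterations.
#' @param burn_in discarded initial iterations.
#' @param thin keep every `thin`-th draw after burn-in.
#' @export
mcmc_settings <- function(iterations = 20000, burn_in = 2000, thin = 10) {
  stopifnot(iterations > burn_in, thin >= 1)
  list(iterations = as.integer(iterations), burn_in = as.integer(burn_in),
       thin = as.integer(thin))
}

# scaled-inverse-chi-squared scale parameter with prior mode `mode` at df nu
.siq_scale <- function(mode, nu) mode * (nu + 2) / nu

#' Indicator matrix of design blocks
#'
#' One 0/1 column per observed block level (no intercept); robust to a
#' single level.
#' @param design_block vector of block labels.
#' @export
block_indicators <- function(design_block) {
  lev <- sort(unique(design_block))
  X <- vapply(lev, function(l) as.numeric(design_block == l),
              numeric(length(design_block)))
  X <- matrix(X, nrow = length(design_block))
  colnames(X) <- paste0("block", lev)
  X
}

#' Fit the Bayesian animal model
#'
#' Gibbs sampler for `y = X beta + Z a + e` with `a ~ N(0, A sigma_a^2)`
#' and `e ~ N(0, I sigma_e^2)`: flat-prior normal full conditionals for the
#' design-block effects, single-site normal full conditionals for the
#' additive effects using the sparse A-inverse, and scaled-inverse-chi-
#' squared full conditionals for both variances. Priors are weakly
#' informative: df 5, prior mode of each variance at half the phenotypic
#' variance.
#'
#' @param phenotypes `data.frame` with `individual_id`, `design_block` and
#'   the trait column.
#' @param trait name of the trait column.
#' @param pedigree a `pedigree`; every phenotyped individual must appear.
#' @param a_inverse optional precomputed [build_a_inverse()] result.
#' @param mcmc a [mcmc_settings()] list.
#' @param seed integer seed.
#' @param prior_df prior degrees of freedom for both variances.
#' @return list of class `pedigree_fit`: `samples` (`data.frame` with
#'   `sigma_a2`, `sigma_e2`, `h2` per retained draw), `a_samples` (draws x
#'   individuals matrix), `beta_samples`, `ebv` (posterior-mean additive
#'   effects, named), `h2` (list `mean`, `ci90`), `sigma_a2`, `sigma_e2`,
#'   `trait`.
#' @export
fit_animal_model <- function(phenotypes, trait, pedigree, a_inverse = NULL,
                             mcmc = mcmc_settings(), seed = 1L,
                             prior_df = 5) {
  validate_pedigree(pedigree)
  y <- phenotypes[[trait]]
  if (is.null(y)) stop_gshap("trait '%s' not found in phenotypes", trait)
  keep <- !is.na(y)
  y <- as.numeric(y[keep])
  if (length(y) < 2 || var(y) <= 0) stop_gshap("phenotype has no variance")
  ids <- phenotypes$individual_id[keep]
  zind <- match(ids, pedigree$individual_id)
  if (anyNA(zind)) stop_gshap("phenotyped individual '%s' missing from pedigree",
                              ids[is.na(zind)][1])
  blocks <- phenotypes$design_block[keep]
  X <- block_indicators(blocks)
  if (is.null(a_inverse)) a_inverse <- build_a_inverse(pedigree)
  Ai <- methods::as(methods::as(a_inverse, "generalMatrix"), "CsparseMatrix")
  vy <- var(y)
  Sa <- .siq_scale(0.5 * vy, prior_df)
  Se <- .siq_scale(0.5 * vy, prior_df)
  set.seed(seed)
  fit <- gibbs_animal_cpp(y, X, zind - 1L, Ai@p, Ai@i, Ai@x,
                          nrow(pedigree), prior_df, Sa, prior_df, Se,
                          mcmc$iterations, mcmc$burn_in, mcmc$thin)
  a_samples <- fit$a
  colnames(a_samples) <- pedigree$individual_id
  h2 <- fit$sigma_a2 / (fit$sigma_a2 + fit$sigma_e2)
  samples <- data.frame(sigma_a2 = fit$sigma_a2, sigma_e2 = fit$sigma_e2,
                        h2 = h2)
  structure(list(
    samples = samples, a_samples = a_samples, beta_samples = fit$beta,
    ebv = setNames(colMeans(a_samples), pedigree$individual_id),
    h2 = list(mean = mean(h2), ci90 = unname(quantile(h2, c(0.05, 0.95)))),
    sigma_a2 = mean(fit$sigma_a2), sigma_e2 = mean(fit$sigma_e2),
    trait = trait
  ), class = "pedigree_fit")
}
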