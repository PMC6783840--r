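# Whole-genome regression: y = X beta + Z m + e with model-specific priors
# on marker effects (the Bayesian alphabet), and the downstream genomic
# variance, heritability and genetic-gain summaries.

.MODEL_CODES <- c(BRR = 0L, BA = 1L, BB = 2L, BC = 3L, BL = 4L)

#' Specify a Bayesian whole-genome regression model
#'
#' Hyperparameters default to the usual apportioning convention: the prior
#' mode of the total marker contribution explains `R2` (default 0.5) of the
#' phenotypic variance, scaled-inverse-chi-squared priors carry `df` 5, the
#' mixture mass at zero `pi` gets a flat Beta(1,1) prior and is sampled
#' unless `pi_fixed`, and the LASSO rate parameter `lambda^2` has a Gamma
#' prior whose mode matches the same apportioning. Unset values (`NULL`)
#' are resolved against the data when fitting.
#'
#' @param model one of `"BRR"`, `"BA"`, `"BB"`, `"BC"`, `"BL"`.
#' @param nu_m,S_m df and scale of the scaled-inverse-chi-squared prior on
#'   marker-effect variances; `S_m = NULL` resolves from `R2`.
#' @param pi prior/initial mixture mass at zero (BB/BC).
#' @param pi_fixed keep `pi` fixed instead of sampling it.
#' @param phi1,phi2 shape and rate of the Gamma prior on `lambda^2` (BL);
#'   `phi2 = NULL` resolves from `R2`.
#' @param bl_printed_rate use the `Exp(lambda^2)` rate convention for the
#'   latent scales instead of the Park-Casella `Exp(lambda^2/2)` default.
#' @param R2 prior proportion of phenotypic variance attributed to markers.
#' @param nu_e,S_e residual-variance prior df and scale; `S_e = NULL`
#'   resolves from `R2`.
#' @param mcmc a [mcmc_settings()] list.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(model = c("BRR", "BA", "BB", "BC", "BL"),
                       nu_m = 5, S_m = NULL, pi = 0.5, pi_fixed = FALSE,
                       phi1 = 1.1, phi2 = NULL, bl_printed_rate = FALSE,
                       R2 = 0.5, nu_e = 5, S_e = NULL,
                       mcmc = mcmc_settings()) {
  model <- match.arg(model)
  stopifnot(nu_m > 0, nu_e > 0, phi1 > 0, pi > 0, pi < 1, R2 > 0, R2 < 1)
  structure(list(model = model, nu_m = nu_m, S_m = S_m, pi = pi,
                 pi_fixed = pi_fixed, phi1 = phi1, phi2 = phi2,
                 bl_printed_rate = bl_printed_rate, R2 = R2,
                 nu_e = nu_e, S_e = S_e, mcmc = mcmc),
            class = "model_spec")
}

#' Fit a Bayesian whole-genome regression by Gibbs sampling
#'
#' Fits `y = X beta + Z m + e` where `Z` holds SNP dosages and/or haplotype
#' copy counts. Marker effects get the prior named in `spec`: a common
#' normal variance (BRR), per-marker scaled-inverse-chi-squared variances
#' (Bayes A), a point-mass/normal mixture with per-marker (Bayes B) or
#' common (Bayes C-pi) slab variance, or the double-exponential via its
#' normal/exponential scale mixture (Bayesian LASSO). Fixed effects carry
#' flat priors; variances scaled-inverse-chi-squared full conditionals.
#'
#' @param y numeric response (no missing values).
#' @param fixed_design numeric matrix of fixed-effect regressors (e.g.
#'   design-block indicators), rows aligned with `y`.
#' @param marker_design a `design_matrix` from [build_design()], or a
#'   numeric matrix (then `freq` defaults to column mean / 2).
#' @param spec a [model_spec()].
#' @param seed integer seed.
#' @return list of class `genomic_fit`: `samples` (list of chains: `beta`,
#'   `m`, `sigma_e2`, and the model's variance parameters), `gebv`
#'   (posterior-mean marker part, named by row), `m_hat`, `sigma_g2` (draws),
#'   `h2` (list `mean`, `ci90`, `draws`), `freq`, `model`, `spec`.
#' @export
fit_whole_regression <- function(y, fixed_design, marker_design, spec,
                                 seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  if (inherits(marker_design, "design_matrix")) {
    Z <- marker_design$M
    freq <- marker_design$freq
  } else {
    Z <- as.matrix(marker_design)
    freq <- colMeans(Z, na.rm = TRUE) / 2
  }
  y <- as.numeric(y)
  if (anyNA(y)) stop_gshap("missing phenotypes must be dropped upstream")
  if (length(y) < 2 || var(y) <= 0) stop_gshap("phenotype has no variance")
  X <- as.matrix(fixed_design)
  if (nrow(X) != length(y) || nrow(Z) != length(y))
    stop_gshap("rows of y, fixed_design and marker_design must align")
  vy <- var(y)
  msx <- 2 * sum(freq * (1 - freq))
  if (msx <= 0) stop_gshap("all marker columns monomorphic")
  S_m <- spec$S_m %||% .siq_scale(vy * spec$R2 / msx, spec$nu_m)
  S_e <- spec$S_e %||% .siq_scale(vy * (1 - spec$R2), spec$nu_e)
  lambda2_0 <- 2 * msx * (1 - spec$R2) / spec$R2
  phi2 <- spec$phi2 %||% ((spec$phi1 - 1) / lambda2_0)
  if (phi2 <= 0) phi2 <- 1e-4
  set.seed(seed)
  raw <- gibbs_wgr_cpp(y, X, Z, .MODEL_CODES[[spec$model]],
                       spec$nu_m, S_m, spec$nu_e, S_e,
                       spec$pi, spec$pi_fixed, spec$phi1, phi2, lambda2_0,
                       spec$bl_printed_rate,
                       spec$mcmc$iterations, spec$mcmc$burn_in,
                       spec$mcmc$thin)
  m_hat <- colMeans(raw$m)
  gebv <- as.vector(Z %*% m_hat)
  names(gebv) <- rownames(Z)
  fit <- structure(list(samples = raw, gebv = gebv, m_hat = m_hat,
                        freq = freq, model = spec$model, spec = spec,
                        S_m = S_m, S_e = S_e),
                   class = "genomic_fit")
  fit$sigma_g2 <- genomic_variance(raw, freq, spec$model)
  fit$h2 <- heritability_posterior(fit$sigma_g2, raw$sigma_e2)
  fit
}

#' Genomic variance from marker-effect posteriors
#'
#' Evaluates, per retained draw, the model-specific genomic variance:
#' `2 sigma_m^2 sum p_i (1 - p_i)` for the common-variance models (BRR,
#' Bayes C), `2 sum p_i (1 - p_i) sigma_mi^2` for the per-marker-variance
#' models (Bayes A, Bayes B; excluded markers contribute zero), and
#' `2 sum tau_i^2 sigma_e^2 p_i (1 - p_i)` for the Bayesian LASSO.
#'
#' @param samples chain list as returned in `genomic_fit$samples`.
#' @param freq per-column allele frequencies `p_i` in (0,1).
#' @param model model name.
#' @return numeric vector of genomic-variance draws.
#' @export
genomic_variance <- function(samples, freq, model) {
  model <- match.arg(model, names(.MODEL_CODES))
  w <- freq * (1 - freq)
  if (any(freq <= 0 | freq >= 1))
    w[freq <= 0 | freq >= 1] <- 0  # monomorphic columns contribute nothing
  p <- length(w)
  if (model %in% c("BRR", "BC")) {
    if (!length(samples$sigma_m2)) stop_gshap("samples lack sigma_m2; model mismatch")
    2 * samples$sigma_m2 * sum(w)
  } else if (model %in% c("BA", "BB")) {
    V <- samples$sigma_mi2
    if (is.null(dim(V)) || ncol(V) != p) stop_gshap("samples lack per-marker variances; model mismatch")
    if (model == "BB") V <- V * samples$delta
    2 * as.vector(V %*% w)
  } else {
    Tau <- samples$tau2
    if (is.null(dim(Tau)) || ncol(Tau) != p) stop_gshap("samples lack tau2; model mismatch")
    2 * as.vector(Tau %*% w) * samples$sigma_e2
  }
}

#' Genomic heritability posterior
#'
#' Per-draw ratio `h_g^2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)` with its
#' posterior mean and 90% credible region.
#'
#' @param sigma_g2_draws,sigma_e2_draws equal-length aligned draws.
#' @return list: `mean`, `ci90` (5% and 95% quantiles), `draws`.
#' @export
heritability_posterior <- function(sigma_g2_draws, sigma_e2_draws) {
  if (length(sigma_g2_draws) != length(sigma_e2_draws))
    stop_gshap("draw vectors must have equal length")
  if (any(sigma_g2_draws < 0) || any(sigma_e2_draws <= 0))
    stop_gshap("variance draws must be positive")
  h <- sigma_g2_draws / (sigma_g2_draws + sigma_e2_draws)
  list(mean = mean(h), ci90 = unname(quantile(h, c(0.05, 0.95))), draws = h)
}

#' Genetic gain under truncation selection
#'
#' `GG = (mean BV of the selected top fraction - population mean BV) /
#' phenotypic mean x 100`.
#'
#' @param breeding_values estimated breeding values (posterior means).
#' @param selection_fraction fraction selected, in (0, 1\].
#' @param phenotypic_mean phenotypic mean of the trait (non-zero); for
#'   ordinal traits the arithmetic mean of observed scores by default.
#' @return list: `gg_percent`, `n_selected`, `mean_selected`, `mean_population`.
#' @export
genetic_gain <- function(breeding_values, selection_fraction, phenotypic_mean) {
  if (selection_fraction <= 0 || selection_fraction > 1)
    stop_gshap("selection_fraction must be in (0, 1]")
  if (phenotypic_mean == 0) stop_gshap("phenotypic mean must be non-zero")
  n <- length(breeding_values)
  n_sel <- max(1L, round(selection_fraction * n))
  sel <- sort(breeding_values, decreasing = TRUE)[seq_len(n_sel)]
  gg <- (mean(sel) - mean(breeding_values)) / phenotypic_mean * 100
  list(gg_percent = gg, n_selected = n_sel, mean_selected = mean(sel),
       mean_population = mean(breeding_values))
}
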