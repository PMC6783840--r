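# Model-comparison machinery: cross-validated predictive ability,
# Tukey-Kramer compact letter displays, credible-set significance flags,
# and the EBV-GEBV regression.

#' Cross-validated predictive ability
#'
#' Repeats, for `n_cycles` random 90/10 splits: fit the model on the
#' training rows, predict genomic breeding values for the validation rows
#' from the training-estimated marker effects, and correlate them with a
#' reference vector on the validation rows. The default reference is the
#' whole-data-fit GEBV; `reference = "adjusted"` instead correlates
#' predictions with validation phenotypes adjusted for the fixed effects.
#' Cycles whose validation vectors have zero variance are skipped and
#' counted, never averaged.
#'
#' @param y numeric response.
#' @param fixed_design fixed-effect matrix aligned with `y`.
#' @param marker_design a `design_matrix` or numeric matrix.
#' @param spec a [model_spec()].
#' @param holdout_fraction validation fraction (default 0.10).
#' @param n_cycles number of cycles (default 20 at desk scale; 100 for
#'   production runs).
#' @param seed integer seed; cycle `k` uses seed `seed + k` for its split
#'   and fit, so per-cycle results are reproducible in isolation.
#' @param reference `"gebv"` (default) or `"adjusted"`.
#' @param whole_fit optional precomputed whole-data `genomic_fit` to reuse
#'   as the reference.
#' @return list of class `cv_result`: `pa_cycles` (per-cycle correlations,
#'   `NA` for skipped cycles), `mean_pa`, `n_cycles`, `n_skipped`, `model`.
#' @export
cross_validate <- function(y, fixed_design, marker_design, spec,
                           holdout_fraction = 0.10, n_cycles = 20,
                           seed = 1L, reference = c("gebv", "adjusted"),
                           whole_fit = NULL) {
  reference <- match.arg(reference)
  stopifnot(holdout_fraction > 0, holdout_fraction < 1, n_cycles >= 1)
  Z <- if (inherits(marker_design, "design_matrix")) marker_design$M
       else as.matrix(marker_design)
  X <- as.matrix(fixed_design)
  n <- length(y)
  n_val <- max(1L, round(holdout_fraction * n))
  if (reference == "gebv" && is.null(whole_fit))
    whole_fit <- fit_whole_regression(y, X, marker_design, spec,
                                      seed = derive_seed(seed, "whole"))
  pa <- rep(NA_real_, n_cycles)
  for (k in seq_len(n_cycles)) {
    cycle_seed <- as.integer((seed + k) %% 2147483647)
    set.seed(cycle_seed)
    val <- sort(sample.int(n, n_val))
    train <- setdiff(seq_len(n), val)
    fit_k <- fit_whole_regression(y[train], X[train, , drop = FALSE],
                                  Z[train, , drop = FALSE], spec,
                                  seed = cycle_seed)
    pred <- as.vector(Z[val, , drop = FALSE] %*% fit_k$m_hat)
    ref <- if (reference == "gebv") {
      whole_fit$gebv[val]
    } else {
      beta_hat <- colMeans(fit_k$samples$beta)
      y[val] - as.vector(X[val, , drop = FALSE] %*% beta_hat)
    }
    if (sd(pred) == 0 || sd(ref) == 0) next  # skipped, stays NA
    pa[k] <- cor(ref, pred)
  }
  structure(list(pa_cycles = pa, mean_pa = mean(pa, na.rm = TRUE),
                 n_cycles = n_cycles, n_skipped = sum(is.na(pa)),
                 model = spec$model, reference = reference),
            class = "cv_result")
}

# compact letter display by insert-absorb on a logical "different" matrix
.letter_display <- function(groups, different) {
  k <- length(groups)
  cols <- list(rep(TRUE, k))  # start with one letter containing everyone
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!different[i, j]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          # split the offending letter column
          c1 <- col; c1[j] <- FALSE
          c2 <- col; c2[i] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1]] <- c2
        }
      }
      # absorb columns contained in another
      drop <- rep(FALSE, length(cols))
      for (a in seq_along(cols)) for (b in seq_along(cols)) {
        if (a != b && !drop[a] && !drop[b] &&
            all(cols[[a]] <= cols[[b]])) drop[a] <- TRUE
      }
      cols <- cols[!drop]
    }
  }
  # letters assigned in order of the best (first) group
  first <- vapply(cols, function(c) which(c)[1], integer(1))
  cols <- cols[order(first)]
  lab <- rep("", k)
  for (ci in seq_along(cols))
    lab[cols[[ci]]] <- paste0(lab[cols[[ci]]], letters[ci])
  setNames(lab, groups)
}

#' All-pairs Tukey-Kramer comparison with compact letters
#'
#' One-way comparison of group means using the studentized-range
#' distribution with the Tukey-Kramer allowance for unequal group sizes.
#' Groups that share a letter are not significantly different at `alpha`;
#' letters are assigned from the best (largest) mean downwards.
#'
#' @param pa_matrix numeric matrix, cycles x groups (columns named), or a
#'   list of per-group numeric vectors. `NA` cycles are dropped per group.
#' @param alpha familywise significance level (default 0.01).
#' @return list of class `tukey_letters`: `means` (sorted, descending),
#'   `letters` (aligned with `means`), `p_values` (groups x groups),
#'   `df_error`, `alpha`.
#' @export
compare_tukey_kramer <- function(pa_matrix, alpha = 0.01) {
  vals <- if (is.list(pa_matrix)) pa_matrix
          else lapply(seq_len(ncol(pa_matrix)), function(j) pa_matrix[, j])
  if (is.null(names(vals)))
    names(vals) <- colnames(pa_matrix) %||% paste0("g", seq_along(vals))
  vals <- lapply(vals, function(v) v[!is.na(v)])
  k <- length(vals)
  if (k < 2) stop_gshap("need at least 2 groups")
  ni <- vapply(vals, length, integer(1))
  if (any(ni < 2)) stop_gshap("need at least 2 observations per group")
  mi <- vapply(vals, mean, numeric(1))
  df <- sum(ni) - k
  mse <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1))) / df
  pval <- matrix(1, k, k, dimnames = list(names(vals), names(vals)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse / 2 * (1 / ni[i] + 1 / ni[j]))
    q <- abs(mi[i] - mi[j]) / se
    pval[i, j] <- pval[j, i] <- ptukey(q, k, df, lower.tail = FALSE)
  }
  ord <- order(-mi)
  different <- (pval < alpha)[ord, ord, drop = FALSE]
  lab <- .letter_display(names(vals)[ord], different)
  structure(list(means = mi[ord], letters = lab, p_values = pval,
                 df_error = df, alpha = alpha),
            class = "tukey_letters")
}

#' Flag significance by 90% credible-set comparison
#'
#' Compares a genomic posterior summary with the pedigree-based one: the
#' default rule stars the genomic estimate when the two credible intervals
#' at `level` do not overlap; `rule = "point"` stars when the pedigree
#' point estimate falls outside the genomic interval.
#'
#' @param genomic_summary,pedigree_summary lists with `ci90` interval
#'   bounds (and `mean` for the point rule), or numeric vectors of draws.
#' @param level credible level in (0,1) (default 0.90).
#' @param rule `"overlap"` (default) or `"point"`.
#' @return list: `significant` (logical), `genomic_ci`, `pedigree_ci`.
#' @export
credible_set_compare <- function(genomic_summary, pedigree_summary,
                                 level = 0.90, rule = c("overlap", "point")) {
  rule <- match.arg(rule)
  if (level <= 0 || level >= 1) stop_gshap("level must be inside (0,1)")
  tails <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci_of <- function(s) {
    if (is.numeric(s) && length(s) > 2) unname(quantile(s, tails))
    else if (!is.null(s$draws)) unname(quantile(s$draws, tails))
    else sort(unname(s$ci90 %||% s$ci))
  }
  g <- ci_of(genomic_summary); p <- ci_of(pedigree_summary)
  sig <- if (rule == "overlap") {
    g[1] > p[2] || g[2] < p[1]
  } else {
    pt <- if (is.numeric(pedigree_summary) && length(pedigree_summary) > 2)
      mean(pedigree_summary) else pedigree_summary$mean
    pt < g[1] || pt > g[2]
  }
  list(significant = sig, genomic_ci = g, pedigree_ci = p)
}

#' Regression of genomic on pedigree breeding values
#'
#' Ordinary least squares of GEBV on EBV with the coefficient of
#' determination.
#'
#' @param ebv,gebv equal-length numeric vectors with positive variance.
#' @return list: `slope`, `intercept`, `r_squared`.
#' @export
ebv_gebv_regression <- function(ebv, gebv) {
  if (length(ebv) != length(gebv)) stop_gshap("vectors must have equal length")
  if (sd(ebv) == 0 || sd(gebv) == 0) stop_gshap("zero-variance input")
  f <- lm(gebv ~ ebv)
  list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
       r_squared = cor(ebv, gebv)^2)
}
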