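# Haplotype-block discovery by the Gabriel confidence-interval algorithm,
# plus background-LD characterization (critical r2, decay profile).

#' Control parameters for Gabriel block detection
#'
#' @param ci_high_strong strong-LD lower bound on the D' CI upper limit
#'   (default 0.98).
#' @param ci_low_strong strong-LD lower bound on the D' CI lower limit
#'   (default 0.70).
#' @param ci_high_recomb strong-recombination upper bound on the CI upper
#'   limit (default 0.90).
#' @param informative_frac minimum fraction of informative pairs inside a
#'   candidate block that must be strong-LD (default 0.95).
#' @param max_span_bp maximum block span in bp (default 500 kbp).
#' @param min_informative_n minimum pairwise-complete individuals for a
#'   pair to be classified (default 20).
#' @param grid_step,alpha_tail passed to [dprime_confidence_bounds()].
#' @export
gabriel_params <- function(ci_high_strong = 0.98, ci_low_strong = 0.70,
                           ci_high_recomb = 0.90, informative_frac = 0.95,
                           max_span_bp = 5e5, min_informative_n = 20,
                           grid_step = 0.01, alpha_tail = 0.05) {
  stopifnot(ci_high_strong <= 1, ci_low_strong <= 1, ci_high_recomb <= 1,
            informative_frac > 0, informative_frac <= 1, max_span_bp > 0)
  list(ci_high_strong = ci_high_strong, ci_low_strong = ci_low_strong,
       ci_high_recomb = ci_high_recomb, informative_frac = informative_frac,
       max_span_bp = max_span_bp, min_informative_n = min_informative_n,
       grid_step = grid_step, alpha_tail = alpha_tail)
}

# classify every intra-chromosomal pair within max_span: returns matrices of
# codes (0 uninformative, 1 strong LD, 2 strong recombination, 3 other)
.classify_pairs <- function(geno, pos, params) {
  m <- ncol(geno)
  code <- matrix(NA_integer_, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (pos[j] - pos[i] > params$max_span_bp) break
      cl <- 0L
      ok <- !is.na(geno[, i]) & !is.na(geno[, j])
      if (sum(ok) >= params$min_informative_n) {
        ci <- tryCatch(
          dprime_confidence_bounds(geno[, i], geno[, j],
                                   grid_step = params$grid_step,
                                   alpha_tail = params$alpha_tail),
          error = function(e) NULL)
        if (!is.null(ci)) {
          cl <- if (ci$ci_high >= params$ci_high_strong &&
                    ci$ci_low >= params$ci_low_strong) 1L
          else if (ci$ci_high < params$ci_high_recomb) 2L
          else 3L
        }
      }
      code[i, j] <- code[j, i] <- cl
    }
  }
  code
}

#' Partition chromosomes into Gabriel haplotype blocks
#'
#' Pairs of SNPs are in strong LD when the 95% D' confidence interval has
#' upper limit >= 0.98 and lower limit >= 0.70; in strong recombination
#' when the upper limit is < 0.90; informative pairs are either. A
#' candidate block \[i..j\] requires the endpoint pair to be strong-LD, at
#' least 95% of its informative pairs strong-LD, and a span within
#' `max_span_bp`. Final blocks are chosen greedily, longest span first
#' (leftmost on ties), without overlap. Haplotype variants of each block
#' are estimated by multi-locus EM.
#'
#' @param genotypes individuals x markers dosage matrix (0/1/2/`NA`),
#'   columns aligned to `marker_map` rows.
#' @param marker_map a `marker_map`.
#' @param params a [gabriel_params()] list.
#' @return A `data.frame` of class `haplo_blocks`: `chromosome`,
#'   `first_marker`, `last_marker` (global column indices), `start_bp`,
#'   `end_bp`, `span_bp`, `n_snps`; attribute `haplotypes` holds the
#'   per-block [em_block_haplotypes()] results.
#' @export
gabriel_blocks <- function(genotypes, marker_map, params = gabriel_params()) {
  validate_marker_map(marker_map)
  if (ncol(genotypes) != nrow(marker_map))
    stop_gshap("genotype columns must align with the marker map")
  out <- list()
  for (chr in unique(marker_map$chromosome)) {
    idx <- which(marker_map$chromosome == chr)
    if (length(idx) < 2) next
    geno <- genotypes[, idx, drop = FALSE]
    pos <- marker_map$position_bp[idx]
    code <- .classify_pairs(geno, pos, params)
    m <- length(idx)
    # cumulative strong / informative counts over windows via recurrence
    S <- matrix(0L, m, m); Ifm <- matrix(0L, m, m)
    for (w in 1:(m - 1)) {
      for (i in 1:(m - w)) {
        j <- i + w
        cl <- code[i, j]
        add_s <- as.integer(!is.na(cl) && cl == 1L)
        add_i <- as.integer(!is.na(cl) && (cl == 1L || cl == 2L))
        if (w == 1) { S[i, j] <- add_s; Ifm[i, j] <- add_i }
        else {
          S[i, j] <- S[i + 1, j] + S[i, j - 1] - S[i + 1, j - 1] + add_s
          Ifm[i, j] <- Ifm[i + 1, j] + Ifm[i, j - 1] - Ifm[i + 1, j - 1] + add_i
        }
      }
    }
    cand <- list()
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        if (pos[j] - pos[i] > params$max_span_bp) break
        if (is.na(code[i, j]) || code[i, j] != 1L) next
        if (Ifm[i, j] == 0) next
        if (S[i, j] / Ifm[i, j] < params$informative_frac) next
        cand[[length(cand) + 1]] <- c(i, j, pos[j] - pos[i])
      }
    }
    if (length(cand) == 0) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, 3], cand[, 1]), , drop = FALSE]
    used <- rep(FALSE, m)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (any(used[i:j])) next
      used[i:j] <- TRUE
      out[[length(out) + 1]] <- data.frame(
        chromosome = chr, first_marker = idx[i], last_marker = idx[j],
        start_bp = pos[i], end_bp = pos[j], span_bp = pos[j] - pos[i],
        n_snps = j - i + 1L
      )
    }
  }
  if (length(out) == 0) {
    blocks <- data.frame(chromosome = integer(0), first_marker = integer(0),
                         last_marker = integer(0), start_bp = integer(0),
                         end_bp = integer(0), span_bp = integer(0),
                         n_snps = integer(0))
  } else {
    blocks <- do.call(rbind, out)
    blocks <- blocks[order(blocks$chromosome, blocks$start_bp), , drop = FALSE]
    rownames(blocks) <- NULL
  }
  haps <- lapply(seq_len(nrow(blocks)), function(b) {
    cols <- blocks$first_marker[b]:blocks$last_marker[b]
    em_block_haplotypes(genotypes[, cols, drop = FALSE])
  })
  attr(blocks, "haplotypes") <- haps
  class(blocks) <- c("haplo_blocks", "data.frame")
  blocks
}

# EM-based r2 for one pair; NA when LD is undefined (monomorphic)
.pair_r2 <- function(ga, gb) {
  tryCatch(ld_stats(em_two_locus(ga, gb))$r2, error = function(e) NA_real_)
}

#' Critical r-squared from unlinked marker pairs
#'
#' Samples inter-chromosomal (unlinked) marker pairs, takes the square
#' root of their r2 values, and returns the square of the 95th empirical
#' percentile (R quantile type 7) — the parametric-population threshold of
#' Breseghello-Sorrells beyond which LD is taken to reflect linkage.
#'
#' @inheritParams gabriel_blocks
#' @param n_pairs number of unlinked pairs to use when more exist
#'   (default 10000); all pairs are used when there are fewer.
#' @param seed seed for the pair subsample.
#' @return scalar critical r2.
#' @export
critical_r2 <- function(genotypes, marker_map, n_pairs = 1e4, seed = 1L) {
  validate_marker_map(marker_map)
  chrs <- marker_map$chromosome
  if (length(unique(chrs)) < 2)
    stop_gshap("critical r2 needs markers on at least 2 chromosomes")
  m <- ncol(genotypes)
  set.seed(seed)
  total_pairs <- choose(m, 2)
  if (total_pairs <= n_pairs) {
    pairs <- t(combn(m, 2))
    pairs <- pairs[chrs[pairs[, 1]] != chrs[pairs[, 2]], , drop = FALSE]
  } else {
    i <- sample.int(m, 3 * n_pairs, replace = TRUE)
    j <- sample.int(m, 3 * n_pairs, replace = TRUE)
    keep <- chrs[i] != chrs[j]
    pairs <- unique(cbind(pmin(i, j), pmax(i, j))[keep, , drop = FALSE])
    pairs <- pairs[seq_len(min(nrow(pairs), n_pairs)), , drop = FALSE]
  }
  r2 <- vapply(seq_len(nrow(pairs)), function(k)
    .pair_r2(genotypes[, pairs[k, 1]], genotypes[, pairs[k, 2]]),
    numeric(1))
  r2 <- r2[!is.na(r2)]
  if (length(r2) == 0) stop_gshap("no informative unlinked pairs")
  unname(quantile(sqrt(r2), 0.95)^2)
}

#' Intra-chromosomal LD decay profile and crossing distance
#'
#' Computes mean r2 of intra-chromosomal marker pairs per physical-distance
#' bin, and the distance at which a 3-bin moving average of the mean r2
#' first falls below the critical value.
#'
#' @inheritParams gabriel_blocks
#' @param bin_width_bp distance bin width.
#' @param max_dist_bp maximum pair distance considered.
#' @param critical critical r2 (e.g. from [critical_r2()]).
#' @param max_pairs_per_chr optional cap on pairs per chromosome (seeded
#'   subsample) to bound compute on dense maps.
#' @param seed seed for the subsample.
#' @return list of class `ld_extent`: `critical_r2`, `decay_table`
#'   (`data.frame`: `mid_bp`, `mean_r2`, `n_pairs`, `smoothed`),
#'   `crossing_distance_bp` (`NA` when no bin crosses).
#' @export
ld_decay_profile <- function(genotypes, marker_map, bin_width_bp,
                             max_dist_bp, critical,
                             max_pairs_per_chr = 5000, seed = 1L) {
  validate_marker_map(marker_map)
  stopifnot(bin_width_bp > 0, max_dist_bp > 0)
  set.seed(seed)
  dist_all <- numeric(0); r2_all <- numeric(0)
  for (chr in unique(marker_map$chromosome)) {
    idx <- which(marker_map$chromosome == chr)
    if (length(idx) < 2) next
    prs <- t(combn(length(idx), 2))
    pos <- marker_map$position_bp[idx]
    d <- pos[prs[, 2]] - pos[prs[, 1]]
    keep <- which(d <= max_dist_bp)
    if (length(keep) > max_pairs_per_chr)
      keep <- sort(sample(keep, max_pairs_per_chr))
    for (k in keep) {
      r2 <- .pair_r2(genotypes[, idx[prs[k, 1]]], genotypes[, idx[prs[k, 2]]])
      if (!is.na(r2)) { dist_all <- c(dist_all, d[k]); r2_all <- c(r2_all, r2) }
    }
  }
  if (length(r2_all) == 0) stop_gshap("no intra-chromosomal pairs within range")
  bin <- pmin(ceiling(dist_all / bin_width_bp), ceiling(max_dist_bp / bin_width_bp))
  n_bins <- ceiling(max_dist_bp / bin_width_bp)
  mean_r2 <- rep(NA_real_, n_bins); n_pairs <- integer(n_bins)
  agg <- tapply(r2_all, bin, mean)
  cnt <- tapply(r2_all, bin, length)
  mean_r2[as.integer(names(agg))] <- agg
  n_pairs[as.integer(names(cnt))] <- cnt
  mids <- (seq_len(n_bins) - 0.5) * bin_width_bp
  # 3-bin centered moving average, ignoring empty bins
  smoothed <- vapply(seq_len(n_bins), function(b) {
    w <- max(1, b - 1):min(n_bins, b + 1)
    v <- mean_r2[w]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  below <- which(!is.na(smoothed) & smoothed < critical)
  crossing <- if (length(below) == 0) NA_real_ else mids[below[1]]
  structure(list(
    critical_r2 = critical,
    decay_table = data.frame(mid_bp = mids, mean_r2 = mean_r2,
                             n_pairs = n_pairs, smoothed = smoothed),
    crossing_distance_bp = crossing
  ), class = "ld_extent")
}

#' Per-chromosome block summary
#'
#' Tabulates, for each chromosome: SNP count, number of blocks, number of
#' haplotype variants, max/min block span and max/min SNPs per block.
#'
#' @param blocks result of [gabriel_blocks()].
#' @param marker_map the marker map used.
#' @return `data.frame`, one row per chromosome plus a `Total` row.
#' @export
block_summary <- function(blocks, marker_map) {
  haps <- attr(blocks, "haplotypes")
  n_var <- vapply(seq_len(nrow(blocks)), function(b)
    nrow(haps[[b]]$variants), integer(1))
  rows <- lapply(sort(unique(marker_map$chromosome)), function(chr) {
    bl <- which(blocks$chromosome == chr)
    data.frame(
      chromosome = as.character(chr),
      n_snps = sum(marker_map$chromosome == chr),
      n_blocks = length(bl),
      n_haplotypes = if (length(bl)) sum(n_var[bl]) else 0L,
      max_span_bp = if (length(bl)) max(blocks$span_bp[bl]) else NA_real_,
      min_span_bp = if (length(bl)) min(blocks$span_bp[bl]) else NA_real_,
      max_snps = if (length(bl)) max(blocks$n_snps[bl]) else NA_integer_,
      min_snps = if (length(bl)) min(blocks$n_snps[bl]) else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  total <- data.frame(chromosome = "Total", n_snps = sum(tab$n_snps),
                      n_blocks = sum(tab$n_blocks),
                      n_haplotypes = sum(tab$n_haplotypes),
                      max_span_bp = NA_real_, min_span_bp = NA_real_,
                      max_snps = NA_integer_, min_snps = NA_integer_,
                      stringsAsFactors = FALSE)
  rbind(tab, total)
}
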