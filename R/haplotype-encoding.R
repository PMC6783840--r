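# Within-block phasing by multi-locus EM, haplotype variant identification,
# and construction of the SNP / HAP / HAP-SNP regressor matrices with
# 0/1/2 copy coding.

# enumerate the compatible (unordered) haplotype pairs of one individual.
# g: dosage vector over k block SNPs (0/1/2/NA). Haplotypes are integer
# codes, bit b set = allele 1 at SNP b (b = 0 for the first SNP).
# Returns a 2-column matrix of codes (a <= b), or NULL if too many
# missing/het sites to enumerate (treated as uninformative).
.compatible_pairs <- function(g, max_ambiguous = 12L) {
  k <- length(g)
  het <- which(!is.na(g) & g == 1L)
  mis <- which(is.na(g))
  if (length(het) + 2L * length(mis) > max_ambiguous) return(NULL)
  base <- 0L
  fixed1 <- which(!is.na(g) & g == 2L)
  if (length(fixed1)) base <- sum(bitwShiftL(1L, fixed1 - 1L))
  # ambiguous positions: het sites take one allele per haplotype (opposite);
  # missing sites take any of the 3 genotypes (00, 11, het)
  amb <- c(het, mis)
  pairs <- matrix(c(base, base), ncol = 2)
  for (s in amb) {
    bit <- bitwShiftL(1L, s - 1L)
    new <- list()
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      if (s %in% het) {
        new[[length(new) + 1]] <- c(a + bit, b)
        new[[length(new) + 1]] <- c(a, b + bit)
      } else {
        new[[length(new) + 1]] <- c(a, b)               # missing -> 0/0
        new[[length(new) + 1]] <- c(a + bit, b + bit)   # missing -> 1/1
        new[[length(new) + 1]] <- c(a + bit, b)         # missing -> het
        new[[length(new) + 1]] <- c(a, b + bit)
      }
    }
    pairs <- do.call(rbind, new)
  }
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  unique(pairs)
}

.hap_string <- function(code, k) {
  paste(as.integer(bitwAnd(bitwShiftR(code, 0:(k - 1)), 1L)), collapse = "")
}

#' Multi-locus EM haplotype frequencies within a block
#'
#' Runs the expectation-maximization algorithm over all haplotypes
#' compatible with the observed unphased genotypes of a block, assuming
#' Hardy-Weinberg pairing. Individuals whose ambiguity (heterozygous plus
#' missing sites) is too large to enumerate are ignored in the E-step but
#' still receive a diplotype afterwards.
#'
#' @param block_genotypes individuals x SNPs dosage matrix (0/1/2/`NA`)
#'   restricted to one block; 2 to 15 SNPs.
#' @param tol convergence tolerance on the max frequency change.
#' @param max_iter maximum EM iterations.
#' @return list of class `block_haplotypes`: `variants` (`data.frame`:
#'   `haplotype` allele string, `frequency`, descending), `diplotypes`
#'   (n x 2 matrix of variant indices into `variants`, `NA` when
#'   unresolvable), `n_snps`, `n_iter`.
#' @export
em_block_haplotypes <- function(block_genotypes, tol = 1e-6, max_iter = 500) {
  g <- as.matrix(block_genotypes)
  k <- ncol(g)
  if (k < 2) stop_gshap("a block needs at least 2 SNPs")
  if (k > 15) stop_gshap("block of %d SNPs exceeds the enumeration cap (15); split it", k)
  n <- nrow(g)
  plist <- lapply(seq_len(n), function(i) .compatible_pairs(g[i, ]))
  codes <- sort(unique(unlist(lapply(plist, function(p) if (is.null(p)) NULL else as.vector(p)))))
  if (length(codes) == 0) stop_gshap("no individual with enumerable genotypes in block")
  cidx <- function(code) match(code, codes)
  H <- length(codes)
  freq <- rep(1 / H, H)
  informative <- which(!vapply(plist, is.null, logical(1)))
  iter <- 0
  repeat {
    iter <- iter + 1
    cnt <- numeric(H)
    for (i in informative) {
      pr <- plist[[i]]
      a <- cidx(pr[, 1]); b <- cidx(pr[, 2])
      w <- freq[a] * freq[b] * ifelse(pr[, 1] == pr[, 2], 1, 2)
      if (sum(w) <= 0) w <- rep(1, length(w))
      w <- w / sum(w)
      for (r in seq_along(w)) {
        cnt[a[r]] <- cnt[a[r]] + w[r]
        cnt[b[r]] <- cnt[b[r]] + w[r]
      }
    }
    new_freq <- cnt / (2 * length(informative))
    if (max(abs(new_freq - freq)) < tol || iter >= max_iter) {
      freq <- new_freq; break
    }
    freq <- new_freq
  }
  ord <- order(-freq, codes)
  variants <- data.frame(
    haplotype = vapply(codes[ord], .hap_string, character(1), k = k),
    frequency = freq[ord], stringsAsFactors = FALSE
  )
  rank_of <- match(seq_along(codes), ord)  # code index -> variant rank
  diplo <- matrix(NA_integer_, n, 2)
  for (i in seq_len(n)) {
    pr <- plist[[i]]
    if (is.null(pr)) next
    a <- cidx(pr[, 1]); b <- cidx(pr[, 2])
    post <- freq[a] * freq[b] * ifelse(pr[, 1] == pr[, 2], 1, 2)
    best <- which(post == max(post))
    if (length(best) > 1) {
      # deterministic tie-break: lexicographically smallest variant pair
      va <- pmin(rank_of[a[best]], rank_of[b[best]])
      vb <- pmax(rank_of[a[best]], rank_of[b[best]])
      best <- best[order(va, vb)][1]
    }
    diplo[i, ] <- sort(c(rank_of[a[best]], rank_of[b[best]]))
  }
  rownames(diplo) <- rownames(g)
  structure(list(variants = variants, diplotypes = diplo,
                 n_snps = k, n_iter = iter),
            class = "block_haplotypes")
}

#' Haplotype copy counts from assigned diplotypes
#'
#' Converts maximum-posterior diplotypes into the 0/1/2 copy coding: for
#' each individual and block variant, 0 when the individual carries no copy
#' of that variant, 1 for one copy, 2 for two copies.
#'
#' @param set a `block_haplotypes` object from [em_block_haplotypes()].
#' @return integer matrix individuals x variants, columns named by the
#'   variant allele strings; rows with unresolved diplotypes are `NA`.
#' @export
assign_diplotypes <- function(set) {
  stopifnot(inherits(set, "block_haplotypes"))
  nv <- nrow(set$variants)
  n <- nrow(set$diplotypes)
  cc <- matrix(0L, n, nv,
               dimnames = list(rownames(set$diplotypes), set$variants$haplotype))
  for (i in seq_len(n)) {
    d <- set$diplotypes[i, ]
    if (anyNA(d)) { cc[i, ] <- NA_integer_; next }
    cc[i, d[1]] <- cc[i, d[1]] + 1L
    cc[i, d[2]] <- cc[i, d[2]] + 1L
  }
  cc
}

#' Build the SNP / HAP / HAP-SNP design matrix
#'
#' `SNP` mode uses all SNP dosage columns, recoded so that 2 is the
#' homozygote of the most frequent allele, 1 the heterozygote and 0 the
#' rare homozygote. `HAP` mode uses one copy-count column per retained
#' haplotype variant (frequency >= `variant_freq_min`) across all blocks.
#' `HAP_SNP` combines the HAP columns with the dosage columns of every SNP
#' not assigned to a block. Missing values are mean-imputed per column when
#' `impute` is `TRUE`; each column records its allele frequency
#' `p = column mean / 2` (used by the genomic-variance formulas).
#'
#' @param genotypes individuals x markers dosage matrix (0/1/2/`NA`).
#' @param blocks a `haplo_blocks` object ([gabriel_blocks()]); may have
#'   zero rows.
#' @param mode one of `"SNP"`, `"HAP"`, `"HAP_SNP"`.
#' @param variant_freq_min minimum EM frequency for a haplotype variant
#'   column (default 0.01).
#' @param impute mean-impute missing values (default `TRUE`).
#' @return list of class `design_matrix`: `M` (numeric matrix, rows =
#'   individuals), `freq` (per-column allele frequency), `source`
#'   (`data.frame`: `type` "snp"/"haplotype", `marker` column index or
#'   `NA`, `block`, `variant`), `mode`.
#' @export
build_design <- function(genotypes, blocks, mode = c("SNP", "HAP", "HAP_SNP"),
                         variant_freq_min = 0.01, impute = TRUE) {
  mode <- match.arg(mode)
  geno <- as.matrix(genotypes)
  m <- ncol(geno)
  in_block <- rep(FALSE, m)
  if (nrow(blocks) > 0)
    for (b in seq_len(nrow(blocks)))
      in_block[blocks$first_marker[b]:blocks$last_marker[b]] <- TRUE

  snp_cols <- function(which_snps) {
    if (length(which_snps) == 0)
      return(list(M = matrix(numeric(0), nrow(geno), 0), src = NULL))
    M <- geno[, which_snps, drop = FALSE]
    # orient so that 2 = homozygote of the most frequent allele
    p1 <- colMeans(M, na.rm = TRUE) / 2
    flip <- !is.na(p1) & p1 < 0.5
    M[, flip] <- 2 - M[, flip]
    list(M = M, src = data.frame(
      type = "snp", marker = which_snps, block = NA_integer_,
      variant = NA_character_, stringsAsFactors = FALSE))
  }
  hap_cols <- function() {
    haps <- attr(blocks, "haplotypes")
    Ms <- list(); srcs <- list()
    for (b in seq_len(nrow(blocks))) {
      cc <- assign_diplotypes(haps[[b]])
      keep <- which(haps[[b]]$variants$frequency >= variant_freq_min)
      if (length(keep) == 0) next
      Ms[[length(Ms) + 1]] <- cc[, keep, drop = FALSE]
      srcs[[length(srcs) + 1]] <- data.frame(
        type = "haplotype", marker = NA_integer_, block = b,
        variant = haps[[b]]$variants$haplotype[keep], stringsAsFactors = FALSE)
    }
    if (length(Ms) == 0)
      return(list(M = matrix(numeric(0), nrow(geno), 0), src = NULL))
    list(M = do.call(cbind, Ms), src = do.call(rbind, srcs))
  }

  parts <- switch(mode,
    SNP = list(snp_cols(seq_len(m))),
    HAP = list(hap_cols()),
    HAP_SNP = list(hap_cols(), snp_cols(which(!in_block)))
  )
  M <- do.call(cbind, lapply(parts, `[[`, "M"))
  src <- do.call(rbind, lapply(parts, `[[`, "src"))
  if (is.null(M) || ncol(M) == 0) stop_gshap("design has no columns")
  storage.mode(M) <- "double"
  if (impute && anyNA(M)) {
    for (j in which(colSums(is.na(M)) > 0)) {
      mu <- mean(M[, j], na.rm = TRUE)
      M[is.na(M[, j]), j] <- mu
    }
  }
  freq <- colMeans(M, na.rm = TRUE) / 2
  colnames(M) <- ifelse(src$type == "snp",
                        paste0("snp", src$marker),
                        paste0("blk", src$block, "_", src$variant))
  rownames(M) <- rownames(geno)
  structure(list(M = M, freq = unname(freq), source = src, mode = mode),
            class = "design_matrix")
}
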