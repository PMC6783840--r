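# Synthetic breeding-population generator: pedigree, gene-dropped genotypes
# with planted strong-LD segments, and RCBD phenotypes with known truth.

#' Build a marker map
#'
#' Scatters markers uniformly over chromosomes and sorts them by
#' (chromosome, position). Without `weights`, marker counts per chromosome
#' differ by at most one.
#'
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param n_markers total number of markers (>= `n_chromosomes`).
#' @param chromosome_length_bp chromosome length in bp (all chromosomes
#'   equal length; must be >= markers assigned to the chromosome so that
#'   positions can be distinct).
#' @param seed integer seed.
#' @param weights optional positive per-chromosome weights for unequal
#'   marker allocation.
#' @return A `data.frame` of class `marker_map` with columns `marker_id`,
#'   `chromosome`, `position_bp`, sorted by (chromosome, position), with
#'   strictly increasing positions within a chromosome.
#' @export
make_marker_map <- function(n_chromosomes, n_markers, chromosome_length_bp,
                            seed = 1L, weights = NULL) {
  if (n_chromosomes < 1 || n_markers < n_chromosomes || chromosome_length_bp < 1)
    stop_gshap("need n_markers >= n_chromosomes >= 1 and a positive chromosome length")
  if (chromosome_length_bp < n_markers)
    stop_gshap("chromosome_length_bp (%d) too short for %d markers",
               chromosome_length_bp, n_markers)
  if (is.null(weights)) {
    counts <- rep(n_markers %/% n_chromosomes, n_chromosomes)
    extra <- n_markers %% n_chromosomes
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  } else {
    if (length(weights) != n_chromosomes || any(weights <= 0))
      stop_gshap("weights must be positive, one per chromosome")
    counts <- pmax(1L, round(n_markers * weights / sum(weights)))
    # fix rounding drift on the largest chromosome
    counts[which.max(counts)] <- counts[which.max(counts)] + n_markers - sum(counts)
  }
  if (any(counts > chromosome_length_bp))
    stop_gshap("chromosome_length_bp (%d) too short for %d distinct positions",
               chromosome_length_bp, max(counts))
  set.seed(seed)
  pos <- lapply(counts, function(k) sort(sample.int(chromosome_length_bp, k)))
  map <- data.frame(
    marker_id = sprintf("snp%05d", seq_len(n_markers)),
    chromosome = rep(seq_len(n_chromosomes), counts),
    position_bp = unlist(pos),
    stringsAsFactors = FALSE
  )
  class(map) <- c("marker_map", "data.frame")
  map
}

validate_marker_map <- function(map) {
  stopifnot(all(c("marker_id", "chromosome", "position_bp") %in% names(map)))
  if (anyDuplicated(map$marker_id)) stop_gshap("duplicated marker ids")
  by_chr <- split(map$position_bp, map$chromosome)
  if (!all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1))))
    stop_gshap("positions must be strictly increasing within chromosome")
  invisible(map)
}

#' Simulate a half-/full-sib family pedigree
#'
#' Founders are unrelated; each family has one known dam. A fraction of
#' families are open-pollinated half-sib families (sire recorded unknown);
#' the rest are full-sib families with one known founder sire.
#'
#' @param n_families number of families.
#' @param progeny_per_family progeny per family.
#' @param half_sib_fraction fraction of families with unknown sire, in \[0,1\].
#' @param n_founders number of unrelated founders (>= 2 and >= `n_families`).
#' @param seed integer seed.
#' @return A `data.frame` of class `pedigree` with columns `individual_id`,
#'   `sire_id`, `dam_id`, `family_id`, `generation`; unknown parents are `NA`.
#'   Parents precede offspring.
#' @export
simulate_pedigree <- function(n_families, progeny_per_family, half_sib_fraction,
                              n_founders, seed = 1L) {
  if (n_founders < 2) stop_gshap("need at least 2 founders")
  if (n_families < 1 || progeny_per_family < 1)
    stop_gshap("n_families and progeny_per_family must be positive")
  if (half_sib_fraction < 0 || half_sib_fraction > 1)
    stop_gshap("half_sib_fraction must be in [0,1]")
  if (n_founders < n_families)
    stop_gshap("need at least one founder dam per family (n_founders >= n_families)")
  set.seed(seed)
  founder_id <- sprintf("F%04d", seq_len(n_founders))
  dams <- founder_id[seq_len(n_families)]
  n_hs <- round(half_sib_fraction * n_families)
  hs_families <- sort(sample.int(n_families, n_hs))
  sire_pool <- setdiff(founder_id, dams)
  if (n_hs < n_families && length(sire_pool) == 0)
    stop_gshap("no founders left to serve as full-sib sires; increase n_founders")
  sires <- rep(NA_character_, n_families)
  fs <- setdiff(seq_len(n_families), hs_families)
  if (length(fs) > 0)
    sires[fs] <- sample(sire_pool, length(fs), replace = length(sire_pool) < length(fs))
  founders <- data.frame(
    individual_id = founder_id, sire_id = NA_character_, dam_id = NA_character_,
    family_id = NA_character_, generation = 0L, stringsAsFactors = FALSE
  )
  n_prog <- n_families * progeny_per_family
  fam_of <- rep(seq_len(n_families), each = progeny_per_family)
  progeny <- data.frame(
    individual_id = sprintf("P%04d", seq_len(n_prog)),
    sire_id = sires[fam_of],
    dam_id = dams[fam_of],
    family_id = sprintf("fam%03d", fam_of),
    generation = 1L, stringsAsFactors = FALSE
  )
  ped <- rbind(founders, progeny)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

validate_pedigree <- function(ped) {
  stopifnot(all(c("individual_id", "sire_id", "dam_id") %in% names(ped)))
  if (anyDuplicated(ped$individual_id)) stop_gshap("duplicated individual ids")
  idx <- match(ped$individual_id, ped$individual_id)
  for (col in c("sire_id", "dam_id")) {
    p <- ped[[col]]
    known <- !is.na(p) & p != UNKNOWN_PARENT
    pos <- match(p[known], ped$individual_id)
    if (anyNA(pos)) stop_gshap("parent '%s' not in pedigree", p[known][is.na(pos)][1])
    if (any(pos >= which(known))) stop_gshap("parents must precede offspring")
  }
  invisible(ped)
}

#' Founder haplotype specification with planted strong-LD segments
#'
#' Defines per-marker founder allele frequencies and a set of perfect-LD
#' segments: within a segment, founder haplotype alleles are generated from
#' a single latent uniform per haplotype (allele = latent < frequency), so
#' at most one recombinant class is absent and pairwise D' = 1, while
#' markers outside segments are mutually independent.
#'
#' @param marker_map a `marker_map`.
#' @param segments `data.frame` with columns `start`, `end`: global row
#'   indices into `marker_map`, each segment contiguous within one
#'   chromosome; or `NULL` for none.
#' @param freq per-marker allele-1 frequencies in \[0.05, 0.95\]; default
#'   drawn uniformly from `maf_range` (randomly oriented).
#' @param maf_range range of minor-allele frequencies for the default draw.
#' @param seed integer seed for the default frequency draw.
#' @return list of class `founder_spec` with elements `freq`, `segments`.
#' @export
founder_spec <- function(marker_map, segments = NULL, freq = NULL,
                         maf_range = c(0.1, 0.5), seed = 1L) {
  validate_marker_map(marker_map)
  m <- nrow(marker_map)
  if (is.null(freq)) {
    set.seed(seed)
    maf <- runif(m, maf_range[1], maf_range[2])
    flip <- runif(m) < 0.5
    freq <- ifelse(flip, 1 - maf, maf)
  }
  if (length(freq) != m) stop_gshap("freq must have one entry per marker")
  if (any(freq < 0.05 | freq > 0.95))
    stop_gshap("founder allele frequencies must lie in [0.05, 0.95]")
  if (is.null(segments)) {
    segments <- data.frame(start = integer(0), end = integer(0))
  } else {
    segments <- as.data.frame(segments)
    stopifnot(all(c("start", "end") %in% names(segments)))
    if (any(segments$start < 1 | segments$end > m | segments$start >= segments$end))
      stop_gshap("segments must satisfy 1 <= start < end <= n_markers")
    for (k in seq_len(nrow(segments))) {
      chr <- marker_map$chromosome[segments$start[k]:segments$end[k]]
      if (length(unique(chr)) != 1)
        stop_gshap("segment %d crosses a chromosome boundary", k)
    }
    o <- order(segments$start)
    segments <- segments[o, , drop = FALSE]
    if (nrow(segments) > 1 && any(segments$start[-1] <= segments$end[-nrow(segments)]))
      stop_gshap("segments must not overlap")
  }
  structure(list(freq = freq, segments = segments), class = "founder_spec")
}

#' Plant random perfect-LD segments on a marker map
#'
#' Convenience builder for [founder_spec()]: places `n_segments`
#' non-overlapping runs of `segment_size` consecutive markers, separated by
#' at least `gap` independent markers and never crossing chromosomes.
#'
#' @inheritParams founder_spec
#' @param n_segments number of segments to plant.
#' @param segment_size markers per segment (length-1 or length-2 range).
#' @param gap minimum independent markers between segments.
#' @export
random_founder_spec <- function(marker_map, n_segments, segment_size = c(3, 6),
                                gap = 10, maf_range = c(0.1, 0.5), seed = 1L) {
  validate_marker_map(marker_map)
  set.seed(seed)
  size_lo <- segment_size[1]
  size_hi <- segment_size[length(segment_size)]
  m <- nrow(marker_map)
  if (n_segments == 0)
    return(founder_spec(marker_map, segments = NULL,
                        maf_range = maf_range, seed = seed + 1L))
  taken <- rep(FALSE, m)
  segs <- list()
  tries <- 0
  while (length(segs) < n_segments && tries < 200 * n_segments) {
    tries <- tries + 1
    k <- if (size_hi > size_lo) sample(size_lo:size_hi, 1) else size_lo
    s <- sample.int(m - k + 1, 1)
    e <- s + k - 1
    lo <- max(1, s - gap); hi <- min(m, e + gap)
    if (any(taken[lo:hi])) next
    if (length(unique(marker_map$chromosome[s:e])) != 1) next
    taken[s:e] <- TRUE
    segs[[length(segs) + 1]] <- c(s, e)
  }
  if (length(segs) < n_segments)
    stop_gshap("could not place %d segments; map too dense or small", n_segments)
  segments <- do.call(rbind, segs)
  founder_spec(marker_map,
               segments = data.frame(start = segments[, 1], end = segments[, 2]),
               maf_range = maf_range, seed = seed + 1L)
}

# sample one founder haplotype (0/1 vector) from the spec
.founder_haplotype <- function(spec, marker_map) {
  m <- length(spec$freq)
  h <- as.integer(runif(m) < spec$freq)
  segs <- spec$segments
  if (nrow(segs) > 0) {
    for (k in seq_len(nrow(segs))) {
      idx <- segs$start[k]:segs$end[k]
      u <- runif(1)
      h[idx] <- as.integer(u < spec$freq[idx])
    }
  }
  h
}

# recombine two parental haplotypes into one gamete
.gamete <- function(h1, h2, marker_map, rate) {
  out <- integer(length(h1))
  for (chr in unique(marker_map$chromosome)) {
    idx <- which(marker_map$chromosome == chr)
    pos <- marker_map$position_bp[idx]
    L <- max(pos)
    cur <- sample.int(2L, 1L)
    if (rate > 0) {
      nxo <- rpois(1, rate * L)
    } else nxo <- 0L
    if (nxo > 0) {
      xo <- sort(runif(nxo, 0, L))
      seg <- findInterval(pos, xo)  # 0..nxo crossovers passed
      use1 <- (seg + cur) %% 2L == 1L
    } else {
      use1 <- rep(cur == 1L, length(idx))
    }
    out[idx] <- ifelse(use1, h1[idx], h2[idx])
  }
  out
}

#' Gene-drop phased genotypes through a pedigree
#'
#' Founders draw haplotypes from `spec`; each offspring gamete is formed by
#' Poisson recombination (no interference) between the parental haplotypes.
#' For half-sib progeny the recorded sire is unknown: the pollen parent is
#' drawn at random from the founders (open pollination) and is not recorded
#' in the pedigree.
#'
#' @param pedigree a `pedigree` (parents before offspring).
#' @param marker_map a `marker_map`.
#' @param spec a [founder_spec()].
#' @param recomb_rate_per_bp crossover rate per bp (default 1e-8).
#' @param seed integer seed.
#' @return A list of class `phased_genotypes`: `h1`, `h2` (individuals x
#'   markers 0/1 matrices, rows named by individual), `marker_map`.
#' @export
drop_genotypes <- function(pedigree, marker_map, spec,
                           recomb_rate_per_bp = 1e-8, seed = 1L) {
  validate_pedigree(pedigree)
  validate_marker_map(marker_map)
  if (!inherits(spec, "founder_spec")) stop_gshap("spec must be a founder_spec")
  if (length(spec$freq) != nrow(marker_map))
    stop_gshap("spec does not match the marker map")
  set.seed(seed)
  n <- nrow(pedigree)
  m <- nrow(marker_map)
  h1 <- matrix(0L, n, m, dimnames = list(pedigree$individual_id, marker_map$marker_id))
  h2 <- h1
  row_of <- function(id) match(id, pedigree$individual_id)
  founder_rows <- which(is.na(pedigree$sire_id) & is.na(pedigree$dam_id))
  for (i in founder_rows) {
    h1[i, ] <- .founder_haplotype(spec, marker_map)
    h2[i, ] <- .founder_haplotype(spec, marker_map)
  }
  for (i in setdiff(seq_len(n), founder_rows)) {
    d <- pedigree$dam_id[i]
    s <- pedigree$sire_id[i]
    di <- if (is.na(d) || d == UNKNOWN_PARENT) sample(founder_rows, 1) else row_of(d)
    si <- if (is.na(s) || s == UNKNOWN_PARENT) sample(founder_rows, 1) else row_of(s)
    h1[i, ] <- .gamete(h1[di, ], h2[di, ], marker_map, recomb_rate_per_bp)
    h2[i, ] <- .gamete(h1[si, ], h2[si, ], marker_map, recomb_rate_per_bp)
  }
  structure(list(h1 = h1, h2 = h2, marker_map = marker_map),
            class = "phased_genotypes")
}

#' Sample unrelated individuals directly from a founder specification
#'
#' Draws `n` unrelated individuals (two independent founder haplotypes
#' each) from the spec, without any pedigree: the panel on which planted
#' LD structure appears uncontaminated by family relatedness.
#'
#' @param spec a [founder_spec()].
#' @param marker_map the matching `marker_map`.
#' @param n number of individuals.
#' @param seed integer seed.
#' @return a `phased_genotypes` object with ids `U0001`, ...
#' @export
sample_founder_genotypes <- function(spec, marker_map, n, seed = 1L) {
  validate_marker_map(marker_map)
  if (!inherits(spec, "founder_spec")) stop_gshap("spec must be a founder_spec")
  set.seed(seed)
  m <- nrow(marker_map)
  ids <- sprintf("U%04d", seq_len(n))
  h1 <- matrix(0L, n, m, dimnames = list(ids, marker_map$marker_id))
  h2 <- h1
  for (i in seq_len(n)) {
    h1[i, ] <- .founder_haplotype(spec, marker_map)
    h2[i, ] <- .founder_haplotype(spec, marker_map)
  }
  structure(list(h1 = h1, h2 = h2, marker_map = marker_map),
            class = "phased_genotypes")
}

#' Dosage matrix (0/1/2) from phased genotypes
#' @param phased a `phased_genotypes` object.
#' @return integer matrix individuals x markers, dosage of allele 1.
#' @export
dosages <- function(phased) {
  stopifnot(inherits(phased, "phased_genotypes"))
  phased$h1 + phased$h2
}

#' Simulate RCBD phenotypes with QTL-driven breeding values
#'
#' An additive trait is generated for every non-founder in the pedigree:
#' `y = mean + design-block effect + breeding value + residual`, where the
#' breeding value is a sum of QTL dosages times normal effects and the
#' residual variance is solved so that `var(BV)/(var(BV)+var(resid))`
#' equals `target_h2` in expectation. Individuals within a family are
#' assigned distinct design blocks (single-tree plots). Ordinal traits are
#' produced by thresholding the latent continuous value at equal-probability
#' quantiles (or supplied cut quantiles).
#'
#' @param phased a `phased_genotypes` covering the pedigree.
#' @param pedigree the pedigree used to generate `phased`.
#' @param n_qtl number of QTL sampled among the markers.
#' @param target_h2 narrow-sense heritability target, in (0,1).
#' @param n_design_blocks number of RCBD blocks (default 30).
#' @param block_sd standard deviation of block effects; default equals the
#'   breeding-value standard deviation (field variation comparable to the
#'   genetic signal).
#' @param ordinal_spec `NULL` for a continuous trait, or
#'   `list(levels = L, probs = NULL)` for an `L`-level ordinal score
#'   `0..L-1` cut at equal-probability (or `probs`) quantiles of the latent.
#' @param seed integer seed.
#' @param trait_name column name for the trait.
#' @param trait_mean grand mean of the latent trait; the default (`NULL`)
#'   sets it to 10 latent standard deviations, i.e. a phenotypic
#'   coefficient of variation of ~10% as typical of field growth and
#'   wood traits.
#' @return list with `phenotypes` (`data.frame`: `individual_id`,
#'   `family_id`, `design_block`, trait column) and `truth` (list of class
#'   `sim_truth`: `qtl_marker_indices`, `qtl_effects`,
#'   `true_breeding_values`, `block_effects`, `target_h2`, `seed`).
#' @export
simulate_phenotypes <- function(phased, pedigree, n_qtl, target_h2,
                                n_design_blocks = 30, block_sd = NULL,
                                ordinal_spec = NULL, seed = 1L,
                                trait_name = "trait", trait_mean = NULL) {
  if (target_h2 <= 0 || target_h2 >= 1)
    stop_gshap("target_h2 must lie strictly inside (0,1)")
  geno <- dosages(phased)
  if (n_qtl > ncol(geno)) stop_gshap("n_qtl exceeds the number of markers")
  prog <- pedigree[pedigree$generation > 0, , drop = FALSE]
  if (nrow(prog) == 0) stop_gshap("pedigree has no non-founder individuals")
  fam_sizes <- table(prog$family_id)
  if (any(fam_sizes > n_design_blocks))
    stop_gshap("family larger than the number of design blocks (single-tree plots)")
  set.seed(seed)
  qtl <- sort(sample.int(ncol(geno), n_qtl))
  eff <- rnorm(n_qtl)
  g_all <- as.vector(geno[, qtl, drop = FALSE] %*% eff)
  names(g_all) <- rownames(geno)
  g <- g_all[prog$individual_id]
  tbv <- g - mean(g)
  v_bv <- var(tbv)
  if (v_bv <= 0) stop_gshap("breeding values degenerate (zero variance)")
  sigma_e <- sqrt(v_bv * (1 - target_h2) / target_h2)
  if (is.null(block_sd)) block_sd <- sqrt(v_bv)
  blk_eff <- rnorm(n_design_blocks, 0, block_sd)
  blk <- integer(nrow(prog))
  for (ix in split(seq_len(nrow(prog)), prog$family_id))
    blk[ix] <- sample.int(n_design_blocks, length(ix))
  resid <- rnorm(nrow(prog), 0, sigma_e)
  latent0 <- blk_eff[blk] + tbv + resid
  if (is.null(trait_mean)) trait_mean <- 10 * sd(latent0)
  latent <- trait_mean + latent0
  value <- latent
  if (!is.null(ordinal_spec)) {
    L <- ordinal_spec$levels
    probs <- ordinal_spec$probs %||% seq_len(L - 1) / L
    cuts <- quantile(latent, probs = probs, names = FALSE)
    value <- findInterval(latent, cuts)  # 0 .. L-1
  }
  phen <- data.frame(individual_id = prog$individual_id,
                     family_id = prog$family_id,
                     design_block = as.integer(blk),
                     stringsAsFactors = FALSE)
  phen[[trait_name]] <- value
  truth <- structure(list(
    qtl_marker_indices = qtl, qtl_effects = eff,
    true_breeding_values = setNames(tbv, prog$individual_id),
    block_effects = blk_eff, target_h2 = target_h2,
    trait_mean = trait_mean, seed = seed
  ), class = "sim_truth")
  list(phenotypes = phen, truth = truth)
}

#' Simulate a complete study-style breeding population
#'
#' One-call generator for the standard synthetic scenario: a mixed
#' half-/full-sib pedigree, gene-dropped genotypes with planted strong-LD
#' segments, and one or more RCBD traits. Defaults emulate a forest-tree
#' breeding trial: 65 families of 10, half of them open-pollinated, 30
#' design blocks with single-tree plots.
#'
#' @param n_chromosomes,n_markers,chromosome_length_bp passed to
#'   [make_marker_map()].
#' @param n_families,progeny_per_family,half_sib_fraction,n_founders passed
#'   to [simulate_pedigree()].
#' @param n_segments,segment_size planted perfect-LD segments, passed to
#'   [random_founder_spec()].
#' @param traits named list; each element is a list with `n_qtl`, `h2` and
#'   optionally `ordinal_levels`.
#' @param n_design_blocks RCBD blocks.
#' @param recomb_rate_per_bp crossover rate.
#' @param seed master seed; stage seeds are derived with [derive_seed()].
#' @return list of class `gs_dataset`: `marker_map`, `pedigree`, `phased`,
#'   `genotypes` (progeny dosage matrix), `phenotypes`, `truth` (per-trait
#'   `sim_truth` plus `segments`), `founder_spec`.
#' @export
simulate_population <- function(n_chromosomes = 3, n_markers = 300,
                                chromosome_length_bp = 5e6,
                                n_families = 65, progeny_per_family = 10,
                                half_sib_fraction = 0.5, n_founders = 130,
                                n_segments = 9, segment_size = c(3, 6),
                                traits = list(trait = list(n_qtl = 100, h2 = 0.4)),
                                n_design_blocks = 30, recomb_rate_per_bp = 1e-8,
                                seed = 1L) {
  map <- make_marker_map(n_chromosomes, n_markers, chromosome_length_bp,
                         seed = derive_seed(seed, "map"))
  ped <- simulate_pedigree(n_families, progeny_per_family, half_sib_fraction,
                           n_founders, seed = derive_seed(seed, "pedigree"))
  spec <- random_founder_spec(map, n_segments = n_segments,
                              segment_size = segment_size,
                              seed = derive_seed(seed, "founders"))
  phased <- drop_genotypes(ped, map, spec, recomb_rate_per_bp,
                           seed = derive_seed(seed, "drop"))
  phen <- NULL
  truth <- list(segments = spec$segments)
  for (tn in names(traits)) {
    tr <- traits[[tn]]
    osp <- if (!is.null(tr$ordinal_levels)) list(levels = tr$ordinal_levels) else NULL
    sim <- simulate_phenotypes(phased, ped, n_qtl = tr$n_qtl, target_h2 = tr$h2,
                               n_design_blocks = n_design_blocks,
                               ordinal_spec = osp,
                               seed = derive_seed(seed, paste0("trait_", tn)),
                               trait_name = tn)
    truth[[tn]] <- sim$truth
    phen <- if (is.null(phen)) sim$phenotypes else {
      stopifnot(identical(phen$individual_id, sim$phenotypes$individual_id))
      cbind(phen, sim$phenotypes[tn])
    }
  }
  prog <- ped$individual_id[ped$generation > 0]
  structure(list(
    marker_map = map, pedigree = ped, phased = phased,
    genotypes = dosages(phased)[prog, , drop = FALSE],
    phenotypes = phen, truth = truth, founder_spec = spec, seed = seed
  ), class = "gs_dataset")
}

#' Study-design trait set
#'
#' Returns the five-trait layout used by the worked examples: tree height
#' and diameter (continuous, low h2), stem straightness (7-level ordinal),
#' branch quality (6-level ordinal) and wood density (continuous, high h2).
#' @param n_qtl QTL per trait.
#' @export
study_traits <- function(n_qtl = 100) {
  list(
    HT  = list(n_qtl = n_qtl, h2 = 0.15),
    DBH = list(n_qtl = n_qtl, h2 = 0.04),
    ST  = list(n_qtl = n_qtl, h2 = 0.06, ordinal_levels = 7),
    BQ  = list(n_qtl = n_qtl, h2 = 0.05, ordinal_levels = 6),
    WD  = list(n_qtl = n_qtl, h2 = 0.46)
  )
}
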