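#' Nucleotide diversity of a haplotype set
#'
#' pi is the average number of pairwise differences between haplotypes,
#' computed through the site-frequency identity
#' `sum_s c_s * (n - c_s) / choose(n, 2)` (`c_s` = derived count at site s),
#' which equals the mean pairwise Hamming distance exactly. `pi_per_site`
#' divides by the region length in bp.
#'
#' @param x A [hap_panel()], `sim_replicate`, or 0/1 haplotype matrix.
#' @param haps Optional subset of haplotypes (index or logical).
#' @param region_length Length used for the per-site value; defaults to the
#'   panel's region length (or 1 for a bare matrix, fractional positions).
#' @return A one-row tibble: `n_hap`, `S`, `pi_region`, `pi_per_site`,
#'   `theta_w`, `tajima_d`, `tajima_defined`.
#' @export
nucleotide_diversity <- function(x, haps = NULL, region_length = NULL) {
  mat <- allele_matrix(x)
  if (!is.null(haps)) mat <- mat[haps, , drop = FALSE]
  n <- nrow(mat)
  if (n < 2) abort("nucleotide diversity needs at least 2 haplotypes.")
  if (is.null(region_length)) region_length <- default_region_length(x)
  cs <- if (ncol(mat)) colSums(mat) else integer(0)
  seg <- cs > 0 & cs < n
  S <- sum(seg)
  pi_region <- if (S) sum(cs[seg] * (n - cs[seg])) / choose(n, 2) else 0
  tw <- watterson_theta(S, n)
  td <- tajimas_d_from_parts(pi_region, S, n)
  tibble(n_hap = n, S = S, pi_region = pi_region,
         pi_per_site = pi_region / region_length, theta_w = tw,
         tajima_d = td$d, tajima_defined = td$defined)
}

allele_matrix <- function(x) {
  if (inherits(x, "hap_panel") || inherits(x, "sim_replicate")) x$alleles
  else as.matrix(x)
}

default_region_length <- function(x) {
  if (inherits(x, "hap_panel")) region_length(x$region) else 1
}

#' Watterson's theta estimator
#'
#' `S / a1` with `a1 = sum(1/i, i = 1..n-1)`, the segregating-sites
#' diversity estimator.
#'
#' @param S Number of segregating sites.
#' @param n Number of haplotypes.
#' @return The estimate (on the same per-region scale as `S`).
#' @export
watterson_theta <- function(S, n) {
  if (n < 2) abort("Watterson's theta needs n >= 2.")
  if (S == 0) return(0)
  S / sum(1 / seq_len(n - 1))
}

tajimas_d_from_parts <- function(pi_region, S, n) {
  if (S == 0) return(list(d = 0, defined = FALSE))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(list(d = 0, defined = FALSE))
  list(d = (pi_region - S / a1) / sqrt(v), defined = TRUE)
}

#' Tajima's D
#'
#' The standardized difference between the pairwise (pi) and
#' segregating-sites (Watterson) diversity estimates, with the classical
#' 1989 normalization. With `S = 0` the statistic is undefined; a flagged 0
#' is returned (`tajima_defined = FALSE` in [nucleotide_diversity()]) so
#' windowed tracks stay numeric.
#'
#' @inheritParams nucleotide_diversity
#' @return Tajima's D (scalar).
#' @export
tajimas_d <- function(x, haps = NULL) {
  nucleotide_diversity(x, haps = haps)$tajima_d
}

#' Single-site FST between two demes
#'
#' Weir & Cockerham's (1984) variance-components estimator for haploid
#' (phased) allele counts, the default; Hudson's `1 - Hw/Hb` estimator is
#' available for sensitivity analysis. The estimate can be negative; a
#' fixed difference gives exactly 1; a site monomorphic across both demes
#' has no defined value and returns `NA`.
#'
#' @param derived_a,total_a Derived and total allele counts in deme A.
#' @param derived_b,total_b Counts in deme B. All arguments are vectorized.
#' @param estimator `"wc84"` (default) or `"hudson"`.
#' @return Numeric vector of per-site FST values (`NA` where undefined).
#' @export
fst_per_site <- function(derived_a, total_a, derived_b, total_b,
                         estimator = c("wc84", "hudson")) {
  estimator <- match.arg(estimator)
  if (any(total_a < 2) || any(total_b < 2)) {
    abort("need at least 2 sampled haplotypes per deme.")
  }
  n1 <- total_a; n2 <- total_b
  p1 <- derived_a / total_a
  p2 <- derived_b / total_b
  mono <- (derived_a + derived_b == 0) | (derived_a + derived_b == total_a + total_b)
  out <- if (estimator == "wc84") {
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2))  # r - 1 = 1
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2  # / (r - 1) = 1
    msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 + n2 - 2)
    denom <- msp + (nc - 1) * msg
    ifelse(denom == 0, NA_real_, (msp - msg) / denom)
  } else {
    hw <- (p1 * (1 - p1) * n1_over(total_a) + p2 * (1 - p2) * n1_over(total_b)) / 2
    hb <- p1 * (1 - p2) + p2 * (1 - p1)
    ifelse(hb == 0, NA_real_, 1 - hw / hb)
  }
  out[mono] <- NA_real_
  out
}

n1_over <- function(n) n / (n - 1)  # small-sample correction for within-heterozygosity

#' FST per site across a two-population panel
#'
#' @param panel A [hap_panel()] with exactly two population labels (or use
#'   `pops` to pick two).
#' @param pops Optional length-2 character vector of population labels.
#' @param estimator Passed to [fst_per_site()].
#' @return Tibble with `site`, `position`, `freq_a`, `freq_b`, `fst`.
#' @export
fst_sites <- function(panel, pops = NULL, estimator = "wc84") {
  if (is.null(pops)) {
    pops <- unique(panel$pop)
    if (length(pops) != 2) abort("panel must have exactly two populations (or give `pops`).")
  }
  a <- panel$alleles[panel$pop == pops[1], , drop = FALSE]
  b <- panel$alleles[panel$pop == pops[2], , drop = FALSE]
  da <- colSums(a); db <- colSums(b)
  tibble(site = seq_len(ncol(a)), position = panel$positions,
         freq_a = da / nrow(a), freq_b = db / nrow(b),
         fst = fst_per_site(da, nrow(a), db, nrow(b), estimator = estimator))
}

#' Linkage disequilibrium r-squared between two binary haplotype vectors
#'
#' `(p_AB - p_A p_B)^2 / (p_A (1-p_A) p_B (1-p_B))` on phased haplotypes;
#' symmetric in its arguments and invariant under swapping allele labels at
#' either locus. Monomorphic input has no defined value and returns `NA`.
#'
#' @param vec_a,vec_b 0/1 vectors of equal length (one entry per haplotype).
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
r_squared <- function(vec_a, vec_b) {
  if (length(vec_a) != length(vec_b)) abort("vectors differ in length.")
  pa <- mean(vec_a); pb <- mean(vec_b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  pab <- mean(vec_a == 1 & vec_b == 1)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Nucleotide diversity among carriers of the derived allele at a site
#'
#' The diversity of the "haplogroup" defined by carrying the derived
#' (alternative) allele at a focal site. Undefined (NA row) with fewer than
#' two carriers.
#'
#' @param x A panel, replicate or matrix.
#' @param site Column index of the focal site.
#' @param haps Optional haplotype subset applied first (e.g. one deme).
#' @param region_length Passed to [nucleotide_diversity()].
#' @return A one-row tibble like [nucleotide_diversity()]'s, plus
#'   `n_carriers`; values are `NA` when fewer than 2 carriers.
#' @export
carrier_pi <- function(x, site, haps = NULL, region_length = NULL) {
  mat <- allele_matrix(x)
  if (!is.null(haps)) mat <- mat[haps, , drop = FALSE]
  carriers <- mat[, site] == 1
  k <- sum(carriers)
  if (k < 2) {
    return(tibble(n_hap = k, S = NA_integer_, pi_region = NA_real_,
                  pi_per_site = NA_real_, theta_w = NA_real_,
                  tajima_d = NA_real_, tajima_defined = FALSE,
                  n_carriers = k))
  }
  if (is.null(region_length)) region_length <- default_region_length(x)
  out <- nucleotide_diversity(mat[carriers, , drop = FALSE],
                              region_length = region_length)
  out$n_carriers <- k
  out
}

#' Mean per-site divergence of a haplotype set from a reference haplotype
#'
#' Average Hamming distance from each subset haplotype to the reference,
#' divided by the region length — the quantity fed to divergence-based
#' dating.
#'
#' @param x Panel, replicate or matrix.
#' @param haps Haplotype subset (rows of the divergent group).
#' @param reference A single haplotype: row index into `x`, or a 0/1 vector.
#' @param region_length Denominator in bp (panel default).
#' @return Per-site divergence (scalar).
#' @export
mean_divergence <- function(x, haps, reference, region_length = NULL) {
  mat <- allele_matrix(x)
  if (is.null(region_length)) region_length <- default_region_length(x)
  ref <- if (length(reference) == 1) mat[reference, ] else reference
  sub <- mat[haps, , drop = FALSE]
  if (nrow(sub) == 0) abort("empty haplotype subset.")
  ref_mat <- matrix(ref, nrow(sub), length(ref), byrow = TRUE)
  mean(rowSums(sub != ref_mat)) / region_length
}

#' Run of homozygosity around a core site for one diploid individual
#'
#' Given the two phased haplotypes of an individual homozygous for the core
#' allele, the ROH length on one side is the bp distance from the core
#' position to the first site, in that direction, where the two haplotypes
#' differ; if they agree all the way, the distance to the region edge.
#' `side = "both"` returns the sum of the two one-sided lengths.
#'
#' @param hap1,hap2 0/1 vectors over the same sites.
#' @param positions bp positions per site (strictly increasing).
#' @param core_position bp position of the core site (must be present).
#' @param side `"downstream"` (toward larger coordinates), `"upstream"`, or
#'   `"both"`.
#' @param region A [gregion()] or `c(start, end)` giving the edges used
#'   when no discordant site bounds the run.
#' @return ROH length in bp.
#' @export
roh_from_core <- function(hap1, hap2, positions, core_position,
                          side = c("downstream", "upstream", "both"),
                          region = NULL) {
  side <- match.arg(side)
  if (inherits(region, "gregion")) region <- c(region$start, region$end)
  if (is.null(region)) region <- range(positions)
  core_idx <- match(core_position, positions)
  if (is.na(core_idx)) abort("core position not found among `positions`.")
  if (hap1[core_idx] != hap2[core_idx]) {
    abort("individual is heterozygous at the core site.")
  }
  diffs <- positions[hap1 != hap2]
  one_side <- function(dir) {
    if (dir == "down") {
      d <- diffs[diffs > core_position]
      if (length(d)) min(d) - core_position else region[2] - core_position
    } else {
      d <- diffs[diffs < core_position]
      if (length(d)) core_position - max(d) else core_position - region[1]
    }
  }
  switch(side,
         downstream = one_side("down"),
         upstream = one_side("up"),
         both = one_side("down") + one_side("up"))
}

#' Cluster haplotypes by sequence alone
#'
#' Hierarchical clustering (complete linkage) on the pairwise Hamming
#' distance between haplotypes — no haplogroup or deletion information
#' enters. Ties in the distance matrix are resolved deterministically by
#' `stats::hclust`'s ordering, so permuting the input rows returns the same
#' tree topology.
#'
#' @param x Panel, replicate or matrix.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return A list: `hclust` (the tree), `order` (leaf ordering),
#'   `cut2` (2-group membership from cutting the tree).
#' @export
cluster_haplotypes <- function(x, linkage = "complete") {
  mat <- allele_matrix(x)
  if (nrow(mat) < 2) abort("clustering needs at least 2 haplotypes.")
  d <- stats::dist(mat, method = "manhattan")  # Hamming for 0/1 data
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, order = hc$order, cut2 = stats::cutree(hc, k = 2))
}

#' Impute deletion status from flanking haplotypes
#'
#' Leave-one-out nearest-haplotype imputation: each haplotype is assigned
#' the deletion status of its closest (minimum Hamming distance) other
#' haplotype, ties broken by majority vote among the tied set and then by
#' lowest haplotype index. This measures how well flanking variation tags
#' the structural variant — with imperfect LD the accuracy is substantially
#' below 1.
#'
#' @param panel A [hap_panel()] whose `deletion` field is set, or a matrix
#'   together with `deletion`.
#' @param deletion Optional 0/1 vector overriding the panel's.
#' @return A list: `predicted` (0/1 per haplotype), `accuracy`
#'   (leave-one-out), and `confusion` (2x2 table).
#' @export
impute_deletion <- function(panel, deletion = NULL) {
  mat <- allele_matrix(panel)
  if (is.null(deletion)) deletion <- panel$deletion
  if (is.null(deletion)) abort("no deletion status available.")
  if (length(unique(deletion)) < 2) {
    abort("training haplotypes are monomorphic for the deletion.")
  }
  d <- as.matrix(stats::dist(mat, method = "manhattan"))
  diag(d) <- Inf
  predicted <- vapply(seq_len(nrow(mat)), function(i) {
    nearest <- which(d[i, ] == min(d[i, ]))
    votes <- deletion[nearest]
    if (mean(votes) == 0.5) votes[1] else as.integer(mean(votes) > 0.5)
  }, integer(1))
  list(predicted = predicted, accuracy = mean(predicted == deletion),
       confusion = table(truth = deletion, predicted = predicted))
}

#' Windowed diversity statistics along a panel
#'
#' Tiles the panel's region into fixed-size windows (3 kb by default,
#' matching the usual tiling for pi and Tajima's D; use 2 kb to mirror
#' cross-population statistic tracks) and computes per-window pi, S,
#' Watterson's theta and Tajima's D.
#'
#' @param panel A [hap_panel()].
#' @param window_size Window width in bp.
#' @param haps Optional haplotype subset.
#' @return A tibble: `chrom`, `start`, `end`, `S`, `pi_per_site`,
#'   `theta_w`, `tajima_d`, `tajima_defined`.
#' @export
windowed_stats <- function(panel, window_size = 3000, haps = NULL) {
  starts <- seq(panel$region$start, panel$region$end, by = window_size)
  purrr::map_dfr(starts, function(s) {
    e <- min(s + window_size - 1, panel$region$end)
    w <- panel_window(panel, from = s, to = e)
    stats <- nucleotide_diversity(w, haps = haps, region_length = e - s + 1)
    tibble(chrom = panel$chrom, start = s, end = e, S = stats$S,
           pi_per_site = stats$pi_per_site, theta_w = stats$theta_w,
           tajima_d = stats$tajima_d, tajima_defined = stats$tajima_defined)
  })
}
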