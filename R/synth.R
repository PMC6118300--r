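#' Specification for a synthetic sweep panel
#'
#' Describes the statistical structure of a two-population phased panel
#' emulating an incomplete sweep: a derived haplogroup at high frequency
#' in population A and (by default) absent from population B, with
#' within-haplogroup diversity several-fold below background, and a
#' deletion allele in imperfect LD with the haplogroup. The defaults mirror
#' the study conditions the package's analyses are designed for: 206 + 216
#' haplotypes, an 8,787 bp region, haplogroup frequency 0.70 vs 0,
#' background pi 7.6e-4 vs haplogroup pi 1.2e-4 (a ~6x contrast), 91%
#' deletion carriage among members and a deletion-haplogroup r-squared of
#' 0.47.
#'
#' @param n_hap_a,n_hap_b Haplotype counts (must be even; pairs form
#'   diploids).
#' @param region_length Region length in bp.
#' @param haplogroup_freq_a,haplogroup_freq_b Haplogroup frequency per
#'   population.
#' @param background_pi,haplogroup_pi Per-site nucleotide diversity of
#'   non-members and members.
#' @param deletion_given_haplogroup P(deletion | member).
#' @param target_r2_deletion Target r-squared between deletion and
#'   haplogroup membership in population A.
#' @param n_core Number of fully linked core SNVs that define the
#'   haplogroup.
#' @param hotspot `NULL`, or `list(position = bp, intensity = p)`: each
#'   member haplotype is, with probability `p`, recombined onto a random
#'   background haplotype upstream of (approximately) `position` — a
#'   recombination hotspot that truncates upstream homozygosity.
#' @param pi_tolerance Relative tolerance of the background-diversity
#'   conditioning step (the coalescent draw is repeated until both
#'   populations' realized diversity is within this fraction of
#'   `background_pi`).
#' @param seed Integer seed; generation is bit-reproducible given the spec
#'   and seed.
#' @return A `sweep_panel_spec` list.
#' @export
sweep_panel_spec <- function(n_hap_a = 206, n_hap_b = 216,
                             region_length = 8787,
                             haplogroup_freq_a = 0.70,
                             haplogroup_freq_b = 0,
                             background_pi = 7.6e-4,
                             haplogroup_pi = 1.2e-4,
                             deletion_given_haplogroup = 0.91,
                             target_r2_deletion = 0.47,
                             n_core = 6, hotspot = NULL,
                             pi_tolerance = 0.15, seed = 1L) {
  fracs <- c(haplogroup_freq_a, haplogroup_freq_b,
             deletion_given_haplogroup, target_r2_deletion)
  if (any(fracs < 0 | fracs > 1)) abort("all fractions must lie in [0, 1].")
  if (n_hap_a %% 2 != 0 || n_hap_b %% 2 != 0) {
    abort("haplotype counts must be even (haplotypes pair into diploids).")
  }
  if (region_length <= 0) abort("region_length must be positive.")
  structure(list(n_hap_a = n_hap_a, n_hap_b = n_hap_b,
                 region_length = region_length,
                 haplogroup_freq_a = haplogroup_freq_a,
                 haplogroup_freq_b = haplogroup_freq_b,
                 background_pi = background_pi,
                 haplogroup_pi = haplogroup_pi,
                 deletion_given_haplogroup = deletion_given_haplogroup,
                 target_r2_deletion = target_r2_deletion,
                 n_core = n_core, hotspot = hotspot,
                 pi_tolerance = pi_tolerance, seed = as.integer(seed)),
            class = "sweep_panel_spec")
}

#' Feasible r-squared bound and non-member carriage solution
#'
#' With membership frequency `q` and carriage `a = P(del | member)`, the
#' deletion-haplogroup r-squared is
#' `r2(b) = q(1-q)(a-b)^2 / (pD(1-pD))` with `b = P(del | non-member)` and
#' `pD = qa + (1-q)b`. `r2(b)` decreases from its maximum at `b = 0`,
#' `r2_max = (1-q) a / (1 - q a)`, to 0 at `b = a`; the generator solves
#' `r2(b) = target` for `b`.
#'
#' @keywords internal
solve_deletion_leak <- function(q, a, target_r2) {
  r2_of <- function(b) {
    pd <- q * a + (1 - q) * b
    q * (1 - q) * (a - b)^2 / (pd * (1 - pd))
  }
  r2_max <- r2_of(0)
  if (target_r2 > r2_max + 1e-12) {
    abort(sprintf(
      "infeasible LD target: with membership frequency %.3f and carriage %.2f the maximum attainable r^2 is %.3f (requested %.3f).",
      q, a, r2_max, target_r2))
  }
  if (target_r2 >= r2_max) return(0)
  stats::uniroot(function(b) r2_of(b) - target_r2, c(0, a),
                 tol = 1e-10)$root
}

#' Generate a synthetic sweep panel with ground-truth labels
#'
#' Background haplotypes for the two populations are drawn from the
#' package's own coalescent engine under a symmetric two-island model
#' whose theta is calibrated so the expected within-population diversity
#' equals `background_pi` (in a symmetric two-island model the within-deme
#' diversity is `2 theta` per region, independent of the migration rate).
#' The haplogroup is built star-like around an anciently diverged founder
#' haplotype (ancestral at all background sites, derived at the `n_core`
#' fully linked core SNVs that define the haplogroup): every member copies
#' the founder and receives a Poisson number of private mutations with
#' mean `haplogroup_pi * L / 2`, giving expected member-pair diversity
#' `haplogroup_pi`. The deletion is assigned by the two conditional
#' carriage probabilities solved in [solve_deletion_leak()].
#'
#' @param spec A [sweep_panel_spec()].
#' @return A list: `panel` (a [hap_panel()] with populations `"popA"`,
#'   `"popB"` and deletion status), `truth` (tibble with per-haplotype
#'   `member` and `deletion`), `core_positions`, and `spec`.
#' @export
generate_sweep_panel <- function(spec) {
  stopifnot(inherits(spec, "sweep_panel_spec"))
  set.seed(spec$seed)
  L <- spec$region_length
  n_a <- spec$n_hap_a
  n_b <- spec$n_hap_b
  n_mem_a <- round(spec$haplogroup_freq_a * n_a)
  n_mem_b <- round(spec$haplogroup_freq_b * n_b)
  n_bg_a <- n_a - n_mem_a
  n_bg_b <- n_b - n_mem_b

  # background coalescent: deme 1 = popA backgrounds, deme 2 = popB.
  # The haplogroup founder is an anciently diverged haplotype and is taken
  # to be ancestral at every background site, so its defining derived
  # variants are exactly the core set (star-like haplogroup structure).
  theta_bg <- spec$background_pi * L / 2
  rho_bg <- min(0.03 * L, 1500)  # smooths coalescent variance in realized diversity
  model <- parse_ms_args(sprintf(
    "ms %d 1 -t %.8g -I 2 %d %d 5 -r %.8g %d",
    n_bg_a + n_bg_b, theta_bg, n_bg_a, n_bg_b, rho_bg, L))
  # a single coalescent draw has large evolutionary variance in realized
  # diversity; condition on both populations landing within 15% of target
  rep <- NULL
  for (try in seq_len(200)) {
    cand <- simulate_coalescent(model, n_reps = 1,
                                seed = spec$seed + 1000L + 7919L * (try - 1L))[[1]]
    ok_a <- n_bg_a < 2 || abs(nucleotide_diversity(
      cand$alleles[seq_len(n_bg_a), , drop = FALSE],
      region_length = L)$pi_per_site / spec$background_pi - 1) < spec$pi_tolerance
    ok_b <- n_bg_b < 2 || abs(nucleotide_diversity(
      cand$alleles[n_bg_a + seq_len(n_bg_b), , drop = FALSE],
      region_length = L)$pi_per_site / spec$background_pi - 1) < spec$pi_tolerance
    if (ok_a && ok_b) { rep <- cand; break }
  }
  if (is.null(rep)) abort("background conditioning failed after 200 draws.")
  bg_bp <- positions_to_bp(rep$positions, L)
  founder_bg <- rep(0L, length(bg_bp))
  bg_a <- rep$alleles[seq_len(n_bg_a), , drop = FALSE]
  bg_b <- rep$alleles[n_bg_a + seq_len(n_bg_b), , drop = FALSE]

  # physical positions for core and private sites, avoiding collisions
  used <- bg_bp
  draw_free <- function(k, lo = 1, hi = L) {
    pool <- setdiff(seq(ceiling(lo), floor(hi)), used)
    if (length(pool) < k) abort("region too dense to place new sites.")
    p <- sort(sample(pool, k))
    used <<- c(used, p)
    p
  }
  hot_frac <- if (is.null(spec$hotspot)) 0 else spec$hotspot$position / L
  core_lo <- max(0.3, hot_frac + 0.05) * L
  core_pos <- if (spec$n_core > 0 && n_mem_a + n_mem_b > 0) {
    pos <- seq(core_lo, 0.95 * L, length.out = spec$n_core)
    vapply(pos, function(p) draw_free(1, p, min(p + L / 50, L)), numeric(1))
  } else numeric(0)

  n_mem <- n_mem_a + n_mem_b
  # total private-mutation count fixed at its expectation; owners drawn
  # multinomially so the star-like singleton structure is preserved
  n_priv <- round(n_mem * spec$haplogroup_pi * L / 2)
  priv_owner_idx <- if (n_priv > 0) sample.int(n_mem, n_priv, replace = TRUE) else integer(0)
  priv_counts <- tabulate(priv_owner_idx, n_mem)
  priv_pos <- if (n_priv > 0) draw_free(n_priv) else numeric(0)
  priv_pos <- sample(priv_pos)  # assign positions to members in random order

  # assemble the full site set
  all_pos <- sort(c(bg_bp, core_pos, priv_pos))
  col_of <- function(p) match(p, all_pos)
  n_hap <- n_a + n_b
  alleles <- matrix(0L, n_hap, length(all_pos))

  member <- logical(n_hap)
  rows_a <- seq_len(n_a)
  rows_b <- n_a + seq_len(n_b)
  member[sample(rows_a, n_mem_a)] <- TRUE
  if (n_mem_b > 0) member[sample(rows_b, n_mem_b)] <- TRUE

  bg_cols <- col_of(bg_bp)
  bg_rows_a <- sample(seq_len(n_bg_a))  # permute background draws
  bg_rows_b <- sample(seq_len(n_bg_b))
  ia <- ib <- 1
  mem_idx <- 0
  mem_rows <- which(member)
  for (h in seq_len(n_hap)) {
    if (member[h]) {
      alleles[h, bg_cols] <- founder_bg
    } else if (h <= n_a) {
      alleles[h, bg_cols] <- bg_a[bg_rows_a[ia], ]
      ia <- ia + 1
    } else {
      alleles[h, bg_cols] <- bg_b[bg_rows_b[ib], ]
      ib <- ib + 1
    }
  }
  if (length(core_pos)) alleles[mem_rows, col_of(core_pos)] <- 1L
  if (length(priv_pos)) {
    owner <- rep(mem_rows, times = priv_counts)
    for (k in seq_along(priv_pos)) {
      alleles[owner[k], col_of(priv_pos[k])] <- 1L
    }
  }

  # optional upstream recombination hotspot acting on member haplotypes
  if (!is.null(spec$hotspot) && n_mem > 0) {
    nonmem_a <- setdiff(rows_a, mem_rows)
    for (h in intersect(mem_rows, rows_a)) {
      if (runif(1) < spec$hotspot$intensity && length(nonmem_a)) {
        brk <- spec$hotspot$position + runif(1, -0.02, 0.02) * L
        donor <- alleles[sample(nonmem_a, 1), ]
        upstream <- all_pos < brk
        alleles[h, upstream] <- donor[upstream]
      }
    }
  }

  # deletion allele: carriage a among members, leak b among non-members
  a <- spec$deletion_given_haplogroup
  q <- n_mem_a / n_a
  b <- if (q > 0 && q < 1 && a > 0) {
    solve_deletion_leak(q, a, spec$target_r2_deletion)
  } else 0.25
  # carriage counts fixed at their expectations (hypergeometric draw), so
  # the realized LD profile is stable across seeds
  deletion <- integer(n_hap)
  assign_carriers <- function(grp, p) {
    k <- round(p * length(grp))
    if (k > 0) deletion[grp[sample.int(length(grp), k)]] <<- 1L
  }
  is_a <- seq_len(n_hap) <= n_a
  assign_carriers(which(member & is_a), a)
  assign_carriers(which(member & !is_a), a)
  assign_carriers(which(!member & is_a), b)
  assign_carriers(which(!member & !is_a), b)

  panel <- hap_panel(alleles, all_pos, chrom = "chr1",
                     region = gregion("chr1", 1, L),
                     pop = c(rep("popA", n_a), rep("popB", n_b)),
                     deletion = deletion,
                     deletion_pos = max(1, floor(0.02 * L)))
  truth <- tibble(haplotype = seq_len(n_hap), pop = panel$pop,
                  member = member, deletion = deletion)
  list(panel = panel, truth = truth, core_positions = core_pos, spec = spec)
}
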