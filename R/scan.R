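#' Null distributions for sweep statistics
#'
#' Internal constructor shared by the empirical and simulated nulls. A
#' `null_distribution` is a tibble of statistic values carrying its
#' provenance (source, frequency-matching window, counts, model command,
#' seed) as attributes; [glance()] returns them as a one-row tibble.
#'
#' @keywords internal
new_null_distribution <- function(values, source, window = NULL,
                                  n_inputs = NA_integer_, model = NULL,
                                  seed = NA_integer_, extra = list()) {
  out <- tibble(value = as.numeric(values))
  attr(out, "source") <- source
  attr(out, "window") <- window
  attr(out, "n_inputs") <- n_inputs
  attr(out, "n_matched") <- nrow(out)
  attr(out, "model_command") <- if (is.null(model)) NA_character_ else model$command
  attr(out, "seed") <- seed
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("null_distribution", class(out))
  out
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d values (source: %s", nrow(x),
              attr(x, "source")))
  w <- attr(x, "window")
  if (!is.null(w)) cat(sprintf(", window [%g, %g]", w[1], w[2]))
  cat(sprintf(", from %s inputs)\n", format(attr(x, "n_inputs"))))
  if (nrow(x)) {
    q <- quantile(x$value, c(0.01, 0.5, 0.99), na.rm = TRUE)
    cat(sprintf("  1%% %.4g | median %.4g | 99%% %.4g\n", q[1], q[2], q[3]))
  }
  invisible(x)
}

#' @rdname new_null_distribution
#' @param x A `null_distribution`.
#' @param ... Unused.
#' @export
glance.null_distribution <- function(x, ...) {
  w <- attr(x, "window")
  tibble(source = attr(x, "source"),
         window_lo = if (is.null(w)) NA_real_ else unname(w[1]),
         window_hi = if (is.null(w)) NA_real_ else unname(w[2]),
         n_inputs = attr(x, "n_inputs"), n_matched = attr(x, "n_matched"),
         model_command = attr(x, "model_command"), seed = attr(x, "seed"))
}

#' A frequency-matching window
#'
#' @param lo,hi Bounds on the derived-allele fraction, `0 <= lo <= hi <= 1`
#'   not enforced upward so that deliberately empty windows (e.g.
#'   `[1.1, 1.2]`) can be used to test the machinery.
#' @return Numeric length-2 vector with class `freq_window`.
#' @export
freq_window <- function(lo, hi) {
  if (lo > hi || lo < 0) abort("need 0 <= lo <= hi.")
  structure(c(lo = lo, hi = hi), class = "freq_window")
}

#' Sample size-matched random regions along a chromosome
#'
#' Uniform random placement of fixed-size regions, optionally constrained
#' to overlap a supplied interval set (for example segmental duplications),
#' for building empirical null distributions of windowed statistics.
#'
#' @param chrom_length Chromosome length in bp.
#' @param region_size Region size in bp.
#' @param n Number of regions.
#' @param restrict_to Optional tibble/data.frame with `start`, `end`
#'   columns; every sampled region must overlap at least one interval.
#' @param chrom Chromosome name for the output.
#' @param seed Optional integer seed.
#' @return A tibble with `chrom`, `start`, `end` (1-based closed).
#' @export
sample_random_regions <- function(chrom_length, region_size, n,
                                  restrict_to = NULL, chrom = "chr1",
                                  seed = NULL) {
  if (region_size > chrom_length) abort("region_size exceeds chrom_length.")
  if (!is.null(seed)) set.seed(seed)
  max_start <- chrom_length - region_size + 1
  if (!is.null(restrict_to)) {
    # feasible iff some interval lies within reach of a valid start
    feasible <- any(restrict_to$end >= 1 & restrict_to$start <= chrom_length)
    if (!feasible) abort("restriction set cannot be overlapped by any region.")
  }
  starts <- numeric(0)
  while (length(starts) < n) {
    cand <- ceiling(runif(max(n - length(starts), 1)) * max_start)
    if (!is.null(restrict_to)) {
      ok <- vapply(cand, function(s) {
        any(restrict_to$start <= s + region_size - 1 & restrict_to$end >= s)
      }, logical(1))
      cand <- cand[ok]
    }
    starts <- c(starts, cand)
  }
  starts <- starts[seq_len(n)]
  tibble(chrom = chrom, start = starts, end = starts + region_size - 1)
}

#' Compare observed statistic values against an empirical null
#'
#' Two-sided Wilcoxon rank-sum test with continuity correction between the
#' target values and the null values, plus the percentile of the target's
#' median within the null distribution. Being rank-based, the result is
#' exactly invariant under any monotone transformation applied jointly to
#' both samples.
#'
#' @param target_values Statistic values observed in the target region(s).
#' @param null_values Values from random/matched regions or simulations.
#' @return A one-row tibble: `percentile` (of the target median in the
#'   null), `p_value`, `n_target`, `n_null`, `target_median`,
#'   `null_median`.
#' @export
empirical_null_test <- function(target_values, null_values) {
  target_values <- target_values[is.finite(target_values)]
  null_values <- null_values[is.finite(null_values)]
  if (!length(target_values) || !length(null_values)) {
    abort("both samples must be non-empty.")
  }
  wt <- suppressWarnings(wilcox.test(target_values, null_values,
                                     correct = TRUE, exact = FALSE))
  med <- median(target_values)
  tibble(percentile = 100 * mean(null_values < med) +
           50 * mean(null_values == med),
         p_value = wt$p.value, n_target = length(target_values),
         n_null = length(null_values), target_median = med,
         null_median = median(null_values))
}

match_window_counts <- function(counts, n, window) {
  freqs <- counts / n
  which(freqs >= window[1] & freqs <= window[2])
}

#' Frequency-matched simulated FST null
#'
#' Simulates replicates under `model`, and for every segregating site
#' whose derived-allele frequency in the focal deme falls inside `window`
#' retains the per-site Weir-Cockerham FST between the two demes. This is
#' the simulated null distribution that an observed core-SNV FST is ranked
#' against.
#'
#' @param model A `demographic_model` with at least two demes.
#' @param window A [freq_window()] on the focal-deme derived frequency.
#' @param focal_deme,other_deme 1-based deme indices.
#' @param n_reps Number of replicates (defaults to the model's).
#' @param seed Root seed for the simulation.
#' @param match_pooled Match on the pooled (all-deme) frequency instead of
#'   the focal deme's, for sensitivity analysis.
#' @return A `null_distribution` of FST values; `glance()` reports the
#'   matched count and provenance.
#' @export
freq_matched_fst_null <- function(model, window, focal_deme = 2,
                                  other_deme = 1, n_reps = model$n_reps,
                                  seed = NULL, match_pooled = FALSE) {
  if (model$npop < 2) abort("model must have at least two demes.")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  nf <- model$deme_sizes[focal_deme]
  no <- model$deme_sizes[other_deme]
  vals <- simulate_coalescent(model, n_reps = n_reps, seed = seed,
                              map = function(rep) {
    if (!length(rep$positions)) return(numeric(0))
    cf <- colSums(rep$alleles[rep$deme == focal_deme, , drop = FALSE])
    co <- colSums(rep$alleles[rep$deme == other_deme, , drop = FALSE])
    sel <- if (match_pooled) {
      match_window_counts(cf + co, nf + no, window)
    } else {
      match_window_counts(cf, nf, window)
    }
    if (!length(sel)) return(numeric(0))
    fst_per_site(cf[sel], nf, co[sel], no)
  })
  vals <- unlist(vals)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) warn("no simulated sites matched the frequency window.")
  new_null_distribution(vals, source = "simulated", window = unclass(window),
                        n_inputs = n_reps, model = model, seed = seed,
                        extra = list(statistic = "fst"))
}

#' Frequency-matched simulated carrier-diversity null
#'
#' As [freq_matched_fst_null()], but each retained value is the nucleotide
#' diversity among the focal-deme haplotypes *carrying* the derived allele
#' at a matched site — the simulated analogue of the diversity of a
#' haplogroup at the observed frequency. Matched sites in complete LD
#' define the same carrier haplogroup; by default one value is retained
#' per distinct carrier group per replicate (`per_site = TRUE` retains one
#' per site instead).
#'
#' @inheritParams freq_matched_fst_null
#' @param per_site Retain one value per matched site rather than per
#'   distinct carrier group.
#' @param region_length bp length used for the per-site diversity scale
#'   (defaults to the model's `-r` site count, or 1).
#' @return A `null_distribution` of per-site pi values.
#' @export
freq_matched_pi_null <- function(model, window, focal_deme = 2,
                                 n_reps = model$n_reps, seed = NULL,
                                 per_site = FALSE, region_length = NULL) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  if (is.null(region_length)) {
    region_length <- if (is.na(model$n_sites)) 1 else model$n_sites
  }
  nf <- model$deme_sizes[focal_deme]
  vals <- simulate_coalescent(model, n_reps = n_reps, seed = seed,
                              map = function(rep) {
    if (!length(rep$positions)) return(numeric(0))
    focal <- rep$alleles[rep$deme == focal_deme, , drop = FALSE]
    cf <- colSums(focal)
    sel <- match_window_counts(cf, nf, window)
    sel <- sel[cf[sel] >= 2]
    if (!length(sel)) return(numeric(0))
    if (!per_site) {
      keys <- vapply(sel, function(j) paste(which(focal[, j] == 1),
                                            collapse = ","), "")
      sel <- sel[!duplicated(keys)]
    }
    vapply(sel, function(j) {
      carrier_pi(focal, j, region_length = region_length)$pi_per_site
    }, numeric(1))
  })
  vals <- unlist(vals)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) warn("no simulated sites matched the frequency window.")
  new_null_distribution(vals, source = "simulated", window = unclass(window),
                        n_inputs = n_reps, model = model, seed = seed,
                        extra = list(statistic = "carrier_pi",
                                     per_site = per_site))
}

#' Core-site-conditioned simulated ROH null
#'
#' For each simulated replicate, finds "core" sites whose derived-allele
#' frequency in the focal deme lies in `window` while the other deme
#' carries exactly zero derived copies. Around each core site, derived
#' carriers in the focal deme are paired into homozygous diploid
#' constructs (shuffled order within the replicate) and the run of
#' homozygosity is measured on both sides of the core; all pair lengths
#' are returned, together with the number of qualifying core sites.
#'
#' @inheritParams freq_matched_fst_null
#' @param region_length bp span of the simulated region (defaults to the
#'   model's `-r` site count).
#' @param side Passed to [roh_from_core()]; the analysis default is
#'   `"both"`.
#' @return A `null_distribution` of ROH lengths in bp; `glance()` also
#'   reports `n_core_sites`.
#' @export
roh_null <- function(model, window, focal_deme = 1, other_deme = 2,
                     n_reps = model$n_reps, seed = NULL,
                     region_length = NULL, side = "both") {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  set.seed(seed)  # the carrier-pairing shuffle uses R's RNG
  if (is.null(region_length)) {
    if (is.na(model$n_sites)) abort("model has no -r site count; give `region_length`.")
    region_length <- model$n_sites
  }
  nf <- model$deme_sizes[focal_deme]
  n_core <- 0L
  res <- simulate_coalescent(model, n_reps = n_reps, seed = seed,
                             map = function(rep) {
    if (!length(rep$positions)) return(numeric(0))
    focal <- rep$alleles[rep$deme == focal_deme, , drop = FALSE]
    other <- rep$alleles[rep$deme == other_deme, , drop = FALSE]
    cf <- colSums(focal)
    co <- colSums(other)
    cores <- intersect(match_window_counts(cf, nf, window), which(co == 0))
    if (!length(cores)) return(numeric(0))
    bp <- positions_to_bp(rep$positions, region_length)
    # deterministic per-replicate shuffle derived from the root seed
    lens <- lapply(cores, function(j) {
      carriers <- which(focal[, j] == 1)
      ord <- sample(carriers)
      pairs <- matrix(ord[seq_len(2 * (length(ord) %/% 2))], ncol = 2,
                      byrow = TRUE)
      apply(pairs, 1, function(pr) {
        roh_from_core(focal[pr[1], ], focal[pr[2], ], bp, bp[j], side = side,
                      region = c(1, region_length))
      })
    })
    attr(lens, "n_core") <- length(cores)
    lens
  })
  all_lens <- numeric(0)
  for (r in res) {
    if (length(r)) {
      n_core <- n_core + (attr(r, "n_core") %||% 0L)
      all_lens <- c(all_lens, unlist(r))
    }
  }
  new_null_distribution(all_lens, source = "simulated",
                        window = unclass(window), n_inputs = n_reps,
                        model = model, seed = seed,
                        extra = list(statistic = "roh", side = side,
                                     n_core_sites = n_core))
}

#' Bootstrap resampling of homozygous constructs
#'
#' Tests for sampling bias in an observed mean ROH: haplogroup member
#' haplotypes are resampled with replacement, paired into artificial
#' homozygous diploids, and the mean one-sided ROH of each bootstrap panel
#' is recorded. If the observed mean falls in the central mass of this
#' distribution, the observed panel looks like a random draw from its own
#' haplotype pool (no consanguinity-style bias).
#'
#' @param member_haps 0/1 matrix of haplogroup member haplotypes.
#' @param positions bp positions of the matrix columns.
#' @param core_position bp position of the core site.
#' @param n_individuals Homozygous constructs per bootstrap panel
#'   (analysis default 238).
#' @param n_boot Number of bootstrap panels (analysis default 500).
#' @param observed_mean Optional observed mean ROH to be ranked.
#' @param side,region Passed to [roh_from_core()].
#' @param seed Optional integer seed.
#' @return A list: `boot_means` (length `n_boot`), `observed_mean`,
#'   `percentile` of the observed value (NA if not supplied).
#' @export
bootstrap_homozygotes <- function(member_haps, positions, core_position,
                                  n_individuals = 238, n_boot = 500,
                                  observed_mean = NULL, side = "downstream",
                                  region = NULL, seed = NULL) {
  member_haps <- as.matrix(member_haps)
  if (nrow(member_haps) < 2) abort("need at least 2 member haplotypes.")
  if (!is.null(seed)) set.seed(seed)
  boot_means <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(member_haps), 2 * n_individuals, replace = TRUE)
    pairs <- matrix(idx, ncol = 2)
    mean(apply(pairs, 1, function(pr) {
      roh_from_core(member_haps[pr[1], ], member_haps[pr[2], ], positions,
                    core_position, side = side, region = region)
    }))
  }, numeric(1))
  pct <- if (is.null(observed_mean)) NA_real_ else {
    100 * (mean(boot_means < observed_mean) +
             0.5 * mean(boot_means == observed_mean))
  }
  list(boot_means = boot_means, observed_mean = observed_mean,
       percentile = pct)
}

#' Identify the differentiated core haplogroup of a panel
#'
#' Ranks sites by between-population differentiation (per-site FST by
#' default), takes the top `n_core` sites, verifies that they are in
#' mutual linkage disequilibrium (all pairwise r-squared above
#' `r2_threshold`, so that they tag a single haplotype group), and defines
#' haplogroup membership as carrying the derived allele at all core sites.
#' Haplotypes carrying at least half — but not all — of the core alleles
#' are flagged as recombinant members.
#'
#' @param panel A two-population [hap_panel()].
#' @param ranking Optional tibble with `site` and a differentiation value
#'   column (`fst`); defaults to [fst_sites()] on the panel.
#' @param n_core Number of top-differentiated sites to take.
#' @param r2_threshold Mutual-LD requirement among core sites (default
#'   0.84).
#' @param focal_pop Population carrying the putative sweep; only sites
#'   whose derived allele is *more* frequent there than in the other
#'   population are candidates (a sweep raises the haplogroup's alleles in
#'   the focal population). Defaults to the panel's first population.
#' @return A list: `core_sites` (tibble of site, position,
#'   differentiation), `member` (logical per haplotype), `recombinant`
#'   (logical), `freq` (membership frequency per population).
#' @export
identify_haplogroup <- function(panel, ranking = NULL, n_core = 6,
                                r2_threshold = 0.84, focal_pop = NULL) {
  pops <- unique(panel$pop)
  if (is.null(focal_pop)) focal_pop <- pops[1]
  if (is.null(ranking)) {
    ranking <- fst_sites(panel, pops = c(focal_pop, setdiff(pops, focal_pop)[1]))
    ranking <- ranking[ranking$freq_a > ranking$freq_b, ]
  }
  stat_col <- setdiff(names(ranking), c("site", "position", "freq_a", "freq_b"))[1]
  ranking <- ranking[is.finite(ranking[[stat_col]]), ]
  ranking <- ranking[order(-ranking[[stat_col]]), ]
  n_core <- min(n_core, nrow(ranking))
  if (n_core == 0) abort("no differentiated sites available.")
  top <- ranking$site[seq_len(n_core)]
  if (n_core > 1) {
    for (i in seq_len(n_core - 1)) {
      for (j in seq((i + 1), n_core)) {
        r2 <- r_squared(panel$alleles[, top[i]], panel$alleles[, top[j]])
        if (is.na(r2) || r2 <= r2_threshold) {
          abort(sprintf(
            "top-differentiated sites %d and %d (positions %s, %s) have r^2 = %.3f <= %.3f; they do not tag a single haplogroup.",
            top[i], top[j], format(panel$positions[top[i]]),
            format(panel$positions[top[j]]), if (is.na(r2)) NaN else r2,
            r2_threshold))
        }
      }
    }
  }
  core_dosage <- rowSums(panel$alleles[, top, drop = FALSE])
  member <- core_dosage == n_core
  recombinant <- core_dosage >= n_core / 2 & !member & core_dosage > 0
  freq <- tapply(member, panel$pop, mean)
  list(core_sites = tibble(site = top,
                           position = panel$positions[top],
                           differentiation = ranking[[stat_col]][seq_len(n_core)]),
       member = member, recombinant = recombinant,
       freq = freq)
}
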