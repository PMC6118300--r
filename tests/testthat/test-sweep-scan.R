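test_that("random regions are size-matched, in range, and restrictable", {
  expect_equal(nrow(sample_random_regions(1e6, 9000, 0)), 0)
  r <- sample_random_regions(1e6, 9000, 200, seed = 1)
  expect_true(all(r$end - r$start + 1 == 9000))
  expect_true(all(r$start >= 1 & r$end <= 1e6))

  sd_set <- tibble::tibble(start = c(2e5, 6e5), end = c(2.1e5, 6.2e5))
  rr <- sample_random_regions(1e6, 9000, 100, restrict_to = sd_set, seed = 2)
  overlaps <- vapply(seq_len(nrow(rr)), function(i) {
    any(sd_set$start <= rr$end[i] & sd_set$end >= rr$start[i])
  }, logical(1))
  expect_true(all(overlaps))

  bad <- tibble::tibble(start = 2e6, end = 2.1e6)
  expect_error(sample_random_regions(1e6, 9000, 10, restrict_to = bad),
               "cannot be overlapped")
})

test_that("the empirical rank test is calibrated, powerful, and rank-invariant", {
  set.seed(99)
  p_null <- replicate(100, {
    empirical_null_test(rnorm(20), rnorm(200))$p_value
  })
  expect_gte(mean(p_null > 0.05), 0.90)

  shifted <- empirical_null_test(rnorm(20) + 5, rnorm(200))
  expect_lt(shifted$p_value, 0.01)
  expect_gt(shifted$percentile, 99)

  a <- rnorm(15); b <- rnorm(60)
  raw <- empirical_null_test(a, b)
  mono <- empirical_null_test(exp(a), exp(b))  # strictly increasing map
  expect_equal(raw$p_value, mono$p_value)
  expect_equal(raw$percentile, mono$percentile)

  expect_error(empirical_null_test(numeric(0), b), "non-empty")
})

test_that("frequency windows validate and empty windows warn", {
  expect_error(freq_window(0.8, 0.2), "lo <= hi")
  m <- parse_ms_args("ms 20 50 -t 3 -I 2 10 10 2")
  expect_warning(
    nd <- freq_matched_fst_null(m, freq_window(1.1, 1.2), focal_deme = 2,
                                other_deme = 1, seed = 3),
    "no simulated sites matched")
  expect_equal(nrow(nd), 0)
  expect_warning(
    pd <- freq_matched_pi_null(m, freq_window(1.1, 1.2), focal_deme = 2,
                               seed = 3),
    "no simulated sites matched")
  expect_equal(nrow(pd), 0)
})

test_that("matched counts grow linearly in the replicate count", {
  m <- parse_ms_args(paper_fst_cmd)
  w <- freq_window(0.69, 0.70)
  per_rep <- unlist(simulate_coalescent(m, n_reps = 1000, seed = 55,
                                        map = function(r) {
    cf <- colSums(r$alleles[r$deme == 2, , drop = FALSE])
    sum(cf %in% 143:144)
  }))
  s250 <- sum(per_rep[1:250])
  s1000 <- sum(per_rep)
  v <- stats::var(per_rep)
  # 4 * S250 and S1000 share the first 250 replicates; compare the scaled
  # difference to 3 SE of 4*S250 - S1000 = 3*S[1:250] - S[251:1000]
  se <- sqrt(9 * 250 * v + 750 * v)
  expect_lt(abs(4 * s250 - s1000), 3 * se + 1)
})

test_that("pi-null carrier groups deduplicate sites in complete LD", {
  m <- parse_ms_args("ms 40 200 -t 8 -r 1 2000 -I 2 20 20 4")
  w <- freq_window(0.2, 0.8)
  grp <- freq_matched_pi_null(m, w, focal_deme = 2, seed = 12,
                              region_length = 2000)
  per <- freq_matched_pi_null(m, w, focal_deme = 2, seed = 12,
                              region_length = 2000, per_site = TRUE)
  expect_lt(nrow(grp), nrow(per))  # low recombination forces shared carriers
  expect_true(all(grp$value >= 0))
  g <- glance(grp)
  expect_equal(g$n_inputs, 200)
  expect_equal(g$n_matched, nrow(grp))
  expect_match(g$model_command, "-I 2 20 20")
})

test_that("with no recombination identical carrier pairs span the region", {
  m <- parse_ms_args("ms 30 120 -t 1 -r 0 5000 -I 2 15 15 3")
  nd <- roh_null(m, freq_window(0.2, 0.95), focal_deme = 1, other_deme = 2,
                 n_reps = 120, seed = 21, side = "both")
  expect_gt(nrow(nd), 0)
  expect_true(all(nd$value <= 4999))
  # theta is tiny, so many carrier pairs are identical over the whole region
  expect_true(any(nd$value == 4999))
})

test_that("bootstrap homozygote resampling is degenerate, configured, calibrated", {
  # all member haplotypes identical: every construct runs to the region edge
  ident <- matrix(rep(c(1, 0, 1, 0), each = 8), nrow = 8)
  pos <- c(100, 400, 600, 900)
  bs <- bootstrap_homozygotes(ident, pos, core_position = 400,
                              n_individuals = 5, n_boot = 20,
                              region = c(1, 1000), seed = 2)
  expect_true(all(bs$boot_means == 600))

  # analysis defaults mirror the study design: 500 panels of 238 constructs
  expect_equal(formals(bootstrap_homozygotes)$n_individuals, 238)
  expect_equal(formals(bootstrap_homozygotes)$n_boot, 500)

  # when the observed panel is itself a bootstrap draw, its percentile is
  # uniform over seeded trials
  set.seed(42)
  members <- matrix(rbinom(40 * 120, 1, 0.25), nrow = 40)
  members[, 1] <- 1L  # every member carries the core allele
  mpos <- sort(sample(2:9999, 120))
  pcts <- vapply(1:200, function(trial) {
    idx <- sample(40, 2 * 25, replace = TRUE)
    obs <- mean(vapply(seq_len(25), function(k) {
      roh_from_core(members[idx[2 * k - 1], ], members[idx[2 * k], ], mpos,
                    core_position = mpos[1], side = "downstream",
                    region = c(1, 10000))
    }, 1))
    bootstrap_homozygotes(members, mpos, core_position = mpos[1],
                          n_individuals = 25, n_boot = 60,
                          observed_mean = obs, region = c(1, 10000),
                          seed = 1000 + trial)$percentile
  }, 1)
  ks <- suppressWarnings(stats::ks.test(pcts / 100, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("haplogroup identification demands mutually linked top sites", {
  g <- generate_sweep_panel(sweep_panel_spec(seed = 7))
  expect_error(identify_haplogroup(g$panel, r2_threshold = 1.01),
               "do not tag a single haplogroup")

  hg1 <- identify_haplogroup(g$panel, n_core = 1)
  expect_equal(nrow(hg1$core_sites), 1)
  expect_identical(hg1$member,
                   g$panel$alleles[, hg1$core_sites$site] == 1)

  hg <- identify_haplogroup(g$panel)
  expect_gte(mean(hg$member == g$truth$member), 0.95)
  expect_equal(unname(hg$freq["popB"]), 0)
  # core sites sit at the top of the differentiation ranking
  ft <- fst_sites(g$panel, pops = c("popA", "popB"))
  expect_true(all(hg$core_sites$differentiation >=
                    sort(ft$fst[ft$freq_a > ft$freq_b], decreasing = TRUE)[6]))
})

test_that("null-distribution containers carry their provenance", {
  m <- parse_ms_args("ms 20 60 -t 3 -I 2 10 10 2")
  nd <- freq_matched_fst_null(m, freq_window(0.1, 0.9), focal_deme = 2,
                              other_deme = 1, seed = 9)
  g <- glance(nd)
  expect_equal(g$source, "simulated")
  expect_equal(c(g$window_lo, g$window_hi), c(0.1, 0.9))
  expect_equal(g$seed, 9)
  expect_equal(g$n_matched, nrow(nd))
  expect_s3_class(autoplot(nd, observed = 0.5), "ggplot")
})
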