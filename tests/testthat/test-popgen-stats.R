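test_that("nucleotide diversity matches pairwise enumeration", {
  mat <- rbind(c(1, 0), c(1, 0), c(0, 0), c(0, 0))
  res <- nucleotide_diversity(mat[, 1, drop = FALSE], region_length = 10)
  expect_equal(res$pi_region, 4 / 6)
  expect_equal(res$pi_per_site, 4 / 60)

  mono <- matrix(0L, 5, 3)
  expect_equal(nucleotide_diversity(mono)$pi_region, 0)
  expect_error(nucleotide_diversity(mat[1, , drop = FALSE]), "at least 2")

  # SFS identity vs brute-force pairwise on random panels
  set.seed(11)
  for (i in 1:15) {
    m <- matrix(rbinom(8 * 12, 1, runif(1, 0.1, 0.9)), nrow = 8)
    expect_equal(nucleotide_diversity(m)$pi_region, brute_pi(m))
  }
})

test_that("Watterson's estimator follows the harmonic-number form", {
  expect_equal(watterson_theta(0, 10), 0)
  expect_equal(watterson_theta(10, 5), 10 / sum(1 / 1:4))
  expect_equal(watterson_theta(10, 5), 4.8)
  # simulator recovers the input theta
  S <- unlist(simulate_coalescent(parse_ms_args("ms 12 800 -t 6"), seed = 4,
                                  map = function(r) length(r$positions)))
  tw <- vapply(S, watterson_theta, 1, n = 12)
  expect_lt(abs(mean(tw) - 6), 3 * sd(tw) / sqrt(length(tw)))
})

test_that("Tajima's D agrees with an independent textbook evaluation", {
  mono <- matrix(0L, 6, 4)
  r0 <- nucleotide_diversity(mono)
  expect_equal(r0$tajima_d, 0)
  expect_false(r0$tajima_defined)

  set.seed(21)
  for (i in 1:10) {
    m <- matrix(rbinom(6 * 15, 1, 0.3), nrow = 6)
    if (all(colSums(m) %in% c(0, 6))) next
    expect_equal(tajimas_d(m), textbook_tajima(m), tolerance = 1e-12)
  }

  # neutral equilibrium: mean D near zero
  d <- unlist(simulate_coalescent(parse_ms_args("ms 20 500 -t 5"), seed = 31,
                                  map = tajimas_d))
  expect_lt(abs(mean(d)), 0.2)
})

test_that("FST estimators behave at the boundaries and match direct WC84", {
  expect_equal(fst_per_site(20, 20, 0, 30), 1)
  expect_lte(fst_per_site(10, 20, 10, 20), 0)
  expect_true(is.na(fst_per_site(0, 20, 0, 30)))
  expect_true(is.na(fst_per_site(20, 20, 30, 30)))

  set.seed(5)
  for (i in 1:20) {
    n1 <- sample(5:50, 1); n2 <- sample(5:50, 1)
    d1 <- sample(0:n1, 1); d2 <- sample(0:n2, 1)
    if (d1 + d2 == 0 || d1 + d2 == n1 + n2) next
    expect_equal(fst_per_site(d1, n1, d2, n2), wc84_direct(d1, n1, d2, n2))
    # allele-label swap leaves both estimators unchanged
    expect_equal(fst_per_site(d1, n1, d2, n2),
                 fst_per_site(n1 - d1, n1, n2 - d2, n2))
    expect_equal(fst_per_site(d1, n1, d2, n2, estimator = "hudson"),
                 fst_per_site(n1 - d1, n1, n2 - d2, n2, estimator = "hudson"))
  }
})

test_that("mean FST decreases with the island migration rate", {
  mean_fst <- vapply(c(1, 5, 20), function(M) {
    m <- parse_ms_args(sprintf("ms 40 300 -t 5 -I 2 20 20 %g", M))
    vals <- simulate_coalescent(m, seed = 50 + M, map = function(r) {
      cc <- deme_counts(r)
      mean(fst_per_site(cc[1, ], 20, cc[2, ], 20), na.rm = TRUE)
    })
    mean(unlist(vals))
  }, 1)
  expect_true(all(diff(mean_fst) < 0))
})

test_that("r-squared has its textbook values and symmetries", {
  a <- c(1, 1, 0, 0)
  expect_equal(r_squared(a, a), 1)
  # p_A = p_B = 0.5 with p_AB = 0.25: perfect equilibrium
  expect_equal(r_squared(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  b <- c(1, 0, 1, 0)
  expect_equal(r_squared(a, b), r_squared(b, a))
  expect_equal(r_squared(a, b), r_squared(1 - a, b))
  expect_true(is.na(r_squared(a, c(1, 1, 1, 1))))
  expect_error(r_squared(a, c(1, 0)), "length")
})

test_that("carrier diversity restricts pi to derived-allele carriers", {
  mat <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 0, 1), c(0, 1, 1))
  cp <- carrier_pi(mat, site = 1, region_length = 10)
  expect_equal(cp$n_carriers, 3)
  expect_equal(cp$pi_region, brute_pi(mat[1:3, , drop = FALSE]))
  expect_true(is.na(carrier_pi(mat, site = 3, haps = 1:2)$pi_region))
  ident <- rbind(c(1, 0, 1), c(1, 0, 1), c(0, 0, 0))
  expect_equal(carrier_pi(ident, site = 1)$pi_region, 0)
})

test_that("mean divergence from a reference haplotype is a scaled Hamming mean", {
  mat <- rbind(rep(0, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(mean_divergence(mat, haps = 2, reference = 1,
                               region_length = 1000), 0.003)
  expect_equal(mean_divergence(mat, haps = 1, reference = 1,
                               region_length = 1000), 0)
})

test_that("ROH from a core site respects boundaries, sides and monotonicity", {
  pos <- c(1000, 2000, 5000, 7000, 9500)
  h1 <- c(1, 1, 1, 0, 1)
  h2 <- c(1, 1, 1, 1, 1)  # discordant only at 7000
  reg <- c(1, 10000)
  expect_equal(roh_from_core(h1, h2, pos, 2000, "downstream", region = reg),
               5000)
  expect_equal(roh_from_core(h1, h2, pos, 2000, "upstream", region = reg),
               1999)
  expect_equal(roh_from_core(h1, h2, pos, 2000, "both", region = reg), 6999)
  # identical pair: run extends to the region edges
  expect_equal(roh_from_core(h2, h2, pos, 2000, "downstream", region = reg),
               8000)
  # immediately adjacent discordant site bounds the run at its distance
  expect_equal(roh_from_core(h1, h2, pos, 5000, "downstream", region = reg),
               2000)
  expect_error(roh_from_core(h1, h2, pos, 7000, "downstream", region = reg),
               "heterozygous")
  expect_error(roh_from_core(h1, h2, pos, 1234, region = reg), "core position")

  # inserting an extra discordant site between core and boundary never
  # lengthens the run
  set.seed(3)
  for (i in 1:10) {
    extra <- sort(sample(setdiff(seq(2100, 6900, by = 100), pos), 1))
    pos2 <- sort(c(pos, extra))
    k <- match(extra, pos2)
    h1b <- append(h1, 0, after = k - 1)
    h2b <- append(h2, 1, after = k - 1)
    expect_lte(roh_from_core(h1b, h2b, pos2, 2000, "downstream", region = reg),
               roh_from_core(h1, h2, pos, 2000, "downstream", region = reg))
  }
})

test_that("haplotype clustering separates blocks and ignores input order", {
  block <- rbind(matrix(rep(c(1, 1, 1, 0, 0, 0), 5), 5, byrow = TRUE),
                 matrix(rep(c(0, 0, 0, 1, 1, 1), 5), 5, byrow = TRUE))
  cl <- cluster_haplotypes(block)
  expect_equal(length(unique(cl$cut2[1:5])), 1)
  expect_equal(length(unique(cl$cut2[6:10])), 1)
  expect_false(cl$cut2[1] == cl$cut2[6])

  perm <- sample(nrow(block))
  cl2 <- cluster_haplotypes(block[perm, ])
  expect_equal(cl2$cut2[order(perm)][1:5], rep(cl2$cut2[order(perm)][1], 5),
               ignore_attr = TRUE)
})

test_that("deletion imputation reflects how well SNVs tag the variant", {
  # perfectly tagged: site 1 is the deletion
  tag <- cbind(c(1, 1, 0, 0, 1, 0), rbinom(6, 1, 0.5))
  res <- impute_deletion(tag, deletion = tag[, 1])
  expect_equal(res$accuracy, 1)

  # deletion independent of all sites: accuracy near the majority rate
  set.seed(8)
  m <- matrix(rbinom(60 * 30, 1, 0.4), nrow = 60)
  del <- rbinom(60, 1, 0.3)
  res2 <- impute_deletion(m, deletion = del)
  expect_lt(abs(res2$accuracy - max(mean(del), 1 - mean(del))), 0.2)

  expect_error(impute_deletion(m, deletion = rep(1, 60)), "monomorphic")

  # imperfect LD on the synthetic panel keeps accuracy well below 1
  g <- generate_sweep_panel(sweep_panel_spec(seed = 7))
  ina <- g$panel$pop == "popA"
  res3 <- impute_deletion(panel_haps(g$panel, ina))
  expect_lt(res3$accuracy, 0.95)
  expect_gt(res3$accuracy, 0.5)
})

test_that("windowed tracks tile the region and agree with direct windows", {
  g <- generate_sweep_panel(sweep_panel_spec(seed = 7))
  w <- windowed_stats(g$panel, window_size = 3000)
  expect_equal(w$start[1], 1)
  expect_equal(nrow(w), 3)
  expect_true(all(w$end <= 8787))
  direct <- nucleotide_diversity(panel_window(g$panel, from = 3001, to = 6000),
                                 region_length = 3000)
  expect_equal(w$pi_per_site[2], direct$pi_per_site)
  expect_equal(w$tajima_d[2], direct$tajima_d)
})
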