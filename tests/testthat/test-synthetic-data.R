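test_that("generated panels hit the specified structure across seeds", {
  for (s in c(7, 21, 99)) {
    g <- generate_sweep_panel(sweep_panel_spec(seed = s))
    truth <- g$truth
    ina <- g$panel$pop == "popA"
    expect_equal(mean(truth$member[ina]), 0.70, tolerance = 0.03 / 0.70)
    expect_equal(sum(truth$member[!ina]), 0)

    pi_m <- nucleotide_diversity(g$panel, haps = ina & truth$member)$pi_per_site
    pi_n <- nucleotide_diversity(g$panel, haps = ina & !truth$member)$pi_per_site
    expect_lt(abs(pi_m / 1.2e-4 - 1), 0.30)
    expect_lt(abs(pi_n / 7.6e-4 - 1), 0.30)

    r2 <- r_squared(g$panel$deletion[ina], as.integer(truth$member[ina]))
    expect_lt(abs(r2 - 0.47), 0.10)
    expect_equal(mean(g$panel$deletion[ina & truth$member]), 0.91,
                 tolerance = 0.03)

    hg <- identify_haplogroup(g$panel)
    expect_gte(mean(hg$member == truth$member), 0.95)
  }
})

test_that("a zero-frequency haplogroup yields an all-negative panel", {
  g <- generate_sweep_panel(sweep_panel_spec(haplogroup_freq_a = 0, seed = 5))
  expect_equal(sum(g$truth$member), 0)
  expect_equal(length(g$core_positions), 0)
  expect_equal(n_hap(g$panel), 206 + 216)
})

test_that("generation is bit-reproducible for a fixed spec and seed", {
  a <- generate_sweep_panel(sweep_panel_spec(seed = 13))
  b <- generate_sweep_panel(sweep_panel_spec(seed = 13))
  expect_identical(a$panel$alleles, b$panel$alleles)
  expect_identical(a$panel$positions, b$panel$positions)
  expect_identical(a$panel$deletion, b$panel$deletion)
  expect_identical(a$truth, b$truth)
  c <- generate_sweep_panel(sweep_panel_spec(seed = 14))
  expect_false(identical(a$panel$alleles, c$panel$alleles))
})

test_that("an unreachable LD target is rejected with the feasible bound", {
  spec <- sweep_panel_spec(haplogroup_freq_a = 0.9,
                           deletion_given_haplogroup = 0.5,
                           target_r2_deletion = 0.9, seed = 1)
  expect_error(generate_sweep_panel(spec), "maximum attainable r\\^2")
})

test_that("realized diversity tightens on a 10x larger region", {
  g <- generate_sweep_panel(sweep_panel_spec(region_length = 87870, seed = 3))
  ina <- g$panel$pop == "popA"
  pi_m <- nucleotide_diversity(g$panel, haps = ina & g$truth$member)$pi_per_site
  pi_n <- nucleotide_diversity(g$panel, haps = ina & !g$truth$member)$pi_per_site
  expect_lt(abs(pi_m / 1.2e-4 - 1), 0.15)
  expect_lt(abs(pi_n / 7.6e-4 - 1), 0.15)
})

test_that("invalid specifications are refused", {
  expect_error(sweep_panel_spec(haplogroup_freq_a = 1.2), "fractions")
  expect_error(sweep_panel_spec(n_hap_a = 205), "even")
  expect_error(sweep_panel_spec(region_length = 0), "positive")
})

test_that("an upstream hotspot truncates upstream homozygosity", {
  g <- generate_sweep_panel(sweep_panel_spec(
    region_length = 100000, haplogroup_pi = 6.25e-5,
    hotspot = list(position = 25000, intensity = 0.6),
    pi_tolerance = 0.25, seed = 4))
  hg <- identify_haplogroup(g$panel)
  ind <- matrix(seq_len(n_hap(g$panel)), ncol = 2, byrow = TRUE)
  ina <- g$panel$pop == "popA"
  hom <- which(hg$member[ind[, 1]] & hg$member[ind[, 2]] & ina[ind[, 1]])
  core <- hg$core_sites$position[1]
  down <- vapply(hom, function(i) roh_from_core(
    g$panel$alleles[ind[i, 1], ], g$panel$alleles[ind[i, 2], ],
    g$panel$positions, core, "downstream", region = g$panel$region), 1)
  up <- vapply(hom, function(i) roh_from_core(
    g$panel$alleles[ind[i, 1], ], g$panel$alleles[ind[i, 2], ],
    g$panel$positions, core, "upstream", region = g$panel$region), 1)
  expect_gt(mean(down), mean(up))
  # upstream runs rarely cross the hotspot; downstream runs dwarf background
  bg <- which(!hg$member[ind[, 1]] & !hg$member[ind[, 2]] & ina[ind[, 1]])
  if (length(bg) >= 2) {
    bg_pairs <- head(bg, 10)
    down_bg <- vapply(bg_pairs, function(i) {
      h1 <- g$panel$alleles[ind[i, 1], ]; h2 <- g$panel$alleles[ind[i, 2], ]
      diffs <- g$panel$positions[h1 != h2]
      d <- diffs[diffs > core]
      if (length(d)) min(d) - core else g$panel$region$end - core
    }, 1)
    expect_gt(mean(down), mean(down_bg))
  }
})
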