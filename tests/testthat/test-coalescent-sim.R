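test_that("both canonical command lines parse field by field", {
  m1 <- parse_ms_args(paper_fst_cmd)
  expect_equal(m1$n_sam, 422L)
  expect_equal(m1$n_reps, 1000L)
  expect_equal(m1$theta, 91.4)
  expect_equal(m1$rho, 5)
  expect_equal(m1$n_sites, 8787L)
  expect_equal(m1$deme_sizes, c(216L, 206L))
  expect_equal(m1$mig[1, 2], 3.2)
  expect_equal(m1$mig[2, 1], 0)
  expect_equal(m1$size_now, c(1, 0.077))
  expect_equal(nrow(m1$events), 4)
  expect_equal(m1$events$time, c(0.0005, 0.001, 0.00875, 0.0425))
  expect_equal(m1$events$type, c("en", "en", "ej", "en"))

  m2 <- parse_ms_args(paper_roh_cmd)
  expect_equal(m2$deme_sizes, c(206L, 216L))
  expect_equal(m2$theta, 750)
  expect_equal(m2$rho, 200)
  expect_equal(m2$n_sites, 200000L)
  expect_equal(m2$mig, matrix(c(0, 9, 9, 0), 2, 2))  # island rate M/(npop-1)
  expect_equal(nrow(m2$events), 3)

  expect_error(parse_ms_args("./ms 10 1 -q"), "unsupported ms flag '-q'")
  expect_error(parse_ms_args("./ms 10 1 -I 2 4 4"), "sum to 8")
})

test_that("theta = 0 yields no segregating sites", {
  reps <- simulate_coalescent(parse_ms_args("ms 10 5 -t 0"), seed = 1)
  expect_true(all(vapply(reps, function(r) length(r$positions), 1L) == 0))
})

test_that("neutral closed forms hold: E[S], E[pi], and the 1/i SFS", {
  m <- parse_ms_args("ms 10 2000 -t 5")
  n <- 10
  S <- numeric(m$n_reps); piv <- numeric(m$n_reps); sfs <- numeric(n - 1)
  reps <- simulate_coalescent(m, seed = 42, map = function(r) {
    cs <- colSums(r$alleles)
    list(S = length(cs), pi = if (length(cs)) sum(cs * (n - cs)) / choose(n, 2) else 0,
         sfs = tabulate(cs, n - 1))
  })
  S <- vapply(reps, `[[`, 1, "S")
  piv <- vapply(reps, `[[`, 1, "pi")
  sfs <- Reduce(`+`, lapply(reps, `[[`, "sfs"))
  es <- 5 * sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(S) - es), 3 * sd(S) / sqrt(length(S)))
  expect_lt(abs(mean(piv) - 5), 3 * sd(piv) / sqrt(length(piv)))
  # SFS shape: sites within a replicate share one genealogy, so pooled
  # counts are overdispersed relative to a multinomial; test each class
  # mean against theta/i with clustering-robust (across-replicate) SEs
  sfs_mat <- do.call(rbind, lapply(reps, `[[`, "sfs"))
  z <- vapply(seq_len(n - 1), function(i) {
    (mean(sfs_mat[, i]) - 5 / i) / (sd(sfs_mat[, i]) / sqrt(nrow(sfs_mat)))
  }, 1)
  expect_lt(max(abs(z)), 4)

  # recombination must not change the marginal mutation process
  Sr <- unlist(simulate_coalescent(parse_ms_args("ms 10 500 -t 5 -r 10 1000"),
                                   seed = 43,
                                   map = function(r) length(r$positions)))
  expect_lt(abs(mean(Sr) - es), 3 * sd(Sr) / sqrt(length(Sr)))
})

test_that("segregating-site counts match a discrete Wright-Fisher oracle", {
  Sc <- unlist(simulate_coalescent(parse_ms_args("ms 5 5000 -t 2"), seed = 9,
                                   map = function(r) length(r$positions)))
  Sw <- haplosweep:::wf_seg_sites_cpp(5L, 2, 1000L, 5000L, 10)
  ks <- suppressWarnings(stats::ks.test(Sc, Sw))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulation is reproducible and sites are proper polymorphisms", {
  m <- parse_ms_args("ms 12 5 -t 4 -r 3 1000 -I 2 6 6 2")
  a <- simulate_coalescent(m, seed = 77)
  b <- simulate_coalescent(m, seed = 77)
  expect_identical(lapply(a, `[[`, "alleles"), lapply(b, `[[`, "alleles"))
  expect_identical(lapply(a, `[[`, "positions"), lapply(b, `[[`, "positions"))
  d <- simulate_coalescent(m, seed = 78)
  expect_false(identical(lapply(a, `[[`, "positions"),
                         lapply(d, `[[`, "positions")))
  for (r in a) {
    expect_true(all(diff(r$positions) >= 0))
    cs <- colSums(r$alleles)
    expect_true(all(cs >= 1 & cs <= nrow(r$alleles) - 1))
    expect_equal(r$deme, rep(1:2, each = 6))
  }
})

test_that("deme frequencies enumerate correctly and are exchangeable", {
  rep <- haplosweep:::new_sim_replicate(
    positions = c(0.1, 0.5, 0.9),
    alleles = rbind(c(1, 0, 1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 0)),
    deme_sizes = c(2L, 2L))
  expect_equal(subpop_frequency(rep, 1, 1), 1)
  expect_equal(subpop_frequency(rep, 2, 1), 0)
  expect_equal(subpop_frequency(rep, 2, 2), 0.5)
  expect_equal(subpop_frequency(rep, 1, 3), 0.5)
  expect_error(subpop_frequency(rep, 3, 1), "deme 3")
  expect_equal(deme_counts(rep), rbind(`1` = c(2L, 0L, 1L),
                                       `2` = c(0L, 1L, 0L)))

  # permuting haplotypes within a deme leaves all frequency statistics as is
  perm <- rep
  perm$alleles <- perm$alleles[c(2, 1, 4, 3), ]
  expect_equal(deme_counts(perm), deme_counts(rep))
})

test_that("models that can never coalesce fail loudly", {
  m <- parse_ms_args("ms 4 1 -t 1 -I 2 2 2")  # isolated demes, no join
  expect_error(simulate_coalescent(m, seed = 1), "isolated demes")
})
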