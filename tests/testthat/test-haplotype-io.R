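test_that("region arithmetic follows the 1-based fully-closed convention", {
  expect_equal(region_length(parse_region("chr1:110246810-110255596")), 8787)
  expect_equal(region_length(parse_region("chr1:110211681-110223007")), 11327)
  expect_equal(region_length(gregion("chr1", 5, 5)), 1)
  expect_error(parse_region("chr1:10"), "cannot parse")
  expect_error(gregion("chr1", 10, 5), "invalid region")
})

test_that("region tables honour both coordinate conventions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t199\tr1", "chr1\t500\t599\tr2"), path)
  closed <- read_region_table(path)
  expect_equal(closed$start, c(100, 500))
  bed <- read_region_table(path, bed_standard = TRUE)
  expect_equal(bed$start, c(101, 501))  # 0-based start shifts up
  expect_equal(bed$end, closed$end)     # half-open end is already closed
})

test_that("fractional positions map to strictly increasing base pairs", {
  bp <- positions_to_bp(c(0.1, 0.10001, 0.100011, 0.5), 1000)
  expect_true(all(diff(bp) > 0))
  expect_equal(bp[1], 101)
  expect_equal(bp[4], 501)
  expect_error(positions_to_bp(c(0.5, 0.1), 1000), "non-decreasing")
  expect_error(positions_to_bp(seq(0, 0.001, length.out = 10), 5), "overflow")
})

test_that("ms text parses, rejects malformed rows, and round-trips", {
  txt <- c("ms 4 2 -t 1", "1 2 3", "", "//", "segsites: 3",
           "positions: 0.10 0.45 0.80",
           "101", "010", "000", "111", "", "//", "segsites: 0", "")
  reps <- read_ms_output(txt)
  expect_length(reps, 2)
  expect_equal(dim(reps[[1]]$alleles), c(4, 3))
  expect_equal(reps[[1]]$positions, c(0.10, 0.45, 0.80))
  expect_equal(reps[[1]]$alleles[1, ], c(1L, 0L, 1L))
  expect_equal(ncol(reps[[2]]$alleles), 0)

  bad <- c("//", "segsites: 3", "positions: 0.1 0.2 0.3", "10", "010")
  expect_error(read_ms_output(bad), "replicate 1")

  expect_identical(read_ms_output(write_ms_output(reps))[[1]]$alleles,
                   reps[[1]]$alleles)

  sims <- simulate_coalescent(parse_ms_args("ms 6 3 -t 3"), seed = 5)
  back <- read_ms_output(write_ms_output(sims))
  for (i in seq_along(sims)) {
    expect_identical(back[[i]]$alleles, sims[[i]]$alleles)
    expect_equal(back[[i]]$positions, round(sims[[i]]$positions, 8),
                 tolerance = 1e-7)
  }
})

test_that("phased VCF round-trips a synthetic panel exactly", {
  g <- generate_sweep_panel(sweep_panel_spec(seed = 7))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(g$panel, path)
  back <- read_phased_vcf(path, region = g$panel$region)
  expect_identical(back$alleles, g$panel$alleles)
  expect_equal(back$positions, g$panel$positions)
  expect_identical(back$deletion, g$panel$deletion)
  expect_identical(back$pop, g$panel$pop)
  expect_equal(attr(back, "skipped"), 0)
})

test_that("written VCF is accepted by an independent validator", {
  g <- generate_sweep_panel(sweep_panel_spec(seed = 7))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(g$panel, path)
  n_rec <- system2("bcftools", c("view", "-H", path), stdout = TRUE,
                   stderr = FALSE)
  expect_equal(length(n_rec), n_sites(g$panel) + 1)  # SNVs + <DEL>
})

test_that("VCF edge cases: deletion-only panels, skips, regions, phasing", {
  # a panel with zero SNVs still writes its <DEL> record
  p0 <- hap_panel(matrix(integer(0), nrow = 4, ncol = 0), numeric(0),
                  region = gregion("chr1", 1, 1000),
                  pop = rep("popA", 4), deletion = c(1L, 0L, 1L, 0L),
                  deletion_pos = 300)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(p0, path)
  back <- read_phased_vcf(path, region = p0$region)
  expect_equal(n_sites(back), 0)
  expect_identical(back$deletion, p0$deletion)

  # multi-allelic record is skipped with a count
  lines <- readLines(path)
  tri <- "chr1\t400\ttri\tA\tG,T\t.\tPASS\t.\tGT\t0|1\t0|0"
  writeLines(append(lines, tri, after = length(lines)), path)
  back2 <- read_phased_vcf(path)
  expect_equal(attr(back2, "skipped"), 1)
  expect_equal(n_sites(back2), 0)

  # a window with no records is an empty panel, not an error
  g <- generate_sweep_panel(sweep_panel_spec(seed = 7))
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(g$panel, path2)
  empty <- read_phased_vcf(path2, region = gregion("chr1", 2, 3))
  expect_equal(n_sites(empty), 0)
  expect_equal(n_hap(empty), n_hap(g$panel))

  # unphased genotypes are refused, naming the sample and site
  lines2 <- readLines(path2)
  lines2 <- sub("(snv1\t.*GT\t)([01])\\|", "\\1\\2/", lines2)
  writeLines(lines2, path2)
  expect_error(read_phased_vcf(path2), "unphased genotype for sample S0001")
})

test_that("panel concatenation preserves haplotypes and adds sites", {
  g <- generate_sweep_panel(sweep_panel_spec(seed = 3))
  left <- panel_window(g$panel, from = 1, to = 4000)
  right <- panel_window(g$panel, from = 4001, to = 8787)
  both <- concat_panels(left, right)
  expect_equal(n_sites(both), n_sites(left) + n_sites(right))
  expect_identical(both$alleles, g$panel$alleles)

  empty <- panel_window(g$panel, from = 2, to = 3)
  expect_identical(concat_panels(g$panel, empty)$alleles, g$panel$alleles)

  other <- panel_haps(right, c(2:n_hap(right), 1))
  expect_error(concat_panels(left, other), "same haplotypes")
  expect_error(concat_panels(left, left), "overlap")
})
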