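# Independent oracles and tiny fixture builders shared across the suite.
# Each oracle is written directly from the published formula or by brute
# force, without reusing package internals.

# mean pairwise Hamming distance, enumerated over all pairs
brute_pi <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) tot <- tot + sum(mat[i, ] != mat[j, ])
  }
  tot / choose(n, 2)
}

# Tajima (1989) D, re-derived from the coefficient chain
textbook_tajima <- function(mat) {
  n <- nrow(mat)
  cs <- colSums(mat)
  seg <- cs > 0 & cs < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi <- brute_pi(mat[, seg, drop = FALSE])
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# Weir & Cockerham (1984) theta-hat for haploid counts, two demes, scalar
wc84_direct <- function(d1, n1, d2, n2) {
  p1 <- d1 / n1; p2 <- d2 / n2
  pbar <- (d1 + d2) / (n1 + n2)
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 + n2 - 2)
  (msp - msg) / (msp + (nc - 1) * msg)
}

# small deterministic two-population panel
toy_panel <- function() {
  alleles <- rbind(
    c(1, 0, 1, 0, 0),
    c(1, 0, 1, 0, 1),
    c(0, 1, 0, 0, 0),
    c(0, 1, 0, 1, 0),
    c(0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 1))
  hap_panel(alleles, positions = c(100, 250, 400, 700, 950),
            region = gregion("chr1", 1, 1000),
            pop = c("popA", "popA", "popA", "popA", "popB", "popB"),
            deletion = c(1L, 1L, 0L, 0L, 0L, 1L), deletion_pos = 500)
}

paper_fst_cmd <- paste(
  "./ms 422 1000 -t 91.4 -I 2 216 206 -m 1 2 3.2 -n 2 0.077",
  "-en 0.0005 1 0.25 -en 0.001 2 0.077 -ej 0.00875 2 1",
  "-en 0.0425 1 0.125 -r 5 8787")

paper_roh_cmd <- paste(
  "./ms 422 1000 -t 750 -r 200 200000 -I 2 206 216 9",
  "-en 0.0005 2 0.25 -en 0.001 1 0.077 -en 0.0425 2 0.125")
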