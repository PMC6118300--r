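#' Phased haplotype panels
#'
#' A `hap_panel` holds a phased binary haplotype matrix (haplotypes x
#' segregating sites; 0 = reference/ancestral, 1 = alternative/derived)
#' together with physical positions, a population label, a sample identifier
#' and haplotype index (0/1 within the diploid) per haplotype, and an
#' optional per-haplotype deletion status for a linked structural variant.
#' Consecutive haplotype pairs `2i-1, 2i` of one sample form a diploid
#' individual.
#'
#' @param alleles Integer 0/1 matrix, haplotypes in rows, sites in columns.
#' @param positions Strictly increasing 1-based bp positions, one per column.
#' @param chrom Chromosome name.
#' @param region Optional [gregion()] giving the panel's span; defaults to
#'   `[1, max(positions)]`.
#' @param pop Population label per haplotype.
#' @param sample_id Sample identifier per haplotype; defaults to pairing
#'   consecutive haplotypes.
#' @param hap_index 0/1 haplotype index within each sample.
#' @param deletion Optional 0/1 vector: does this haplotype carry the
#'   deletion allele?
#' @param deletion_pos Optional bp position of the deletion (used when the
#'   panel is written to VCF).
#' @return A `hap_panel` object.
#' @export
hap_panel <- function(alleles, positions, chrom = "chr1", region = NULL,
                      pop, sample_id = NULL, hap_index = NULL,
                      deletion = NULL, deletion_pos = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n <- nrow(alleles)
  if (ncol(alleles) != length(positions)) {
    abort("`positions` must have one entry per allele-matrix column.")
  }
  if (length(positions) && any(diff(positions) <= 0)) {
    abort("positions must be strictly increasing.")
  }
  if (length(alleles) && !all(alleles %in% c(0L, 1L))) {
    abort("allele matrix entries must be 0 or 1.")
  }
  if (length(pop) != n) abort("`pop` must have one label per haplotype.")
  if (is.null(sample_id)) {
    if (n %% 2 != 0) abort("odd haplotype count needs explicit `sample_id`.")
    sample_id <- rep(sprintf("S%04d", seq_len(n / 2)), each = 2)
  }
  if (is.null(hap_index)) hap_index <- rep(c(0L, 1L), length.out = n)
  if (!is.null(deletion) && length(deletion) != n) {
    abort("`deletion` must have one entry per haplotype.")
  }
  if (is.null(region)) {
    region <- gregion(chrom, 1, max(c(positions, 1, deletion_pos)))
  }
  structure(
    list(alleles = alleles, positions = as.numeric(positions),
         chrom = chrom, region = region, pop = as.character(pop),
         sample_id = as.character(sample_id),
         hap_index = as.integer(hap_index),
         deletion = if (is.null(deletion)) NULL else as.integer(deletion),
         deletion_pos = deletion_pos),
    class = "hap_panel"
  )
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %d haplotypes x %d sites on %s:%d-%d\n",
              n_hap(x), n_sites(x), x$chrom, as.integer(x$region$start),
              as.integer(x$region$end)))
  tab <- table(x$pop)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  if (!is.null(x$deletion)) {
    cat(sprintf("  deletion allele: %d/%d haplotypes carry it\n",
                sum(x$deletion), n_hap(x)))
  }
  invisible(x)
}

#' Number of haplotypes / sites in a panel
#' @param panel A [hap_panel()].
#' @return An integer count.
#' @export
n_hap <- function(panel) nrow(panel$alleles)

#' @rdname n_hap
#' @export
n_sites <- function(panel) ncol(panel$alleles)

#' Subset a panel
#'
#' `panel_haps()` keeps a subset of haplotypes (all sites, including now
#' monomorphic ones, are retained so positions stay comparable across
#' subsets). `panel_window()` keeps the sites falling inside a region or
#' between two bp bounds.
#'
#' @param panel A [hap_panel()].
#' @param haps Logical or integer index of haplotypes to keep.
#' @return A new `hap_panel`.
#' @export
panel_haps <- function(panel, haps) {
  hap_panel(panel$alleles[haps, , drop = FALSE], panel$positions,
            chrom = panel$chrom, region = panel$region,
            pop = panel$pop[haps], sample_id = panel$sample_id[haps],
            hap_index = panel$hap_index[haps],
            deletion = if (is.null(panel$deletion)) NULL else panel$deletion[haps],
            deletion_pos = panel$deletion_pos)
}

#' @rdname panel_haps
#' @param region A [gregion()] (its `chrom` is ignored for matching), or
#'   `NULL` to use `from`/`to`.
#' @param from,to Inclusive bp bounds used when `region` is `NULL`.
#' @export
panel_window <- function(panel, region = NULL, from = NULL, to = NULL) {
  if (!is.null(region)) {
    from <- region$start
    to <- region$end
  } else {
    region <- gregion(panel$chrom, from, to)
  }
  keep <- panel$positions >= from & panel$positions <= to
  hap_panel(panel$alleles[, keep, drop = FALSE], panel$positions[keep],
            chrom = panel$chrom, region = region, pop = panel$pop,
            sample_id = panel$sample_id, hap_index = panel$hap_index,
            deletion = panel$deletion, deletion_pos = panel$deletion_pos)
}

#' Concatenate two region panels over the same haplotypes
#'
#' Used to analyse a combined two-target region (for example an upstream and
#' a downstream flank of a structural variant) as one haplotype alignment.
#' Both panels must contain the same haplotypes in the same order; sites are
#' concatenated with their original physical positions preserved.
#'
#' @param panel_a,panel_b Panels sharing haplotypes (same `sample_id`,
#'   `hap_index`, `pop` vectors).
#' @return A `hap_panel` spanning both regions.
#' @export
concat_panels <- function(panel_a, panel_b) {
  same <- identical(panel_a$sample_id, panel_b$sample_id) &&
    identical(panel_a$hap_index, panel_b$hap_index) &&
    identical(panel_a$pop, panel_b$pop)
  if (!same) abort("panels do not contain the same haplotypes in the same order.")
  if (n_sites(panel_b) == 0) return(panel_a)
  if (n_sites(panel_a) == 0) return(panel_b)
  if (max(panel_a$positions) >= min(panel_b$positions)) {
    abort("panel regions overlap; concat expects disjoint, ordered regions.")
  }
  region <- gregion(panel_a$chrom, min(panel_a$region$start, panel_b$region$start),
                    max(panel_a$region$end, panel_b$region$end))
  hap_panel(cbind(panel_a$alleles, panel_b$alleles),
            c(panel_a$positions, panel_b$positions),
            chrom = panel_a$chrom, region = region, pop = panel_a$pop,
            sample_id = panel_a$sample_id, hap_index = panel_a$hap_index,
            deletion = panel_a$deletion,
            deletion_pos = panel_a$deletion_pos %||% panel_b$deletion_pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Panel summary as a tibble
#'
#' One row per haplotype with population, sample, haplotype index and (if
#' present) deletion status — convenient for joining against statistics.
#'
#' @param x A [hap_panel()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hap_panel <- function(x, ...) {
  tibble(haplotype = seq_len(n_hap(x)), sample_id = x$sample_id,
         hap_index = x$hap_index, pop = x$pop,
         deletion = if (is.null(x$deletion)) NA_integer_ else x$deletion)
}
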