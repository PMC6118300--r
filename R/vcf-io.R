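#' Write a haplotype panel as a phased VCF
#'
#' Emits a plain-text VCF 4.2 with one biallelic SNV record per segregating
#' site (A/G alleles, phased `GT` with the `|` separator) and, when the
#' panel carries deletion status, one symbolic `<DEL>` record with an `END`
#' INFO key. Reading the file back with [read_phased_vcf()] reproduces the
#' panel exactly, and a population map sidecar (`<path>.pops`) is written
#' so the labels survive the round trip.
#'
#' @param panel A [hap_panel()] with an even number of haplotypes per
#'   sample (consecutive pairs form diploids).
#' @param path Output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_fixture_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "hap_panel"))
  if (n_hap(panel) == 0) abort("cannot write an empty panel.")
  samples <- unique(panel$sample_id)
  idx1 <- match(samples, panel$sample_id)           # hap_index 0
  idx2 <- idx1 + 1L                                  # hap_index 1
  if (!all(panel$sample_id[idx2] == samples)) {
    abort("haplotypes of each sample must be adjacent (phased pairs).")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", panel$chrom,
            as.integer(max(panel$region$end, panel$positions, panel$deletion_pos %||% 0))),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_field <- function(a1, a2) paste0(a1, "|", a2)
  records <- character(0)
  pos_all <- panel$positions
  del_pos <- panel$deletion_pos
  make_snv <- function(j) {
    gts <- gt_field(panel$alleles[idx1, j], panel$alleles[idx2, j])
    paste(c(panel$chrom, format(pos_all[j], scientific = FALSE),
            sprintf("snv%d", j), "A", "G", ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }
  make_del <- function() {
    gts <- gt_field(panel$deletion[idx1], panel$deletion[idx2])
    end_pos <- as.integer(del_pos + 1)
    paste(c(panel$chrom, format(as.integer(del_pos), scientific = FALSE),
            "sv_del", "N", "<DEL>", ".", "PASS",
            sprintf("END=%d;SVTYPE=DEL", end_pos), "GT", gts),
          collapse = "\t")
  }
  j <- 1
  n_snv <- length(pos_all)
  emitted_del <- is.null(panel$deletion) || is.null(del_pos)
  while (j <= n_snv || !emitted_del) {
    if (!emitted_del && (j > n_snv || del_pos < pos_all[j])) {
      records <- c(records, make_del())
      emitted_del <- TRUE
    } else {
      records <- c(records, make_snv(j))
      j <- j + 1
    }
  }
  writeLines(c(header, records), path)
  writeLines(paste(samples,
                   panel$pop[idx1], sep = "\t"),
             paste0(path, ".pops"))
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#'
#' Biallelic SNV records become columns of the allele matrix (0 =
#' reference, 1 = alternative); a symbolic `<DEL>` record is routed to the
#' per-haplotype `deletion` field rather than the matrix. Multi-allelic and
#' non-SNV, non-DEL records are skipped with a count. All genotypes must be
#' phased (`|`); an unphased genotype raises an error naming the sample and
#' site. Parsing is delegated to \pkg{vcfR}.
#'
#' @param path VCF file path.
#' @param region Optional [gregion()]; only records inside it are kept.
#'   A region spanning no records yields a 0-site panel, not an error.
#' @param populations Named assignment of samples to populations: a tibble
#'   or data.frame with columns `sample` and `pop`, a named vector, or
#'   `NULL` to read the `<path>.pops` sidecar (falling back to a single
#'   population "pop1").
#' @return A list-free [hap_panel()]; the number of skipped records is
#'   attached as `attr(panel, "skipped")`.
#' @export
read_phased_vcf <- function(path, region = NULL, populations = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt[, -1, drop = FALSE]
  samples <- colnames(gt)
  pos <- as.numeric(fix$POS)
  keep_region <- if (is.null(region)) rep(TRUE, nrow(fix)) else {
    pos >= region$start & pos <= region$end
  }
  is_del <- fix$ALT == "<DEL>"
  is_snv <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$ALT != "<DEL>"
  skipped <- sum(keep_region & !is_snv & !is_del)
  split_gt <- function(rows) {
    g <- gt[rows, , drop = FALSE]
    n_rec <- nrow(g)
    h1 <- matrix(0L, n_rec, length(samples))
    h2 <- matrix(0L, n_rec, length(samples))
    for (r in seq_len(n_rec)) {
      fields <- sub(":.*$", "", g[r, ])
      bad <- grepl("/", fields, fixed = TRUE) | !grepl("|", fields, fixed = TRUE)
      if (any(bad)) {
        abort(sprintf("unphased genotype for sample %s at %s:%s",
                      samples[which(bad)[1]], fix$CHROM[rows[r]],
                      fix$POS[rows[r]]))
      }
      parts <- strsplit(fields, "|", fixed = TRUE)
      h1[r, ] <- as.integer(vapply(parts, `[`, "", 1))
      h2[r, ] <- as.integer(vapply(parts, `[`, "", 2))
    }
    list(h1 = h1, h2 = h2)
  }
  snv_rows <- which(keep_region & is_snv)
  g <- split_gt(snv_rows)
  n_hap_total <- 2 * length(samples)
  alleles <- matrix(0L, n_hap_total, length(snv_rows))
  alleles[seq(1, n_hap_total, by = 2), ] <- t(g$h1)
  alleles[seq(2, n_hap_total, by = 2), ] <- t(g$h2)
  deletion <- NULL
  deletion_pos <- NULL
  del_rows <- which(keep_region & is_del)
  if (length(del_rows) >= 1) {
    if (length(del_rows) > 1) {
      warn("multiple <DEL> records; using the first.")
      del_rows <- del_rows[1]
    }
    gd <- split_gt(del_rows)
    deletion <- integer(n_hap_total)
    deletion[seq(1, n_hap_total, by = 2)] <- gd$h1[1, ]
    deletion[seq(2, n_hap_total, by = 2)] <- gd$h2[1, ]
    deletion_pos <- pos[del_rows]
  }
  pop_map <- resolve_populations(populations, path, samples)
  chrom <- if (nrow(fix)) fix$CHROM[1] else "chr1"
  panel_region <- region %||% gregion(chrom, 1,
                                      max(c(pos[keep_region], 1), na.rm = TRUE))
  panel <- hap_panel(alleles, pos[snv_rows], chrom = chrom,
                     region = panel_region,
                     pop = rep(pop_map[samples], each = 2),
                     sample_id = rep(samples, each = 2),
                     hap_index = rep(c(0L, 1L), length(samples)),
                     deletion = deletion, deletion_pos = deletion_pos)
  attr(panel, "skipped") <- skipped
  panel
}

resolve_populations <- function(populations, path, samples) {
  if (is.data.frame(populations)) {
    return(setNames(as.character(populations$pop),
                    as.character(populations$sample)))
  }
  if (!is.null(populations)) return(populations)
  sidecar <- paste0(path, ".pops")
  if (file.exists(sidecar)) {
    df <- utils::read.table(sidecar, sep = "\t", stringsAsFactors = FALSE)
    return(setNames(df[[2]], df[[1]]))
  }
  setNames(rep("pop1", length(samples)), samples)
}
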