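#' Genomic regions (1-based, fully closed)
#'
#' A `gregion` is a minimal genomic interval record. Coordinates are 1-based
#' and fully closed on both ends, so a region printed as
#' `chr1:110246810-110255596` has length `end - start + 1` = 8,787 bp. This
#' is the convention used throughout the package; the only conversion to
#' 0-based half-open coordinates happens in [read_region_table()] when a
#' BED-standard file is read.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param name Optional region label.
#' @return A `gregion` object.
#' @examples
#' region_length(gregion("chr1", 110246810, 110255596))  # 8787
#' @export
gregion <- function(chrom, start, end, name = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) != 1 || length(start) != 1 || length(end) != 1) {
    abort("`chrom`, `start` and `end` must be scalars.")
  }
  if (is.na(start) || is.na(end) || start < 1 || end < start) {
    abort("invalid region: need 1 <= start <= end.")
  }
  structure(
    list(chrom = as.character(chrom), start = start, end = end,
         name = if (is.null(name)) NA_character_ else as.character(name)),
    class = "gregion"
  )
}

#' @export
print.gregion <- function(x, ...) {
  cat(sprintf("<gregion> %s:%s-%s (%s bp)%s\n", x$chrom,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              format(region_length(x), big.mark = ","),
              if (is.na(x$name)) "" else paste0(" [", x$name, "]")))
  invisible(x)
}

#' Parse a region string such as "chr1:110246810-110255596"
#'
#' @param x A character vector of `chrom:start-end` strings (commas in
#'   numbers are tolerated).
#' @return A `gregion` for a single string, otherwise a list of them.
#' @export
parse_region <- function(x) {
  parse1 <- function(s) {
    s <- gsub(",", "", s, fixed = TRUE)
    m <- regmatches(s, regexec("^([^:]+):([0-9]+)-([0-9]+)$", s))[[1]]
    if (length(m) != 4) abort(sprintf("cannot parse region string '%s'", s))
    gregion(m[2], as.numeric(m[3]), as.numeric(m[4]))
  }
  if (length(x) == 1) parse1(x) else lapply(x, parse1)
}

#' Length of a region in base pairs
#'
#' Under the 1-based fully-closed convention the length is
#' `end - start + 1`.
#'
#' @param region A [gregion()].
#' @return Length in bp.
#' @export
region_length <- function(region) {
  stopifnot(inherits(region, "gregion"))
  region$end - region$start + 1
}

#' Read a region list from a tab-separated file
#'
#' The file has columns chrom, start, end and optionally name. By default
#' coordinates are interpreted as 1-based fully closed (the convention used
#' by this package, which diverges from BED proper); set
#' `bed_standard = TRUE` for 0-based half-open BED input, which is converted
#' on read.
#'
#' @param path File path.
#' @param bed_standard Interpret coordinates as standard BED (0-based,
#'   half-open)?
#' @return A tibble with columns `chrom`, `start`, `end`, `name` in the
#'   package's 1-based closed convention.
#' @export
read_region_table <- function(path, bed_standard = FALSE) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name" else df$name <- NA_character_
  df <- df[, c("chrom", "start", "end", "name")]
  if (bed_standard) df$start <- df$start + 1  # half-open end is already closed
  as_tibble(df)
}

#' Map fractional simulator positions to base-pair coordinates
#'
#' Simulated variant positions live on the unit interval; downstream
#' run-of-homozygosity statistics need physical distances. Positions are
#' mapped as `floor(pos * region_length) + 1` and ties are broken by bumping
#' a colliding position to the next free base pair, preserving strict order.
#'
#' @param pos Numeric vector of non-decreasing fractional positions in
#'   `[0, 1)`.
#' @param region_length Region length in bp.
#' @return Integer vector of strictly increasing 1-based positions.
#' @export
positions_to_bp <- function(pos, region_length) {
  if (length(pos) == 0) return(integer(0))
  if (is.unsorted(pos)) abort("fractional positions must be non-decreasing")
  bp <- floor(pos * region_length) + 1
  for (i in seq_along(bp)[-1]) {
    if (bp[i] <= bp[i - 1]) bp[i] <- bp[i - 1] + 1
  }
  if (bp[length(bp)] > region_length) {
    abort("position collisions overflow the region; more sites than base pairs")
  }
  as.integer(bp)
}
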