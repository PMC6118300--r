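#' Read and write ms-dialect simulation output
#'
#' The ms dialect is the plain-text interchange format of Hudson-style
#' coalescent simulators: replicates are introduced by a `//` line followed
#' by `segsites: <S>`, a `positions: ...` line of fractional coordinates,
#' and one 0/1 row per haplotype (1 = derived). `read_ms_output()` parses
#' text (or a file) into a list of `sim_replicate` objects;
#' `write_ms_output()` does the inverse, so `write(read(x))` round-trips
#' well-formed input up to numeric printing precision.
#'
#' @param text Character scalar of ms output, a character vector of lines,
#'   or a path to a file.
#' @param deme_sizes Optional integer vector assigning the first
#'   `deme_sizes[1]` rows to deme 1 and so on (as with `ms -I`).
#' @return A list of `sim_replicate` objects: each has `positions`
#'   (fractional, non-decreasing), `alleles` (haplotype x site 0/1 matrix)
#'   and `deme` (integer label per haplotype).
#' @export
read_ms_output <- function(text, deme_sizes = NULL) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text)
  } else if (length(text) == 1) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  starts <- which(trimws(lines) == "//" | startsWith(trimws(lines), "// "))
  if (length(starts) == 0) abort("no `//` replicate blocks found in ms text.")
  bounds <- c(starts, length(lines) + 1L)
  reps <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[(bounds[b] + 1L):(bounds[b + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    segline <- grep("^segsites:", block, value = TRUE)
    if (length(segline) != 1) {
      abort(sprintf("replicate %d: missing or duplicated `segsites:` line.", b))
    }
    S <- as.integer(sub("^segsites:\\s*", "", segline))
    if (S == 0) {
      reps[[b]] <- new_sim_replicate(numeric(0),
                                     matrix(integer(0), nrow = 0, ncol = 0),
                                     deme_sizes)
      next
    }
    posline <- grep("^positions:", block, value = TRUE)
    if (length(posline) != 1) {
      abort(sprintf("replicate %d: missing `positions:` line.", b))
    }
    pos <- as.numeric(strsplit(trimws(sub("^positions:", "", posline)),
                               "\\s+")[[1]])
    if (length(pos) != S) {
      abort(sprintf("replicate %d: %d positions for segsites %d.",
                    b, length(pos), S))
    }
    rows <- block[grepl("^[01]+$", block)]
    if (length(rows) == 0) abort(sprintf("replicate %d: no haplotype rows.", b))
    if (any(nchar(rows) != S)) {
      abort(sprintf("replicate %d: haplotype row length differs from segsites (%d).",
                    b, S))
    }
    mat <- matrix(as.integer(unlist(strsplit(rows, "", fixed = TRUE))),
                  nrow = length(rows), byrow = TRUE)
    reps[[b]] <- new_sim_replicate(pos, mat, deme_sizes)
  }
  reps
}

new_sim_replicate <- function(positions, alleles, deme_sizes = NULL,
                              seed = NA_integer_) {
  n <- nrow(alleles)
  deme <- if (is.null(deme_sizes)) rep(1L, n) else rep(seq_along(deme_sizes),
                                                       times = deme_sizes)
  if (length(deme) != n && n > 0) {
    abort("deme sizes do not sum to the haplotype count.")
  }
  structure(list(positions = positions, alleles = alleles,
                 deme = deme[seq_len(n)], seed = seed),
            class = "sim_replicate")
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat(sprintf("<sim_replicate> %d haplotypes, %d segregating sites, %d deme(s)\n",
              nrow(x$alleles), length(x$positions),
              length(unique(x$deme))))
  invisible(x)
}

#' @rdname read_ms_output
#' @param replicates A list of `sim_replicate` objects (or a single one).
#' @param path Optional file path; when given, text is written there.
#' @param digits Printing precision for positions.
#' @return `write_ms_output()`: the character vector of lines (invisibly
#'   when `path` is given).
#' @export
write_ms_output <- function(replicates, path = NULL, digits = 8) {
  if (inherits(replicates, "sim_replicate")) replicates <- list(replicates)
  out <- character(0)
  for (rep in replicates) {
    S <- length(rep$positions)
    out <- c(out, "//", paste0("segsites: ", S))
    if (S > 0) {
      out <- c(out,
               paste0("positions: ",
                      paste(formatC(rep$positions, digits = digits,
                                    format = "f"), collapse = " ")),
               apply(rep$alleles, 1, paste, collapse = ""))
    }
    out <- c(out, "")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
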