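#' Parse an ms command line into a demographic model
#'
#' Supports exactly the flag subset needed for Hudson-style neutral null
#' models of a two-deme split with bottlenecks and migration:
#' `-t` (theta = 4*N0*mu per region), `-r rho nsites` (rho = 4*N0*r per
#' region), `-I npop n1 n2 ... [M]` (island migration at rate
#' `M/(npop-1)` between every pair), `-m i j x` (single entry of the
#' migration matrix, backwards rate of lineages moving i -> j), `-n i x`
#' (present relative size of deme i), `-en t i x` (deme size change at time
#' t, in units of 4*N0 generations) and `-ej t i j` (all deme-i lineages
#' join deme j at time t; migration into the vanished deme is switched
#' off). Any other flag is rejected. Deme indices are 1-based on the
#' command line, as in ms.
#'
#' @param command An ms command string, e.g.
#'   `"./ms 422 1000 -t 91.4 -I 2 216 206 -m 1 2 3.2 ..."`. The leading
#'   program token is optional.
#' @return A `demographic_model` object with elements `n_sam`, `n_reps`,
#'   `theta`, `rho`, `n_sites`, `npop`, `deme_sizes`, `mig` (npop x npop
#'   matrix), `size_now`, `events` (tibble with `time`, `type`, `deme`,
#'   `x`) and the original `command` string.
#' @examples
#' m <- parse_ms_args("./ms 422 1000 -t 91.4 -I 2 216 206 -m 1 2 3.2 -n 2 0.077
#'   -en 0.0005 1 0.25 -en 0.001 2 0.077 -ej 0.00875 2 1 -en 0.0425 1 0.125
#'   -r 5 8787")
#' m$theta
#' @export
parse_ms_args <- function(command) {
  tok <- strsplit(trimws(gsub("\\s+", " ", command)), " ")[[1]]
  tok <- tok[nzchar(tok)]
  if (length(tok) && grepl("ms$", tok[1]) && is.na(suppressWarnings(as.numeric(tok[1])))) {
    tok <- tok[-1]
  }
  if (length(tok) < 2) abort("command must start with `[./ms] nsam nreps`.")
  n_sam <- as.integer(tok[1])
  n_reps <- as.integer(tok[2])
  if (is.na(n_sam) || is.na(n_reps)) abort("nsam / nreps are not integers.")
  i <- 3
  theta <- 0
  rho <- 0
  n_sites <- NA_integer_
  npop <- 1L
  deme_sizes <- n_sam
  mig <- matrix(0, 1, 1)
  size_now <- 1
  events <- list()
  num <- function(j) {
    v <- suppressWarnings(as.numeric(tok[j]))
    if (any(is.na(v))) abort(sprintf("expected a number near '%s'", tok[j[1]]))
    v
  }
  while (i <= length(tok)) {
    flag <- tok[i]
    if (flag == "-t") {
      theta <- num(i + 1); i <- i + 2
    } else if (flag == "-r") {
      rho <- num(i + 1); n_sites <- as.integer(num(i + 2)); i <- i + 3
    } else if (flag == "-I") {
      npop <- as.integer(num(i + 1))
      deme_sizes <- as.integer(num(i + 1 + seq_len(npop)))
      i <- i + 2 + npop
      mig <- matrix(0, npop, npop)
      size_now <- rep(1, npop)
      # optional trailing island migration rate
      if (i <= length(tok) && !startsWith(tok[i], "-")) {
        M <- num(i)
        mig[] <- M / (npop - 1)
        diag(mig) <- 0
        i <- i + 1
      }
      if (sum(deme_sizes) != n_sam) {
        abort(sprintf("-I subsample sizes sum to %d but nsam is %d.",
                      sum(deme_sizes), n_sam))
      }
    } else if (flag == "-m") {
      from <- as.integer(num(i + 1)); to <- as.integer(num(i + 2))
      mig[from, to] <- num(i + 3); i <- i + 4
    } else if (flag == "-n") {
      size_now[as.integer(num(i + 1))] <- num(i + 2); i <- i + 3
    } else if (flag == "-en") {
      events[[length(events) + 1]] <-
        list(time = num(i + 1), type = "en",
             deme = as.integer(num(i + 2)), x = num(i + 3))
      i <- i + 4
    } else if (flag == "-ej") {
      events[[length(events) + 1]] <-
        list(time = num(i + 1), type = "ej",
             deme = as.integer(num(i + 2)), x = num(i + 3))
      i <- i + 4
    } else {
      abort(sprintf("unsupported ms flag '%s' (supported: -t -r -I -m -n -en -ej).",
                    flag))
    }
  }
  ev <- if (length(events)) {
    dplyr::bind_rows(lapply(events, as_tibble))
  } else {
    tibble(time = numeric(0), type = character(0), deme = integer(0),
           x = numeric(0))
  }
  ev <- ev[order(ev$time), ]
  structure(
    list(n_sam = n_sam, n_reps = n_reps, theta = theta, rho = rho,
         n_sites = n_sites, npop = npop, deme_sizes = deme_sizes,
         mig = mig, size_now = size_now, events = ev,
         command = trimws(gsub("\\s+", " ", command))),
    class = "demographic_model"
  )
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("<demographic_model> n = %d (%s), %d replicate(s)\n", x$n_sam,
              paste(x$deme_sizes, collapse = " + "), x$n_reps))
  cat(sprintf("  theta = %g, rho = %g over %s sites, %d event(s)\n",
              x$theta, x$rho,
              ifelse(is.na(x$n_sites), "NA", format(x$n_sites)),
              nrow(x$events)))
  invisible(x)
}

model_events_matrix <- function(model) {
  ev <- model$events
  if (nrow(ev) == 0) return(matrix(numeric(0), 0, 4))
  cbind(ev$time, ifelse(ev$type == "en", 0, 1), ev$deme - 1,
        ifelse(ev$type == "en", ev$x, ev$deme * 0 + (ev$x - 1)))
}

#' Simulate replicates under a demographic model
#'
#' Runs the package's Hudson coalescent-with-recombination engine.
#' Replicates are generated from independent RNG streams derived from
#' `seed` and the replicate index, so `simulate_coalescent(m, seed = s)[i]`
#' is reproducible on its own and results do not depend on R's RNG state.
#'
#' With `map` supplied, each replicate is reduced to `map(rep)` as soon as
#' it is generated and the full haplotype matrix is discarded — use this for
#' long runs whose per-replicate output would not fit in memory.
#'
#' @param model A `demographic_model` from [parse_ms_args()].
#' @param n_reps Number of replicates (defaults to the model's).
#' @param seed Integer root seed; `NULL` draws one from R's RNG.
#' @param map Optional function applied to each `sim_replicate`.
#' @param max_events Guard on the per-replicate event count, so a model
#'   that cannot coalesce (for example isolated demes) fails loudly rather
#'   than spinning.
#' @return A list of `sim_replicate` objects, or of `map()` values.
#' @export
simulate_coalescent <- function(model, n_reps = model$n_reps, seed = NULL,
                                map = NULL, max_events = 5e7) {
  stopifnot(inherits(model, "demographic_model"))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  ev <- model_events_matrix(model)
  out <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    raw <- sim_replicate_cpp(model$deme_sizes, model$theta, model$rho,
                             model$mig, ev, model$size_now, seed, i,
                             max_events)
    rep <- new_sim_replicate(raw$positions, raw$alleles,
                             deme_sizes = model$deme_sizes, seed = seed)
    out[[i]] <- if (is.null(map)) rep else map(rep)
  }
  out
}

#' Derived-allele frequency of a site within one deme
#'
#' @param rep A `sim_replicate`.
#' @param deme Deme label (1-based).
#' @param site Site index (column) in the replicate.
#' @return Fraction of that deme's haplotypes carrying the derived allele;
#'   0 when the site is absent from the deme.
#' @export
subpop_frequency <- function(rep, deme, site) {
  stopifnot(inherits(rep, "sim_replicate"))
  if (!deme %in% rep$deme) abort(sprintf("deme %s not present.", deme))
  rows <- rep$deme == deme
  if (site < 1 || site > ncol(rep$alleles)) abort("site index out of range.")
  mean(rep$alleles[rows, site])
}

#' Per-deme derived-allele counts for every site of a replicate
#'
#' @param rep A `sim_replicate`.
#' @return Integer matrix demes x sites of derived-allele counts.
#' @export
deme_counts <- function(rep) {
  demes <- sort(unique(rep$deme))
  out <- matrix(0L, length(demes), ncol(rep$alleles),
                dimnames = list(demes, NULL))
  for (d in seq_along(demes)) {
    out[d, ] <- colSums(rep$alleles[rep$deme == demes[d], , drop = FALSE])
  }
  out
}
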