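#' Parameters shared by the age estimators
#'
#' @param Ne Effective population size (diploid individuals).
#' @param gen_time Generation time in years.
#' @param r Per-bp per-generation recombination rate; the default
#'   `1.45e-8` with half-width `r_sd = 0.05e-8` reflects the commonly used
#'   pedigree interval (1.41–1.51e-8).
#' @param r_sd Half-width of the recombination-rate interval, used to
#'   propagate uncertainty in [sweep_onset_from_roh()].
#' @param u Per-site per-generation mutation rate (recorded for
#'   completeness; not used by the three estimators).
#' @param D_hc Human-chimpanzee per-site sequence divergence.
#' @param T_hc_low,T_hc_high Human-chimpanzee split time bracket in years
#'   (recent and old estimates).
#' @return A `dating_params` list.
#' @export
dating_params <- function(Ne = 1e4, gen_time = 25, r = 1.45e-8,
                          r_sd = 0.05e-8, u = 3e-8, D_hc = 0.01747,
                          T_hc_low = 5e6, T_hc_high = 12e6) {
  p <- list(Ne = Ne, gen_time = gen_time, r = r, r_sd = r_sd, u = u,
            D_hc = D_hc, T_hc_low = T_hc_low, T_hc_high = T_hc_high)
  if (any(unlist(p) <= 0)) abort("all dating parameters must be positive.")
  structure(p, class = "dating_params")
}

new_age_estimate <- function(method, value, low = NA_real_, high = NA_real_,
                             params, detail = list()) {
  structure(list(method = method, value = value, low = low, high = high,
                 params = params, detail = detail),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  rng <- if (is.finite(x$low)) sprintf(" (range %.3g - %.3g)", x$low, x$high) else ""
  cat(sprintf("<age_estimate> %s: %.4g years%s\n", x$method, x$value, rng))
  invisible(x)
}

#' @rdname dating_params
#' @param x An `age_estimate`.
#' @param ... Unused.
#' @export
tidy.age_estimate <- function(x, ...) {
  tibble(method = x$method, years = x$value, low = x$low, high = x$high,
         Ne = x$params$Ne, gen_time = x$params$gen_time, r = x$params$r,
         u = x$params$u)
}

#' Expected neutral drift time to reach a frequency
#'
#' The Kimura-Ohta expected age of a neutral allele observed at frequency
#' `x` that entered the population as a single copy:
#' `t = -4 Ne x log(x) / (1 - x)` generations, converted to years. Under
#' neutrality this is the expected time for the haplogroup to drift from
#' `1/(2 Ne)` to its current frequency; a much younger haplogroup at the
#' same frequency implicates selection. The formula is injectable through
#' `formula_fn` so alternative drift-time variants can be swapped in.
#'
#' @param x Current allele frequency, in (0, 1).
#' @param params A [dating_params()].
#' @param formula_fn Function `(x, Ne) -> generations`; the default is the
#'   Kimura-Ohta expected-age form above.
#' @return An `age_estimate` (method `"drift-time"`).
#' @examples
#' neutral_time_to_frequency(0.7, dating_params(Ne = 1e4, gen_time = 25))
#' @export
neutral_time_to_frequency <- function(x, params = dating_params(),
                                      formula_fn = NULL) {
  if (!is.numeric(x) || x <= 0 || x >= 1) abort("`x` must lie strictly in (0, 1).")
  if (is.null(formula_fn)) {
    formula_fn <- function(x, Ne) -4 * Ne * x * log(x) / (1 - x)
  }
  gens <- formula_fn(x, params$Ne)
  new_age_estimate("drift-time", gens * params$gen_time, params = params,
                   detail = list(x = x, generations = gens))
}

#' Coalescent age from sequence divergence
#'
#' Scales the per-site divergence `d` of a haplogroup from a root
#' haplotype by the human-chimpanzee divergence calibration:
#' `age = d / D_hc * T_hc` years. The returned range brackets the value
#' using the recent and old split-time estimates.
#'
#' @param d Per-site sequence divergence from the root haplotype.
#' @param params A [dating_params()].
#' @return An `age_estimate` (method `"divergence"`) whose `low`/`high`
#'   use `T_hc_low` / `T_hc_high`; `value` uses `T_hc_low`.
#' @examples
#' divergence_age(0.001048, dating_params())  # ~300k - 720k years
#' @export
divergence_age <- function(d, params = dating_params()) {
  if (d < 0) abort("divergence must be non-negative.")
  lo <- d / params$D_hc * params$T_hc_low
  hi <- d / params$D_hc * params$T_hc_high
  new_age_estimate("divergence", lo, low = lo, high = hi, params = params,
                   detail = list(d = d))
}

#' Sweep onset time from run-of-homozygosity length
#'
#' A haplotype swept to high frequency `t` generations ago retains a run
#' of homozygosity of length `L` until recombination has had time to break
#' it: the run decays rapidly once \eqn{r L t} reaches 1, so the onset is
#' dated as `t = 1 / (r L)` generations. Uncertainty is propagated from
#' the recombination-rate interval r +/- r_sd.
#'
#' @param L ROH length in bp. This is the per-individual total (both
#'   flanks); callers holding a one-sided mean should double it.
#' @param params A [dating_params()].
#' @return An `age_estimate` (method `"roh-onset"`).
#' @examples
#' sweep_onset_from_roh(16000, dating_params())
#' @export
sweep_onset_from_roh <- function(L, params = dating_params()) {
  if (L <= 0) abort("ROH length must be positive.")
  gens <- 1 / (params$r * L)
  lo <- 1 / ((params$r + params$r_sd) * L) * params$gen_time
  hi <- 1 / ((params$r - params$r_sd) * L) * params$gen_time
  new_age_estimate("roh-onset", gens * params$gen_time, low = lo, high = hi,
                   params = params, detail = list(L = L, generations = gens))
}
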