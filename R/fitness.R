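# Fitness scheme. Sexually antagonistic selection is symmetric: a
# genotype's male fitness and its female fitness are exact reciprocals
# ((1+s) vs 1/(1+s), (1+hs) vs 1/(1+hs)). Male fitness carries a second,
# meiosis-dependent factor: chiasmatic males pay the aneuploidy cost
# (1-k); achiasmatic males pay the Muller's-ratchet mutational load
# (1-delta)^(U t) with U = mu*L. Fitnesses are relative (values > 1 are
# fine); the recursion divides by mean fitness.

#' Muller's-ratchet mutational load
#'
#' Multiplicative fitness cost of deleterious mutations accumulating on a
#' non-recombining Y: `(1 - delta)^(mu * L * t)`, where `U = mu * L` is
#' the genomic deleterious mutation rate over the newly non-recombining
#' sites and `t` is generations since the achiasmy allele arose. Computed
#' in log space so extreme exponents do not underflow prematurely.
#'
#' @param mu Per-site per-generation mutation rate (>= 0).
#' @param L Number of coding sites exposed to the ratchet (>= 0).
#' @param delta Per-mutation fitness effect (0 <= delta < 1).
#' @param t Time in generations (>= 0; vectorised).
#' @return The load multiplier in (0, 1]; `load(0) = 1`.
#' @examples
#' mutational_load(1e-9, 5e6, 0.03, 1000) # == 0.97^5
#' @export
mutational_load <- function(mu, L, delta, t) {
  if (any(c(mu, L, t) < 0)) {
    stop("`mu`, `L` and `t` must be non-negative.", call. = FALSE)
  }
  if (delta < 0 || delta >= 1) {
    stop("`delta` must lie in [0, 1).", call. = FALSE)
  }
  exp(mu * L * t * log1p(-delta))
}

#' Female fitness
#'
#' Female fitness at the sexually antagonistic locus: `mm` -> `1/(1+s)`,
#' `mf` -> `1/(1+hs)`, `ff` -> `1`. Females are unaffected by the meiosis
#' locus, the aneuploidy rate, and the mutational load.
#'
#' @param sal_genotype Genotype at the sexually antagonistic locus
#'   (`"mm"`, `"mf"`, `"fm"`, or `"ff"`; a length-2 vector also works).
#' @param s Selection coefficient (>= 0).
#' @param h Dominance factor of allele `m`.
#' @return Relative fitness.
#' @examples
#' female_fitness("mm", s = 0.2) # 1/1.2
#' @export
female_fitness <- function(sal_genotype, s, h = 0.5) {
  1 / sal_male_factor(sal_genotype, s, h)
}

#' Male fitness
#'
#' Product of the sexually antagonistic factor (`(1+s)`, `(1+hs)`, or 1
#' for `mm`, `mf`, `ff`) and the meiosis-dependent factor: achiasmatic
#' males (genotype containing `a`) carry the mutational load
#' `(1-delta)^(mu*L*t)`; chiasmatic males (`cc`) pay the aneuploidy cost
#' `(1-k)`. The two study conditions set `k = 0` or `L = 0` respectively,
#' but the formula composes both generically.
#'
#' @inheritParams female_fitness
#' @param ml_genotype Genotype at the meiosis locus (`"cc"`, `"ac"`,
#'   `"aa"`).
#' @param k Aneuploidy rate of chiasmatic males.
#' @param mu,L,delta,t Mutational-load parameters, see
#'   [mutational_load()].
#' @return Relative fitness.
#' @examples
#' male_fitness("mm", "cc", s = 0.1, k = 0.02) # 1.1 * 0.98
#' @export
male_fitness <- function(sal_genotype, ml_genotype, s, h = 0.5, k = 0,
                         mu = 1e-9, L = 0, delta = 0.03, t = 0) {
  ml <- split_genotype(ml_genotype, c("c", "a"), "ml_genotype")
  ml_factor <- if (any(ml == "a")) {
    mutational_load(mu, L, delta, t)
  } else {
    1 - k
  }
  sal_male_factor(sal_genotype, s, h) * ml_factor
}

sal_male_factor <- function(sal_genotype, s, h) {
  g <- split_genotype(sal_genotype, c("m", "f"), "sal_genotype")
  n_m <- sum(g == "m")
  switch(as.character(n_m),
    "2" = 1 + s,
    "1" = 1 + h * s,
    "0" = 1
  )
}
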