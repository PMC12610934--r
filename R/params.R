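#' Model parameters
#'
#' Bundle and validate the scalar parameters of the achiasmy-invasion
#' model. Defaults reproduce the headline study conditions: mutation rate
#' `mu = 1e-9` per site per generation, per-mutation fitness effect
#' `delta = 0.03`, initial achiasmy-allele frequency `p0 = 1e-4`
#' (rescaled by the chromosome class's relative effective population size
#' when `ne_adjust = TRUE`), 1000 generations, and a fixation threshold
#' of 0.99.
#'
#' @param s Selection coefficient at the sexually antagonistic locus
#'   (dimensionless, >= 0).
#' @param h Dominance factor of the male-beneficial allele `m` (in
#'   \[0, 1\]).
#' @param k Sex-chromosome aneuploidy rate of chiasmatic males; applied as
#'   a viability cost `(1 - k)`, never as gamete loss. In \[0, 1).
#' @param R1 Recombination fraction between the sex-determining locus and
#'   the sexually antagonistic locus (in \[0, 0.5\]).
#' @param R2 Recombination fraction between the sexually antagonistic
#'   locus and the meiosis locus. Forced to 0.5 when
#'   `location = "autosome"` (the meiosis locus then assorts
#'   independently of the sex chromosome).
#' @param mu Per-site per-generation deleterious mutation rate.
#' @param L Number of coding sites newly exposed to Muller's ratchet when
#'   the Y stops recombining (sites, >= 0).
#' @param delta Per-mutation fitness effect (0 <= delta < 1).
#' @param location Chromosome carrying the achiasmy mutation:
#'   `"Y"`, `"X"`, or `"autosome"`.
#' @param p0 Nominal initial frequency of the achiasmy allele.
#' @param ne_adjust If `TRUE`, the realised initial frequency within the
#'   mutation's chromosome class is `p0` divided by that class's relative
#'   effective population size (autosome 1, X 0.75, Y 0.25).
#' @param max_generations Iteration cap (generations).
#' @param fixation_threshold Within-class achiasmy-allele frequency at or
#'   above which the run is classified `fixed`.
#' @param equilibrium_tol Absolute per-generation change in the tracked
#'   frequency below which the population is declared at equilibrium.
#' @param loss_threshold Within-class frequency below which the allele is
#'   treated as numerically lost and iteration stops early.
#' @param burn_in Generations to iterate without the achiasmy allele
#'   before introducing it (lets the sexually antagonistic locus settle
#'   first). Off (0) by default: alleles at that locus simply start at
#'   equal frequencies.
#'
#' @return An object of class `achiasma_params` (a validated named list).
#' @examples
#' model_params(location = "Y", k = 0.02, L = 0)
#' @export
model_params <- function(s = 0,
                         h = 0.5,
                         k = 0,
                         R1 = 0.1,
                         R2 = 0.1,
                         mu = 1e-9,
                         L = 0,
                         delta = 0.03,
                         location = c("Y", "X", "autosome"),
                         p0 = 1e-4,
                         ne_adjust = TRUE,
                         max_generations = 1000L,
                         fixation_threshold = 0.99,
                         equilibrium_tol = 1e-9,
                         loss_threshold = 1e-15,
                         burn_in = 0L) {
  location <- match.arg(location)
  r2_supplied <- !missing(R2)
  if (location == "autosome") {
    if (r2_supplied && R2 != 0.5) {
      stop("`R2` must be 0.5 when `location = \"autosome\"` ",
        "(an autosomal meiosis locus assorts independently ",
        "of the sex chromosome).",
        call. = FALSE
      )
    }
    R2 <- 0.5
  }

  check_scalar <- function(x, nm, lo = -Inf, hi = Inf,
                           lo_open = FALSE, hi_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("`%s` must be a finite numeric scalar.", nm),
        call. = FALSE
      )
    }
    bad <- if (lo_open) x <= lo else x < lo
    bad <- bad || if (hi_open) x >= hi else x > hi
    if (bad) {
      stop(sprintf(
        "`%s` = %g is outside %s%g, %g%s.", nm, x,
        if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
      ), call. = FALSE)
    }
    as.numeric(x)
  }

  p <- list(
    s = check_scalar(s, "s", lo = 0),
    h = check_scalar(h, "h", lo = 0, hi = 1),
    k = check_scalar(k, "k", lo = 0, hi = 1, hi_open = TRUE),
    R1 = check_scalar(R1, "R1", lo = 0, hi = 0.5),
    R2 = check_scalar(R2, "R2", lo = 0, hi = 0.5),
    mu = check_scalar(mu, "mu", lo = 0),
    L = check_scalar(L, "L", lo = 0),
    delta = check_scalar(delta, "delta", lo = 0, hi = 1, hi_open = TRUE),
    location = location,
    p0 = check_scalar(p0, "p0", lo = 0, hi = 1, hi_open = TRUE),
    ne_adjust = isTRUE(ne_adjust),
    max_generations = as.integer(
      check_scalar(max_generations, "max_generations", lo = 0)
    ),
    fixation_threshold = check_scalar(
      fixation_threshold, "fixation_threshold",
      lo = 0, hi = 1
    ),
    equilibrium_tol = check_scalar(equilibrium_tol, "equilibrium_tol", lo = 0),
    loss_threshold = check_scalar(loss_threshold, "loss_threshold", lo = 0),
    burn_in = as.integer(check_scalar(burn_in, "burn_in", lo = 0))
  )
  structure(p, class = "achiasma_params")
}

#' @export
print.achiasma_params <- function(x, ...) {
  cat("<achiasma_params>\n")
  cat(sprintf(
    "  location=%s  s=%g  h=%g  k=%g  R1=%g  R2=%g\n",
    x$location, x$s, x$h, x$k, x$R1, x$R2
  ))
  cat(sprintf(
    "  mu=%g  L=%g  delta=%g  (U = mu*L = %g)\n",
    x$mu, x$L, x$delta, x$mu * x$L
  ))
  cat(sprintf(
    "  p0=%g  ne_adjust=%s  max_generations=%d  fixation_threshold=%g\n",
    x$p0, x$ne_adjust, x$max_generations, x$fixation_threshold
  ))
  invisible(x)
}

#' Relative effective population size of a chromosome class
#'
#' Standard breeding-sex accounting: with `n_females` breeding females and
#' `n_males` breeding males, effective sizes are
#' `Ne_A = 4 Nf Nm / (Nf + Nm)` for autosomes,
#' `Ne_X = 9 Nf Nm / (4 Nf + 2 Nm)` for the X, and `Ne_Y = Nm / 2` for the
#' Y. The returned value is the ratio to the autosomal `Ne`; with equal
#' sex numbers this is 1 (autosome), 0.75 (X), and 0.25 (Y).
#'
#' @param location `"autosome"`, `"X"`, or `"Y"`.
#' @param n_females,n_males Numbers of breeding females and males.
#' @return A numeric scalar, the class's `Ne` relative to autosomes.
#' @examples
#' relative_ne("X") # 0.75
#' relative_ne("Y") # 0.25
#' @export
relative_ne <- function(location = c("autosome", "X", "Y"),
                        n_females = 1, n_males = 1) {
  location <- match.arg(location)
  nf <- n_females
  nm <- n_males
  ne_a <- 4 * nf * nm / (nf + nm)
  ne <- switch(location,
    autosome = ne_a,
    X = 9 * nf * nm / (4 * nf + 2 * nm),
    Y = nm / 2
  )
  ne / ne_a
}
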