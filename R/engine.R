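# Vectorised one-generation recursion. Everything that does not depend
# on the generation counter is precomputed once per parameter set:
# meiosis tables for the 16 female and 16 male (egg x sperm) genotype
# combinations and the time-constant fitness factors. Genotype index g
# corresponds to as.vector(outer(egg, sperm_slice)): g = (s - 1) * 4 + e.

build_engine <- function(params) {
  stopifnot(inherits(params, "achiasma_params"))
  R1 <- params$R1
  R2 <- params$R2

  t_f <- matrix(0, 16L, 4L, dimnames = list(NULL, EGG_HAPLOTYPES))
  t_m <- matrix(0, 16L, 8L, dimnames = list(NULL, SPERM_HAPLOTYPES))
  w_f <- numeric(16L)
  w_m_sal <- numeric(16L)
  male_achiasmatic <- logical(16L)

  for (si in 1:4) {
    for (ei in 1:4) {
      g <- (si - 1L) * 4L + ei
      e_hap <- EGG_HAPLOTYPES[ei]
      # Female offspring: sperm is X-bearing (classes 1:4).
      sx_hap <- SPERM_HAPLOTYPES[si]
      d <- meiosis_dist(e_hap, sx_hap, R1, R2, suppress_recombination = FALSE)
      t_f[g, ] <- d[EGG_HAPLOTYPES] # all products X-bearing
      w_f[g] <- female_fitness(
        c(hap_sal(e_hap), hap_sal(sx_hap)), params$s, params$h
      )
      # Male offspring: sperm is Y-bearing (classes 5:8).
      sy_hap <- SPERM_HAPLOTYPES[si + 4L]
      achiasmatic <- hap_carries_a(e_hap) || hap_carries_a(sy_hap)
      # Achiasmy abolishes crossing over, not independent assortment:
      # a sex-linked meiosis locus is fully suppressed in achiasmatic
      # males, while an autosomal one still assorts at R2 = 0.5.
      t_m[g, ] <- if (achiasmatic && params$location == "autosome") {
        meiosis_dist(e_hap, sy_hap, 0, 0.5, suppress_recombination = FALSE)
      } else {
        meiosis_dist(e_hap, sy_hap, R1, R2,
          suppress_recombination = achiasmatic
        )
      }
      w_m_sal[g] <- sal_male_factor(
        c(hap_sal(e_hap), hap_sal(sy_hap)), params$s, params$h
      )
      male_achiasmatic[g] <- achiasmatic
    }
  }

  list(
    t_f = t_f,
    t_m = t_m,
    w_f = w_f,
    # Split the male ML factor so the per-generation update is one FMA:
    # w_m(t) = w_m_load * load(t) + w_m_chiasmatic.
    w_m_load = w_m_sal * male_achiasmatic,
    w_m_chiasmatic = w_m_sal * (!male_achiasmatic) * (1 - params$k),
    log_load_per_gen = params$mu * params$L * log1p(-params$delta)
  )
}

# One generation given the precomputed engine; egg and sperm are bare
# numeric vectors (length 4 and 8). Returns a list(egg, sperm).
engine_step <- function(engine, egg, sperm, t) {
  gf <- as.vector(outer(egg, sperm[1:4])) * engine$w_f
  load_t <- exp(engine$log_load_per_gen * t)
  w_m <- engine$w_m_load * load_t + engine$w_m_chiasmatic
  gm <- as.vector(outer(egg, sperm[5:8])) * w_m

  egg_new <- as.vector(crossprod(engine$t_f, gf))
  sperm_new <- as.vector(crossprod(engine$t_m, gm))
  se <- sum(egg_new)
  ss <- sum(sperm_new)
  if (se <= 0 || ss <= 0 || !is.finite(se) || !is.finite(ss)) {
    stop("Total fitness-weighted gamete frequency underflowed.",
      call. = FALSE
    )
  }
  list(egg = egg_new / se, sperm = sperm_new / ss)
}

#' Advance the population by one generation
#'
#' Applies the full life cycle once: random union of gametes, sex
#' determination, sex-specific viability selection on adults at
#' generation `t`, then sex-specific meiosis — females always recombine
#' at `R1`, `R2`; males carrying at least one achiasmy allele undergo no
#' crossing over, so with a sex-linked meiosis locus they transmit their
#' haplotypes intact, while an autosomal meiosis locus
#' (`location = "autosome"`) still assorts independently (`R2 = 0.5`) —
#' and renormalisation of the resulting egg and sperm pools.
#' Deterministic: identical inputs give identical outputs.
#'
#' @param pools A [gamete_pools()] object.
#' @param params An [model_params()] object.
#' @param t Generation index (enters male fitness through the mutational
#'   load `(1-delta)^(mu*L*t)`).
#' @return A new [gamete_pools()] object.
#' @examples
#' p <- initialize_pools(model_params(location = "Y", k = 0.02))
#' step_generation(p, model_params(location = "Y", k = 0.02), t = 0)
#' @export
step_generation <- function(pools, params, t = 0) {
  validate_pools(pools)
  stopifnot(t >= 0)
  engine <- build_engine(params)
  st <- engine_step(engine, unname(pools$egg), unname(pools$sperm), t)
  gamete_pools(
    stats::setNames(st$egg, EGG_HAPLOTYPES),
    stats::setNames(st$sperm, SPERM_HAPLOTYPES)
  )
}
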