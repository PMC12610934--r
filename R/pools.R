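# Gamete pools: the state of the recursion. Egg frequencies over the 4
# X-bearing haplotypes and sperm frequencies over all 8 haplotypes, each
# summing to 1. Y-bearing sperm always total 0.5: every male makes half
# X and half Y gametes (aneuploidy is a fitness cost, not gamete loss).

#' Construct a pair of gamete pools
#'
#' @param egg_freq Named numeric vector of frequencies over the 4 egg
#'   haplotypes (`X_mc`, `X_ma`, `X_fc`, `X_fa`).
#' @param sperm_freq Named numeric vector of frequencies over all 8 sperm
#'   haplotypes.
#' @param validate Check pool invariants (non-negative, sums to 1,
#'   Y-sperm total 0.5)? Default `TRUE`.
#' @return An object of class `gamete_pools`: a list with numeric vectors
#'   `egg` and `sperm` in canonical haplotype order.
#' @examples
#' gamete_pools(
#'   c(X_mc = 0.5, X_fc = 0.5),
#'   c(X_mc = 0.25, X_fc = 0.25, Y_mc = 0.25, Y_fc = 0.25)
#' )
#' @export
gamete_pools <- function(egg_freq, sperm_freq, validate = TRUE) {
  egg <- stats::setNames(numeric(4L), EGG_HAPLOTYPES)
  sperm <- stats::setNames(numeric(8L), SPERM_HAPLOTYPES)
  fill <- function(slot, x, what) {
    if (is.null(names(x)) || any(!names(x) %in% names(slot))) {
      stop(sprintf("`%s` must be named with valid %s haplotypes.",
        what, what
      ), call. = FALSE)
    }
    slot[names(x)] <- as.numeric(x)
    slot
  }
  pools <- structure(
    list(
      egg = fill(egg, egg_freq, "egg"),
      sperm = fill(sperm, sperm_freq, "sperm")
    ),
    class = "gamete_pools"
  )
  if (validate) validate_pools(pools)
  pools
}

#' Validate gamete-pool invariants
#'
#' @param pools A [gamete_pools()] object.
#' @param tolerance Numerical tolerance on the sum constraints.
#' @return `pools`, invisibly; errors if any invariant fails.
#' @export
validate_pools <- function(pools, tolerance = 1e-12) {
  stopifnot(inherits(pools, "gamete_pools"))
  if (any(pools$egg < 0) || any(pools$sperm < 0)) {
    stop("Gamete frequencies must be non-negative.", call. = FALSE)
  }
  if (abs(sum(pools$egg) - 1) > tolerance) {
    stop("Egg frequencies must sum to 1.", call. = FALSE)
  }
  if (abs(sum(pools$sperm) - 1) > tolerance) {
    stop("Sperm frequencies must sum to 1.", call. = FALSE)
  }
  y_total <- sum(pools$sperm[hap_sdl(SPERM_HAPLOTYPES) == "Y"])
  if (abs(y_total - 0.5) > tolerance) {
    stop("Y-bearing sperm must total 0.5.", call. = FALSE)
  }
  invisible(pools)
}

#' @export
print.gamete_pools <- function(x, ...) {
  cat("<gamete_pools>\n egg: ")
  print(round(x$egg, 6))
  cat(" sperm: ")
  print(round(x$sperm, 6))
  invisible(x)
}

#' @export
as_tibble.gamete_pools <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      pool = "egg", haplotype = names(x$egg),
      frequency = unname(x$egg)
    ),
    tibble::tibble(
      pool = "sperm", haplotype = names(x$sperm),
      frequency = unname(x$sperm)
    )
  )
}

#' Initial gamete pools for an invasion run
#'
#' The sexually antagonistic alleles `m` and `f` start at frequency 0.5
#' on every chromosome class, in linkage equilibrium with the other loci.
#' The achiasmy allele `a` is placed on the chromosome class named by
#' `params$location` at a conditional (within-class) frequency of `p0`,
#' divided by the class's relative effective population size (autosome 1,
#' X 0.75, Y 0.25) when `ne_adjust` is on — a new mutation is "one copy"
#' in a smaller pool of chromosomes, so its starting frequency within the
#' class is correspondingly higher.
#'
#' @param params An [model_params()] object.
#' @return A [gamete_pools()] object satisfying all pool invariants.
#' @examples
#' initialize_pools(model_params(location = "Y", p0 = 1e-4))
#' @export
initialize_pools <- function(params) {
  stopifnot(inherits(params, "achiasma_params"))
  q <- initial_class_frequency(params)
  # Conditional frequency of `a` within each gamete class.
  q_egg <- switch(params$location, Y = 0, X = q, autosome = q)
  q_spx <- q_egg
  q_spy <- switch(params$location, Y = q, X = 0, autosome = q)

  sal <- c(m = 0.5, f = 0.5)
  class_vec <- function(qa) {
    c(sal["m"] * (1 - qa), sal["m"] * qa, sal["f"] * (1 - qa), sal["f"] * qa)
  }
  egg <- stats::setNames(class_vec(q_egg), EGG_HAPLOTYPES)
  sperm <- stats::setNames(
    c(0.5 * class_vec(q_spx), 0.5 * class_vec(q_spy)),
    SPERM_HAPLOTYPES
  )
  gamete_pools(egg, sperm)
}

# Realised initial within-class frequency of the achiasmy allele.
initial_class_frequency <- function(params) {
  if (!params$ne_adjust) {
    return(params$p0)
  }
  q <- params$p0 / relative_ne(params$location)
  if (q >= 1) {
    stop("Ne-adjusted initial frequency p0 / relative_ne >= 1.",
      call. = FALSE
    )
  }
  q
}

#' Allele frequency in a pair of gamete pools
#'
#' Population-wide frequencies weight the egg and sperm pools equally
#' (each parent sex contributes half the gene copies of a zygote).
#' Restricted queries condition on a chromosome class: `restrict_to =
#' "Y"` counts only Y-bearing sperm; `restrict_to = "X"` counts eggs and
#' X-bearing sperm, in the 2:1 egg:sperm ratio with which X copies enter
#' zygotes.
#'
#' @param pools A [gamete_pools()] object.
#' @param locus `"sdl"`, `"sal"`, or `"ml"`.
#' @param allele The allele whose frequency is requested (`X`/`Y`,
#'   `m`/`f`, or `c`/`a`).
#' @param restrict_to `NULL` (population-wide), `"X"`, or `"Y"`.
#' @return A frequency in \[0, 1\].
#' @examples
#' p <- initialize_pools(model_params(location = "Y", p0 = 1e-4))
#' allele_frequency(p, "ml", "a", restrict_to = "Y") # 4e-4
#' @export
allele_frequency <- function(pools, locus = c("ml", "sal", "sdl"), allele,
                             restrict_to = NULL) {
  validate_pools(pools)
  locus <- match.arg(locus)
  get <- switch(locus, sdl = hap_sdl, sal = hap_sal, ml = hap_ml)
  valid <- switch(locus,
    sdl = c("X", "Y"), sal = c("m", "f"), ml = c("c", "a")
  )
  if (!allele %in% valid) {
    stop(sprintf(
      "Unknown allele '%s' for locus '%s'.", allele, locus
    ), call. = FALSE)
  }
  egg_hit <- get(names(pools$egg)) == allele
  sp_hit <- get(names(pools$sperm)) == allele
  sp_x <- hap_sdl(names(pools$sperm)) == "X"

  if (is.null(restrict_to)) {
    return(0.5 * sum(pools$egg[egg_hit]) + 0.5 * sum(pools$sperm[sp_hit]))
  }
  if (identical(restrict_to, "Y")) {
    num <- sum(pools$sperm[sp_hit & !sp_x])
    den <- sum(pools$sperm[!sp_x])
  } else if (identical(restrict_to, "X")) {
    # Each zygote gets one X from its mother and, half the time, one
    # from its father: eggs carry twice the X copies sperm do.
    num <- 2 * sum(pools$egg[egg_hit]) + sum(pools$sperm[sp_hit & sp_x])
    den <- 2 * sum(pools$egg) + sum(pools$sperm[sp_x])
  } else {
    stop("`restrict_to` must be NULL, \"X\", or \"Y\".", call. = FALSE)
  }
  if (den == 0) {
    stop("Empty chromosome class in `restrict_to` query.", call. = FALSE)
  }
  num / den
}

# Within-class frequency of the achiasmy allele for a mutation location;
# this is the quantity the fixation threshold is applied to.
class_a_frequency <- function(pools, location) {
  switch(location,
    Y = allele_frequency(pools, "ml", "a", restrict_to = "Y"),
    X = allele_frequency(pools, "ml", "a", restrict_to = "X"),
    autosome = allele_frequency(pools, "ml", "a")
  )
}

#' Random union of gametes
#'
#' Offspring genotype frequencies under random mating: an (egg, sperm)
#' pair occurs with probability `egg_freq * sperm_freq`; offspring
#' receiving an X sperm are female, a Y sperm male. Frequencies are
#' renormalised within each sex.
#'
#' @param pools A [gamete_pools()] object.
#' @return A tibble with columns `sex` (`"female"`/`"male"`),
#'   `egg_haplotype`, `sperm_haplotype`, and `frequency`; frequencies sum
#'   to 1 within each sex.
#' @export
union_gametes <- function(pools) {
  validate_pools(pools)
  grid <- tidyr::expand_grid(
    egg_haplotype = EGG_HAPLOTYPES,
    sperm_haplotype = SPERM_HAPLOTYPES
  )
  grid$frequency <- pools$egg[grid$egg_haplotype] *
    pools$sperm[grid$sperm_haplotype]
  grid$sex <- ifelse(hap_sdl(grid$sperm_haplotype) == "Y", "male", "female")
  tot <- tapply(grid$frequency, grid$sex, sum)
  if (any(tot == 0)) {
    stop("Degenerate pools: one sex has total frequency 0.", call. = FALSE)
  }
  grid$frequency <- as.numeric(grid$frequency / tot[grid$sex])
  dplyr::select(
    grid, "sex", "egg_haplotype", "sperm_haplotype", "frequency"
  )
}
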