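# Sex-specific meiosis with recombination in two intervals:
# SDL --R1-- SAL --R2-- ML. No crossover interference: the intervals
# recombine independently, so the four meiotic classes have probabilities
# (1-R1)(1-R2), R1(1-R2), (1-R1)R2, R1*R2, each split 0.5/0.5 between
# reciprocal products.

#' Gamete distribution from one parent
#'
#' Enumerates the meiotic products of a diploid parent with haplotypes
#' `parent1` and `parent2`. When `suppress_recombination = TRUE` (an
#' achiasmatic male) the parental haplotypes are transmitted intact, each
#' with probability 0.5. Females always recombine at `R1`, `R2`
#' regardless of their meiosis-locus genotype.
#'
#' @param parent1,parent2 Haplotype strings (see [haplotype_table()]).
#' @param R1 Recombination fraction between the sex-determining and the
#'   sexually antagonistic locus, in \[0, 0.5\].
#' @param R2 Recombination fraction between the sexually antagonistic and
#'   the meiosis locus, in \[0, 0.5\].
#' @param suppress_recombination If `TRUE`, no crossing over occurs.
#' @return A tibble with columns `haplotype` and `probability`, one row
#'   per possible gamete haplotype (rows with probability 0 included),
#'   summing to 1.
#' @examples
#' # An achiasmatic male transmits parental haplotypes only:
#' meiosis_products("X_ma", "Y_fc", 0.1, 0.1, suppress_recombination = TRUE)
#' @export
meiosis_products <- function(parent1, parent2, R1, R2,
                             suppress_recombination = FALSE) {
  assert_haplotype(parent1, "parent1")
  assert_haplotype(parent2, "parent2")
  d <- meiosis_dist(parent1, parent2, R1, R2, suppress_recombination)
  tibble::tibble(haplotype = names(d), probability = unname(d))
}

# Internal: named numeric over the 8 haplotypes.
meiosis_dist <- function(parent1, parent2, R1, R2,
                         suppress_recombination = FALSE) {
  for (r in c(R1 = R1, R2 = R2)) {
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 0.5) {
      stop("Recombination fractions must lie in [0, 0.5].", call. = FALSE)
    }
  }
  if (hap_sdl(parent1) == "Y" && hap_sdl(parent2) == "Y") {
    stop("Invalid parent: two Y-bearing haplotypes.", call. = FALSE)
  }
  out <- stats::setNames(numeric(8L), SPERM_HAPLOTYPES)
  add <- function(h, p) out[h] <<- out[h] + p

  if (isTRUE(suppress_recombination)) {
    add(parent1, 0.5)
    add(parent2, 0.5)
    return(out)
  }

  a <- c(hap_sdl(parent1), hap_sdl(parent2))
  b <- c(hap_sal(parent1), hap_sal(parent2))
  cc <- c(hap_ml(parent1), hap_ml(parent2))
  gam <- function(i, j, l) paste0(a[i], "_", b[j], cc[l])
  # Four crossover classes; each yields two reciprocal products.
  classes <- list(
    list(p = (1 - R1) * (1 - R2), idx = rbind(c(1, 1, 1), c(2, 2, 2))),
    list(p = R1 * (1 - R2), idx = rbind(c(1, 2, 2), c(2, 1, 1))),
    list(p = (1 - R1) * R2, idx = rbind(c(1, 1, 2), c(2, 2, 1))),
    list(p = R1 * R2, idx = rbind(c(1, 2, 1), c(2, 1, 2)))
  )
  for (cl in classes) {
    for (r in 1:2) {
      add(gam(cl$idx[r, 1], cl$idx[r, 2], cl$idx[r, 3]), cl$p / 2)
    }
  }
  out
}

#' Does a meiosis-locus genotype make a male achiasmatic?
#'
#' The achiasmy allele `a` is dominant and sex-limited: any male carrying
#' at least one `a` undergoes achiasmatic meiosis (no recombination
#' anywhere); females recombine normally whatever their genotype, so this
#' predicate is only ever applied to males.
#'
#' @param ml_genotype Genotype at the meiosis locus: either a
#'   two-character string (`"cc"`, `"ac"`, `"ca"`, `"aa"`) or a
#'   length-two character vector of alleles.
#' @return `TRUE` if the genotype contains at least one `a`.
#' @examples
#' is_achiasmatic_male("ac")
#' is_achiasmatic_male(c("c", "c"))
#' @export
is_achiasmatic_male <- function(ml_genotype) {
  alleles <- split_genotype(ml_genotype, c("c", "a"), "ml_genotype")
  any(alleles == "a")
}

# Accepts "xy" or c("x","y"); checks both alleles are in `valid`.
split_genotype <- function(g, valid, arg) {
  if (is.character(g) && length(g) == 1L && nchar(g) == 2L) {
    g <- strsplit(g, "")[[1L]]
  }
  if (!is.character(g) || length(g) != 2L || any(!g %in% valid)) {
    stop(sprintf(
      "`%s` must be an unordered pair over {%s}.",
      arg, paste(valid, collapse = ", ")
    ), call. = FALSE)
  }
  g
}
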