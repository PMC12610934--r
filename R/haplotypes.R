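#' Gamete haplotype bookkeeping
#'
#' The model tracks three biallelic loci on one chromosome:
#' the sex-determining locus (SDL, alleles `X`/`Y`), the sexually
#' antagonistic locus (SAL, alleles `m` male-beneficial / `f`
#' female-beneficial), and the meiosis locus (ML, alleles `c` chiasmatic /
#' `a` achiasmatic). A haplotype is written `"<SDL>_<SAL><ML>"`, e.g.
#' `"X_mc"` or `"Y_fa"`. Eggs always carry `X`, so there are 4 egg
#' haplotypes and 8 sperm haplotypes.
#'
#' @return A tibble with one row per haplotype and columns `haplotype`,
#'   `sdl`, `sal`, `ml`.
#' @examples
#' haplotype_table()
#' @export
haplotype_table <- function() {
  tibble::tibble(
    haplotype = SPERM_HAPLOTYPES,
    sdl = hap_sdl(SPERM_HAPLOTYPES),
    sal = hap_sal(SPERM_HAPLOTYPES),
    ml  = hap_ml(SPERM_HAPLOTYPES)
  )
}

# Canonical orderings used throughout; sperm order puts the X-bearing
# classes first so sperm[1:4] always lines up with the egg classes.
EGG_HAPLOTYPES <- c("X_mc", "X_ma", "X_fc", "X_fa")
SPERM_HAPLOTYPES <- c(
  "X_mc", "X_ma", "X_fc", "X_fa",
  "Y_mc", "Y_ma", "Y_fc", "Y_fa"
)

hap_sdl <- function(h) substr(h, 1L, 1L)
hap_sal <- function(h) substr(h, 3L, 3L)
hap_ml <- function(h) substr(h, 4L, 4L)

hap_carries_a <- function(h) hap_ml(h) == "a"

assert_haplotype <- function(h, arg = "haplotype") {
  if (!is.character(h) || any(!h %in% SPERM_HAPLOTYPES)) {
    stop(sprintf(
      "`%s` must be one of: %s", arg,
      paste(SPERM_HAPLOTYPES, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(h)
}
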