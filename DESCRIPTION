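Package: achiasma
Title: Deterministic Population Genetics of the Evolution of Achiasmatic Meiosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, infinite-population model of the invasion of
    mutations that abolish crossing over in the heterogametic sex
    (achiasmatic meiosis). The model tracks gamete frequencies at three
    biallelic loci -- a sex-determining locus, a sexually antagonistic
    locus, and a meiosis-modifier locus -- through random mating,
    sex-specific viability selection, and sex-specific meiosis with
    recombination. Selective forces include sexually antagonistic
    selection, a sex-chromosome aneuploidy cost paid by chiasmatic males,
    and an exponentially compounding mutational load from Muller's ratchet
    on the non-recombining Y. Includes factorial parameter-sweep machinery
    that classifies fixation outcomes across grids of selection strength,
    aneuploidy rate, and exposed coding length, and renders the resulting
    invasion heatmaps, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
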