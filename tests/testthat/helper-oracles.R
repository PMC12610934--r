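# Independent oracles, deliberately coded differently from the package
# internals so they can catch implementation errors.

# Scalar recursion for the within-Y frequency of a Y-located achiasmy
# allele with s = 0: achiasmatic males have ML fitness lambda(t) =
# (1-delta)^(mu*L*t) (or 1 when L = 0), chiasmatic males (1-k).
scalar_y_recursion <- function(p0, k = 0, mu = 0, L = 0, delta = 0.03,
                               n_generations = 1000,
                               fixation_threshold = NULL) {
  p <- p0
  out <- numeric(n_generations + 1)
  out[1] <- p
  for (t in 0:(n_generations - 1)) {
    lambda <- (1 - delta)^(mu * L * t)
    p <- p * lambda / (p * lambda + (1 - p) * (1 - k))
    out[t + 2] <- p
    if (!is.null(fixation_threshold) && p >= fixation_threshold) {
      return(list(trajectory = out[1:(t + 2)], fixed_at = as.integer(t + 1)))
    }
  }
  list(trajectory = out, fixed_at = NA_integer_)
}

# Per-locus transmission model of meiosis: the gamete takes its
# sex-determining allele from parent 1 or 2 with probability 1/2, the
# sexually antagonistic allele from the same parent with probability
# (1 - R1), and the meiosis allele from the SAL's parent with
# probability (1 - R2). Enumerates the 8 origin patterns directly —
# a different decomposition from the package's crossover-class one.
oracle_transmit <- function(h1, h2, R1, R2) {
  loci <- rbind(
    c(substr(h1, 1, 1), substr(h2, 1, 1)),
    c(substr(h1, 3, 3), substr(h2, 3, 3)),
    c(substr(h1, 4, 4), substr(h2, 4, 4))
  )
  out <- numeric(0)
  for (o1 in 1:2) {
    for (o2 in 1:2) {
      for (o3 in 1:2) {
        p <- 0.5 *
          (if (o2 == o1) 1 - R1 else R1) *
          (if (o3 == o2) 1 - R2 else R2)
        g <- paste0(loci[1, o1], "_", loci[2, o2], loci[3, o3])
        out[g] <- (if (g %in% names(out)) out[[g]] else 0) + p
      }
    }
  }
  out
}

# Brute-force one-generation update: explicit loops over every ordered
# (egg, sperm) genotype combination, Table-style fitness arithmetic, and
# oracle_transmit() for meiosis.
brute_step <- function(pools, params, t) {
  eggs <- setNames(numeric(4), names(pools$egg))
  sperm <- setNames(numeric(8), names(pools$sperm))
  sal_count <- function(h) (substr(h, 3, 3) == "m")
  load_t <- (1 - params$delta)^(params$mu * params$L * t)

  for (e in names(pools$egg)) {
    for (s in names(pools$sperm)) {
      freq <- pools$egg[[e]] * pools$sperm[[s]]
      n_m <- sal_count(e) + sal_count(s)
      sal_f <- c(1, 1 + params$h * params$s, 1 + params$s)[n_m + 1]
      if (substr(s, 1, 1) == "X") {
        w <- 1 / sal_f
        d <- oracle_transmit(e, s, params$R1, params$R2)
        for (g in names(d)) eggs[[g]] <- eggs[[g]] + freq * w * d[[g]]
      } else {
        achiasmatic <- substr(e, 4, 4) == "a" || substr(s, 4, 4) == "a"
        w <- sal_f * (if (achiasmatic) load_t else 1 - params$k)
        d <- if (achiasmatic) {
          if (params$location == "autosome") {
            oracle_transmit(e, s, 0, 0.5)
          } else {
            setNames(c(0.5, 0.5), c(e, s))
          }
        } else {
          oracle_transmit(e, s, params$R1, params$R2)
        }
        for (g in names(d)) sperm[[g]] <- sperm[[g]] + freq * w * d[[g]]
      }
    }
  }
  list(egg = eggs / sum(eggs), sperm = sperm / sum(sperm))
}

# Pools with arbitrary (valid) structure for property tests: random egg
# simplex, random X-sperm and Y-sperm halves.
random_pools <- function() {
  egg <- stats::runif(4)
  egg <- egg / sum(egg)
  spx <- stats::runif(4)
  spx <- 0.5 * spx / sum(spx)
  spy <- stats::runif(4)
  spy <- 0.5 * spy / sum(spy)
  gamete_pools(
    setNames(egg, c("X_mc", "X_ma", "X_fc", "X_fa")),
    setNames(
      c(spx, spy),
      c(
        "X_mc", "X_ma", "X_fc", "X_fa",
        "Y_mc", "Y_ma", "Y_fc", "Y_fa"
      )
    )
  )
}

random_params <- function() {
  model_params(
    s = stats::runif(1, 0, 0.5),
    h = sample(c(0, 0.5, 1), 1),
    k = stats::runif(1, 0, 0.05),
    R1 = stats::runif(1, 0, 0.5),
    R2 = stats::runif(1, 0, 0.5),
    L = sample(c(0, 1e6, 5e6), 1),
    location = sample(c("X", "Y"), 1),
    p0 = 1e-4
  )
}

# Small strided heatmap sweep shared by sweep and acceptance tests.
run_panel <- function(location, model, stride = 10, h = 0.5, R1 = 0.1) {
  g <- default_grids()
  sg <- function(x) x[seq(1, length(x), by = stride)]
  d <- build_design(
    locations = location,
    L_grid = sg(g$L_grid), s_grid = sg(g$s_grid), k_grid = sg(g$k_grid),
    h_values = h, R1 = R1, models = model
  )
  heatmap_matrix(run_sweep(d), location, model)
}

# Copy a params object with some fields changed, revalidating.
modifyList_params <- function(params, ...) {
  vals <- utils::modifyList(unclass(params), list(...))
  do.call(model_params, vals)
}
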