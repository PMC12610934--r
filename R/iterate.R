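# Iterating the recursion until fixation, loss, or the generation cap.

# Fast within-class achiasmy-allele frequency from bare vectors.
# Index maps: egg a-carriers {2,4}; sperm a-carriers {2,4,6,8};
# X-sperm {1:4}, Y-sperm {5:8}.
fast_class_a <- function(egg, sperm, location) {
  switch(location,
    Y = (sperm[6L] + sperm[8L]) / (sperm[5L] + sperm[6L] + sperm[7L] + sperm[8L]),
    X = (2 * (egg[2L] + egg[4L]) + sperm[2L] + sperm[4L]) /
      (2 + sperm[1L] + sperm[2L] + sperm[3L] + sperm[4L]),
    autosome = 0.5 * (egg[2L] + egg[4L]) +
      0.5 * (sperm[2L] + sperm[4L] + sperm[6L] + sperm[8L])
  )
}

#' Run an invasion trajectory
#'
#' Initialises gamete pools per [initialize_pools()] (optionally after a
#' burn-in without the achiasmy allele) and applies [step_generation()]'s
#' recursion until the within-class achiasmy-allele frequency reaches
#' `fixation_threshold`, drops below `loss_threshold`, or
#' `max_generations` is hit. The generation counter that drives the
#' mutational load starts at 0 when the achiasmy allele is introduced.
#'
#' @param params An [model_params()] object.
#' @param record_trajectory Keep the per-generation trajectory tibble?
#'   Set `FALSE` in large sweeps to save memory.
#' @return An object of class `achiasma_sim`: a list with elements
#'   `params`, `trajectory` (tibble: `generation`, `a_frequency`
#'   population-wide, `a_frequency_within_class`, `sal_m_frequency`),
#'   `final_frequency` (within-class), `generations_run`, `outcome`
#'   (`"fixed"` or `"not_fixed"`), `generations_to_fixation`,
#'   `generations_to_equilibrium`, and `final_pools`.
#' @examples
#' sim <- iterate_model(model_params(location = "Y", k = 0.05, p0 = 1e-4))
#' glance(sim)
#' @export
iterate_model <- function(params, record_trajectory = TRUE) {
  stopifnot(inherits(params, "achiasma_params"))
  engine <- build_engine(params)

  if (params$burn_in > 0L) {
    p_burn <- params
    p_burn$p0 <- 0
    pools <- initialize_pools(p_burn)
    egg <- unname(pools$egg)
    sperm <- unname(pools$sperm)
    for (g in seq_len(params$burn_in)) {
      st <- engine_step(engine, egg, sperm, t = 0)
      egg <- st$egg
      sperm <- st$sperm
    }
    q <- initial_class_frequency(params)
    st <- introduce_allele(egg, sperm, params$location, q)
    egg <- st$egg
    sperm <- st$sperm
  } else {
    pools <- initialize_pools(params)
    egg <- unname(pools$egg)
    sperm <- unname(pools$sperm)
  }

  max_gen <- params$max_generations
  n_rec <- max_gen + 1L
  if (record_trajectory) {
    traj_a <- numeric(n_rec)
    traj_cls <- numeric(n_rec)
    traj_m <- numeric(n_rec)
  }
  pop_a <- function(egg, sperm) {
    0.5 * (egg[2L] + egg[4L]) +
      0.5 * (sperm[2L] + sperm[4L] + sperm[6L] + sperm[8L])
  }
  pop_m <- function(egg, sperm) {
    0.5 * (egg[1L] + egg[2L]) +
      0.5 * (sperm[1L] + sperm[2L] + sperm[5L] + sperm[6L])
  }

  freq <- fast_class_a(egg, sperm, params$location)
  if (record_trajectory) {
    traj_a[1L] <- pop_a(egg, sperm)
    traj_cls[1L] <- freq
    traj_m[1L] <- pop_m(egg, sperm)
  }
  gens_to_fix <- if (freq >= params$fixation_threshold) 0L else NA_integer_
  gens_to_eq <- NA_integer_
  g <- 0L

  while (is.na(gens_to_fix) && g < max_gen && freq >= params$loss_threshold) {
    st <- engine_step(engine, egg, sperm, t = g)
    egg <- st$egg
    sperm <- st$sperm
    g <- g + 1L
    new_freq <- fast_class_a(egg, sperm, params$location)
    if (record_trajectory) {
      traj_a[g + 1L] <- pop_a(egg, sperm)
      traj_cls[g + 1L] <- new_freq
      traj_m[g + 1L] <- pop_m(egg, sperm)
    }
    if (is.na(gens_to_eq) && abs(new_freq - freq) < params$equilibrium_tol) {
      gens_to_eq <- g
    }
    freq <- new_freq
    if (freq >= params$fixation_threshold) gens_to_fix <- g
  }

  outcome <- if (!is.na(gens_to_fix)) "fixed" else "not_fixed"
  trajectory <- if (record_trajectory) {
    tibble::tibble(
      generation = 0:g,
      a_frequency = traj_a[1:(g + 1L)],
      a_frequency_within_class = traj_cls[1:(g + 1L)],
      sal_m_frequency = traj_m[1:(g + 1L)]
    )
  } else {
    NULL
  }

  structure(
    list(
      params = params,
      trajectory = trajectory,
      final_frequency = freq,
      final_frequency_population = pop_a(egg, sperm),
      generations_run = g,
      outcome = outcome,
      generations_to_fixation = gens_to_fix,
      generations_to_equilibrium = gens_to_eq,
      final_pools = gamete_pools(
        stats::setNames(egg, EGG_HAPLOTYPES),
        stats::setNames(sperm, SPERM_HAPLOTYPES)
      )
    ),
    class = "achiasma_sim"
  )
}

# Move a fraction q of each chiasmatic haplotype's mass to its
# achiasmatic counterpart within the target chromosome class.
introduce_allele <- function(egg, sperm, location, q) {
  shift <- function(v, c_idx, a_idx) {
    moved <- v[c_idx] * q
    v[c_idx] <- v[c_idx] - moved
    v[a_idx] <- v[a_idx] + moved
    v
  }
  if (location %in% c("X", "autosome")) {
    egg <- shift(egg, c(1L, 3L), c(2L, 4L))
    sperm <- shift(sperm, c(1L, 3L), c(2L, 4L))
  }
  if (location %in% c("Y", "autosome")) {
    sperm <- shift(sperm, c(5L, 7L), c(6L, 8L))
  }
  list(egg = egg, sperm = sperm)
}

#' @export
print.achiasma_sim <- function(x, ...) {
  cat("<achiasma_sim>\n")
  cat(sprintf(
    "  location=%s  outcome=%s  final within-class a-frequency=%.6g\n",
    x$params$location, x$outcome, x$final_frequency
  ))
  cat(sprintf(
    "  generations run=%d  to fixation=%s  to equilibrium=%s\n",
    x$generations_run,
    ifelse(is.na(x$generations_to_fixation), "-", x$generations_to_fixation),
    ifelse(is.na(x$generations_to_equilibrium), "-", x$generations_to_equilibrium)
  ))
  invisible(x)
}

#' @rdname iterate_model
#' @param x An `achiasma_sim` object.
#' @param ... Unused.
#' @export
tidy.achiasma_sim <- function(x, ...) {
  if (is.null(x$trajectory)) {
    stop("Trajectory was not recorded; rerun with record_trajectory = TRUE.",
      call. = FALSE
    )
  }
  x$trajectory
}

#' @rdname iterate_model
#' @export
glance.achiasma_sim <- function(x, ...) {
  tibble::tibble(
    location = x$params$location,
    s = x$params$s,
    h = x$params$h,
    k = x$params$k,
    L = x$params$L,
    R1 = x$params$R1,
    R2 = x$params$R2,
    final_frequency = x$final_frequency,
    final_frequency_population = x$final_frequency_population,
    outcome = x$outcome,
    generations_run = x$generations_run,
    generations_to_fixation = x$generations_to_fixation,
    generations_to_equilibrium = x$generations_to_equilibrium
  )
}

#' @rdname iterate_model
#' @param object An `achiasma_sim` object.
#' @export
autoplot.achiasma_sim <- function(object, ...) {
  d <- tidy(object)
  d_long <- tidyr::pivot_longer(
    d, -"generation",
    names_to = "series", values_to = "frequency"
  )
  ggplot2::ggplot(
    d_long,
    ggplot2::aes(
      x = .data$generation, y = .data$frequency,
      colour = .data$series
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(
      a_frequency = "#33658a",
      a_frequency_within_class = "#f26419",
      sal_m_frequency = "#758e4f"
    )) +
    ggplot2::labs(
      x = "Generation", y = "Frequency", colour = NULL,
      title = sprintf(
        "Achiasmy-allele trajectory (%s-located mutation)",
        object$params$location
      )
    ) +
    ggplot2::theme_minimal()
}
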