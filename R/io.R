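# Serialization: JSON run configuration, trajectory / sweep CSV, and
# heatmap TSV with axis values in the first row and column. Frequencies
# are written at full (round-trippable) precision.

config_keys <- function() {
  c(
    "s", "h", "k", "R1", "R2", "mu", "L", "delta", "location", "p0",
    "ne_adjust", "max_generations", "fixation_threshold",
    "equilibrium_tol", "loss_threshold", "burn_in"
  )
}

#' Default run configuration
#'
#' A flat named list mirroring [model_params()] with the headline study
#' defaults (`mu = 1e-9`, `delta = 0.03`, `p0 = 1e-4`,
#' `max_generations = 1000`, `fixation_threshold = 0.99`).
#'
#' @return A named list with one entry per configurable parameter.
#' @export
default_run_config <- function() {
  p <- model_params()
  p <- unclass(p)
  p[config_keys()]
}

#' Read a JSON run configuration
#'
#' Unknown keys are an error (catching typos early). Keys present in
#' `overrides` take precedence over the file; keys absent from both fall
#' back to the package defaults.
#'
#' @param path Path to a JSON document with a subset of the keys of
#'   [default_run_config()].
#' @param overrides A named list (or `"key=value"` character vector, as
#'   from a command line) applied on top of the file.
#' @return An [model_params()] object.
#' @export
read_run_config <- function(path, overrides = NULL) {
  cfg <- if (is.null(path)) {
    list()
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  ov <- parse_overrides(overrides)
  for (x in list(cfg, ov)) {
    bad <- setdiff(names(x), config_keys())
    if (length(bad) > 0L) {
      stop(sprintf(
        "Unknown configuration key(s): %s", paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
  }
  cfg[names(ov)] <- ov
  # Only pass keys the user supplied, so model_params() can tell an
  # explicit R2 from its default (location = "autosome" forces R2 = 0.5).
  do.call(model_params, cfg)
}

parse_overrides <- function(overrides) {
  if (is.null(overrides) || length(overrides) == 0L) {
    return(list())
  }
  if (is.list(overrides)) {
    return(overrides)
  }
  stopifnot(is.character(overrides))
  parts <- strsplit(overrides, "=", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("Overrides must have the form key=value.", call. = FALSE)
  }
  keys <- vapply(parts, `[[`, "", 1L)
  vals <- lapply(parts, function(p) {
    v <- p[[2L]]
    if (p[[1L]] == "location") {
      v
    } else if (tolower(v) %in% c("true", "false")) {
      as.logical(toupper(v))
    } else {
      as.numeric(v)
    }
  })
  stats::setNames(vals, keys)
}

#' Write / read a trajectory CSV
#'
#' Columns: `generation`, `a_frequency` (population-wide),
#' `a_frequency_within_class`, `sal_m_frequency`.
#'
#' @param sim An `achiasma_sim` object with a recorded trajectory.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(sim, path) {
  readr::write_csv(tidy(sim), path)
  invisible(path)
}

#' Write a run summary JSON
#'
#' Full-precision parameters and outcome of a single [iterate_model()]
#' run.
#'
#' @inheritParams write_trajectory_csv
#' @return `path`, invisibly.
#' @export
write_sim_summary_json <- function(sim, path) {
  out <- list(
    params = unclass(sim$params),
    final_frequency = sim$final_frequency,
    final_frequency_population = sim$final_frequency_population,
    outcome = sim$outcome,
    generations_run = sim$generations_run,
    generations_to_fixation = sim$generations_to_fixation,
    generations_to_equilibrium = sim$generations_to_equilibrium,
    package_version = as.character(utils::packageVersion("achiasma"))
  )
  jsonlite::write_json(out, path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null",
    pretty = TRUE
  )
  invisible(path)
}

#' Write / read a sweep result CSV
#'
#' One row per condition; frequencies serialized at full precision so a
#' read-back reproduces the records exactly.
#'
#' @param result An `achiasma_sweep` tibble.
#' @param path Output file.
#' @return `path` invisibly (write) or the sweep tibble (read).
#' @export
write_sweep_csv <- function(result, path) {
  readr::write_csv(tibble::as_tibble(result), path)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  # utils::read.csv parses doubles with strtod, which is exact on the
  # shortest-round-trip representations the writer emits.
  out <- utils::read.csv(path, colClasses = c(
    condition = "integer", model = "character", location = "character",
    L = "numeric", s = "numeric", h = "numeric", k = "numeric",
    R1 = "numeric", R2 = "numeric", final_frequency = "numeric",
    outcome = "character", generations_run = "integer",
    generations_to_fixation = "integer",
    generations_to_equilibrium = "integer", error = "character"
  ))
  out <- tibble::as_tibble(out)
  structure(out, class = c("achiasma_sweep", class(tibble::tibble())))
}

#' Write / read a heatmap TSV
#'
#' Axis values occupy the first row (coding length `L`) and first column
#' (`s` or `k`); the top-left cell names the row axis. Values are written
#' with 17 significant digits.
#'
#' @param m An `achiasma_heatmap` matrix from [heatmap_matrix()].
#' @param path Output file.
#' @return `path` invisibly (write) or a plain numeric matrix with axis
#'   dimnames (read).
#' @export
write_heatmap_tsv <- function(m, path) {
  stopifnot(inherits(m, "achiasma_heatmap"))
  fmt <- function(x) sprintf("%.17g", x)
  header <- paste(
    c(attr(m, "s_or_k"), fmt(attr(m, "col_values"))),
    collapse = "\t"
  )
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(
      fmt(attr(m, "row_values")[i]),
      fmt(unclass(m)[i, ])
    ), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_heatmap_tsv
#' @export
read_heatmap_tsv <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  cols <- as.numeric(header[-1L])
  body <- do.call(rbind, lapply(lines[-1L], function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]])
  }))
  m <- body[, -1L, drop = FALSE]
  dimnames(m) <- list(
    sprintf("%.17g", body[, 1L]), sprintf("%.17g", cols)
  )
  m
}

#' Write a provenance sidecar JSON for a sweep
#'
#' Records the design dimensions, shared parameters and package version
#' needed to reproduce a sweep exactly.
#'
#' @param design An `achiasma_design` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_provenance_json <- function(design, path) {
  defaults <- attr(design, "defaults")
  out <- list(
    package = "achiasma",
    package_version = as.character(utils::packageVersion("achiasma")),
    n_conditions = nrow(design),
    locations = unique(design$location),
    models = unique(design$model),
    L_values = sort(unique(design$L)),
    s_values = sort(unique(design$s[design$model == "sexual_antagonism"])),
    h_values = sort(unique(design$h[design$model == "sexual_antagonism"])),
    k_values = sort(unique(design$k[design$model == "aneuploidy"])),
    R1 = unique(design$R1),
    shared_defaults = unclass(defaults)
  )
  jsonlite::write_json(out, path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}
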