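# Factorial experiment machinery: grids over exposed coding length (L),
# selection coefficient (s), dominance (h) and aneuploidy rate (k),
# crossed with mutation locations, under the exclusivity rule that the
# sexual-antagonism conditions set k = 0 and the aneuploidy conditions
# set s = 0.

#' Default parameter grids
#'
#' The published factorial uses 200 values per axis: exposed coding
#' length `L` from 0 to 5 Mb in 25 kb increments (0 included, the 5 Mb
#' endpoint excluded, so 200 values), selection coefficients spanning
#' (0, 0.5\] and aneuploidy rates spanning (0, 0.05\] (the zero endpoint
#' of each is the other model's baseline, so it is excluded and the upper
#' endpoint included).
#'
#' @param n Number of grid points per axis.
#' @param L_max,L_step Upper limit (exclusive) and increment of the
#'   coding-length grid, in sites.
#' @param s_max,k_max Upper limits (inclusive) of the selection and
#'   aneuploidy grids.
#' @return A list with numeric vectors `L_grid`, `s_grid`, `k_grid`,
#'   each strictly increasing, each of length `n`.
#' @examples
#' str(default_grids())
#' @export
default_grids <- function(n = 200L, L_max = 5e6, L_step = 25e3,
                          s_max = 0.5, k_max = 0.05) {
  list(
    L_grid = L_step * (seq_len(n) - 1),
    s_grid = s_max * seq_len(n) / n,
    k_grid = k_max * seq_len(n) / n
  )
}

# Every `stride`-th grid value, keeping the first.
stride_grid <- function(grid, stride) {
  grid[seq(1L, length(grid), by = as.integer(stride))]
}

#' Materialise a factorial sweep design
#'
#' Builds the full condition list: for every location and every `L`, the
#' sexual-antagonism conditions (each `s` in `s_grid` crossed with each
#' `h`, with `k = 0`) followed by the aneuploidy conditions (each `k` in
#' `k_grid`, with `s = 0`). The condition count is therefore
#' `|locations| * |L_grid| * (|s_grid| * |h_values| + |k_grid|)`; the
#' published grids give 3 * 200 * (200 * 3 + 200) = 480,000. Ordering is
#' deterministic: location, then `L`, then the s-by-h block, then the k
#' block.
#'
#' @param locations Character subset of `c("autosome", "X", "Y")`.
#' @param L_grid,s_grid,k_grid Numeric grids (see [default_grids()]).
#' @param h_values Dominance factors for the sexual-antagonism
#'   conditions.
#' @param R1 Recombination fraction between sex-determining and sexually
#'   antagonistic locus, shared by all conditions.
#' @param models Which condition blocks to include:
#'   `"sexual_antagonism"`, `"aneuploidy"`, or both (the default, the
#'   published design).
#' @param defaults An [model_params()] object supplying the
#'   remaining shared parameters (mutation rate, per-mutation effect,
#'   initial frequency, stopping rules).
#' @return A tibble of class `achiasma_design`, one row per condition,
#'   with columns `condition`, `model` (`"sexual_antagonism"` /
#'   `"aneuploidy"`), `location`, `L`, `s`, `h`, `k`, `R1`, `R2`.
#' @examples
#' g <- default_grids(n = 4)
#' build_design(locations = "Y", L_grid = g$L_grid, s_grid = g$s_grid,
#'   k_grid = g$k_grid)
#' @export
build_design <- function(locations = c("autosome", "X", "Y"),
                         L_grid = default_grids()$L_grid,
                         s_grid = default_grids()$s_grid,
                         k_grid = default_grids()$k_grid,
                         h_values = c(0, 0.5, 1),
                         R1 = 0.1,
                         models = c("sexual_antagonism", "aneuploidy"),
                         defaults = model_params()) {
  stopifnot(inherits(defaults, "achiasma_params"))
  models <- match.arg(models, several.ok = TRUE)
  if (!all(locations %in% c("autosome", "X", "Y"))) {
    stop("`locations` must be a subset of {autosome, X, Y}.", call. = FALSE)
  }
  for (nm in c("L_grid", "s_grid", "k_grid", "h_values")) {
    v <- get(nm)
    if (any(v < 0)) stop(sprintf("`%s` has negative values.", nm), call. = FALSE)
  }
  if (any(k_grid >= 1)) stop("`k_grid` values must be < 1.", call. = FALSE)

  if (length(locations) == 0L) {
    des <- tibble::tibble(
      condition = integer(), model = character(), location = character(),
      L = numeric(), s = numeric(), h = numeric(), k = numeric(),
      R1 = numeric(), R2 = numeric()
    )
  } else {
    # Per (location, L): the s-by-h block (k = 0), then the k block (s = 0).
    blocks <- list()
    if ("sexual_antagonism" %in% models) {
      sa_block <- tidyr::expand_grid(s = s_grid, h = h_values)
      sa_block$k <- 0
      sa_block$model <- "sexual_antagonism"
      blocks <- c(blocks, list(sa_block))
    }
    if ("aneuploidy" %in% models) {
      blocks <- c(blocks, list(tibble::tibble(
        s = 0, h = defaults$h, k = k_grid, model = "aneuploidy"
      )))
    }
    blocks <- dplyr::bind_rows(blocks)
    des <- tidyr::expand_grid(
      location = locations, L = L_grid, blocks
    )
    des$R1 <- R1
    des$R2 <- ifelse(des$location == "autosome", 0.5, defaults$R2)
    des$condition <- seq_len(nrow(des))
    des <- dplyr::select(
      des, "condition", "model", "location", "L", "s", "h", "k", "R1", "R2"
    )
  }
  structure(des,
    class = c("achiasma_design", class(des)),
    defaults = defaults
  )
}

#' Run every condition of a sweep design
#'
#' Calls [iterate_model()] once per design row. Conditions are
#' independent and the model is deterministic, so results do not depend
#' on execution order. A condition that errors is recorded in the `error`
#' column rather than aborting the sweep.
#'
#' @param design An `achiasma_design` tibble from [build_design()].
#' @param progress Print progress every `progress` conditions to stderr
#'   (0 = silent).
#' @return A tibble of class `achiasma_sweep`: the design columns plus
#'   `final_frequency` (within-class), `outcome`, `generations_run`,
#'   `generations_to_fixation`, `generations_to_equilibrium`, `error`.
#' @examples
#' g <- default_grids(n = 2)
#' d <- build_design(locations = "Y", L_grid = 0, s_grid = g$s_grid,
#'   k_grid = g$k_grid, h_values = 0.5)
#' run_sweep(d)
#' @export
run_sweep <- function(design, progress = 0) {
  stopifnot(inherits(design, "achiasma_design"))
  defaults <- attr(design, "defaults")
  n <- nrow(design)
  final_frequency <- numeric(n)
  outcome <- character(n)
  generations_run <- integer(n)
  generations_to_fixation <- rep(NA_integer_, n)
  generations_to_equilibrium <- rep(NA_integer_, n)
  err <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    row <- design[i, ]
    res <- tryCatch(
      {
        p <- condition_params(row, defaults)
        iterate_model(p, record_trajectory = FALSE)
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      err[i] <- conditionMessage(res)
      final_frequency[i] <- NA_real_
      outcome[i] <- NA_character_
    } else {
      final_frequency[i] <- res$final_frequency
      outcome[i] <- res$outcome
      generations_run[i] <- res$generations_run
      generations_to_fixation[i] <- res$generations_to_fixation
      generations_to_equilibrium[i] <- res$generations_to_equilibrium
    }
    if (progress > 0 && (i %% progress == 0L || i == n)) {
      message(sprintf("sweep: %d / %d conditions done", i, n))
    }
  }

  out <- dplyr::bind_cols(
    tibble::as_tibble(design),
    tibble::tibble(
      final_frequency, outcome, generations_run,
      generations_to_fixation, generations_to_equilibrium,
      error = err
    )
  )
  structure(out,
    class = c("achiasma_sweep", class(tibble::tibble())),
    defaults = defaults
  )
}

# ModelParams for one design row.
condition_params <- function(row, defaults) {
  p <- defaults
  p$location <- row$location
  p$L <- row$L
  p$s <- row$s
  p$h <- row$h
  p$k <- row$k
  p$R1 <- row$R1
  p$R2 <- if (row$location == "autosome") 0.5 else row$R2
  p
}

#' Extract one heatmap matrix from a sweep result
#'
#' Final achiasmy-allele frequencies for one (location, model) slice,
#' arranged with the varying selective parameter (`s` for the
#' sexual-antagonism model, `k` for the aneuploidy model) on the rows and
#' the exposed coding length `L` on the columns — the layout of the
#' published invasion heatmaps.
#'
#' @param result An `achiasma_sweep` tibble.
#' @param location One of `"autosome"`, `"X"`, `"Y"`.
#' @param model `"sexual_antagonism"` or `"aneuploidy"`.
#' @param h For the sexual-antagonism model with several dominance
#'   values, which `h` slice to extract (default: the single value
#'   present, else an error).
#' @return A numeric matrix of class `achiasma_heatmap` with `dimnames`
#'   set to the axis values and attributes `s_or_k` (row-axis name),
#'   `location`, `model`.
#' @export
heatmap_matrix <- function(result, location, model, h = NULL) {
  stopifnot(inherits(result, "achiasma_sweep"))
  model <- match.arg(model, c("sexual_antagonism", "aneuploidy"))
  location <- match.arg(location, c("autosome", "X", "Y"))
  sl <- result[result$model == model & result$location == location, ]
  if (model == "sexual_antagonism") {
    hs <- unique(sl$h)
    if (is.null(h)) {
      if (length(hs) > 1L) {
        stop("Slice contains several dominance values; pass `h`.",
          call. = FALSE
        )
      }
      h <- hs
    }
    sl <- sl[sl$h == h, ]
    row_var <- "s"
  } else {
    row_var <- "k"
  }
  if (nrow(sl) == 0L) {
    stop("Requested slice is not present in the sweep result.",
      call. = FALSE
    )
  }
  rows <- sort(unique(sl[[row_var]]))
  cols <- sort(unique(sl$L))
  if (nrow(sl) != length(rows) * length(cols) ||
    anyNA(sl$final_frequency)) {
    stop("Requested slice is incomplete (missing or failed cells).",
      call. = FALSE
    )
  }
  m <- matrix(NA_real_, length(rows), length(cols),
    dimnames = list(format(rows, trim = TRUE), format(cols, trim = TRUE))
  )
  m[cbind(match(sl[[row_var]], rows), match(sl$L, cols))] <-
    sl$final_frequency
  structure(m,
    class = c("achiasma_heatmap", "matrix", "array"),
    s_or_k = row_var, location = location, model = model,
    row_values = rows, col_values = cols
  )
}

#' Plot an invasion heatmap
#'
#' @param object An `achiasma_heatmap` matrix from [heatmap_matrix()].
#' @param ... Unused.
#' @return A ggplot: final achiasmy-allele frequency over the
#'   (selection-or-aneuploidy, coding length) grid.
#' @export
autoplot.achiasma_heatmap <- function(object, ...) {
  d <- tidyr::expand_grid(
    row = attr(object, "row_values"),
    col = attr(object, "col_values")
  )
  d$final_frequency <- as.vector(t(unclass(object)))
  row_lab <- if (attr(object, "s_or_k") == "s") {
    "Selection coefficient s"
  } else {
    "Aneuploidy rate k"
  }
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$col, y = .data$row, fill = .data$final_frequency)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "Final\nfrequency") +
    ggplot2::labs(
      x = "Exposed coding length L (sites)", y = row_lab,
      title = sprintf(
        "%s, %s-located mutation",
        gsub("_", " ", attr(object, "model")), attr(object, "location")
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.achiasma_heatmap
#' @param x An `achiasma_heatmap` object.
#' @param y Unused.
#' @export
plot.achiasma_heatmap <- function(x, y, ...) {
  print(autoplot.achiasma_heatmap(x, ...))
}
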