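#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation trajectory
#'
#' Returns the census series in long form: one row per step, species class
#' and count, ready for plotting or summarising with dplyr.
#'
#' @param x an `rw_trajectory`.
#' @param ... unused.
#' @return A tibble with columns `step`, `class`, `count`.
#' @export
tidy.rw_trajectory <- function(x, ...) {
  x$census |>
    dplyr::select("step", "rep", "nsr", "asr", "control", "other_rna") |>
    tidyr::pivot_longer(-"step", names_to = "class", values_to = "count")
}

#' @describeIn tidy.rw_trajectory one-row summary: final counts, protocell
#'   total, and whether each ribozyme exceeded the inoculum threshold.
#' @param threshold spread threshold for the summary flags.
#' @export
glance.rw_trajectory <- function(x, threshold = x$params$spread_threshold, ...) {
  last <- x$census[nrow(x$census), ]
  tibble::tibble(
    steps = last$step, rep = last$rep, nsr = last$nsr, asr = last$asr,
    control = last$control, other_rna = last$other_rna,
    cells_total = last$cells_total,
    rep_spread = last$rep > threshold, nsr_spread = last$nsr > threshold,
    asr_spread = last$asr > threshold)
}

#' Plot a census trajectory
#'
#' Copy-number time series per RNA class (the time-series figure layout).
#'
#' @param object an `rw_trajectory`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.rw_trajectory <- function(object, ...) {
  cols <- c(rep = "#d62728", nsr = "#2ca02c", asr = "#1f77b4",
            control = "#7f7f7f", other_rna = "#c7c7c7")
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$step, y = .data$count,
                                 colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = cols) +
    ggplot2::labs(x = "Monte-Carlo step", y = "copies", colour = NULL)
}

#' @export
tidy.rw_sweep <- function(x, ...) {
  x |>
    tidyr::pivot_longer(c("rep", "nsr", "asr", "control",
                          "co_rep_nsr_asr", "co_rep_asr"),
                        names_to = "species", values_to = "spread_cases")
}

#' Plot a spreading-chance sweep
#'
#' Spreading-case counts per parameter value (the sweep bar-chart layout).
#'
#' @param object an `rw_sweep` tibble from [run_sweep()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.rw_sweep <- function(object, ...) {
  tidy(object) |>
    dplyr::filter(.data$species %in% c("rep", "nsr", "asr", "control")) |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$value),
                                 y = .data$spread_cases,
                                 fill = .data$species)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(rep = "#d62728", nsr = "#2ca02c",
                                          asr = "#1f77b4",
                                          control = "#7f7f7f")) +
    ggplot2::labs(x = unique(object$parameter), y = "spreading cases",
                  fill = NULL)
}

#' Write sweep results as tidy CSV
#'
#' @param x an `rw_sweep`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
rw_write_sweep <- function(x, path) {
  readr::write_csv(tidy(x), path)
  invisible(path)
}

#' Write a census series as CSV
#'
#' @param x an `rw_trajectory`.
#' @param path output path.
#' @param scale optional display scale divisor applied to the precursor
#'   column (`np`), matching the published 1/200 display convention; raw
#'   counts are written when `NULL`.
#' @return The path, invisibly.
#' @export
rw_write_census <- function(x, path, scale = NULL) {
  cs <- x$census
  if (!is.null(scale)) cs$np <- cs$np / scale
  readr::write_csv(cs, path)
  invisible(path)
}
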