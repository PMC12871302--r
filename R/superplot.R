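#' Replicate-aware (SuperPlot) summary
#'
#' Summarizes measurements hierarchically: units (axons, fields, wells)
#' are first averaged within each (genotype, biological replicate), the
#' genotype grand mean is the unweighted mean of those replicate means,
#' and the reported dispersion is the SD of replicate means (n - 1
#' denominator) — never the SD of pooled units, which would
#' pseudoreplicate.  Genotypes with a single replicate are flagged and
#' get an undefined SD.
#'
#' @param data tibble with one row per unit.
#' @param value column holding the measured value (tidy-eval).
#' @param genotype,replicate grouping columns (tidy-eval; defaults
#'   `genotype`, `replicate_id`).
#' @return Object of class `superplot_summary`: list of tibbles
#'   `replicates` (`genotype`, `replicate_id`, `rep_mean`, `n_units`) and
#'   `genotypes` (`genotype`, `grand_mean`, `sd_rep`, `n_replicates`,
#'   `flagged`).
#' @examples
#' d <- tibble::tibble(genotype = "WT", replicate_id = rep(1:2, each = 3),
#'                     value = c(1, 2, 3, 3, 4, 5))
#' superplot_summarize(d, value)
#' @export
superplot_summarize <- function(data, value, genotype = genotype,
                                replicate = replicate_id) {
  if (!nrow(data)) abort_bad_arg("empty measurement table")
  reps <- data |>
    dplyr::group_by(genotype = {{ genotype }}, replicate_id = {{ replicate }}) |>
    dplyr::summarise(rep_mean = mean({{ value }}), n_units = dplyr::n(),
                     .groups = "drop")
  geno <- reps |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(
      grand_mean = mean(.data$rep_mean),
      sd_rep = if (dplyr::n() > 1) stats::sd(.data$rep_mean) else NA_real_,
      n_replicates = dplyr::n(),
      flagged = dplyr::n() < 2,
      .groups = "drop")
  structure(list(replicates = reps, genotypes = geno),
            class = "superplot_summary")
}

#' @export
print.superplot_summary <- function(x, ...) {
  cat("<superplot_summary>\n")
  print(x$genotypes)
  invisible(x)
}

#' @rdname superplot_summarize
#' @param x a `superplot_summary`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.superplot_summary <- function(x, ...) x$genotypes

#' SuperPlot of unit-level data with replicate means
#'
#' Jittered unit-level points at half opacity, with larger open symbols
#' at each replicate mean and an error bar of +/- SD of replicate means,
#' shapes mapped to the biological replicate.
#'
#' @inheritParams superplot_summarize
#' @return A ggplot object.
#' @export
plot_superplot <- function(data, value, genotype = genotype,
                           replicate = replicate_id) {
  s <- superplot_summarize(data, {{ value }}, {{ genotype }}, {{ replicate }})
  dd <- dplyr::mutate(data, .genotype = {{ genotype }},
                      .replicate = factor({{ replicate }}),
                      .value = {{ value }})
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$.genotype, y = .data$.value)) +
    ggplot2::geom_jitter(ggplot2::aes(shape = .data$.replicate),
                         width = 0.15, alpha = 0.5) +
    ggplot2::geom_point(data = dplyr::mutate(s$replicates,
                                             .replicate = factor(.data$replicate_id)),
                        ggplot2::aes(x = .data$genotype, y = .data$rep_mean,
                                     shape = .data$.replicate),
                        size = 4, stroke = 1.1, fill = NA) +
    ggplot2::geom_errorbar(data = s$genotypes,
                           ggplot2::aes(x = .data$genotype,
                                        y = .data$grand_mean,
                                        ymin = .data$grand_mean - .data$sd_rep,
                                        ymax = .data$grand_mean + .data$sd_rep),
                           width = 0.2) +
    ggplot2::scale_shape_manual(values = c(21, 22, 24, 23, 25)[
      seq_along(unique(dd$.replicate))]) +
    ggplot2::labs(x = NULL, shape = "replicate") +
    ggplot2::theme_classic()
}
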