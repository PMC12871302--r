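#' Default pipeline configuration
#'
#' @param seed master seed; per-stage seeds are derived as small fixed
#'   offsets from it.
#' @param out_dir output directory (created if needed); `NULL` keeps
#'   results in memory only.
#' @param genotypes genotype labels to run.
#' @param stages analysis stages to execute, a subset of
#'   `c("transport", "comets", "mea", "qpcr", "synapse")`.
#' @param n_axons axons per genotype for the imaging stages.
#' @param duration_s movie / recording duration per unit.
#' @param n_replicates biological replicates for SuperPlot grouping.
#' @return A named list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1, out_dir = NULL,
                           genotypes = c("WT", "C92X", "P305L", "R350G"),
                           stages = c("transport", "comets", "mea", "qpcr", "synapse"),
                           n_axons = 9, duration_s = 300, n_replicates = 3) {
  list(seed = seed, out_dir = out_dir, genotypes = genotypes, stages = stages,
       n_axons = n_axons, duration_s = duration_s, n_replicates = n_replicates)
}

#' Run the full synthetic-generation + analysis pipeline
#'
#' For each requested stage and genotype: generate ground-truth data,
#' run the corresponding analysis, and aggregate unit-level results with
#' the replicate-aware SuperPlot summary.  With `out_dir` set, tidy CSV
#' tables and a JSON run manifest (seed, parameters, package version)
#' are written; outputs are a pure function of the configuration.
#'
#' @param config list from [default_config()].
#' @return (Invisibly) a named list of stage result tibbles plus the
#'   manifest.
#' @examples
#' res <- run_pipeline(default_config(seed = 1, stages = "qpcr"))
#' res$qpcr
#' @export
run_pipeline <- function(config = default_config()) {
  known <- c("transport", "comets", "mea", "qpcr", "synapse")
  bad <- setdiff(config$stages, known)
  if (length(bad)) {
    rlang::abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
                 class = "axonsynkit_config_error")
  }
  res <- list()
  reps <- seq_len(config$n_replicates)

  if ("transport" %in% config$stages) {
    rows <- purrr::map(config$genotypes, function(g) {
      purrr::map(reps, function(r) {
        p <- genotype_params(g)
        trk <- gen_svp_tracks(p, config$n_axons, config$duration_s,
                              seed = config$seed + 11 * r + stage_offset(g))
        summarize_transport(trk, config$duration_s) |>
          dplyr::mutate(genotype = g, replicate_id = r, .before = 1)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    res$transport <- rows
    res$transport_superplot <- tidy(superplot_summarize(rows, .data$antero_flux))
  }

  if ("comets" %in% config$stages) {
    rows <- purrr::map(config$genotypes, function(g) {
      purrr::map(reps, function(r) {
        p <- genotype_params(g)
        ax <- gen_comet_site_axon(p, config$n_axons, 100, config$duration_s,
                                  seed = config$seed + 101 + 11 * r + stage_offset(g))
        purrr::map(seq_len(config$n_axons), function(a) {
          s <- ax$sites[ax$sites$axon_id == a, ]
          k <- ax$comets[ax$comets$axon_id == a, ]
          assoc <- associate_comets(k, s)
          tibble::tibble(
            genotype = g, replicate_id = r, axon_id = a,
            site_density = site_density(s, 100),
            comet_density = comet_density(k, 100, config$duration_s),
            frac_comets_assoc = if (nrow(k)) mean(assoc$associated) else NA_real_,
            frac_sites_active = suppressWarnings(sites_with_comets(s, k)))
        }) |> dplyr::bind_rows()
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    res$comets <- rows
    res$comet_regression <- rows |>
      dplyr::group_by(.data$genotype) |>
      dplyr::group_modify(~ glance(density_regression(.x))) |>
      dplyr::ungroup()
  }

  if ("mea" %in% config$stages) {
    rows <- purrr::map(config$genotypes, function(g) {
      purrr::map(reps, function(r) {
        p <- coculture_params(genotype_params(g))
        rec <- gen_mea_recording(p, duration_s = min(config$duration_s, 300),
                                 seed = config$seed + 202 + 11 * r + stage_offset(g),
                                 well_id = sprintf("%s_r%d", g, r))
        summarize_well(rec) |>
          dplyr::mutate(genotype = g, replicate_id = r, .before = 1)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    res$mea <- rows
  }

  if ("qpcr" %in% config$stages) {
    rel <- stats::setNames(
      purrr::map_dbl(config$genotypes, ~ genotype_params(.x)$rel_expr),
      config$genotypes)
    ct <- gen_ct_table(rel, noise_sd = 0.15, n_reps = config$n_replicates,
                       seed = config$seed + 303)
    res$qpcr_ct <- ct
    res$qpcr <- delta_delta_ct(ct)
  }

  if ("synapse" %in% config$stages) {
    frac <- c(WT = 0.6, C92X = 0.45, P305L = 0.5, R350G = 0.5)
    rows <- purrr::map(config$genotypes, function(g) {
      purrr::map(reps, function(r) {
        f <- gen_synapse_field(120, unname(frac[g]),
                               seed = config$seed + 404 + 11 * r + stage_offset(g))
        m <- match_appositions(f$pre, f$post, f$max_gap_um)
        synapse_table(f$pre, f$post, m, f$map2_area_um2) |>
          dplyr::mutate(genotype = g, replicate_id = r, .before = 1)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    res$synapse <- rows
    counts <- rbind(apposed = rows$n_matched, lone = rows$n_pre - rows$n_matched)
    counts <- t(rowsum(t(counts), rows$genotype))
    res$synapse_chisq <- chi_square_independence(counts)
  }

  res$manifest <- list(
    seed = config$seed, genotypes = config$genotypes, stages = config$stages,
    n_axons = config$n_axons, duration_s = config$duration_s,
    n_replicates = config$n_replicates,
    package_version = as.character(utils::packageVersion("axonsynkit")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in setdiff(names(res), "manifest")) {
      if (is.data.frame(res[[nm]])) {
        readr::write_csv(res[[nm]], file.path(config$out_dir, paste0(nm, ".csv")))
      }
    }
    jsonlite::write_json(res$manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

# deterministic small per-genotype seed offset
stage_offset <- function(genotype) {
  match(genotype, c("WT", "C92X", "P305L", "R350G"), nomatch = 5L) * 1000L
}
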