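#' Generate a synthetic Ct table
#'
#' Builds a tidy qRT-PCR cycle-threshold table with a housekeeping gene
#' and a target gene whose per-genotype relative expression is exactly
#' `rel_expr`: the target Ct for genotype g is
#' `ct_ref - log2(rel_expr[g]) + noise`, housekeeping Ct is
#' `ct_housekeeping + noise`.
#'
#' @param rel_expr named vector of relative expression fractions (> 0),
#'   e.g. `c(WT = 1, C92X = 0.15)`; the reference genotype should be 1.
#' @param ct_ref reference-genotype target Ct (cycles).
#' @param ct_housekeeping housekeeping Ct (cycles).
#' @param noise_sd Gaussian Ct noise SD (cycles).
#' @param n_reps biological replicates per genotype (>= 1).
#' @param target_gene,housekeeping_gene gene labels.
#' @param seed integer seed.
#' @return Tidy tibble: `sample_id`, `genotype`, `replicate_id`, `gene`,
#'   `ct`.
#' @examples
#' gen_ct_table(c(WT = 1, C92X = 0.15), noise_sd = 0, n_reps = 1, seed = 1)
#' @export
gen_ct_table <- function(rel_expr, ct_ref = 20, ct_housekeeping = 15,
                         noise_sd = 0.2, n_reps = 3,
                         target_gene = "KIF1A", housekeeping_gene = "GAPDH",
                         seed = NULL) {
  if (any(rel_expr <= 0)) abort_bad_arg("`rel_expr` values must be > 0")
  if (n_reps < 1) abort_bad_arg("`n_reps` must be >= 1")
  local_seed_if(seed)
  grid <- tidyr::expand_grid(genotype = names(rel_expr),
                             replicate_id = seq_len(n_reps))
  grid$sample_id <- paste(grid$genotype, grid$replicate_id, sep = "_")
  target <- dplyr::mutate(grid, gene = target_gene,
                          ct = ct_ref - log2(unname(rel_expr[.data$genotype])) +
                            stats::rnorm(dplyr::n(), 0, noise_sd))
  hk <- dplyr::mutate(grid, gene = housekeeping_gene,
                      ct = ct_housekeeping + stats::rnorm(dplyr::n(), 0, noise_sd))
  dplyr::bind_rows(target, hk) |>
    dplyr::select("sample_id", "genotype", "replicate_id", "gene", "ct") |>
    dplyr::arrange(.data$genotype, .data$replicate_id, .data$gene)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Livak delta-delta-Ct with housekeeping normalization: per sample,
#' `dCt = Ct(target) - Ct(housekeeping)`; per genotype,
#' `ddCt = mean dCt - mean dCt(reference)`; relative expression is
#' `2^-ddCt` (the reference genotype returns exactly 1).  With
#' `per_sample = TRUE`, `2^-ddCt` is instead computed per sample against
#' the reference mean dCt and then averaged per genotype.
#'
#' @param table tidy Ct tibble (`sample_id`, `genotype`, `gene`, `ct`).
#' @param target_gene,housekeeping_gene gene labels (defaults KIF1A /
#'   GAPDH).
#' @param reference_genotype baseline genotype (default `"WT"`).
#' @param per_sample average per-sample fold changes instead of the
#'   aggregate Livak form.
#' @return Tibble `genotype`, `n`, `delta_ct`, `delta_delta_ct`,
#'   `rel_expr`.
#' @examples
#' ct <- gen_ct_table(c(WT = 1, C92X = 0.15), noise_sd = 0, n_reps = 2, seed = 1)
#' delta_delta_ct(ct)
#' @export
delta_delta_ct <- function(table, target_gene = "KIF1A",
                           housekeeping_gene = "GAPDH",
                           reference_genotype = "WT", per_sample = FALSE) {
  tg <- table[table$gene == target_gene, ]
  hk <- table[table$gene == housekeeping_gene, ]
  if (!nrow(tg)) abort_bad_arg("target gene absent from table")
  if (!all(tg$sample_id %in% hk$sample_id)) {
    abort_bad_arg("housekeeping gene missing for some samples")
  }
  if (!reference_genotype %in% tg$genotype) {
    abort_bad_arg("reference genotype absent from table")
  }
  dct <- dplyr::inner_join(
    dplyr::select(tg, "sample_id", "genotype", ct_target = "ct"),
    dplyr::select(hk, "sample_id", ct_hk = "ct"),
    by = "sample_id") |>
    dplyr::mutate(dct = .data$ct_target - .data$ct_hk)
  ref_mean <- mean(dct$dct[dct$genotype == reference_genotype])
  if (per_sample) {
    dct |>
      dplyr::group_by(.data$genotype) |>
      dplyr::summarise(n = dplyr::n(),
                       delta_ct = mean(.data$dct),
                       delta_delta_ct = mean(.data$dct) - ref_mean,
                       rel_expr = mean(2^-(.data$dct - ref_mean)),
                       .groups = "drop")
  } else {
    dct |>
      dplyr::group_by(.data$genotype) |>
      dplyr::summarise(n = dplyr::n(), delta_ct = mean(.data$dct), .groups = "drop") |>
      dplyr::mutate(delta_delta_ct = .data$delta_ct - ref_mean,
                    rel_expr = 2^-.data$delta_delta_ct)
  }
}
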