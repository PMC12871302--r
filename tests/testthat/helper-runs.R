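# Cached full-pipeline runs shared across test files (generate -> render ->
# trace -> summarize is the expensive step; several checks reuse one run).

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# per-axon transport summaries from the traced pipeline
traced_transport_run <- function(genotype, n_axons, seed0 = 42) {
  key <- sprintf("transport_%s_%d_%d", genotype, n_axons, seed0)
  cached(key, {
    p <- genotype_params(genotype)
    dplyr::bind_rows(lapply(seq_len(n_axons), function(ax) {
      trk <- gen_svp_tracks(p, n_axons = 1, seed = seed0 + ax)
      k <- render_kymograph(trk, length_um = 100, duration_s = 300,
                            seed = seed0 + 10000 + ax)
      tr <- trace_tracks(k)
      dplyr::mutate(summarize_transport(tr, 300), axon_id = ax)
    }))
  })
}

# per-axon detected site densities from rendered comet-mode kymographs
detected_site_run <- function(genotype, n_axons, seed0 = 42) {
  key <- sprintf("sites_%s_%d_%d", genotype, n_axons, seed0)
  cached(key, {
    p <- genotype_params(genotype)
    vapply(seq_len(n_axons), function(ax) {
      field <- gen_comet_site_axon(p, n_axons = 1, length_um = 100,
                                   duration_s = 300, seed = seed0 + 500 + ax)
      k <- render_kymograph(sites = field$sites, length_um = 100,
                            duration_s = 300, dt_s = 1,
                            seed = seed0 + 20000 + ax)
      site_density(detect_svp_sites(k), 100)
    }, numeric(1))
  })
}

# end-to-end MEA voltage pipeline mean firing rate for one well
traced_well_mfr <- function(params, duration_s, seed) {
  rec <- gen_mea_recording(params, duration_s = duration_s, seed = seed,
                           with_traces = TRUE)
  rec <- detect_mea_spikes(rec)
  suppressWarnings(mean_firing_rate(rec))
}
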