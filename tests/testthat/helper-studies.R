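# The replicate studies behind the acceptance tests are expensive, so they
# are computed once per test run and cached for every block that scores
# them. Seeds are fixed; 20 replicates per study.

.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function(key) {
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  st <- switch(key,
    s1_iscc = run_replicates(simulation_spec("S1", seed = 20100L),
                             method = "iscc", R = 20L),
    s1_scc = run_replicates(simulation_spec("S1", seed = 20100L),
                            method = "scc", R = 20L),
    s2_iscc = run_replicates(simulation_spec("S2", seed = 20200L),
                             method = "iscc", R = 20L),
    s3_iscc = run_replicates(simulation_spec("S3", seed = 20300L),
                             method = "iscc", R = 20L),
    s1_both = run_replicates(simulation_spec("S1", theta_both = 0.7,
                                             seed = 20400L),
                             method = "iscc", R = 20L),
    s2_both = run_replicates(simulation_spec("S2", theta_both = 0.7,
                                             seed = 20500L),
                             method = "iscc", R = 20L),
    stop("unknown study: ", key))
  .study_cache[[key]] <- st
  st
}
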