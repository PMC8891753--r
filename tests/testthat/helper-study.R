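# One shared study-scale pipeline run for the acceptance checks (built
# lazily, reused across test blocks so the expensive stages run once).

.study_cache <- new.env(parent = emptyenv())
.study_cache$suite_start <- Sys.time()

get_study_run <- function(seed = 7L) {
  if (is.null(.study_cache$run)) {
    study <- simulate_study(seed = seed)
    t0 <- Sys.time()
    run <- run_pipeline(
      proteome = study$proteome, panels = study$panels,
      site_annotations = study$binding_sites,
      ref_lhcf = study$ref_lhcf, lhcf_panel = study$lhcf_panel,
      species_class = study$species_class, lhcz_refs = study$lhcz_refs,
      config = fcp_config(seed = seed))
    .study_cache$elapsed <- as.numeric(Sys.time() - t0, units = "secs")
    .study_cache$study <- study
    .study_cache$run <- run
  }
  list(study = .study_cache$study, run = .study_cache$run,
       elapsed = .study_cache$elapsed,
       suite_start = .study_cache$suite_start)
}
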