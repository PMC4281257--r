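# Lazily cached default-scale simulated study shared by the end-to-end
# checks (50 scaffolds x 100 kb, 2e5 methyl-read copies per variant).
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- generate_genome(synthetic_config(seed = 1L))
      t0 <- Sys.time()
      res <- suppressMessages(suppressWarnings(run_pipeline(b)))
      elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      cache <<- list(bundle = b, result = res, elapsed = elapsed)
    }
    cache
  }
})
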