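# The reference planted-signal mixture (12 taxa, 20,000 sites, seed
# 42) drives several end-to-end checks. Scoring it is the expensive
# part of the suite, so it is computed once on first use and shared.

.mixture_cache <- new.env(parent = emptyenv())

default_mixture_results <- function() {
  if (!is.null(.mixture_cache$res)) return(.mixture_cache$res)
  sim <- simulate_mixture(mixture_spec())
  tab <- per_site_table(sim$alignment, sim$trees)
  records <- classify_sites(tab, 0.5)
  .mixture_cache$res <- list(sim = sim, tab = tab, records = records)
  .mixture_cache$res
}
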