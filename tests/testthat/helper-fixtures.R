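# Shared synthetic fixtures, cached per seed so the evaluation-scale tests
# do not regenerate networks and kernels repeatedly.

.bundle_cache <- new.env(parent = emptyenv())

fixture_bundle <- function(seed, rewired = FALSE, beta = 0.1) {
  key <- paste0("s", seed, if (rewired) "_rw" else "")
  if (!is.null(.bundle_cache[[key]])) return(.bundle_cache[[key]])
  fix <- generate_fixture(fixture_spec(seed = seed))
  nets <- fixture_networks(fix)
  if (rewired) {
    nets <- lapply(nets, rewire_degree_preserving, swaps_per_edge = 10,
                   seed = seed)
  }
  out <- list(fix = fix, nets = nets,
              imps = compute_importances(nets, beta = beta))
  .bundle_cache[[key]] <- out
  out
}

# Small fixture for CLI round trips: quick but structurally complete.
small_fixture_files <- function(dir, seed = 11) {
  spec <- fixture_spec(n_genes = 120, n_modules = 6, p_in = 0.3, p_out = 0.02,
                       rho = 0.8, n_arrays = 20, n_families = 4,
                       family_size = 5, seed = seed)
  write_fixture(generate_fixture(spec), dir)
}
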