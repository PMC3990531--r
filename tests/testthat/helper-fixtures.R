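# Expensive simulation fixtures shared across test files, computed at most
# once per test run.

.socnet_test_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .socnet_test_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .socnet_test_cache)
  }
  get(key, envir = .socnet_test_cache, inherits = FALSE)
}

# Free-running self-organization from isolated nodes (N = 256, theta = 0),
# long enough to converge; snapshots retained after the transient. Used for
# the fixed-ratio comparison and as the source of evolved critical networks.
fixture_free_run <- function() {
  cached_fixture("free_run", {
    evolve(
      make_random_network(256, 0),
      adaptation_config(n_epochs = 5000, snapshot_after = 4000, seed = 101)
    )
  })
}

fixture_critical_ensembles <- function() {
  cached_fixture("crit_ens", {
    ev <- fixture_free_run()
    picks <- round(seq(1, length(ev$snapshots), length.out = 3))
    lapply(seq_along(picks), function(i) {
      snap <- ev$snapshots[[picks[i]]]
      list(
        network = snap,
        ensemble = run_ensemble(snap, 1e5, t_e = 20, seed = 200 + i)
      )
    })
  })
}
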