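## Shared sensitivity panel: 10 achievable targets (30-60 nt, mixed
## topologies) with desired values realised by a reference sequence, and 5
## design runs per target.  Computed once, lazily, and reused by the
## sensitivity and shape-exactness acceptance tests.

.panel_store <- new.env(parent = emptyenv())

sensitivity_runs <- function() {
    if (!is.null(.panel_store$runs)) return(.panel_store$runs)
    panel <- generateBenchmarkPanel(n = 10L, lengths = c(30L, 60L),
                                    seed = 20260924L, backend = "toy")
    runs <- lapply(seq_along(panel), function(i) {
        set <- designSequences(panel[[i]]$goals, nRuns = 5L,
                               seed = 4000L + i, backend = "toy")
        list(goals = panel[[i]]$goals, df = as.data.frame(set))
    })
    .panel_store$runs <- runs
    runs
}
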