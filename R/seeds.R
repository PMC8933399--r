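# Counter-based expansion of the master seed into independent per-stage,
# per-unit seeds.  Adding a stage (new stage id) never perturbs the streams of
# existing stages, and all derived seeds stay below 2^31.
STAGE <- list(covariates = 1L, tractography = 2L, timeseries = 3L,
              mcs_degree = 4L, modularity_null = 5L, mcs_segregation = 6L,
              ancova = 7L, misc = 8L)

stage_seed <- function(master, stage, unit = 0L) {
  s <- (as.numeric(master) %% 2147483647) * 48271 +
    as.numeric(stage) * 1299709 + as.numeric(unit) * 7919
  as.integer(s %% 2147483647)
}
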