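# Small configurations shared across test files. Sizes are chosen so a run
# completes in well under a second while still exercising every code path.

tiny_config <- function(...) {
  args <- list(N = 30, C = 500, M = 12, n_traits = 8, m = 4, generations = 20)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# deterministic two-host, two-OTU population with hosts fixed on opposite
# OTUs and per-OTU scores (+1, -1) for both host and microbe
polarized_pop <- function(s_h = 10, s_m = 10, mode = "tms", ma = 100, me = 0) {
  cfg <- sim_config(N = 2, C = 10, M = 2, n_traits = 2, m = 1,
                    ma_percent = ma, me_percent = me,
                    s_h = s_h, s_m = s_m, microbial_mode = mode,
                    generations = 5,
                    phenomes = rbind(1L, 2L),
                    effects = list(host = c(1L, -1L), microbe = c(1L, -1L)),
                    init_counts = rbind(c(10, 0), c(0, 10)))
  seed_population(cfg)
}
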