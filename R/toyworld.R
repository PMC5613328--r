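# Toy worlds: tiny, fully specified configurations small enough that every
# one-step expectation (acquisition probabilities, reproduction
# probabilities, expected offspring counts) has a closed form, for use as
# oracles against the stochastic engine.

toy_world_presets <- function() {
  path <- system.file("extdata", "toy_worlds.yaml", package = "holosim",
                      mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Build a toy world from a frozen preset
#'
#' Presets (`"two-otu"`, `"neutral"`, `"antagonist"`) are fully explicit:
#' phenomes, effect tables and initial counts are all fixed, so
#' [seed_population()] consumes no randomness and the world is identical on
#' every load.
#'
#' @param preset preset name; see `names(holosim:::toy_world_presets())`.
#' @return a [sim_config()] with all components specified explicitly.
#' @examples
#' world <- make_toy_world("two-otu")
#' expectation_oracle(seed_population(world))
#' @export
make_toy_world <- function(preset) {
  presets <- toy_world_presets()
  if (!preset %in% names(presets))
    stop("unknown toy-world preset '", preset, "'; available: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[preset]]
  phenomes <- do.call(rbind, lapply(p$phenomes, as.integer))
  counts <- do.call(rbind, lapply(p$init_counts, as.numeric))
  sim_config(N = p$n_hosts, C = p$capacity, M = p$n_otus,
             n_traits = p$n_traits, m = p$m,
             ma_percent = p$ma_percent, me_percent = p$me_percent,
             s_h = p$s_h, s_m = p$s_m, microbial_mode = p$microbial_mode,
             generations = p$generations,
             phenomes = phenomes,
             effects = list(host = as.integer(p$host_effects),
                            microbe = as.integer(p$microbe_effects)),
             init_counts = counts)
}

#' Closed-form one-step expectations for a tiny population
#'
#' For a population small enough to enumerate (N <= 10, M <= 10, C <= 1000),
#' computes exactly: the reproduction probabilities q over parents, the
#' per-parent acquisition probability vectors p, the per-parent expected
#' offspring counts C*p, and the marginal expected counts of one offspring
#' slot, C * sum_parents q_p * p_p. These are the oracles Monte Carlo draws
#' from [step_population()] are compared against.
#'
#' @param pop a `holosim_population` (e.g. from a [make_toy_world()] config).
#' @return list with `q`, `p` (parents x OTU matrix), `per_parent_expected`
#'   (C*p), and `marginal_expected` (length-M vector).
#' @export
expectation_oracle <- function(pop) {
  cfg <- pop$config
  if (cfg$N > 10 || cfg$M > 10 || cfg$C > 1000)
    stop("world too large to enumerate: need N <= 10, M <= 10, C <= 1000")
  q <- reproduction_probabilities(host_fitness_vector(pop))
  env <- assemble_environment(pop$counts, pop$fixed_pool, cfg$me_percent)
  rel <- pop$counts / cfg$C
  p <- t(vapply(seq_len(cfg$N), function(i) {
    S <- source_community(rel[i, ], env, cfg$ma_percent)
    acquisition_probabilities(S, microbe_fitness_for(pop, pop$lineage[i]))
  }, numeric(cfg$M)))
  list(q = q,
       p = p,
       per_parent_expected = cfg$C * p,
       marginal_expected = cfg$C * drop(q %*% p))
}
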