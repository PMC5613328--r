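# The generation loop: host fitness evaluation, fitness-weighted Wright-Fisher
# reproduction, heritable HMS influence, environment refresh, and offspring
# microbiome acquisition. The update is strictly two-phase: all parental
# fitnesses and the environment are computed from the parental generation's
# final microbiomes before any offspring is created.

#' Simulation configuration
#'
#' Collects every tunable parameter of a run. Defaults follow the small-scale
#' setting (N = 500 hosts, C = 10^4 microbes per host, 150 OTUs, a 10-trait
#' pool with 5 traits per phenome, 10^4 generations); the large setting
#' (N = 5000, C = 10^9, 25 traits, 2x10^5 generations) runs through the same
#' code path.
#'
#' @param N host population size (constant across generations).
#' @param C microbiome capacity: slots per host, fixed for the whole run.
#' @param M number of microbial OTUs in the initial environmental pool.
#' @param n_traits size of the trait pool.
#' @param m traits per phenome (see [default_traits_per_phenome()]).
#' @param ma_percent parental percentage x of mixed acquisition, in [0, 100].
#' @param me_percent pooled-parental percentage y of the mixed environment.
#' @param s_h host selection coefficient (>= 1; 1 switches HS off).
#' @param s_m microbial selection coefficient (>= 1; 1 switches TMS/HMS off).
#' @param microbial_mode `"none"`, `"tms"` (universal trait scores) or
#'   `"hms"` (heritable host-lineage scores).
#' @param generations number of host generations to simulate.
#' @param record_every recording interval; `NULL` means
#'   `max(1, floor(generations / 200))`.
#' @param acquisition `"single"`: mix abundances first, then one multinomial
#'   draw of C slots (default); `"split"`: draw `round(C*x/100)` slots from the
#'   parent and the rest from the environment in two multinomials. The two
#'   schemes have identical marginal expectations.
#' @param effect_probs probability weights for (-1, 0, +1) effect scores.
#' @param phenomes,effects,hms,init_counts optional explicit components
#'   (used by toy worlds and restart-from-snapshot); when `NULL` they are
#'   drawn at seeding.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(N = 500, C = 10000, M = 150, n_traits = 10, m = 5,
                       ma_percent = 50, me_percent = 50,
                       s_h = 1, s_m = 1,
                       microbial_mode = c("none", "tms", "hms"),
                       generations = 10000, record_every = NULL,
                       acquisition = c("single", "split"),
                       effect_probs = c(1, 1, 1) / 3,
                       phenomes = NULL, effects = NULL, hms = NULL,
                       init_counts = NULL) {
  cfg <- list(N = N, C = C, M = M, n_traits = n_traits, m = m,
              ma_percent = ma_percent, me_percent = me_percent,
              s_h = s_h, s_m = s_m,
              microbial_mode = match.arg(microbial_mode),
              generations = generations, record_every = record_every,
              acquisition = match.arg(acquisition),
              effect_probs = effect_probs,
              phenomes = phenomes, effects = effects, hms = hms,
              init_counts = init_counts)
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (N < 1 || C < 1 || M < 1) stop("N, C and M must be at least 1")
    if (m > n_traits)
      stop("traits per phenome (m) cannot exceed trait pool size (n_traits)")
    if (ma_percent < 0 || ma_percent > 100 || me_percent < 0 || me_percent > 100)
      stop("ma_percent and me_percent must lie in [0, 100]")
    if (s_h < 1 || s_m < 1) stop("selection coefficients must be >= 1")
    if (generations < 0) stop("generations must be non-negative")
  })
  if (!is.null(cfg$phenomes) &&
      (nrow(cfg$phenomes) != cfg$M || ncol(cfg$phenomes) != cfg$m))
    stop("explicit phenomes must be an M x m matrix")
  if (!is.null(cfg$init_counts) &&
      (nrow(cfg$init_counts) != cfg$N || ncol(cfg$init_counts) != cfg$M))
    stop("explicit init_counts must be an N x M matrix")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("holosim configuration\n")
  cat(sprintf("  hosts N = %d, capacity C = %s, OTUs M = %d\n",
              x$N, format(x$C, big.mark = ","), x$M))
  cat(sprintf("  traits: pool n = %d, per phenome m = %d\n", x$n_traits, x$m))
  cat(sprintf("  acquisition MA(%g) * ME(%g), scheme '%s'\n",
              x$ma_percent, x$me_percent, x$acquisition))
  cat(sprintf("  selection: s_h = %g, s_m = %g, microbial mode '%s'\n",
              x$s_h, x$s_m, x$microbial_mode))
  cat(sprintf("  generations = %d\n", as.integer(x$generations)))
  invisible(x)
}

# Per-run caches derived once from phenomes + effect tables: per-OTU host
# scores, per-context microbial fitness, OTU classes, per-lineage consistency.
build_cache <- function(cfg, phenomes, effects, hms) {
  host_score_otu <- otu_trait_scores(phenomes, effects$host)
  cache <- list(
    otu_host_score = host_score_otu,
    otu_class = classify_otu(phenomes, effects$host))
  if (cfg$microbial_mode == "hms") {
    # one microbial fitness vector per founding lineage, rows aligned to hms
    score_mat <- t(apply(hms, 1, function(v) otu_trait_scores(phenomes, v)))
    cache$f_microbe <- cfg$s_m^score_mat
    cache$consistency <- apply(hms, 1, function(v) consistency(effects$host, v))
  } else {
    mvec <- microbe_effect_context(cfg$microbial_mode, effects)
    score <- otu_trait_scores(phenomes, mvec)
    cache$f_microbe <- cfg$s_m^score
    cache$consistency <- consistency(effects$host, mvec)
  }
  cache
}

#' Seed the initial population
#'
#' Draws phenomes, effect tables and (under HMS) per-lineage influence
#' vectors, then seeds every host's microbiome as a multinomial draw of C
#' microbes from the uniform fixed environmental pool. Uses the current RNG
#' state; call `set.seed()` first (or use [run_simulation()]'s `seed`
#' argument) for reproducibility.
#'
#' @param config a [sim_config()].
#' @return an object of class `holosim_population`: generation index `t`,
#'   host x OTU count matrix `counts`, lineage ids, phenomes, effect tables,
#'   HMS influences, the fixed pool, and derived caches.
#' @export
seed_population <- function(config) {
  cfg <- validate_config(config)
  phenomes <- if (is.null(cfg$phenomes))
    assign_phenomes(cfg$M, cfg$n_traits, cfg$m) else cfg$phenomes
  effects <- if (is.null(cfg$effects))
    effect_table(cfg$n_traits, cfg$effect_probs) else cfg$effects
  hms <- NULL
  if (cfg$microbial_mode == "hms")
    hms <- if (is.null(cfg$hms))
      hms_influences(cfg$N, cfg$n_traits, cfg$effect_probs) else cfg$hms
  fixed_pool <- rep(1 / cfg$M, cfg$M)
  counts <- if (is.null(cfg$init_counts)) {
    t(vapply(seq_len(cfg$N),
             function(i) sample_microbiome(fixed_pool, cfg$C),
             numeric(cfg$M)))
  } else cfg$init_counts
  pop <- list(t = 0L,
              config = cfg,
              counts = counts,
              lineage = seq_len(cfg$N),
              phenomes = phenomes,
              effects = effects,
              hms = hms,
              fixed_pool = fixed_pool,
              cache = build_cache(cfg, phenomes, effects, hms))
  class(pop) <- "holosim_population"
  pop
}

#' @export
print.holosim_population <- function(x, ...) {
  cat(sprintf("holosim population at generation %d: %d hosts x %d OTUs, C = %s\n",
              x$t, nrow(x$counts), ncol(x$counts),
              format(x$config$C, big.mark = ",")))
  invisible(x)
}

host_fitness_vector <- function(pop) {
  rel <- pop$counts / pop$config$C
  beta <- drop(rel %*% pop$cache$otu_host_score)
  pop$config$s_h^beta
}

#' Wright-Fisher reproduction probabilities
#'
#' q_i = f_i / sum_k f_k over host absolute fitnesses. With host selection off
#' (s_h = 1) every f_i = 1 and q is uniform.
#'
#' @param f_host vector of host absolute fitnesses (all > 0).
#' @return probability vector summing to 1.
#' @export
reproduction_probabilities <- function(f_host) {
  if (any(f_host <= 0)) stop("host fitnesses must be positive")
  f_host / sum(f_host)
}

# Microbial fitness vector for an offspring, by lineage under HMS.
microbe_fitness_for <- function(pop, lineage_id) {
  f <- pop$cache$f_microbe
  if (is.matrix(f)) f[lineage_id, ] else f
}

#' Advance the population by one host generation
#'
#' One Wright-Fisher step: (1) host fitnesses from the parental microbiomes;
#' (2) N parent assignments drawn with probability proportional to fitness;
#' (3) the environment assembled from all parental microbiomes; (4) each
#' offspring's microbiome drawn from its source community, weighted by
#' microbial fitness in the offspring's own context (universal under TMS,
#' lineage-specific under HMS); (5) lineage labels (and with them HMS
#' influence vectors) copied from parent to offspring.
#'
#' @param pop a `holosim_population`.
#' @return the population at generation `t + 1`.
#' @export
step_population <- function(pop) {
  cfg <- pop$config
  N <- cfg$N; C <- cfg$C; M <- cfg$M
  x <- cfg$ma_percent / 100
  rel <- pop$counts / C

  f_host <- host_fitness_vector(pop)
  q <- reproduction_probabilities(f_host)
  parents <- sample.int(N, N, replace = TRUE, prob = q)

  env <- assemble_environment(pop$counts, pop$fixed_pool, cfg$me_percent)

  split_scheme <- cfg$acquisition == "split"
  rmultinom <- stats::rmultinom  # avoid per-call namespace lookup in the loop
  f_mat <- is.matrix(pop$cache$f_microbe)
  f_all <- pop$cache$f_microbe
  lin <- pop$lineage
  newc <- matrix(0, N, M)
  if (!split_scheme) {
    # hot path: rmultinom normalizes the weight vector internally, so the
    # selection-weighted source f*S need not be renormalized first
    env_part <- (1 - x) * env
    for (j in seq_len(N)) {
      pj <- parents[j]
      f <- if (f_mat) f_all[lin[pj], ] else f_all
      z <- f * (x * rel[pj, ] + env_part)
      if (sum(z) <= 0) stop("degenerate source community: all abundances zero")
      newc[j, ] <- stats::rmultinom(1, C, z)
    }
  } else {
    Cp <- round(C * x)
    for (j in seq_len(N)) {
      pj <- parents[j]
      f <- if (f_mat) f_all[lin[pj], ] else f_all
      draw <- numeric(M)
      if (Cp > 0)
        draw <- draw + sample_microbiome(acquisition_probabilities(rel[pj, ], f), Cp)
      if (C - Cp > 0)
        draw <- draw + sample_microbiome(acquisition_probabilities(env, f), C - Cp)
      newc[j, ] <- draw
    }
  }

  pop$counts <- newc
  pop$lineage <- pop$lineage[parents]
  pop$t <- pop$t + 1L
  pop
}

#' Run a simulation and record summary time series
#'
#' Seeds a population (unless `init` resumes from a saved one), iterates
#' [step_population()], and records a [summarize_generation()] row at the
#' initial state, at every `record_every`-th generation, and at the final
#' generation. The initial record is always kept because fitness fold changes
#' are reported relative to it.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed; when given, `set.seed(seed)` is called
#'   so the whole run is reproducible from `(config, seed)`.
#' @param generations number of generations; defaults to `config$generations`.
#' @param record_every recording interval; defaults to `config$record_every`,
#'   then to `max(1, floor(generations / 200))`.
#' @param init optional `holosim_population` to resume from.
#' @return an object of class `holosim_run`: a `summary` data frame (one row
#'   per recorded generation), the final `population`, and the `config` and
#'   `seed` used.
#' @export
run_simulation <- function(config, seed = NULL, generations = config$generations,
                           record_every = NULL, init = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(record_every))
    record_every <- if (!is.null(config$record_every)) config$record_every
                    else max(1L, as.integer(floor(generations / 200)))
  pop <- if (is.null(init)) seed_population(config) else init
  records <- vector("list", as.integer(generations / record_every) + 2L)
  k <- 1L
  records[[k]] <- summarize_generation(pop)
  if (generations >= 1) {
    for (g in seq_len(generations)) {
      pop <- step_population(pop)
      if (pop$t %% record_every == 0L || g == generations) {
        k <- k + 1L
        records[[k]] <- summarize_generation(pop)
      }
    }
  }
  summary <- do.call(rbind, records[seq_len(k)])
  # the final generation can coincide with a regular recording point
  summary <- summary[!duplicated(summary$t), , drop = FALSE]
  rownames(summary) <- NULL
  out <- list(summary = summary, population = pop, config = pop$config,
              seed = seed)
  class(out) <- "holosim_run"
  out
}

#' @export
print.holosim_run <- function(x, ...) {
  n <- nrow(x$summary)
  last <- x$summary[n, ]
  cat(sprintf("holosim run: %d generations, %d recorded snapshots\n",
              x$population$t, n))
  cat(sprintf("  final: alpha = %.3f, beta = %.3f, gamma = %.3f\n",
              last$alpha, last$beta, last$gamma))
  cat(sprintf("  final: mean host w = %.4g, mean microbe w = %.4g\n",
              last$mean_host_w, last$mean_microbe_w))
  invisible(x)
}

#' Derive a replicate seed from a root seed
#'
#' Deterministic splitting rule used by the sweep drivers so every
#' (grid cell, replicate) pair gets its own reproducible stream:
#' `(root * 48271 + index * 100003) mod (2^31 - 1)`, kept strictly positive.
#' Panels that should be compared with common random numbers pass the same
#' `index` (derived from acquisition percentages and replicate only, not from
#' selection parameters).
#'
#' @param root integer root seed.
#' @param index non-negative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, index) {
  m <- 2147483647
  s <- (abs(as.double(root)) %% m) * 48271 + as.double(index) * 100003 + 1
  as.integer(s %% m)
}
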