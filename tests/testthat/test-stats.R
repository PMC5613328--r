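# Summary statistics, checked against direct-formula arithmetic computed
# here rather than against the implementation's own internals.

test_that("shannon matches the direct formula", {
  expect_equal(shannon(c(0, 10, 0)), 0)
  expect_equal(shannon(rep(3, 150)), log(150))
  expect_equal(shannon(c(1, 3)), -(0.25 * log(0.25) + 0.75 * log(0.75)))
  expect_equal(shannon(c(1, 1, 2), base = 2),
               -(0.25 * log2(0.25) * 2 + 0.5 * log2(0.5)))
  expect_error(shannon(c(0, 0)), "empty")
  set.seed(14)
  for (i in 1:10) {
    x <- stats::rpois(20, 5)
    x[1] <- x[1] + 1  # never all-zero
    p <- x[x > 0] / sum(x)
    expect_equal(shannon(x), -sum(p * log(p)))
  }
})

test_that("bray_curtis matches the direct formula", {
  expect_equal(bray_curtis(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(bray_curtis(c(1, 0), c(1, 0, 0)), "equal length")
  set.seed(15)
  for (i in 1:10) {
    a <- stats::runif(12); a <- a / sum(a)
    b <- stats::runif(12); b <- b / sum(b)
    expect_equal(bray_curtis(a, b), 1 - sum(pmin(a, b)))
  }
})

test_that("diversity_summary partitions alpha, beta and gamma correctly", {
  # all hosts identical: no between-host variation
  same <- rbind(c(4, 6), c(4, 6), c(4, 6))
  d <- diversity_summary(same)
  expect_equal(d[["beta"]], 0)
  expect_equal(d[["alpha"]], d[["gamma"]])

  # two hosts fixed on different OTUs: complete partitioning
  split <- rbind(c(10, 0), c(0, 10))
  d2 <- diversity_summary(split)
  expect_equal(d2[["alpha"]], 0)
  expect_equal(d2[["beta"]], 1)
  expect_equal(d2[["gamma"]], log(2))

  # three-host fixture against per-definition arithmetic
  cts <- rbind(c(5, 5, 0), c(2, 2, 6), c(0, 1, 9))
  d3 <- diversity_summary(cts)
  sh <- function(x) { p <- x[x > 0] / sum(x); -sum(p * log(p)) }
  bc <- function(a, b) 1 - sum(pmin(a / sum(a), b / sum(b)))
  expect_equal(d3[["alpha"]], mean(c(sh(cts[1, ]), sh(cts[2, ]), sh(cts[3, ]))))
  expect_equal(d3[["gamma"]], sh(colSums(cts)))
  expect_equal(d3[["beta"]], mean(c(bc(cts[1, ], cts[2, ]),
                                    bc(cts[1, ], cts[3, ]),
                                    bc(cts[2, ], cts[3, ]))))

  expect_true(is.na(diversity_summary(matrix(c(1, 2), 1))[["beta"]]))

  # pooling cannot reduce entropy below the mean of components
  set.seed(16)
  for (i in 1:10) {
    cts <- matrix(stats::rpois(5 * 8, 4) + 1, 5, 8)
    d <- diversity_summary(cts)
    expect_gte(d[["gamma"]], d[["alpha"]] - 1e-12)
  }
})

test_that("fitness_summary reports mean relative fitnesses per context", {
  # neutral: both means exactly 1
  pop <- polarized_pop(s_h = 1, s_m = 1, mode = "none")
  fs <- fitness_summary(pop)
  expect_equal(fs[["mean_host_w"]], 1)
  expect_equal(fs[["mean_microbe_w"]], 1)

  # polarized world, s = 10: host w = (1, 0.01), microbe w likewise
  pop <- polarized_pop(s_h = 10, s_m = 10)
  fs <- fitness_summary(pop)
  expect_equal(fs[["mean_host_w"]], mean(c(1, 0.01)))
  expect_equal(fs[["mean_microbe_w"]], mean(c(1, 0.01)))

  # all hosts carrying only beta = 1 OTUs: maximum microbe fitness
  pop$counts <- rbind(c(10, 0), c(10, 0))
  expect_equal(fitness_summary(pop)[["mean_microbe_w"]], 1)
})

test_that("log_fold_change uses base 10 and rejects non-positive input", {
  expect_equal(log_fold_change(3, 3), 0)
  expect_equal(log_fold_change(30, 3), 1)
  expect_equal(log_fold_change(0.505, 0.7), log10(0.505 / 0.7))
  expect_equal(log_fold_change(8, 2, base = 2), 2)
  expect_error(log_fold_change(0, 1), "positive")
})

test_that("composition is the abundance-weighted class breakdown", {
  # forced commensal: all-zero host effects
  pop <- polarized_pop()
  pop$effects$host <- c(0L, 0L)
  pop$cache <- holosim:::build_cache(pop$config, pop$phenomes, pop$effects, NULL)
  comp <- composition(pop)
  expect_equal(comp$abundance, c(0, 1, 0))

  # 60/40 pooled over one beneficial and one pathogenic OTU
  pop <- polarized_pop()
  pop$counts <- rbind(c(10, 0), c(2, 8))
  comp <- composition(pop)
  expect_equal(comp$abundance[comp$type == "beneficial"], 0.6)
  expect_equal(comp$abundance[comp$type == "pathogenic"], 0.4)
  expect_equal(sum(comp$abundance), 1)
  expect_equal(sum(comp$otus), 1)

  set.seed(17)
  cfg <- tiny_config(s_m = 10, microbial_mode = "tms")
  pop <- seed_population(cfg)
  expect_equal(sum(composition(pop)$abundance), 1, tolerance = 1e-12)
})

test_that("consistency is the cosine between effect vectors", {
  expect_equal(consistency(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(consistency(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(consistency(c(1, 1, 0), c(1, -1, 0)), 0)
  expect_equal(consistency(c(1, 1), c(-1, -1)), -1)
  expect_equal(consistency(c(0, 0), c(1, -1)), 0)  # zero-vector convention
  expect_error(consistency(c(1, 0), c(1, 0, 0)), "equal length")

  # invariant under joint permutation and positive scaling
  set.seed(18)
  h <- effect_scores(10); m <- effect_scores(10)
  perm <- sample.int(10)
  expect_equal(consistency(h, m), consistency(h[perm], m[perm]))
  expect_equal(consistency(h, m), consistency(3 * h, 0.5 * m))
  # sign antisymmetry: flipping one vector flips the cosine
  expect_equal(consistency(h, -m), -consistency(h, m))
})

test_that("mean_consistency averages per-host cosines under HMS", {
  cfg <- sim_config(N = 2, C = 10, M = 2, n_traits = 2, m = 1,
                    s_m = 10, microbial_mode = "hms", generations = 1,
                    phenomes = rbind(1L, 2L),
                    effects = list(host = c(1L, -1L), microbe = c(1L, -1L)),
                    hms = rbind(c(1L, -1L), c(-1L, 1L)),
                    init_counts = rbind(c(5, 5), c(5, 5)))
  pop <- seed_population(cfg)
  expect_equal(mean_consistency(pop), mean(c(1, -1)))
  pop$lineage <- c(1L, 1L)  # after lineage 1 sweeps
  expect_equal(mean_consistency(pop), 1)
})

test_that("pearson_r matches the closed form and rejects degenerate input", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(2, 2, 4)), sqrt(3) / 2)
  expect_error(pearson_r(c(1, 2), c(1, 2)), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("summaries are pure functions of the population state", {
  cfg <- tiny_config(s_h = 10, s_m = 10, microbial_mode = "hms")
  run <- run_simulation(cfg, seed = 19, generations = 5, record_every = 5)
  again <- summarize_generation(run$population)
  final <- run$summary[nrow(run$summary), ]
  rownames(again) <- rownames(final) <- NULL
  expect_identical(final, again)
})
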