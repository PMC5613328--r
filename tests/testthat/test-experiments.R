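# Sweep drivers, replicate seeding, and the composition / consistency
# experiments, exercised on deliberately tiny grids.

test_that("a 1x1 sweep with one replicate equals a single run", {
  spec <- sweep_spec(ma_percent = 50, me_percent = 50, s_h = 10, s_m = 10,
                     microbial_mode = "tms", replicates = 1, scale = "ci",
                     generations = 10, seed = 5,
                     N = 20, C = 200, M = 8)
  res <- run_sweep(spec)
  expect_equal(nrow(res$records), 1)
  cfg <- sim_config(N = 20, C = 200, M = 8, n_traits = 10, m = 5,
                    ma_percent = 50, me_percent = 50, s_h = 10, s_m = 10,
                    microbial_mode = "tms", generations = 10)
  run <- run_simulation(cfg, seed = res$records$seed, record_every = 10)
  expect_equal(res$records$alpha, run$summary$alpha[nrow(run$summary)])
  expect_equal(res$records$host_w, run$summary$mean_host_w[nrow(run$summary)])
})

test_that("sweeps are reproducible and share seeds across selection panels", {
  spec <- sweep_spec(ma_percent = c(0, 100), me_percent = 0,
                     s_h = c(1, 10), s_m = 1, microbial_mode = "none",
                     replicates = 2, scale = "ci", generations = 5, seed = 9,
                     N = 15, C = 100, M = 6)
  r1 <- run_sweep(spec)
  r2 <- run_sweep(spec)
  expect_identical(r1$records, r2$records)
  # common random numbers: same (ma, me, replicate) across s_h panels
  rec <- r1$records
  a <- rec[rec$s_h == 1, c("ma", "me", "replicate", "seed")]
  b <- rec[rec$s_h == 10, c("ma", "me", "replicate", "seed")]
  a <- a[order(a$ma, a$replicate), ]; rownames(a) <- NULL
  b <- b[order(b$ma, b$replicate), ]; rownames(b) <- NULL
  expect_identical(a, b)
  # initial states are identical across panels given common seeds
  expect_equal(rec$alpha0[rec$s_h == 1], rec$alpha0[rec$s_h == 10])
})

test_that("heatmap matrices are ME x MA with replicate SD attached", {
  spec <- sweep_spec(ma_percent = c(0, 50, 100), me_percent = c(0, 100),
                     s_h = 1, s_m = 1, microbial_mode = "none",
                     replicates = 2, scale = "ci", generations = 5, seed = 2,
                     N = 15, C = 100, M = 6)
  res <- run_sweep(spec)
  m <- heatmap_matrix(res, "alpha")
  expect_equal(dim(m), c(2, 3))
  expect_equal(rownames(m), c("0", "100"))
  expect_equal(colnames(m), c("0", "50", "100"))
  expect_equal(dim(attr(m, "sd")), c(2, 3))
  expect_true(all(is.finite(m)))
  expect_error(heatmap_matrix(res, "nonsense"), "unknown statistic")
  expect_error(heatmap_matrix(res, "alpha", s_h = 99), "no records")
})

test_that("failed cells are recorded without aborting the sweep", {
  spec <- sweep_spec(ma_percent = 0, me_percent = 0, s_h = 1, s_m = 1,
                     microbial_mode = "none", replicates = 1, scale = "ci",
                     generations = 5, seed = 1, N = 15, C = 100, M = 6,
                     m = 99)  # traits per phenome exceeds the pool
  res <- run_sweep(spec)
  expect_equal(nrow(res$records), 1)
  expect_match(res$records$error, "cannot exceed")
  expect_true(is.na(res$records$alpha))
})

test_that("composition experiment starts all cells from the same seeds", {
  ce <- composition_experiment(modes = "hs_hms", cells = list(c(0, 0), c(90, 90)),
                               s_h = 10, s_m = 10, replicates = 2,
                               scale = "ci", generations = 5, seed = 4,
                               N = 15, C = 200, M = 10)
  init <- ce$summary[ce$summary$phase == "initial", ]
  # MA/ME do not enter seeding, so initial compositions match across cells
  expect_equal(init$beneficial[init$ma == 0], init$beneficial[init$ma == 90])
  expect_equal(init$pathogenic[init$ma == 0], init$pathogenic[init$ma == 90])
  fin <- ce$summary[ce$summary$phase == "final", ]
  expect_equal(unname(rowSums(fin[, c("beneficial", "commensal", "pathogenic")])),
               rep(1, nrow(fin)), tolerance = 1e-12)
})

test_that("consistency experiment records per-replicate cosines and r", {
  ce <- consistency_experiment(s = 10, replicates = 6, scale = "ci",
                               generations = 5, seed = 8,
                               N = 15, C = 200, M = 10)
  expect_equal(nrow(ce$records), 6)
  expect_true(all(abs(ce$records$consistency) <= 1))
  expect_true(is.na(ce$r) || abs(ce$r) <= 1)
  # deterministic given the root seed
  ce2 <- consistency_experiment(s = 10, replicates = 6, scale = "ci",
                                generations = 5, seed = 8,
                                N = 15, C = 200, M = 10)
  expect_identical(ce$records, ce2$records)
})

test_that("degenerate consistency variance yields r = NA with a message", {
  # freeze identical effect tables across replicates
  eff <- list(host = c(1L, -1L, rep(0L, 8)), microbe = c(1L, 1L, rep(0L, 8)))
  expect_message(
    ce <- consistency_experiment(s = 10, replicates = 3, scale = "ci",
                                 generations = 3, seed = 1,
                                 N = 10, C = 100, M = 6, effects = eff),
    "degenerate")
  expect_true(is.na(ce$r))
})
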