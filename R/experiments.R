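# Parameter-grid sweeps with replicate management: diversity heatmaps over
# MA x ME grids per (s_h, s_m) panel, microbe-type composition experiments,
# and the HS-TMS consistency / host-fitness-change correlation experiment.

#' Scale presets
#'
#' Named parameter bundles: `small` (500 hosts, 10^4 microbes each, 150 OTUs,
#' 10-trait pool, 10^4 generations, 50 replicates), `large` (5000 hosts, 10^9
#' microbes, 25-trait pool, 2x10^5 generations, 5 replicates), and `ci`, a
#' desk-scale bundle (100 hosts, 2000 microbes, 40 OTUs, 500 generations,
#' 5 replicates) that exercises the full machinery in minutes. Presets are
#' data, not code: any field can be overridden.
#'
#' @return named list of preset parameter lists.
#' @export
scale_presets <- function() {
  list(
    small = list(N = 500, C = 1e4, M = 150, n_traits = 10, m = 5,
                 generations = 1e4, replicates = 50),
    large = list(N = 5000, C = 1e9, M = 150, n_traits = 25, m = 5,
                 generations = 2e5, replicates = 5),
    ci = list(N = 100, C = 2000, M = 40, n_traits = 10, m = 5,
              generations = 500, replicates = 5)
  )
}

preset_params <- function(scale) {
  presets <- scale_presets()
  if (!scale %in% names(presets))
    stop("unknown scale preset '", scale, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[scale]]
}

#' Specify a parameter sweep
#'
#' A full factorial grid over acquisition percentages and selection
#' coefficients, run for `replicates` independent replicates per cell. Base
#' parameters come from a scale preset and can be overridden via `...`
#' (passed to [sim_config()]). Replicate seeds are derived from `seed` with
#' [derive_seed()] using an index built from (me, ma, replicate) only, so
#' panels differing in selection parameters share common random numbers.
#'
#' @param ma_percent,me_percent vectors of grid levels in [0, 100].
#' @param s_h,s_m vectors of selection coefficients (>= 1).
#' @param microbial_mode one or more of `"none"`, `"tms"`, `"hms"`.
#' @param replicates replicates per cell; `NULL` takes the preset's value.
#' @param scale preset name (see [scale_presets()]).
#' @param generations generations per run; `NULL` takes the preset's value.
#' @param seed root seed for the whole sweep.
#' @param ... further [sim_config()] overrides applied to every cell.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(ma_percent = seq(0, 100, by = 10),
                       me_percent = seq(0, 100, by = 10),
                       s_h = 1, s_m = 1, microbial_mode = "none",
                       replicates = NULL, scale = "ci",
                       generations = NULL, seed = 1, ...) {
  base <- preset_params(scale)
  if (is.null(replicates)) replicates <- base$replicates
  if (is.null(generations)) generations <- base$generations
  spec <- list(ma_percent = ma_percent, me_percent = me_percent,
               s_h = s_h, s_m = s_m, microbial_mode = microbial_mode,
               replicates = replicates, scale = scale,
               generations = generations, seed = seed,
               base = base, overrides = list(...))
  class(spec) <- "sweep_spec"
  spec
}

cell_config <- function(spec, ma, me, sh, sm, mode) {
  args <- list(N = spec$base$N, C = spec$base$C, M = spec$base$M,
               n_traits = spec$base$n_traits, m = spec$base$m,
               ma_percent = ma, me_percent = me,
               s_h = sh, s_m = sm, microbial_mode = mode,
               generations = spec$generations)
  args[names(spec$overrides)] <- spec$overrides
  do.call(sim_config, args)
}

# common-random-number stream index: depends on (me, ma, replicate) only
crn_index <- function(ma, me, rep) {
  as.double(rep) * 10201 + as.double(me) * 101 + as.double(ma)
}

#' Run a parameter sweep
#'
#' Executes [run_simulation()] for every grid cell and replicate, recording
#' initial and final summary statistics and log10 fold changes of mean host
#' and microbe relative fitness. A failing cell is recorded with its error
#' message and the sweep continues.
#'
#' @param spec a [sweep_spec()].
#' @param progress print one line per completed cell.
#' @return an object of class `sweep_result`: long-format `records` data
#'   frame (one row per cell x replicate) plus the spec.
#' @export
run_sweep <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- expand.grid(ma = spec$ma_percent, me = spec$me_percent,
                      s_h = spec$s_h, s_m = spec$s_m,
                      mode = spec$microbial_mode,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid) * spec$replicates)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, ]
    for (r in seq_len(spec$replicates)) {
      k <- k + 1L
      run_seed <- derive_seed(spec$seed, crn_index(cell$ma, cell$me, r))
      rows[[k]] <- tryCatch({
        cfg <- cell_config(spec, cell$ma, cell$me, cell$s_h, cell$s_m, cell$mode)
        run <- run_simulation(cfg, seed = run_seed,
                              record_every = max(1L, as.integer(spec$generations)))
        s0 <- run$summary[1, ]
        sf <- run$summary[nrow(run$summary), ]
        data.frame(ma = cell$ma, me = cell$me, s_h = cell$s_h, s_m = cell$s_m,
                   mode = cell$mode, replicate = r, seed = run_seed,
                   alpha0 = s0$alpha, beta0 = s0$beta, gamma0 = s0$gamma,
                   alpha = sf$alpha, beta = sf$beta, gamma = sf$gamma,
                   host_w0 = s0$mean_host_w, host_w = sf$mean_host_w,
                   microbe_w0 = s0$mean_microbe_w, microbe_w = sf$mean_microbe_w,
                   lfc_host = log_fold_change(sf$mean_host_w, s0$mean_host_w),
                   lfc_microbe = log_fold_change(sf$mean_microbe_w,
                                                 s0$mean_microbe_w),
                   frac_beneficial = sf$frac_beneficial,
                   frac_commensal = sf$frac_commensal,
                   frac_pathogenic = sf$frac_pathogenic,
                   consistency = sf$mean_consistency,
                   error = NA_character_)
      }, error = function(e) {
        data.frame(ma = cell$ma, me = cell$me, s_h = cell$s_h, s_m = cell$s_m,
                   mode = cell$mode, replicate = r, seed = run_seed,
                   alpha0 = NA_real_, beta0 = NA_real_, gamma0 = NA_real_,
                   alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                   host_w0 = NA_real_, host_w = NA_real_,
                   microbe_w0 = NA_real_, microbe_w = NA_real_,
                   lfc_host = NA_real_, lfc_microbe = NA_real_,
                   frac_beneficial = NA_real_, frac_commensal = NA_real_,
                   frac_pathogenic = NA_real_, consistency = NA_real_,
                   error = conditionMessage(e))
      })
    }
    if (progress)
      message(sprintf("cell %d/%d done (MA %g, ME %g, s_h %g, s_m %g, %s)",
                      g, nrow(grid), cell$ma, cell$me, cell$s_h, cell$s_m,
                      cell$mode))
  }
  out <- list(records = do.call(rbind, rows), spec = spec)
  class(out) <- "sweep_result"
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  n_err <- sum(!is.na(x$records$error))
  cat(sprintf("holosim sweep: %d records (%d cells x %d replicates), %d failed\n",
              nrow(x$records),
              nrow(x$records) / x$spec$replicates, x$spec$replicates, n_err))
  invisible(x)
}

#' Heatmap matrix of a sweep statistic
#'
#' Replicate-averaged matrix of one final statistic over the MA x ME grid for
#' one (s_h, s_m, mode) panel: rows are ME levels, columns MA levels. The
#' replicate standard deviation is attached as attribute `"sd"`.
#'
#' @param result a `sweep_result`.
#' @param stat column of the records to aggregate (default `"alpha"`).
#' @param s_h,s_m,mode panel selectors; `NULL` keeps all (only sensible when
#'   the sweep had a single level).
#' @return numeric matrix (ME x MA) with attribute `"sd"`.
#' @export
heatmap_matrix <- function(result, stat = "alpha", s_h = NULL, s_m = NULL,
                           mode = NULL) {
  stopifnot(inherits(result, "sweep_result"))
  rec <- result$records
  if (!stat %in% names(rec)) stop("unknown statistic '", stat, "'")
  if (!is.null(s_h)) rec <- rec[rec$s_h == s_h, ]
  if (!is.null(s_m)) rec <- rec[rec$s_m == s_m, ]
  if (!is.null(mode)) rec <- rec[rec$mode == mode, ]
  if (nrow(rec) == 0) stop("no records match the requested panel")
  me_levels <- sort(unique(rec$me)); ma_levels <- sort(unique(rec$ma))
  agg <- function(f) {
    m <- matrix(NA_real_, length(me_levels), length(ma_levels),
                dimnames = list(me = me_levels, ma = ma_levels))
    for (i in seq_along(me_levels)) for (j in seq_along(ma_levels)) {
      v <- rec[[stat]][rec$me == me_levels[i] & rec$ma == ma_levels[j]]
      m[i, j] <- f(v)
    }
    m
  }
  out <- agg(function(v) mean(v, na.rm = TRUE))
  attr(out, "sd") <- agg(function(v) stats::sd(v, na.rm = TRUE))
  out
}

#' Microbe-type composition experiment
#'
#' Runs the selective models over a handful of MA*ME cells and reports the
#' replicate-averaged beneficial/commensal/pathogenic fractions at the final
#' generation, together with the initial composition (`phase = "initial"`).
#' Replicate seeds depend only on the replicate index, so all modes and cells
#' start from the same initial conditions.
#'
#' @param modes character vector; each entry is `"hs"`, `"hs_tms"` or
#'   `"hs_hms"`.
#' @param cells list of `c(ma, me)` percentage pairs.
#' @param s_h,s_m selection coefficients applied where the mode activates
#'   them.
#' @param replicates replicates per mode x cell.
#' @param scale preset name.
#' @param generations generations per run; `NULL` takes the preset's value.
#' @param seed root seed.
#' @param ... further [sim_config()] overrides.
#' @return list with `summary` (replicate-averaged fractions per mode x cell
#'   x phase) and `records` (per-replicate final fractions).
#' @export
composition_experiment <- function(modes = c("hs", "hs_tms", "hs_hms"),
                                   cells = list(c(0, 0), c(50, 50), c(90, 90)),
                                   s_h = 100, s_m = 100, replicates = 5,
                                   scale = "ci", generations = NULL, seed = 1,
                                   ...) {
  base <- preset_params(scale)
  if (is.null(generations)) generations <- base$generations
  mode_params <- list(
    hs = list(s_h = s_h, s_m = 1, microbial_mode = "none"),
    hs_tms = list(s_h = s_h, s_m = s_m, microbial_mode = "tms"),
    hs_hms = list(s_h = s_h, s_m = s_m, microbial_mode = "hms"))
  if (!all(modes %in% names(mode_params)))
    stop("modes must be among: ", paste(names(mode_params), collapse = ", "))
  overrides <- list(...)
  rows <- list(); init_rows <- list()
  for (mode in modes) {
    mp <- mode_params[[mode]]
    for (cell in cells) {
      for (r in seq_len(replicates)) {
        args <- c(list(N = base$N, C = base$C, M = base$M,
                       n_traits = base$n_traits, m = base$m,
                       ma_percent = cell[1], me_percent = cell[2],
                       generations = generations), mp)
        args[names(overrides)] <- overrides
        cfg <- do.call(sim_config, args)
        run <- run_simulation(cfg, seed = derive_seed(seed, r),
                              record_every = max(1L, as.integer(generations)))
        s0 <- run$summary[1, ]; sf <- run$summary[nrow(run$summary), ]
        rows[[length(rows) + 1L]] <- data.frame(
          mode = mode, ma = cell[1], me = cell[2], replicate = r,
          beneficial = sf$frac_beneficial, commensal = sf$frac_commensal,
          pathogenic = sf$frac_pathogenic)
        init_rows[[length(init_rows) + 1L]] <- data.frame(
          mode = mode, ma = cell[1], me = cell[2], replicate = r,
          beneficial = s0$frac_beneficial, commensal = s0$frac_commensal,
          pathogenic = s0$frac_pathogenic)
      }
    }
  }
  records <- do.call(rbind, rows)
  initial <- do.call(rbind, init_rows)
  avg <- function(df, phase) {
    a <- stats::aggregate(df[c("beneficial", "commensal", "pathogenic")],
                          by = df[c("mode", "ma", "me")], FUN = mean)
    a$phase <- phase
    a
  }
  summary <- rbind(avg(initial, "initial"), avg(records, "final"))
  list(summary = summary[order(summary$mode, summary$ma, summary$me), ],
       records = records, initial = initial)
}

#' HS-TMS consistency vs host-fitness-change experiment
#'
#' Under joint host selection and trait-mediated microbial selection, each
#' replicate's universal effect tables are drawn afresh, so the HS-TMS
#' consistency (cosine between the host-effect and microbe-effect vectors) is
#' fixed over time within a replicate but random across replicates. This
#' experiment records, per replicate, the initial consistency and the change
#' in mean host relative fitness (final minus initial), and the Pearson
#' correlation between the two across replicates.
#'
#' @param s selection coefficient applied to both HS and TMS.
#' @param replicates number of replicates (>= 10 for a meaningful r).
#' @param ma_percent,me_percent acquisition percentages.
#' @param scale preset name.
#' @param generations generations per run; `NULL` takes the preset's value.
#' @param seed root seed.
#' @param ... further [sim_config()] overrides.
#' @return list with `records` (replicate, seed, consistency, initial/final
#'   mean host w, `host_w_change`) and `r` (Pearson correlation; `NA` with a
#'   message if the consistency has zero variance).
#' @export
consistency_experiment <- function(s = 10, replicates = 50,
                                   ma_percent = 50, me_percent = 50,
                                   scale = "ci", generations = NULL, seed = 1,
                                   ...) {
  if (replicates < 3) stop("at least 3 replicates are required")
  base <- preset_params(scale)
  if (is.null(generations)) generations <- base$generations
  overrides <- list(...)
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    args <- list(N = base$N, C = base$C, M = base$M,
                 n_traits = base$n_traits, m = base$m,
                 ma_percent = ma_percent, me_percent = me_percent,
                 s_h = s, s_m = s, microbial_mode = "tms",
                 generations = generations)
    args[names(overrides)] <- overrides
    cfg <- do.call(sim_config, args)
    run_seed <- derive_seed(seed, r)
    run <- run_simulation(cfg, seed = run_seed,
                          record_every = max(1L, as.integer(generations)))
    s0 <- run$summary[1, ]; sf <- run$summary[nrow(run$summary), ]
    rows[[r]] <- data.frame(replicate = r, seed = run_seed,
                            consistency = s0$mean_consistency,
                            host_w0 = s0$mean_host_w, host_w = sf$mean_host_w,
                            host_w_change = sf$mean_host_w - s0$mean_host_w)
  }
  records <- do.call(rbind, rows)
  r_val <- if (stats::sd(records$consistency) == 0 ||
               stats::sd(records$host_w_change) == 0) {
    message("degenerate variance: Pearson r undefined")
    NA_real_
  } else {
    pearson_r(records$consistency, records$host_w_change)
  }
  list(records = records, r = r_val)
}
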