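# Community assembly: the environmental pool (mixed environment, ME_y), the
# per-offspring source community (mixed acquisition, MA_x), and the
# selection-weighted multinomial draw that fills a microbiome's C slots.

#' Assemble the environmental microbial pool
#'
#' The environment available to a generation of offspring is a convex mixture
#' of (i) the pool obtained by summing all parental microbiome counts and
#' renormalizing, weighted `y/100`, and (ii) a fixed, unchanging reservoir,
#' weighted `1 - y/100`. `y = 0` is the pure fixed environment (FE), `y = 100`
#' the pure pooled environment (PE). All parents contribute with equal weight
#' (equal capacities), regardless of their realized reproductive success.
#'
#' @param parental_counts host x OTU count matrix of the parental generation.
#' @param fixed_pool relative-abundance vector of the fixed reservoir.
#' @param y pooled-parental percentage in [0, 100].
#' @return relative-abundance vector of the mixed environment (sums to 1).
#' @export
assemble_environment <- function(parental_counts, fixed_pool, y) {
  if (is.null(dim(parental_counts)) || nrow(parental_counts) < 1)
    stop("at least one parental microbiome is required")
  if (y < 0 || y > 100) stop("y must lie in [0, 100]")
  if (ncol(parental_counts) != length(fixed_pool))
    stop("parental counts and fixed pool disagree on the number of OTUs")
  pooled <- colSums(parental_counts)
  pooled <- pooled / sum(pooled)
  (y / 100) * pooled + (1 - y / 100) * fixed_pool
}

#' Build an offspring's source community
#'
#' The source community S is the convex mixture of the assigned parent's
#' relative abundances (weight `x/100`) and the environment (weight
#' `1 - x/100`). `x = 100` is pure parental acquisition (PA), `x = 0` pure
#' environmental acquisition (EA).
#'
#' @param parent_abund parent relative-abundance vector.
#' @param env environment relative-abundance vector.
#' @param x parental percentage in [0, 100].
#' @return relative-abundance vector S (sums to 1).
#' @export
source_community <- function(parent_abund, env, x) {
  if (x < 0 || x > 100) stop("x must lie in [0, 100]")
  if (length(parent_abund) != length(env))
    stop("parent and environment disagree on the number of OTUs")
  (x / 100) * parent_abund + (1 - x / 100) * env
}

#' Selection-weighted acquisition probabilities
#'
#' The probability that a slot in an offspring microbiome is filled by OTU i
#' is p_i = f_i a_i / sum_k f_k a_k: abundance in the source community,
#' reweighted by microbial fitness. With all f_i equal this is the identity on
#' the source abundances (the neutral model); OTUs absent from the source can
#' never be acquired.
#'
#' @param source relative-abundance vector of the source community.
#' @param fitness per-OTU microbial fitness vector (all entries > 0).
#' @return probability vector summing to 1.
#' @export
acquisition_probabilities <- function(source, fitness) {
  if (length(source) != length(fitness))
    stop("source and fitness disagree on the number of OTUs")
  if (any(fitness <= 0)) stop("all microbial fitness values must be positive")
  z <- fitness * source
  tot <- sum(z)
  if (tot <= 0) stop("empty source community: no OTU has positive abundance")
  z / tot
}

#' Fill a microbiome by multinomial sampling
#'
#' One multinomial draw of `capacity` microbes over the OTUs with the given
#' probabilities. Probabilities are renormalized if they deviate from 1 by no
#' more than `tol`; a larger deviation is an error.
#'
#' @param prob acquisition probability vector.
#' @param capacity microbiome capacity C (total slots).
#' @param tol tolerance on `sum(prob) == 1` before renormalizing.
#' @return integer count vector summing to `capacity`.
#' @export
sample_microbiome <- function(prob, capacity, tol = 1e-9) {
  if (capacity < 1) stop("capacity must be at least 1")
  s <- sum(prob)
  if (abs(s - 1) > tol) stop("probabilities must sum to 1")
  drop(stats::rmultinom(1, capacity, prob / s))
}

#' Lotka-Volterra growth rate equivalent of a selection coefficient
#'
#' The discrete per-generation reweighting by s^beta is the integral of
#' exponential growth at rate alpha = beta * a over one host generation of
#' length T, with a = ln(s)/T. `s = 1` gives a = 0: no growth-rate
#' differences, the neutral model.
#'
#' @param s selection coefficient, >= 1.
#' @param T host generation time, > 0.
#' @return the growth-rate bound a = ln(s)/T.
#' @export
lv_growth_rate <- function(s, T) {
  if (any(s < 1)) stop("selection coefficient s must be >= 1")
  if (any(T <= 0)) stop("generation time T must be positive")
  log(s) / T
}
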