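# Summary statistics: Shannon alpha/gamma diversity, Bray-Curtis beta
# diversity, host/microbe relative fitness, beneficial/commensal/pathogenic
# composition, and host-microbe trait-fitness consistency. All are pure
# functions of a population snapshot. Shannon and Bray-Curtis computations
# are delegated to vegan.

#' Shannon-Wiener index
#'
#' H = -sum a_i log(a_i) over OTUs with positive abundance. Natural log by
#' default (configurable base); ranges from 0 (single OTU) to log(M)
#' (uniform over M OTUs).
#'
#' @param counts non-negative count or abundance vector, not all zero.
#' @param base logarithm base.
#' @return the Shannon index.
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("cannot compute Shannon index of an empty community")
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' Bray-Curtis dissimilarity between two communities
#'
#' For relative abundances, d = 1 - sum min(a_i, b_i); 0 for identical
#' communities, 1 for disjoint supports.
#'
#' @param a,b relative-abundance vectors of equal length.
#' @return the dissimilarity in [0, 1].
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("abundance vectors must have equal length")
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' Alpha, beta and gamma diversity of a host population
#'
#' alpha: mean within-host Shannon index; gamma: Shannon index of the pooled
#' (elementwise-summed) population microbiome; beta: mean pairwise
#' Bray-Curtis dissimilarity between hosts' relative-abundance profiles.
#' Pooling cannot reduce entropy below the mean of the components, so
#' gamma >= alpha always. For very large populations the pair set is
#' subsampled (at most `max_pairs` random pairs, using the current RNG) and
#' the result carries attribute `beta_subsampled = TRUE`.
#'
#' @param counts host x OTU count matrix.
#' @param max_pairs cap on the number of host pairs entering beta.
#' @return named numeric vector `c(alpha, beta, gamma)`; `beta` is `NA` for a
#'   single host.
#' @export
diversity_summary <- function(counts, max_pairs = 1e5) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  if (any(counts < 0) || any(rowSums(counts) <= 0))
    stop("every host microbiome must have non-negative counts and be non-empty")
  alpha <- mean(as.numeric(vegan::diversity(counts, index = "shannon")))
  gamma <- shannon(colSums(counts))
  N <- nrow(counts)
  subsampled <- FALSE
  if (N < 2) {
    beta <- NA_real_
  } else {
    rel <- counts / rowSums(counts)
    n_pairs <- N * (N - 1) / 2
    if (n_pairs <= max_pairs) {
      beta <- mean(vegan::vegdist(rel, method = "bray"))
    } else {
      subsampled <- TRUE
      i <- sample.int(N, max_pairs, replace = TRUE)
      j <- sample.int(N - 1, max_pairs, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)  # j != i, uniform over ordered pairs
      beta <- mean(rowSums(abs(rel[i, , drop = FALSE] - rel[j, , drop = FALSE])) / 2)
    }
  }
  out <- c(alpha = alpha, beta = beta, gamma = gamma)
  attr(out, "beta_subsampled") <- subsampled
  out
}

#' Mean host and microbe relative fitness
#'
#' `mean_host_w`: arithmetic mean over hosts of w_host = s_h^beta_host / s_h.
#' `mean_microbe_w`: mean over hosts of the abundance-weighted mean of
#' per-OTU microbial relative fitness, each host evaluated in its own context
#' (universal under TMS, lineage-specific under HMS). In the neutral limit
#' (s_h = s_m = 1) both are exactly 1.
#'
#' @param pop a `holosim_population`.
#' @return named numeric vector `c(mean_host_w, mean_microbe_w)`.
#' @export
fitness_summary <- function(pop) {
  cfg <- pop$config
  rel <- pop$counts / cfg$C
  w_host <- host_fitness_vector(pop) / cfg$s_h
  f_m <- pop$cache$f_microbe
  if (is.matrix(f_m)) {
    w_mat <- f_m[pop$lineage, , drop = FALSE] / cfg$s_m
    w_microbe <- mean(rowSums(rel * w_mat))
  } else {
    w_microbe <- mean(drop(rel %*% (f_m / cfg$s_m)))
  }
  c(mean_host_w = mean(w_host), mean_microbe_w = w_microbe)
}

#' Log fold change between two positive means
#'
#' `log(final/initial)` in base 10 by default, matching the convention of
#' reporting fitness trajectories as log final fold change relative to the
#' initial level.
#'
#' @param final,initial positive values.
#' @param base logarithm base.
#' @return the log fold change.
#' @export
log_fold_change <- function(final, initial, base = 10) {
  if (any(final <= 0) || any(initial <= 0))
    stop("log fold change requires positive values")
  log(final / initial, base = base)
}

#' Beneficial / commensal / pathogenic composition
#'
#' Each OTU is classified by the sign of its net host-effect score
#' ([classify_otu()]); the population composition is the fraction of the
#' pooled population microbiome in each class, abundance-weighted. An
#' unweighted variant (fraction of OTU identities present anywhere in the
#' population) is reported alongside.
#'
#' @param pop a `holosim_population`.
#' @return data frame with columns `type`, `abundance` (abundance-weighted
#'   fractions, summing to 1) and `otus` (presence-based fractions).
#' @export
composition <- function(pop) {
  cls <- pop$cache$otu_class
  pooled <- colSums(pop$counts)
  ab <- tapply(pooled / sum(pooled), cls, sum, default = 0)
  present <- pooled > 0
  ot <- tapply(as.numeric(present), cls, sum, default = 0) / sum(present)
  data.frame(type = levels(cls),
             abundance = as.numeric(ab[levels(cls)]),
             otus = as.numeric(ot[levels(cls)]))
}

#' Consistency between host-effect and microbe-effect trait vectors
#'
#' cos(theta) = sum(h_k m_k) / sqrt(sum(h_k^2) sum(m_k^2)): +1 when the two
#' selection regimes favor exactly the same traits, -1 when they are fully
#' antagonistic. If either vector is all zero, one regime exerts no influence
#' and the consistency is 0 by convention.
#'
#' @param h host-effect score vector.
#' @param m microbe-effect score vector of the same length.
#' @return cosine in [-1, 1].
#' @export
consistency <- function(h, m) {
  if (length(h) != length(m)) stop("effect vectors must have equal length")
  nh <- sum(h^2); nm <- sum(m^2)
  if (nh == 0 || nm == 0) return(0)
  sum(h * m) / sqrt(nh * nm)
}

#' Population mean consistency
#'
#' The mean over hosts of each host's consistency between the universal
#' host-effect vector and the microbe-effect vector active in that host
#' (identical across hosts under TMS; lineage-specific under HMS; 0 with
#' microbial selection off).
#'
#' @param pop a `holosim_population`.
#' @return mean cosine in [-1, 1].
#' @export
mean_consistency <- function(pop) {
  cons <- pop$cache$consistency
  if (length(cons) > 1) mean(cons[pop$lineage]) else as.numeric(cons)
}

#' One-row summary of a population snapshot
#'
#' All statistics recorded along a run: generation index, alpha/beta/gamma
#' diversity, mean host and microbe relative fitness, abundance-weighted
#' beneficial/commensal/pathogenic fractions, and mean consistency.
#'
#' @param pop a `holosim_population`.
#' @return one-row data frame.
#' @export
summarize_generation <- function(pop) {
  div <- diversity_summary(pop$counts)
  fit <- fitness_summary(pop)
  comp <- composition(pop)
  data.frame(t = pop$t,
             alpha = div[["alpha"]], beta = div[["beta"]], gamma = div[["gamma"]],
             mean_host_w = fit[["mean_host_w"]],
             mean_microbe_w = fit[["mean_microbe_w"]],
             frac_beneficial = comp$abundance[comp$type == "beneficial"],
             frac_commensal = comp$abundance[comp$type == "commensal"],
             frac_pathogenic = comp$abundance[comp$type == "pathogenic"],
             mean_consistency = mean_consistency(pop))
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation between paired observations; requires at least
#' 3 pairs and nonzero variance in both.
#'
#' @param xs,ys paired numeric vectors.
#' @return the correlation coefficient r.
#' @export
pearson_r <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must be paired")
  if (length(xs) < 3) stop("at least 3 paired observations are required")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(xs, ys)
}
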