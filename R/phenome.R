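# Phenomes, trait effect scores, and the fitness map shared by hosts and
# microbes. A phenome is the fixed complement of m distinct traits carried by
# an OTU; each trait carries one score for the host it sits in and one score
# for the microbe itself, both in {-1, 0, +1}. Fitness is f = s^beta with beta
# the mean score over the phenome, so f is bounded in [1/s, s] and relative
# fitness w = f/s in [1/s^2, 1].

#' Assign phenomes to a set of OTUs
#'
#' Each OTU receives a phenome of `m` distinct trait indices sampled uniformly
#' without replacement from a pool of `n_traits` traits. Phenomes are fixed for
#' the whole simulation: there is no trait gain or loss, mutation, or
#' recombination.
#'
#' @param n_otu number of OTUs (rows of the returned matrix).
#' @param n_traits size of the trait pool.
#' @param m traits per phenome; must not exceed `n_traits`.
#' @return integer matrix with `n_otu` rows and `m` columns of trait indices
#'   in `1:n_traits`; each row has `m` distinct entries, sorted.
#' @examples
#' set.seed(1)
#' assign_phenomes(4, n_traits = 10, m = 5)
#' @export
assign_phenomes <- function(n_otu, n_traits, m) {
  if (m > n_traits)
    stop("traits per phenome (m = ", m, ") cannot exceed trait pool size (n_traits = ",
         n_traits, ")")
  if (n_otu < 1) stop("n_otu must be at least 1")
  t(vapply(seq_len(n_otu),
           function(i) sort(sample.int(n_traits, m)),
           integer(m)))
}

#' Draw a vector of trait effect scores
#'
#' Scores are i.i.d. over \{-1, 0, +1\} with probabilities `probs`
#' (negative, neutral, positive). The default is uniform, the maximum-entropy
#' choice on the stated support.
#'
#' @param n_traits length of the vector.
#' @param probs length-3 probability weights for (-1, 0, +1).
#' @return integer vector of length `n_traits` with values in \{-1, 0, 1\}.
#' @export
effect_scores <- function(n_traits, probs = c(1, 1, 1) / 3) {
  if (length(probs) != 3 || any(probs < 0) || sum(probs) <= 0)
    stop("probs must be 3 non-negative weights for (-1, 0, +1)")
  sample(c(-1L, 0L, 1L), n_traits, replace = TRUE, prob = probs)
}

#' Build the universal effect table for a run
#'
#' One host-effect vector (used by host selection, HS) and one microbe-effect
#' vector (used by trait-mediated microbial selection, TMS), drawn once at the
#' start of a run and fixed thereafter. The two vectors are drawn
#' independently; the realized correlation between them (the HS--TMS
#' consistency, [consistency()]) varies from run to run.
#'
#' @inheritParams effect_scores
#' @return list with integer vectors `host` and `microbe`, each of length
#'   `n_traits`.
#' @export
effect_table <- function(n_traits, probs = c(1, 1, 1) / 3) {
  list(host = effect_scores(n_traits, probs),
       microbe = effect_scores(n_traits, probs))
}

#' Draw heritable host-lineage influence vectors (HMS)
#'
#' Under host-mediated microbial selection every founding host lineage carries
#' its own microbe-effect vector, inherited verbatim by all its offspring.
#' Drawn once at seeding; no new vectors arise later.
#'
#' @param n_hosts number of founding lineages.
#' @inheritParams effect_scores
#' @return integer matrix, `n_hosts` x `n_traits`, values in \{-1, 0, 1\}.
#' @export
hms_influences <- function(n_hosts, n_traits, probs = c(1, 1, 1) / 3) {
  matrix(effect_scores(n_hosts * n_traits, probs), nrow = n_hosts)
}

#' Mean trait score of one phenome
#'
#' beta = (sum of effect scores over the phenome's traits) / m, in [-1, 1].
#'
#' @param phenome integer vector of trait indices.
#' @param effects length-`n_traits` score vector.
#' @return the mean score beta.
#' @export
trait_score <- function(phenome, effects) {
  if (any(phenome < 1L) || any(phenome > length(effects)))
    stop("phenome indexes traits outside the effect vector")
  mean(effects[phenome])
}

#' Mean trait scores for all OTUs at once
#'
#' Vectorized [trait_score()] over the rows of a phenome matrix.
#'
#' @param phenomes integer matrix of trait indices (one row per OTU).
#' @param effects length-`n_traits` score vector.
#' @return numeric vector of per-OTU mean scores.
#' @export
otu_trait_scores <- function(phenomes, effects) {
  if (max(phenomes) > length(effects))
    stop("phenomes index traits outside the effect vector")
  rowMeans(matrix(effects[phenomes], nrow = nrow(phenomes)))
}

#' Absolute fitness from a mean trait score
#'
#' f = s^beta. With s = 1 every fitness is 1 and the model collapses to the
#' neutral case; with s > 1, f ranges over [1/s, s].
#'
#' @param beta mean trait score in [-1, 1].
#' @param s selection coefficient, >= 1.
#' @return absolute fitness f.
#' @export
absolute_fitness <- function(beta, s) {
  if (any(s < 1)) stop("selection coefficient s must be >= 1")
  s^beta
}

#' Relative fitness
#'
#' w = f/s, the fitness relative to the fittest possible phenome (beta = 1).
#' Ranges over [1/s^2, 1]; the fittest agent is expected to leave s^2 times
#' as many descendants per generation as the least fit.
#'
#' @param f absolute fitness.
#' @param s selection coefficient, >= 1.
#' @return relative fitness w.
#' @export
relative_fitness <- function(f, s) {
  if (any(s < 1)) stop("selection coefficient s must be >= 1")
  f / s
}

#' Abundance-weighted host trait score
#'
#' The host's mean trait score is the abundance-weighted mean of its OTUs'
#' per-phenome host scores: beta_host = sum_i a_i * beta_i. Host fitness is
#' then `absolute_fitness(beta_host, s_h)`.
#'
#' @param abundances relative-abundance vector over OTUs (sums to 1).
#' @param phenomes integer phenome matrix (one row per OTU).
#' @param host_effects universal host-effect score vector.
#' @param tol tolerance on `sum(abundances) == 1`.
#' @return beta_host in [-1, 1].
#' @export
host_score <- function(abundances, phenomes, host_effects, tol = 1e-8) {
  if (length(abundances) != nrow(phenomes))
    stop("length(abundances) must equal nrow(phenomes)")
  if (abs(sum(abundances) - 1) > tol)
    stop("abundances must sum to 1")
  sum(abundances * otu_trait_scores(phenomes, host_effects))
}

#' Microbe-effect vector in a given host context
#'
#' Returns the trait-score vector that governs microbial acquisition for a
#' particular host: under TMS the universal microbe-effect vector (identical
#' in every host), under HMS the host lineage's heritable influence vector,
#' and with microbial selection off an all-zero vector (every microbe fitness
#' equals 1).
#'
#' @param mode one of `"none"`, `"tms"`, `"hms"`.
#' @param effects effect table from [effect_table()].
#' @param hms_influence the host's influence vector (required for `"hms"`).
#' @return length-`n_traits` score vector.
#' @export
microbe_effect_context <- function(mode = c("none", "tms", "hms"), effects,
                                   hms_influence = NULL) {
  mode <- match.arg(mode)
  switch(mode,
    none = integer(length(effects$host)),
    tms = effects$microbe,
    hms = {
      if (is.null(hms_influence))
        stop("mode 'hms' requires the host's influence vector")
      hms_influence
    })
}

#' Classify OTUs by their net effect on host fitness
#'
#' The sign of the summed host-effect scores over an OTU's phenome:
#' positive = beneficial, zero = commensal, negative = pathogenic. Host-effect
#' scores are universal in all selection modes, so this classification is the
#' same for every host (including under HMS, where only the microbe-effect
#' scores are host-specific).
#'
#' @param phenomes integer phenome matrix (one row per OTU).
#' @param host_effects universal host-effect score vector.
#' @return factor with levels `beneficial`, `commensal`, `pathogenic`.
#' @export
classify_otu <- function(phenomes, host_effects) {
  net <- rowSums(matrix(host_effects[phenomes], nrow = nrow(phenomes)))
  factor(ifelse(net > 0, "beneficial", ifelse(net < 0, "pathogenic", "commensal")),
         levels = c("beneficial", "commensal", "pathogenic"))
}

#' Default traits per phenome from genome-size scaling
#'
#' Bacterial genome sizes average ~3 Mbp with a maximum of ~14 Mbp. If phenome
#' size scales linearly with genome size and the largest genome carries the
#' full trait pool, the average phenome holds
#' `round(avg_genome / max_genome * n_traits)` traits -- 5 with the default
#' 25-trait pool.
#'
#' @param avg_genome_mbp average bacterial genome size (Mbp).
#' @param max_genome_mbp maximum bacterial genome size (Mbp).
#' @param n_traits trait-pool size carried by the maximum genome.
#' @return integer number of traits per phenome.
#' @export
default_traits_per_phenome <- function(avg_genome_mbp = 3, max_genome_mbp = 14,
                                       n_traits = 25) {
  if (max_genome_mbp <= 0 || avg_genome_mbp <= 0)
    stop("genome sizes must be positive")
  as.integer(round(avg_genome_mbp / max_genome_mbp * n_traits))
}
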