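## Exact computation with the inhomogeneous 1D Ising distribution of one
## estimation region.  All heavy chain recursions live in src/ising.cpp and
## use per-step rescaling, so partition functions and marginal likelihoods
## of chains with hundreds of sites and large |a|, |c| stay finite in
## double precision.

#' Build the per-site Ising potentials of a region
#'
#' Converts the five region parameters theta = (alpha', alpha, alpha'',
#' beta, gamma) into per-site fields and couplings: the region's first
#' and last CpG get the boundary intrinsic parameters alpha' and alpha''
#' in place of alpha (these absorb coupling across the region boundary,
#' keeping regions statistically independent), so
#' a_1 = alpha' + beta rho_1, a_R = alpha'' + beta rho_R,
#' a_n = alpha + beta rho_n otherwise, and c_n = gamma / d_n.
#'
#' @param theta numeric vector of length 5: `(alpha_p, alpha, alpha_pp,
#'   beta, gamma)`.
#' @param rho per-site CpG density of the region's sites.
#' @param dist per-site distances; entry 1 is ignored.
#' @return a [RegionModel-class].
#' @export
buildPotentials <- function(theta, rho, dist) {
  theta <- as.numeric(theta)
  if (length(theta) != 5L) stop("theta must have 5 entries")
  names(theta) <- c("alpha_p", "alpha", "alpha_pp", "beta", "gamma")
  R <- length(rho)
  if (R < 1L) stop("region must contain at least one CpG site")
  if (length(dist) != R) stop("rho and dist must have equal length")
  if (R > 1L && any(dist[-1L] <= 0, na.rm = FALSE))
    stop("distances must be positive")
  alpha <- rep(theta[["alpha"]], R)
  alpha[1L] <- theta[["alpha_p"]]
  alpha[R] <- theta[["alpha_pp"]]
  a <- alpha + theta[["beta"]] * rho
  cc <- rep(NA_real_, R)
  if (R > 1L) cc[-1L] <- theta[["gamma"]] / dist[-1L]
  new("RegionModel", theta = theta, a = a, c = cc)
}

#' Construct a RegionModel directly from fields and couplings
#'
#' Useful for simulation designs that specify constant `a` and `c` rather
#' than region parameters.
#'
#' @param a per-site field (recycled).
#' @param c per-pair coupling (recycled over pairs); ignored for R = 1.
#' @param R number of CpG sites.
#' @export
regionModel <- function(a, c = 0, R = length(a)) {
  a <- rep_len(a, R)
  cc <- c(NA_real_, rep_len(c, max(R - 1L, 0L)))[seq_len(R)]
  theta <- c(alpha_p = NA_real_, alpha = NA_real_, alpha_pp = NA_real_,
             beta = NA_real_, gamma = NA_real_)
  new("RegionModel", theta = theta, a = a, c = cc)
}

.modelC <- function(model) {
  cc <- model@c
  cc[1L] <- 0
  cc
}

#' Log partition function
#'
#' @param model a [RegionModel-class].
#' @return `log Z` (the partition function is returned in the log domain).
#' @export
logPartitionFunction <- function(model) {
  cpp_ising_logZ(model@a, .modelC(model))
}

#' Probability of one full methylation state
#'
#' @param model a [RegionModel-class].
#' @param x binary vector of length R.
#' @export
stateProbability <- function(model, x) {
  R <- length(model@a)
  if (length(x) != R) stop("state length must match the region")
  if (!all(x %in% c(0, 1))) stop("states must be binary")
  s <- 2 * x - 1
  cc <- .modelC(model)
  loge <- sum(model@a * s)
  if (R > 1L) loge <- loge + sum(cc[-1L] * s[-1L] * s[-R])
  exp(loge - logPartitionFunction(model))
}

#' Per-site methylation marginals `Pr(X_n = 1)`
#'
#' @param model a [RegionModel-class].
#' @export
siteMarginals <- function(model) {
  cpp_ising_site_marginals(model@a, .modelC(model))
}

#' Marginal likelihood of a partial observation
#'
#' Probability of the observed states after summing the Ising distribution
#' over all unobserved sites of the region.  When the observed sites form
#' one contiguous run the marginal is exact (message passing over the
#' flanks); otherwise the observation is split into maximal contiguous runs
#' and the product of the exact run marginals is returned, which treats the
#' runs as independent.  An empty observation has probability 1 by
#' convention.
#'
#' @param model a [RegionModel-class].
#' @param sites observed site indices (1-based within the region).
#' @param states observed binary states, parallel to `sites`.
#' @param log return the log probability?
#' @export
blockMarginalLikelihood <- function(model, sites, states, log = FALSE) {
  if (length(sites) != length(states)) stop("sites/states length mismatch")
  if (length(sites) == 0L) return(if (log) 0 else 1)
  o <- order(sites)
  sites <- as.integer(sites[o]); states <- as.integer(states[o])
  if (anyDuplicated(sites)) stop("duplicate observed sites")
  R <- length(model@a)
  if (any(sites < 1L | sites > R)) stop("site index outside the region")
  if (!all(states %in% c(0L, 1L))) stop("states must be binary")
  ll <- cpp_ising_read_logliks(model@a, .modelC(model),
                               c(0L, length(sites)), sites, states)[1L]
  if (log) ll else exp(ll)
}

#' Marginal likelihoods of many reads at once
#'
#' Vectorized over the reads of an [ObservationMatrix-class]; messages are
#' computed once per model.  Returns per-read log likelihoods.
#'
#' @param model a [RegionModel-class].
#' @param obs an [ObservationMatrix-class] over the same region.
#' @export
readLogLikelihoods <- function(model, obs) {
  cpp_ising_read_logliks(model@a, .modelC(model), obs@ptr, obs@sites,
                         obs@states)
}

#' PMF of the methylation level of a genomic unit
#'
#' Computes the distribution of L = (1/K) sum of the states of a contiguous
#' run of K CpG sites, marginalizing exactly over all other sites of the
#' region, by a dynamic program over (site, methylated count).
#'
#' @param model a [RegionModel-class].
#' @param guSites contiguous site indices of the GU (1-based within the
#'   region).
#' @return a [LevelPMF-class].
#' @export
levelPMF <- function(model, guSites) {
  guSites <- as.integer(guSites)
  if (length(guSites) == 0L) stop("GU must contain at least one CpG site")
  if (length(guSites) > 1L && any(diff(guSites) != 1L))
    stop("GU sites must be contiguous")
  R <- length(model@a)
  if (guSites[1L] < 1L || guSites[length(guSites)] > R)
    stop("GU outside the region")
  p <- cpp_ising_level_pmf(model@a, .modelC(model),
                           guSites[1L], guSites[length(guSites)])
  new("LevelPMF", K = length(guSites), p = as.numeric(p))
}

#' Exact samples from the region's Ising distribution
#'
#' Forward sampling using backward messages: X_1 from its exact marginal,
#' then each X_n from the exact conditional given X_{n-1}.  Driven by R's
#' RNG, so results are reproducible under `set.seed()`.
#'
#' @param model a [RegionModel-class].
#' @param n number of independent state vectors.
#' @param seed optional seed applied before sampling.
#' @return n x R binary matrix.
#' @export
sampleStates <- function(model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cpp_ising_sample(model@a, .modelC(model), as.integer(n))
}
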