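## Maximum marginal likelihood estimation of the five region parameters
## from incomplete reads, region eligibility filters, the unconstrained
## (2R - 1)-parameter Ising fit, and AIC model comparison.

#' Assemble an ObservationMatrix from a list of reads
#'
#' @param reads list; each element a list with integer `sites` (1-based CpG
#'   index within the region) and binary `states`.
#' @return an [ObservationMatrix-class].
#' @export
observationMatrix <- function(reads) {
  lens <- vapply(reads, function(r) length(r$sites), integer(1))
  sites <- integer(sum(lens)); states <- integer(sum(lens))
  off <- 0L
  for (r in reads) {
    o <- order(r$sites)
    n <- length(r$sites)
    sites[off + seq_len(n)] <- as.integer(r$sites[o])
    states[off + seq_len(n)] <- as.integer(r$states[o])
    off <- off + n
  }
  new("ObservationMatrix", ptr = c(0L, cumsum(lens)), sites = sites,
      states = states)
}

#' Region eligibility filters
#'
#' A region is modeled only when it has at least `minCpGs` CpG sites, at
#' least `minObsFraction` of its sites are observed by one or more reads,
#' and the average depth of coverage (total site observations per CpG
#' site) is at least `minDepth`.
#'
#' @param nSitesRegion number of CpG sites in the region.
#' @param obs an [ObservationMatrix-class].
#' @param minCpGs,minObsFraction,minDepth filter thresholds.
#' @return list with `pass` (logical) and `reason` (`NA`, `"min_sites"`,
#'   `"coverage_fraction"` or `"depth"`).
#' @export
regionEligible <- function(nSitesRegion, obs, minCpGs = 10,
                           minObsFraction = 2 / 3, minDepth = 2.5) {
  if (nSitesRegion < minCpGs)
    return(list(pass = FALSE, reason = "min_sites"))
  observed <- length(unique(obs@sites))
  if (observed / nSitesRegion < minObsFraction)
    return(list(pass = FALSE, reason = "coverage_fraction"))
  if (length(obs@sites) / nSitesRegion < minDepth)
    return(list(pass = FALSE, reason = "depth"))
  list(pass = TRUE, reason = NA_character_)
}

#' Average marginalized log-likelihood of the region parameters
#'
#' (1/M) sum over reads of the log marginal likelihood of the read's
#' observed states under the Ising model built from `theta`.
#'
#' @param theta 5-vector (alpha', alpha, alpha'', beta, gamma).
#' @param slice region layout slice from [regionSlice()].
#' @param obs an [ObservationMatrix-class].
#' @export
averageMarginalLogLik <- function(theta, slice, obs) {
  model <- buildPotentials(theta, slice$rho, slice$dist)
  mean(readLogLikelihoods(model, obs))
}

#' Optimizer configuration for region fitting
#'
#' A bounded, derivative-free, multi-start search: `nStarts` Nelder-Mead
#' runs from a fixed center start plus seeded random starts, each on a
#' logistic reparameterization of the box (so iterates always satisfy the
#' bounds), splitting `budget` function evaluations between starts.
#' Default bounds: |a_n| near 10 already saturates the site marginals, and
#' gamma / d with d >= 2 keeps couplings moderate.
#'
#' @param lower,upper box bounds for (alpha', alpha, alpha'', beta, gamma).
#' @param nStarts number of optimizer starts.
#' @param budget total function-evaluation budget.
#' @param reltol relative convergence tolerance per start.
#' @export
optimizerConfig <- function(lower = c(-10, -10, -10, -100, -20),
                            upper = c(10, 10, 10, 100, 20),
                            nStarts = 4L, budget = 5000L, reltol = 1e-8) {
  stopifnot(length(lower) == 5L, length(upper) == 5L, all(upper > lower))
  list(lower = lower, upper = upper, nStarts = as.integer(nStarts),
       budget = as.integer(budget), reltol = reltol)
}

.boxTransform <- function(u, lower, upper) {
  lower + (upper - lower) * stats::plogis(u)
}

.boxInverse <- function(theta, lower, upper) {
  z <- (theta - lower) / (upper - lower)
  stats::qlogis(pmin(pmax(z, 1e-8), 1 - 1e-8))
}

#' Fit the five region parameters by maximum marginal likelihood
#'
#' @param slice region layout slice from [regionSlice()].
#' @param obs an [ObservationMatrix-class] for the region.
#' @param config an [optimizerConfig()].
#' @param seed integer seed controlling the random starts (the fit is
#'   deterministic given the seed).
#' @return list (`FitResult`): `theta` (named 5-vector), `loglik` (average
#'   marginalized log-likelihood at the optimum), `nParams` = 5, `model`
#'   (the fitted [RegionModel-class]) and `status` (`"fitted"` or
#'   `"skipped(opt_fail)"`).
#' @export
estimateRegionParams <- function(slice, obs, config = optimizerConfig(),
                                 seed = 1L) {
  if (nReads(obs) == 0L)
    return(list(theta = NULL, loglik = NA_real_, nParams = 5L,
                model = NULL, status = "skipped(no_reads)"))
  negobj <- function(u) {
    theta <- .boxTransform(u, config$lower, config$upper)
    ll <- averageMarginalLogLik(theta, slice, obs)
    if (!is.finite(ll)) 1e10 else -ll
  }
  mid <- .boxInverse((config$lower + config$upper) / 2,
                     config$lower, config$upper)
  starts <- list(mid)
  if (config$nStarts > 1L) {
    rng <- .withSeed(seed, {
      matrix(stats::runif(5L * (config$nStarts - 1L), 0.2, 0.8),
             ncol = 5L)
    })
    for (i in seq_len(config$nStarts - 1L))
      starts[[i + 1L]] <- stats::qlogis(rng[i, ])
  }
  maxit <- max(100L, config$budget %/% config$nStarts)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, negobj, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = config$reltol)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best) || !is.finite(best$value))
    return(list(theta = NULL, loglik = NA_real_, nParams = 5L,
                model = NULL, status = "skipped(opt_fail)"))
  theta <- .boxTransform(best$par, config$lower, config$upper)
  names(theta) <- c("alpha_p", "alpha", "alpha_pp", "beta", "gamma")
  model <- buildPotentials(theta, slice$rho, slice$dist)
  list(theta = theta, loglik = -best$value, nParams = 5L, model = model,
       status = "fitted")
}

#' Fit the unconstrained Ising model (2R - 1 free parameters)
#'
#' Maximizes the same marginal likelihood over all per-site fields a_n and
#' per-pair couplings c_n, without the density/distance parameterization.
#' Initialized from the constrained fit when supplied, which guarantees the
#' achieved likelihood is no worse than the constrained one (nesting).
#'
#' @param slice region layout slice.
#' @param obs an [ObservationMatrix-class].
#' @param init optional constrained `FitResult` used as starting point.
#' @param maxR complexity guard: regions with more CpG sites are skipped.
#' @param bounds box half-width for each free parameter.
#' @param maxit optimizer iteration cap.
#' @return a `FitResult` list with `nParams = 2R - 1` and a `model`.
#' @export
fitGeneralIsing <- function(slice, obs, init = NULL, maxR = 25L,
                            bounds = 20, maxit = 2000L) {
  R <- length(slice$rho)
  if (R > maxR)
    return(list(theta = NULL, loglik = NA_real_, nParams = 2L * R - 1L,
                model = NULL, status = "skipped(too_large)"))
  p0 <- if (!is.null(init) && !is.null(init$model)) {
    c(init$model@a, if (R > 1L) init$model@c[-1L])
  } else {
    numeric(2L * R - 1L)
  }
  p0 <- pmin(pmax(p0, -bounds + 1e-6), bounds - 1e-6)
  mkmodel <- function(p) {
    regionModel(a = p[seq_len(R)],
                c = if (R > 1L) p[R + seq_len(R - 1L)] else 0, R = R)
  }
  negobj <- function(p) {
    ll <- mean(readLogLikelihoods(mkmodel(p), obs))
    if (!is.finite(ll)) 1e10 else -ll
  }
  fit <- optim(p0, negobj, method = "L-BFGS-B", lower = -bounds,
               upper = bounds, control = list(maxit = maxit))
  model <- mkmodel(fit$par)
  list(theta = fit$par, loglik = -fit$value, nParams = 2L * R - 1L,
       model = model, status = "fitted")
}

#' AIC comparison of the constrained and unconstrained Ising fits
#'
#' AIC_i = -2 * M * (average marginalized log-likelihood of fit i) + 2 p_i.
#' The AIC probability that model 1 is the best of the pair is
#' pi = exp(-Delta_1/2) / (exp(-Delta_1/2) + exp(-Delta_2/2)) with
#' Delta_i = AIC_i - min(AIC_1, AIC_2).
#'
#' @param fit1,fit2 `FitResult` lists on the same data (fit1 constrained,
#'   fit2 unconstrained).
#' @param obs the shared [ObservationMatrix-class].
#' @return list (`ModelComparison`) with `aic1`, `aic2`, `pi`.
#' @export
aicCompare <- function(fit1, fit2, obs) {
  M <- nReads(obs)
  aic <- function(f) -2 * M * f$loglik + 2 * f$nParams
  a1 <- aic(fit1); a2 <- aic(fit2)
  d1 <- a1 - min(a1, a2); d2 <- a2 - min(a1, a2)
  list(aic1 = a1, aic2 = a2,
       pi = exp(-d1 / 2) / (exp(-d1 / 2) + exp(-d2 / 2)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
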