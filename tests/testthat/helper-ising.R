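# Brute-force enumeration oracle for the 1D Ising chain: sums over all 2^R
# states directly.  Independent of the transfer-matrix implementation.
bruteIsing <- function(a, cc) {
  R <- length(a)
  states <- as.matrix(expand.grid(rep(list(0:1), R)))
  colnames(states) <- NULL
  e <- apply(states, 1, function(x) {
    s <- 2 * x - 1
    sum(a * s) + if (R > 1) sum(cc * s[-1] * s[-R]) else 0
  })
  w <- exp(e)
  list(Z = sum(w), p = w / sum(w), states = states)
}

bruteMarginals <- function(b) {
  vapply(seq_len(ncol(b$states)), function(n) sum(b$p[b$states[, n] == 1]),
         numeric(1))
}

bruteLevelPMF <- function(b, guCols) {
  cnt <- rowSums(b$states[, guCols, drop = FALSE])
  as.numeric(tapply(b$p, factor(cnt, levels = 0:length(guCols)), sum,
                    default = 0))
}

# marginal prob of observing fixed states at a site subset
bruteBlockMarginal <- function(b, sites, st) {
  keep <- rep(TRUE, nrow(b$states))
  for (k in seq_along(sites)) keep <- keep & b$states[, sites[k]] == st[k]
  sum(b$p[keep])
}

randomModel <- function(R, scale = 1) {
  regionModel(a = stats::rnorm(R, 0, scale),
              c = if (R > 1) stats::rnorm(R - 1, 0, scale) else 0, R = R)
}

# uniform-island layout slice used in estimation tests
uniformSlice <- function(R = 20, spacing = 15) {
  pos <- seq(1L, by = spacing, length.out = R)
  d <- computeCpGDistances(pos)
  d[1] <- NA
  list(sites = seq_len(R), positions = pos,
       rho = computeCpGDensity(pos), dist = d)
}

fullReadObs <- function(states) {
  observationMatrix(lapply(seq_len(nrow(states)), function(i)
    list(sites = seq_len(ncol(states)), states = states[i, ])))
}
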