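# Independent brute-force oracles: hand-coded densities and enumerations,
# kept free of the package's vectorised code paths.

oracle_pois_logpmf <- function(x, lambda) {
  x * log(lambda) - lambda - lgamma(x + 1)
}

oracle_normal_logpdf <- function(x, mu, sd) {
  -0.5 * log(2 * pi) - log(sd) - 0.5 * ((x - mu) / sd)^2
}

# Triple-loop Poisson log-likelihood over observed cells.
oracle_loglik <- function(dataset, latent, dynamics) {
  dm <- dim(dataset$counts)
  total <- 0
  for (d in seq_len(dm[1])) {
    td <- latent$times[latent$permutation[d]]
    for (m in seq_len(dm[2])) for (l in seq_len(dm[3])) {
      if (!dataset$mask[d, m, l]) next
      lam <- exp(dynamics$layer_k[m, l] * td + dynamics$layer_a[m, l])
      total <- total + oracle_pois_logpmf(dataset$counts[d, m, l], lam)
    }
  }
  total
}

# Term-by-term hierarchical prior log-density.
oracle_logprior <- function(dynamics) {
  total <- 0
  M <- length(dynamics$population_a)
  L <- ncol(dynamics$layer_a)
  for (m in seq_len(M)) {
    total <- total + oracle_normal_logpdf(dynamics$population_a[m], 0, 1) +
      oracle_normal_logpdf(dynamics$population_k[m], 0, 1)
    for (l in seq_len(L)) {
      total <- total +
        oracle_normal_logpdf(dynamics$layer_a[m, l], dynamics$population_a[m], 1) +
        oracle_normal_logpdf(dynamics$layer_k[m, l], dynamics$population_k[m], 1)
    }
  }
  total
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (i in 0:(n - 1)) {
      out <- c(out, list(append(p, n, after = i)))
    }
  }
  out
}

# Random small model instance with a fixed seed.
random_instance <- function(D, M, L, seed, missing = 0.15) {
  set.seed(seed)
  dyn <- dynamics_params(
    population_a = rnorm(M), population_k = rnorm(M),
    layer_a = matrix(rnorm(M * L, 0, 1), M, L),
    layer_k = matrix(rnorm(M * L, 0, 1), M, L))
  lat <- latent_state(sort(runif(D)), sample.int(D))
  counts <- array(rpois(D * M * L, 3), c(D, M, L))
  mask <- array(runif(D * M * L) >= missing, c(D, M, L))
  for (d in which(rowSums(matrix(mask, D)) == 0)) mask[d, 1, 1] <- TRUE
  for (m in which(!apply(mask, 2, any))) mask[1, m, 1] <- TRUE
  list(dataset = neuropath_dataset(counts, mask), latent = lat, dynamics = dyn)
}
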