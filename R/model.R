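#' Dynamic parameters of the exponential pathology model
#'
#' Each measurement m has population-level intercept `a_m` and slope `k_m`;
#' each measurement-layer pair has layer-level `a_m^l`, `k_m^l` drawn around
#' the population values. The expected count in a cell is
#' `exp(k_m^l * t + a_m^l)` at latent time t, so `k` is the (exponential)
#' rise rate of the pathology variable and `a` its log initial level.
#'
#' @param population_a,population_k numeric vectors of length M.
#' @param layer_a,layer_k numeric M x L matrices.
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(population_a, population_k, layer_a, layer_k) {
  layer_a <- as.matrix(layer_a); layer_k <- as.matrix(layer_k)
  M <- length(population_a)
  if (length(population_k) != M) stop("population parameter lengths differ")
  if (!identical(dim(layer_a), dim(layer_k)) || nrow(layer_a) != M)
    stop("layer parameter shapes inconsistent with population parameters")
  vals <- c(population_a, population_k, layer_a, layer_k)
  if (any(!is.finite(vals))) stop("dynamic parameters must be finite")
  structure(list(population_a = as.numeric(population_a),
                 population_k = as.numeric(population_k),
                 layer_a = layer_a, layer_k = layer_k),
            class = "dynamics_params")
}

#' Latent donor ordering state
#'
#' `times` is the sorted vector of latent times (the CPS values attached to
#' the D rank slots) and `permutation` assigns each donor to a slot:
#' donor d sits at time `times[permutation[d]]`.
#'
#' @param times numeric vector, sorted ascending, all in `[0, 1]`.
#' @param permutation integer permutation of `seq_along(times)`.
#' @return An object of class `latent_state`.
#' @export
latent_state <- function(times, permutation = seq_along(times)) {
  times <- as.numeric(times)
  permutation <- as.integer(permutation)
  if (is.unsorted(times)) stop("`times` must be sorted ascending")
  if (any(times < 0 | times > 1)) stop("`times` must lie in [0, 1]")
  if (!setequal(permutation, seq_along(times)) ||
      length(permutation) != length(times))
    stop("`permutation` must be a permutation of the donor indices")
  structure(list(times = times, permutation = permutation),
            class = "latent_state")
}

#' Expected count under the exponential dynamics
#'
#' The observation model's mean: `exp(slope * time + intercept)`.
#'
#' @param time latent time in `[0, 1]` (vectorised).
#' @param slope,intercept dynamic parameters.
#' @return Strictly positive rate(s).
#' @examples
#' poisson_rate(0, 5, 0)            # 1
#' poisson_rate(1, log(2), log(3))  # 6
#' @export
poisson_rate <- function(time, slope, intercept) {
  stopifnot(all(time >= 0 & time <= 1))
  exp(slope * time + intercept)
}

.check_shapes <- function(dataset, latent, dynamics) {
  dm <- dim(dataset$counts)
  if (length(latent$times) != dm[1])
    stop("latent state has ", length(latent$times), " donors, dataset ", dm[1])
  if (nrow(dynamics$layer_a) != dm[2] || ncol(dynamics$layer_a) != dm[3])
    stop("dynamics shaped ", nrow(dynamics$layer_a), "x", ncol(dynamics$layer_a),
         ", dataset needs ", dm[2], "x", dm[3])
}

# Core likelihood on flattened matrices; kv/av are length-V layer params.
.loglik_flat <- function(fl, td, kv, av) {
  eta <- outer(td, kv) + rep(av, each = length(td))
  sum(fl$W * (fl$X * eta - exp(eta)) - fl$lgX)
}

#' Poisson log-likelihood of a dataset
#'
#' Sum over observed cells of the Poisson log-pmf of count `X_d^{m,l}` at
#' rate `exp(k_m^l * t_{pi(d)} + a_m^l)`; masked cells contribute nothing.
#'
#' @param dataset a [neuropath_dataset()].
#' @param latent a [latent_state()].
#' @param dynamics a [dynamics_params()].
#' @return Finite scalar log-likelihood.
#' @export
log_likelihood <- function(dataset, latent, dynamics) {
  .check_shapes(dataset, latent, dynamics)
  fl <- .flatten_dataset(dataset)
  td <- latent$times[latent$permutation]
  .loglik_flat(fl, td, as.vector(dynamics$layer_k), as.vector(dynamics$layer_a))
}

#' Log-density of the hierarchical prior on the dynamic parameters
#'
#' Population parameters are standard normal; layer parameters are normal
#' with unit standard deviation around their population values.
#'
#' @inheritParams log_likelihood
#' @return Scalar log prior density.
#' @export
log_prior_dynamics <- function(dynamics) {
  sum(stats::dnorm(dynamics$population_a, 0, 1, log = TRUE)) +
    sum(stats::dnorm(dynamics$population_k, 0, 1, log = TRUE)) +
    sum(stats::dnorm(dynamics$layer_a, dynamics$population_a, 1, log = TRUE)) +
    sum(stats::dnorm(dynamics$layer_k, dynamics$population_k, 1, log = TRUE))
}

#' Unnormalised log joint density
#'
#' `log_likelihood + log_prior_dynamics`. The priors on the sorted times
#' (uniform order statistics) and the permutation (uniform) are flat over
#' their supports and enter only as constants, so they are dropped.
#'
#' @inheritParams log_likelihood
#' @return Scalar unnormalised log joint.
#' @export
log_joint <- function(dataset, latent, dynamics) {
  log_likelihood(dataset, latent, dynamics) + log_prior_dynamics(dynamics)
}

#' Apply the direction-flip symmetry to a latent state and dynamics
#'
#' The model is invariant under reversing the disease direction:
#' `t -> 1 - t` (with slot order reversed), `k -> -k`, `a -> a + k` at both
#' layer and population level. This map preserves the likelihood exactly and
#' is an involution; [orient_draws()] uses it to fix the direction so that
#' CPS increases with pathology.
#'
#' @param latent a [latent_state()].
#' @param dynamics a [dynamics_params()].
#' @return List with flipped `latent` and `dynamics`.
#' @export
flip_state <- function(latent, dynamics) {
  D <- length(latent$times)
  list(
    latent = latent_state(rev(1 - latent$times), D + 1L - latent$permutation),
    dynamics = dynamics_params(
      dynamics$population_a + dynamics$population_k,
      -dynamics$population_k,
      dynamics$layer_a + dynamics$layer_k,
      -dynamics$layer_k))
}
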