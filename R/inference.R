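#' Configuration for the block Gibbs sampler
#'
#' One sweep updates, in order, the sorted latent times (slice sampling
#' within neighbour brackets), the donor permutation (Gumbel-Sinkhorn with
#' Hungarian rounding) and the dynamic parameters (exact Gibbs for the
#' population level, adaptive random-walk Metropolis for the layer level).
#'
#' @param n_sweeps total Gibbs sweeps per chain.
#' @param burn_in sweeps discarded (and used for proposal adaptation);
#'   must be `< n_sweeps`.
#' @param n_chains number of independently initialised chains.
#' @param sinkhorn_temperature positive relaxation temperature for the
#'   permutation block.
#' @param sinkhorn_iters Sinkhorn balancing iterations.
#' @param dynamics_steps_per_sweep Metropolis scans of the layer parameters
#'   per sweep.
#' @param seed integer master seed; chain c runs on `seed + 1000 * (c - 1)`.
#' @param anchor_measurement measurement name or index used by
#'   [orient_draws()] to fix the disease direction, or `NULL` to pick the
#'   measurement with the largest posterior mean |population slope|.
#' @return An object of class `gibbs_config`.
#' @export
gibbs_config <- function(n_sweeps = 500L, burn_in = 100L, n_chains = 2L,
                         sinkhorn_temperature = 1, sinkhorn_iters = 100L,
                         dynamics_steps_per_sweep = 2L, seed = 1L,
                         anchor_measurement = NULL) {
  stopifnot(n_sweeps >= 1, burn_in >= 0, burn_in < n_sweeps, n_chains >= 1,
            sinkhorn_temperature > 0, sinkhorn_iters >= 1,
            dynamics_steps_per_sweep >= 1)
  structure(list(n_sweeps = as.integer(n_sweeps), burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains),
                 sinkhorn_temperature = sinkhorn_temperature,
                 sinkhorn_iters = as.integer(sinkhorn_iters),
                 dynamics_steps_per_sweep = as.integer(dynamics_steps_per_sweep),
                 seed = as.integer(seed),
                 anchor_measurement = anchor_measurement),
            class = "gibbs_config")
}

# log-likelihood of one donor's observed cells at candidate time t, up to the
# lgamma constant: sum_v W (X * eta - exp(eta)).
.donor_loglik_t <- function(t, x, w, kv, av) {
  eta <- kv * t + av
  sum(w * (x * eta - exp(eta)))
}

#' Slice-sample the sorted latent times
#'
#' Updates each slot's time by slice sampling its full conditional -- the
#' Poisson likelihood of the donor occupying that slot -- restricted to the
#' bracket formed by the neighbouring times (boundary slots clamped to
#' `[0, 1]`). Under the uniform order-statistics prior the conditional of one
#' sorted time given the others is flat on the bracket, so a flat likelihood
#' leaves the prior invariant.
#'
#' @param dataset a [neuropath_dataset()].
#' @param permutation integer permutation (donor d occupies slot
#'   `permutation[d]`).
#' @param dynamics a [dynamics_params()].
#' @param current_times sorted numeric vector in `[0, 1]`.
#' @param max_shrink maximum shrinkage steps per slice update.
#' @return Updated sorted times vector.
#' @export
sample_times <- function(dataset, permutation, dynamics, current_times,
                         max_shrink = 100L) {
  .sample_times_fl(.flatten_dataset(dataset), as.vector(dynamics$layer_k),
                   as.vector(dynamics$layer_a), permutation, current_times,
                   max_shrink)
}

.sample_times_fl <- function(fl, kv, av, permutation, current_times,
                             max_shrink = 100L) {
  D <- length(current_times)
  inv <- integer(D); inv[permutation] <- seq_len(D)  # slot -> donor
  t <- current_times
  for (j in seq_len(D)) {
    lo <- if (j == 1L) 0 else t[j - 1L]
    hi <- if (j == D) 1 else t[j + 1L]
    if (hi - lo <= 0) next
    d <- inv[j]
    x <- fl$X[d, ]; w <- fl$W[d, ]
    f0 <- .donor_loglik_t(t[j], x, w, kv, av)
    logy <- f0 - stats::rexp(1)
    L <- lo; R <- hi
    for (i in seq_len(max_shrink)) {
      prop <- stats::runif(1, L, R)
      if (.donor_loglik_t(prop, x, w, kv, av) >= logy) {
        t[j] <- prop
        break
      }
      if (prop < t[j]) L <- prop else R <- prop
    }
  }
  t
}

#' Donor-by-slot log-likelihood score matrix
#'
#' Entry `(d, j)` is the Poisson log-likelihood of donor d's observed cells
#' evaluated at slot time `t_j`; the input to the Gumbel-Sinkhorn
#' permutation block.
#'
#' @param dataset a [neuropath_dataset()].
#' @param times sorted slot times.
#' @param dynamics a [dynamics_params()].
#' @return D x D numeric matrix of finite log-likelihood scores.
#' @export
permutation_score_matrix <- function(dataset, times, dynamics) {
  .score_matrix_fl(.flatten_dataset(dataset), times,
                   as.vector(dynamics$layer_k), as.vector(dynamics$layer_a))
}

.score_matrix_fl <- function(fl, times, kv, av) {
  eta <- outer(times, kv) + rep(av, each = length(times))  # slots x V
  (fl$X * fl$W) %*% t(eta) - fl$W %*% t(exp(eta)) - rowSums(fl$lgX)
}

# Log-domain Sinkhorn balancing of scores/temperature.
.sinkhorn_log <- function(scores, temperature, n_iters) {
  lm <- scores / temperature
  for (i in seq_len(n_iters)) {
    lm <- lm - .row_lse(lm)
    lm <- sweep(lm, 2, .col_lse(lm))
  }
  lm
}

#' Sinkhorn balancing of a score matrix
#'
#' Computes `exp(scores / temperature)` and alternately normalises rows and
#' columns `n_iters` times (carried out in log space), yielding an
#' approximately doubly stochastic relaxation of the permutation implied by
#' the scores.
#'
#' @param scores finite D x D matrix.
#' @param temperature positive relaxation temperature.
#' @param n_iters balancing iterations.
#' @return D x D nonnegative matrix with row and column sums near 1.
#' @export
sinkhorn_normalize <- function(scores, temperature = 1, n_iters = 100L) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores),
            all(is.finite(scores)), temperature > 0, n_iters >= 1)
  exp(.sinkhorn_log(scores, temperature, n_iters))
}

#' Sample a donor permutation via Gumbel-Sinkhorn
#'
#' Perturbs the donor-by-slot score matrix with i.i.d. Gumbel(0,1) noise,
#' balances it with Sinkhorn iterations at the configured temperature, and
#' rounds the log of the balanced matrix to a hard permutation by
#' maximum-weight bipartite matching. This approximates the intractable
#' conditional over permutations; with `gumbel_noise = FALSE` it returns the
#' deterministic matching on the raw scores.
#'
#' @param dataset a [neuropath_dataset()].
#' @param times sorted slot times.
#' @param dynamics a [dynamics_params()].
#' @param temperature,sinkhorn_iters Sinkhorn parameters.
#' @param gumbel_noise add Gumbel perturbation (set `FALSE` for the
#'   deterministic argmax assignment).
#' @return Integer permutation: donor d is assigned slot `result[d]`.
#' @export
sample_permutation <- function(dataset, times, dynamics, temperature = 1,
                               sinkhorn_iters = 100L, gumbel_noise = TRUE) {
  .sample_permutation_scores(
    permutation_score_matrix(dataset, times, dynamics),
    temperature, sinkhorn_iters, gumbel_noise)
}

.sample_permutation_scores <- function(scores, temperature = 1,
                                       sinkhorn_iters = 100L,
                                       gumbel_noise = TRUE) {
  D <- nrow(scores)
  if (D == 1L) return(1L)
  if (gumbel_noise) scores <- scores + matrix(.rgumbel(D * D), D, D)
  lm <- .sinkhorn_log(scores, temperature, sinkhorn_iters)
  .max_assignment(pmax(lm, -1e6))
}

# Conditional Gibbs draw of a population parameter given its layer values:
# Normal(0,1) prior and L Normal(., 1) likelihood terms give
# Normal(sum(layer)/ (L+1), 1/(L+1)).
.draw_population <- function(layer_mat) {
  L <- ncol(layer_mat)
  stats::rnorm(nrow(layer_mat), rowSums(layer_mat) / (L + 1), sqrt(1 / (L + 1)))
}

#' Metropolis-within-Gibbs update of the dynamic parameters
#'
#' Population intercepts and slopes are conjugate given the layer values and
#' are drawn exactly. Layer parameters are updated one at a time by
#' random-walk Metropolis on their full conditional (Poisson likelihood of
#' the D cells in that measurement-layer column plus the Normal(population,
#' 1) prior). Proposal scales adapt toward a 0.44 acceptance rate while
#' `adapt = TRUE` (burn-in only) and are frozen afterwards, so the stored
#' draws come from a fixed, detailed-balance-respecting kernel.
#'
#' @param dataset a [neuropath_dataset()].
#' @param times sorted slot times.
#' @param permutation donor-to-slot assignment.
#' @param dynamics current [dynamics_params()].
#' @param steps Metropolis scans over all layer parameters.
#' @param state sampler state (proposal scales, acceptance counts) as
#'   returned by a previous call, or `NULL` to initialise.
#' @param adapt adapt proposal scales (use only during burn-in).
#' @return List: updated `dynamics`, updated `state` (with elements
#'   `scale_a`, `scale_k`, `accept`, `proposals`).
#' @export
sample_dynamics <- function(dataset, times, permutation, dynamics,
                            steps = 1L, state = NULL, adapt = FALSE) {
  .sample_dynamics_fl(.flatten_dataset(dataset), times, permutation, dynamics,
                      steps, state, adapt)
}

.sample_dynamics_fl <- function(fl, times, permutation, dynamics,
                                steps = 1L, state = NULL, adapt = FALSE) {
  td <- times[permutation]
  M <- nrow(dynamics$layer_a); L <- ncol(dynamics$layer_a)
  V <- M * L
  if (is.null(state))
    state <- list(scale_a = rep(0.5, V), scale_k = rep(0.5, V),
                  accept = 0, proposals = 0)
  la <- as.vector(dynamics$layer_a); lk <- as.vector(dynamics$layer_k)
  pa <- dynamics$population_a; pk <- dynamics$population_k
  mi <- fl$meas_index
  # per-column cached conditional log-density (likelihood + prior)
  col_logp <- function(v, a, k) {
    eta <- k * td + a
    sum(fl$W[, v] * (fl$X[, v] * eta - exp(eta))) +
      stats::dnorm(a, pa[mi[v]], 1, log = TRUE) +
      stats::dnorm(k, pk[mi[v]], 1, log = TRUE)
  }
  acc <- 0; nprop <- 0
  for (s in seq_len(steps)) {
    pa <- .draw_population(matrix(la, M, L))
    pk <- .draw_population(matrix(lk, M, L))
    for (v in seq_len(V)) {
      cur <- col_logp(v, la[v], lk[v])
      # intercept update
      prop_a <- la[v] + state$scale_a[v] * stats::rnorm(1)
      new <- col_logp(v, prop_a, lk[v])
      nprop <- nprop + 1
      ok <- is.finite(new) && log(stats::runif(1)) < new - cur
      if (ok) { la[v] <- prop_a; cur <- new; acc <- acc + 1 }
      if (adapt) state$scale_a[v] <- state$scale_a[v] *
          exp(0.1 * ((if (ok) 1 else 0) - 0.44))
      # slope update
      prop_k <- lk[v] + state$scale_k[v] * stats::rnorm(1)
      new <- col_logp(v, la[v], prop_k)
      nprop <- nprop + 1
      ok <- is.finite(new) && log(stats::runif(1)) < new - cur
      if (ok) { lk[v] <- prop_k; acc <- acc + 1 }
      if (adapt) state$scale_k[v] <- state$scale_k[v] *
          exp(0.1 * ((if (ok) 1 else 0) - 0.44))
    }
  }
  state$accept <- state$accept + acc
  state$proposals <- state$proposals + nprop
  list(dynamics = dynamics_params(pa, pk, matrix(la, M, L), matrix(lk, M, L)),
       state = state)
}

#' Run the block Gibbs sampler
#'
#' Cycles times, permutation and dynamics updates for `n_sweeps` sweeps in
#' each of `n_chains` chains, storing post-burn-in draws. Chains initialise
#' times at equal spacing `j/(D+1)`, the permutation from the donors' total
#' observed counts perturbed by Gumbel jitter (an informative but
#' chain-randomised start), and the dynamics from the hierarchical prior.
#'
#' @param dataset a [neuropath_dataset()].
#' @param config a [gibbs_config()].
#' @return An object of class `cps_draws`: list with `times` (S x D),
#'   `permutation` (S x D), `population_a`/`population_k` (S x M), `layer_a`/
#'   `layer_k` (S x M x L arrays), `log_joint` (S), `chain` (S),
#'   `acceptance` (per-chain dynamics acceptance rate), plus dataset labels
#'   and the config.
#' @export
run_gibbs <- function(dataset, config) {
  stopifnot(inherits(dataset, "neuropath_dataset"),
            inherits(config, "gibbs_config"))
  dm <- dim(dataset$counts)
  D <- dm[1]; M <- dm[2]; L <- dm[3]
  S_per <- config$n_sweeps - config$burn_in
  S <- S_per * config$n_chains
  out <- list(times = matrix(NA_real_, S, D),
              permutation = matrix(NA_integer_, S, D),
              population_a = matrix(NA_real_, S, M),
              population_k = matrix(NA_real_, S, M),
              layer_a = array(NA_real_, c(S, M, L)),
              layer_k = array(NA_real_, c(S, M, L)),
              log_joint = numeric(S), chain = integer(S),
              acceptance = numeric(config$n_chains),
              donor_ids = dataset$donor_ids,
              measurement_names = dataset$measurement_names,
              layer_names = dataset$layer_names,
              config = config)
  fl <- .flatten_dataset(dataset)
  total <- rowSums(fl$X * fl$W)
  row <- 0L
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 1000L * (ch - 1L))
    t <- seq_len(D) / (D + 1)
    perm <- rank(rank(total) + .rgumbel(D), ties.method = "first")
    pa <- stats::rnorm(M); pk <- stats::rnorm(M)
    dyn <- dynamics_params(pa, pk,
                           matrix(stats::rnorm(M * L, pa, 1), M, L),
                           matrix(stats::rnorm(M * L, pk, 1), M, L))
    dstate <- NULL
    lj <- .loglik_flat(fl, t[perm], as.vector(dyn$layer_k),
                       as.vector(dyn$layer_a)) + log_prior_dynamics(dyn)
    if (!is.finite(lj)) stop("bad initialization: non-finite log joint")
    for (sweep in seq_len(config$n_sweeps)) {
      kv <- as.vector(dyn$layer_k); av <- as.vector(dyn$layer_a)
      t <- .sample_times_fl(fl, kv, av, perm, t)
      perm <- .sample_permutation_scores(
        .score_matrix_fl(fl, t, kv, av),
        temperature = config$sinkhorn_temperature,
        sinkhorn_iters = config$sinkhorn_iters)
      upd <- .sample_dynamics_fl(fl, t, perm, dyn,
                                 steps = config$dynamics_steps_per_sweep,
                                 state = dstate,
                                 adapt = sweep <= config$burn_in)
      dyn <- upd$dynamics; dstate <- upd$state
      if (sweep > config$burn_in) {
        row <- row + 1L
        out$times[row, ] <- t
        out$permutation[row, ] <- perm
        out$population_a[row, ] <- dyn$population_a
        out$population_k[row, ] <- dyn$population_k
        out$layer_a[row, , ] <- dyn$layer_a
        out$layer_k[row, , ] <- dyn$layer_k
        out$log_joint[row] <- .loglik_flat(fl, t[perm], as.vector(dyn$layer_k),
                                           as.vector(dyn$layer_a)) +
          log_prior_dynamics(dyn)
        out$chain[row] <- ch
      }
    }
    out$acceptance[ch] <- dstate$accept / dstate$proposals
  }
  class(out) <- "cps_draws"
  out
}

#' @export
print.cps_draws <- function(x, ...) {
  cat(sprintf("cps_draws: %d draws (%d chains) for %d donors, %d measurements x %d layers\n",
              nrow(x$times), length(unique(x$chain)), ncol(x$times),
              ncol(x$population_a), dim(x$layer_a)[3]))
  invisible(x)
}

.resolve_measurement <- function(x, measurement_names) {
  if (is.numeric(x)) {
    if (x < 1 || x > length(measurement_names)) stop("anchor index out of range")
    return(as.integer(x))
  }
  idx <- match(x, measurement_names)
  if (is.na(idx)) stop("unknown anchor measurement: ", x)
  idx
}

#' Orient posterior draws so CPS increases with pathology
#'
#' The likelihood is invariant under the direction flip (`t -> 1 - t` with
#' slots reversed, `k -> -k`, `a -> a + k`); draws therefore mix between the
#' two mirror modes. This applies the exact flip to every draw whose anchor
#' population slope is negative, after which all draws satisfy
#' `population_k[anchor] >= 0`. The flip preserves each draw's likelihood, so
#' the operation is pure post-processing.
#'
#' @param draws a `cps_draws` object.
#' @param anchor_measurement measurement name or index whose population slope
#'   is constrained nonnegative; `NULL` uses the config's anchor, or failing
#'   that the measurement with largest mean |population slope|.
#' @return Oriented `cps_draws` (with attribute `anchor` set).
#' @export
orient_draws <- function(draws, anchor_measurement = NULL) {
  anchor_measurement <- anchor_measurement %||%
    draws$config$anchor_measurement %||%
    which.max(abs(colMeans(draws$population_k)))
  anchor <- .resolve_measurement(anchor_measurement, draws$measurement_names)
  flip <- draws$population_k[, anchor] < 0
  if (any(flip)) {
    D <- ncol(draws$times)
    draws$times[flip, ] <- 1 - draws$times[flip, D:1, drop = FALSE]
    draws$permutation[flip, ] <- D + 1L - draws$permutation[flip, , drop = FALSE]
    draws$layer_a[flip, , ] <- draws$layer_a[flip, , , drop = FALSE] +
      draws$layer_k[flip, , , drop = FALSE]
    draws$layer_k[flip, , ] <- -draws$layer_k[flip, , , drop = FALSE]
    draws$population_a[flip, ] <- draws$population_a[flip, , drop = FALSE] +
      draws$population_k[flip, , drop = FALSE]
    draws$population_k[flip, ] <- -draws$population_k[flip, , drop = FALSE]
  }
  attr(draws, "anchor") <- anchor
  draws
}

# Split-Rhat (Gelman et al.): split each chain's trace in half, compare
# between- and within-half variances. NA when fewer than 4 values or zero
# variance.
.split_rhat <- function(x, chain) {
  halves <- list()
  for (ch in unique(chain)) {
    xs <- x[chain == ch]
    n <- length(xs)
    if (n < 4) next
    h <- n %/% 2
    halves <- c(halves, list(xs[1:h]), list(xs[(n - h + 1):n]))
  }
  if (length(halves) < 2) return(NA_real_)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(h) h[1:n])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarise posterior draws into per-donor CPS estimates
#'
#' Pools each donor's time `times[perm[d]]` across draws and chains and
#' reports the posterior mean (the CPS), standard deviation, equal-tailed 90%
#' interval, rank of the mean, and split-Rhat convergence diagnostic.
#'
#' @param draws a `cps_draws` object, ideally after [orient_draws()].
#' @return An object of class `cps_result`: data frame with columns
#'   `donor_id`, `cps_mean`, `cps_sd`, `cps_q05`, `cps_q95`, `rank`, `rhat`.
#' @export
summarize_cps <- function(draws) {
  S <- nrow(draws$times)
  if (S == 0) stop("no stored draws")
  D <- ncol(draws$times)
  cps <- matrix(NA_real_, S, D)
  for (s in seq_len(S)) cps[s, ] <- draws$times[s, ][draws$permutation[s, ]]
  res <- data.frame(
    donor_id = draws$donor_ids,
    cps_mean = colMeans(cps),
    cps_sd = apply(cps, 2, stats::sd),
    cps_q05 = apply(cps, 2, stats::quantile, probs = 0.05),
    cps_q95 = apply(cps, 2, stats::quantile, probs = 0.95),
    stringsAsFactors = FALSE)
  res$rank <- rank(res$cps_mean, ties.method = "first")
  res$rhat <- vapply(seq_len(D),
                     function(d) .split_rhat(cps[, d], draws$chain), 0)
  if (S == 1) res$cps_sd <- rep(0, D)
  class(res) <- c("cps_result", "data.frame")
  res
}
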