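# Flat-likelihood helpers: with all slopes zero the likelihood carries no
# information about the times, so the time block must leave the uniform
# order-statistics prior invariant.
flat_dataset <- function(D, counts = 2) {
  neuropath_dataset(array(counts, c(D, 1, 1)))
}
flat_dynamics <- dynamics_params(0, 0, matrix(0), matrix(0))

test_that("slice-sampled times leave the flat-likelihood prior invariant (D=1)", {
  ds <- flat_dataset(1)
  set.seed(1)
  draws <- numeric(5000)
  t <- 0.5
  for (i in seq_along(draws)) {
    t <- sample_times(ds, 1L, flat_dynamics, t)
    draws[i] <- t
  }
  expect_gt(suppressWarnings(ks.test(draws, punif))$p.value, 0.01)
})

test_that("flat-likelihood sorted-time marginals follow the order-statistics law (D=3)", {
  ds <- flat_dataset(3)
  set.seed(2)
  n_iter <- 6000
  keep <- matrix(NA_real_, n_iter, 3)
  t <- c(0.25, 0.5, 0.75)
  for (i in seq_len(n_iter)) {
    t <- sample_times(ds, 1:3, flat_dynamics, t)
    keep[i, ] <- t
  }
  thin <- keep[seq(501, n_iter, by = 5), ]
  for (j in 1:3) {
    # j-th order statistic of 3 uniforms ~ Beta(j, 3 - j + 1)
    p <- suppressWarnings(ks.test(thin[, j], pbeta, j, 3 - j + 1))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("time updates respect the neighbour brackets and bounds", {
  inst <- random_instance(D = 8, M = 2, L = 2, seed = 3)
  set.seed(4)
  t <- inst$latent$times
  for (i in 1:50) {
    t <- sample_times(inst$dataset, inst$latent$permutation, inst$dynamics, t)
    expect_false(is.unsorted(t))
    expect_true(all(t >= 0 & t <= 1))
  }
})

test_that("permutation score matrix matches per-donor per-slot brute force", {
  inst <- random_instance(D = 3, M = 2, L = 2, seed = 5)
  S <- permutation_score_matrix(inst$dataset, inst$latent$times, inst$dynamics)
  for (d in 1:3) for (j in 1:3) {
    # brute force: donor d's cells only, at slot j
    manual <- 0
    for (m in 1:2) for (l in 1:2) {
      if (!inst$dataset$mask[d, m, l]) next
      lam <- exp(inst$dynamics$layer_k[m, l] * inst$latent$times[j] +
                   inst$dynamics$layer_a[m, l])
      manual <- manual + oracle_pois_logpmf(inst$dataset$counts[d, m, l], lam)
    }
    expect_equal(S[d, j], manual, tolerance = 1e-10)
  }
  # D = 1: the matrix is the dataset log-likelihood
  inst1 <- random_instance(D = 1, M = 2, L = 2, seed = 6)
  S1 <- permutation_score_matrix(inst1$dataset, inst1$latent$times,
                                 inst1$dynamics)
  expect_equal(S1[1, 1],
               log_likelihood(inst1$dataset, inst1$latent, inst1$dynamics))
  # flat likelihood: all slot columns identical
  Sf <- permutation_score_matrix(flat_dataset(4), seq(0.2, 0.8, 0.2),
                                 flat_dynamics)
  expect_equal(Sf[, 1], Sf[, 2])
  expect_equal(Sf[, 1], Sf[, 4])
})

test_that("sinkhorn balancing reaches its known fixed points", {
  # uniform scores: symmetric fixed point 1/D
  U <- sinkhorn_normalize(matrix(1, 4, 4), 1, 100)
  expect_equal(U, matrix(0.25, 4, 4), tolerance = 1e-8)
  # strong diagonal at low temperature: near the identity vertex
  Ident <- sinkhorn_normalize(diag(4) * 50, 0.5, 200)
  expect_true(max(abs(Ident - diag(4))) < 1e-3)
  # row/column sums balanced
  set.seed(7)
  S <- sinkhorn_normalize(matrix(rnorm(25), 5, 5), 1, 100)
  expect_true(all(abs(rowSums(S) - 1) < 1e-6))
  expect_true(all(abs(colSums(S) - 1) < 1e-6))
  # 2x2 closed form: balanced matrix is [[q, 1-q], [1-q, q]] with
  # q/(1-q) = sqrt(K11 K22 / (K12 K21)) for K = exp(scores/T)
  sc <- matrix(c(1.3, -0.2, 0.4, 0.9), 2, 2)
  B <- sinkhorn_normalize(sc, 1, 200)
  r <- sqrt(exp(sc[1, 1] + sc[2, 2] - sc[1, 2] - sc[2, 1]))
  q <- r / (1 + r)
  expect_equal(B, matrix(c(q, 1 - q, 1 - q, q), 2, 2), tolerance = 1e-8)
})

test_that("noiseless low-temperature permutation draws equal the exact argmax", {
  inst <- random_instance(D = 4, M = 2, L = 2, seed = 8)
  S <- permutation_score_matrix(inst$dataset, inst$latent$times, inst$dynamics)
  best <- NULL; bv <- -Inf
  for (p in all_permutations(4)) {
    v <- sum(S[cbind(1:4, p)])
    if (v > bv) { bv <- v; best <- p }
  }
  got <- sample_permutation(inst$dataset, inst$latent$times, inst$dynamics,
                            temperature = 0.05, sinkhorn_iters = 200,
                            gumbel_noise = FALSE)
  expect_identical(got, as.integer(best))
  # D = 1 degenerate case
  inst1 <- random_instance(D = 1, M = 1, L = 1, seed = 9)
  expect_identical(
    sample_permutation(inst1$dataset, 0.5, inst1$dynamics), 1L)
})

test_that("two-donor permutation frequencies track the enumerated conditional", {
  # gap chosen small so the per-entry Gumbel perturbation stays close to the
  # exact softmax over the two permutations
  ds <- neuropath_dataset(array(c(1, 3, 1, 3), c(2, 2, 1)))
  dyn <- dynamics_params(c(0, 0), c(0.1, 0.1), matrix(0, 2, 1),
                         matrix(0.1, 2, 1))
  times <- c(0.2, 0.8)
  S <- permutation_score_matrix(ds, times, dyn)
  s_id <- S[1, 1] + S[2, 2]
  s_sw <- S[1, 2] + S[2, 1]
  p_better <- exp(max(s_id, s_sw)) / (exp(s_id) + exp(s_sw))
  better <- if (s_id >= s_sw) c(1L, 2L) else c(2L, 1L)
  set.seed(10)
  hits <- 0
  n_draw <- 2000
  for (i in seq_len(n_draw)) {
    p <- sample_permutation(ds, times, dyn, sinkhorn_iters = 20)
    hits <- hits + identical(p, better)
  }
  expect_lt(abs(hits / n_draw - p_better), 0.05)
})

test_that("dynamics updates recover the prior on an all-masked dataset", {
  ds <- neuropath_dataset(array(0, c(3, 1, 1)), mask = array(FALSE, c(3, 1, 1)))
  dyn <- dynamics_params(0, 0, matrix(0), matrix(0))
  state <- NULL
  set.seed(11)
  n <- 4000
  pop_k <- numeric(n); layer_k <- numeric(n)
  for (i in seq_len(n)) {
    upd <- sample_dynamics(ds, c(0.25, 0.5, 0.75), 1:3, dyn, steps = 2,
                           state = state, adapt = i <= 500)
    dyn <- upd$dynamics; state <- upd$state
    pop_k[i] <- dyn$population_k; layer_k[i] <- dyn$layer_k[1, 1]
  }
  keep <- 501:n
  expect_lt(abs(mean(pop_k[keep])), 0.12)
  expect_lt(abs(sd(pop_k[keep]) - 1), 0.12)
  expect_lt(abs(mean(layer_k[keep])), 0.18)
  expect_lt(abs(sd(layer_k[keep]) - sqrt(2)), 0.18)  # N(0,1) + N(.,1) layers
})

test_that("dynamics posterior concentrates on the grid-search maximum", {
  # single measurement/layer, informative data at known times
  set.seed(12)
  D <- 50
  times <- seq_len(D) / (D + 1)
  k_true <- 2; a_true <- 3
  counts <- array(rpois(D, exp(k_true * times + a_true)), c(D, 1, 1))
  ds <- neuropath_dataset(counts)
  grid <- expand.grid(k = seq(1, 3, 0.02), a = seq(2, 4, 0.02))
  ll <- mapply(function(k, a) {
    sum(counts[, 1, 1] * (k * times + a) - exp(k * times + a))
  }, grid$k, grid$a)
  mle <- grid[which.max(ll), ]
  dyn <- dynamics_params(0, 0, matrix(0), matrix(0))
  state <- NULL
  n <- 3000
  ks <- numeric(n); as <- numeric(n)
  for (i in seq_len(n)) {
    upd <- sample_dynamics(ds, times, seq_len(D), dyn, steps = 2,
                           state = state, adapt = i <= 500)
    dyn <- upd$dynamics; state <- upd$state
    ks[i] <- dyn$layer_k[1, 1]; as[i] <- dyn$layer_a[1, 1]
  }
  keep <- 1001:n
  expect_lt(abs(mean(ks[keep]) - mle$k), 3 * sd(ks[keep]) + 0.02)
  expect_lt(abs(mean(as[keep]) - mle$a), 3 * sd(as[keep]) + 0.02)
})

test_that("joint-distribution (Geweke-style) check keeps prior marginals", {
  # alternate data simulation and parameter updates; the marginal law of the
  # parameters must stay at the prior if the kernel targets the posterior
  set.seed(13)
  D <- 3
  times <- c(0.2, 0.5, 0.8)
  dyn <- dynamics_params(0, 0, matrix(0), matrix(0))
  state <- NULL
  n <- 3000
  pop_a <- numeric(n)
  for (i in seq_len(n)) {
    lam <- exp(dyn$layer_k[1, 1] * times + dyn$layer_a[1, 1])
    ds <- neuropath_dataset(array(rpois(D, pmin(lam, 1e6)), c(D, 1, 1)))
    for (s in 1:3) {
      upd <- sample_dynamics(ds, times, 1:3, dyn, steps = 2, state = state,
                             adapt = i <= 300)
      dyn <- upd$dynamics; state <- upd$state
    }
    pop_a[i] <- dyn$population_a
  }
  keep <- 501:n
  expect_lt(abs(mean(pop_a[keep])), 0.15)
  expect_lt(abs(sd(pop_a[keep]) - 1), 0.15)
})

test_that("run_gibbs bookkeeping, invariants and determinism hold", {
  sim <- simulate_dataset(simulation_config(5, 2, 2, slope_scale = 2,
                                            layer_sd = 0.3, seed = 14))
  cfg <- gibbs_config(n_sweeps = 10, burn_in = 5, n_chains = 2, seed = 15)
  dr <- run_gibbs(sim$dataset, cfg)
  expect_equal(nrow(dr$times), 10)  # (10 - 5) x 2 chains
  expect_true(all(apply(dr$times, 1, function(t) !is.unsorted(t))))
  expect_true(all(dr$times >= 0 & dr$times <= 1))
  expect_true(all(apply(dr$permutation, 1,
                        function(p) setequal(p, 1:5))))
  expect_true(all(is.finite(dr$log_joint)))
  dr2 <- run_gibbs(sim$dataset, cfg)
  expect_identical(dr$times, dr2$times)
  expect_identical(dr$permutation, dr2$permutation)
  expect_identical(dr$layer_k, dr2$layer_k)
})

test_that("a flat-likelihood posterior centres every donor near 0.5", {
  ds <- neuropath_dataset(array(0, c(6, 1, 1)), mask = array(FALSE, c(6, 1, 1)))
  dr <- run_gibbs(ds, gibbs_config(n_sweeps = 1200, burn_in = 200,
                                   n_chains = 1, seed = 16,
                                   sinkhorn_iters = 20))
  res <- summarize_cps(dr)
  expect_true(all(abs(res$cps_mean - 0.5) < 0.1))
  expect_true(all(res$cps_sd > 0.2))
})

test_that("orientation fixes the anchor sign without touching the likelihood", {
  sim <- simulate_dataset(simulation_config(8, 2, 2, slope_scale = 2,
                                            layer_sd = 0.3, seed = 17))
  dr <- run_gibbs(sim$dataset, gibbs_config(n_sweeps = 40, burn_in = 20,
                                            n_chains = 2, seed = 18))
  draw_loglik <- function(draws, s) {
    dyn <- dynamics_params(draws$population_a[s, ], draws$population_k[s, ],
                           draws$layer_a[s, , ], draws$layer_k[s, , ])
    log_likelihood(sim$dataset,
                   latent_state(draws$times[s, ], draws$permutation[s, ]), dyn)
  }
  orient <- orient_draws(dr, anchor_measurement = "meas_1")
  expect_true(all(orient$population_k[, 1] >= 0))
  for (s in c(1, 10, 25, 40)) {
    expect_equal(draw_loglik(orient, s), draw_loglik(dr, s), tolerance = 1e-8)
  }
  # involution: orienting twice changes nothing further
  again <- orient_draws(orient, anchor_measurement = "meas_1")
  expect_equal(again$times, orient$times)
  expect_equal(again$population_k, orient$population_k)
  expect_error(orient_draws(dr, anchor_measurement = "nope"), "unknown anchor")
})

test_that("summarize_cps reproduces hand-computed pooled statistics", {
  toy <- structure(list(
    times = rbind(c(0.1, 0.6), c(0.2, 0.7), c(0.3, 0.8), c(0.4, 0.9)),
    permutation = rbind(c(2L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 1L)),
    population_a = matrix(0, 4, 1), population_k = matrix(1, 4, 1),
    layer_a = array(0, c(4, 1, 1)), layer_k = array(1, c(4, 1, 1)),
    log_joint = rep(0, 4), chain = rep(1L, 4),
    donor_ids = c("d1", "d2"), measurement_names = "m",
    layer_names = "L1", config = NULL), class = "cps_draws")
  res <- summarize_cps(toy)
  # donor 1 pools (0.6, 0.7, 0.3, 0.9); donor 2 pools (0.1, 0.2, 0.8, 0.4)
  expect_equal(res$cps_mean, c(mean(c(0.6, 0.7, 0.3, 0.9)),
                               mean(c(0.1, 0.2, 0.8, 0.4))))
  expect_equal(res$cps_sd, c(sd(c(0.6, 0.7, 0.3, 0.9)),
                             sd(c(0.1, 0.2, 0.8, 0.4))))
  expect_equal(res$cps_q05[1],
               unname(quantile(c(0.6, 0.7, 0.3, 0.9), 0.05)))
  expect_equal(as.numeric(res$rank), c(2, 1))
  single <- toy
  single$times <- toy$times[1, , drop = FALSE]
  single$permutation <- toy$permutation[1, , drop = FALSE]
  single$population_a <- toy$population_a[1, , drop = FALSE]
  single$population_k <- toy$population_k[1, , drop = FALSE]
  single$layer_a <- toy$layer_a[1, , , drop = FALSE]
  single$layer_k <- toy$layer_k[1, , , drop = FALSE]
  single$log_joint <- 0; single$chain <- 1L
  res1 <- summarize_cps(single)
  expect_equal(res1$cps_mean, c(0.6, 0.1))
  expect_equal(res1$cps_sd, c(0, 0))
  expect_true(all(is.na(res1$rhat)))
})
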