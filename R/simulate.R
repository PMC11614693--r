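#' Configuration for the synthetic neuropathology generator
#'
#' Describes a panel of `n_donors` donors, `n_measurements` informative
#' measurements and `n_layers` cortical layers. Population slopes `k_m` are
#' drawn `Normal(0, slope_scale^2)` and intercepts `a_m`
#' `Normal(0, intercept_scale^2)`; layer-level parameters deviate from the
#' population values with standard deviation `layer_sd` (the model's
#' hierarchical prior uses 1). `n_null_measurements` appends nuisance
#' variables whose slopes are exactly zero, carrying no ordering information.
#'
#' @param n_donors,n_measurements,n_layers positive integers.
#' @param slope_scale,intercept_scale nonnegative; spread of the population
#'   dynamics across measurements.
#' @param layer_sd nonnegative; spread of layer-level deviations.
#' @param time_spacing `"equal"` places donor times at `d/(D+1)`;
#'   `"uniform_order_statistics"` sorts D Uniform(0,1) draws.
#' @param missing_fraction fraction of cells masked completely at random,
#'   in `[0, 1)`.
#' @param n_null_measurements nonnegative count of zero-slope nuisance
#'   variables.
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_donors, n_measurements, n_layers,
                              slope_scale = 1, intercept_scale = 1,
                              layer_sd = 1,
                              time_spacing = c("equal",
                                               "uniform_order_statistics"),
                              missing_fraction = 0,
                              n_null_measurements = 0L,
                              seed = 1L) {
  time_spacing <- match.arg(time_spacing)
  stopifnot(n_donors >= 1, n_layers >= 1,
            n_measurements + n_null_measurements >= 1, n_measurements >= 0,
            slope_scale >= 0, intercept_scale >= 0, layer_sd >= 0,
            missing_fraction >= 0, missing_fraction < 1,
            n_null_measurements >= 0)
  structure(list(n_donors = as.integer(n_donors),
                 n_measurements = as.integer(n_measurements),
                 n_layers = as.integer(n_layers),
                 slope_scale = slope_scale, intercept_scale = intercept_scale,
                 layer_sd = layer_sd, time_spacing = time_spacing,
                 missing_fraction = missing_fraction,
                 n_null_measurements = as.integer(n_null_measurements),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a neuropathology panel with known ground truth
#'
#' Draws latent donor times, a random donor-to-slot permutation, hierarchical
#' dynamic parameters, and Poisson counts with mean
#' `exp(k_m^l * t_{pi(d)} + a_m^l)`. Null measurements have all slopes fixed
#' at zero so their counts are independent of the donor ordering.
#'
#' @param config a [simulation_config()].
#' @param fixed_times optional sorted vector of D times in `[0, 1]`
#'   overriding the `time_spacing` draw (for controlled recovery or moment
#'   studies).
#' @param fixed_permutation optional donor-to-slot permutation overriding the
#'   random shuffle.
#' @param fixed_dynamics optional [dynamics_params()] overriding the
#'   hierarchical parameter draw.
#' @return List with elements `dataset` (a [neuropath_dataset()]) and
#'   `truth` (list: `true_times`, `true_permutation`, `true_dynamics`,
#'   `donor_times` = per-donor times `true_times[true_permutation]`).
#' @examples
#' sim <- simulate_dataset(simulation_config(5, 2, 3, seed = 1))
#' sim$dataset
#' @export
simulate_dataset <- function(config, fixed_times = NULL,
                             fixed_permutation = NULL,
                             fixed_dynamics = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  D <- config$n_donors
  M <- config$n_measurements + config$n_null_measurements
  L <- config$n_layers

  times <- fixed_times %||% switch(config$time_spacing,
    equal = seq_len(D) / (D + 1),
    uniform_order_statistics = sort(stats::runif(D)))
  if (is.unsorted(times) || any(times < 0 | times > 1) || length(times) != D)
    stop("`fixed_times` must be D sorted values in [0, 1]")
  perm <- fixed_permutation %||% sample.int(D)

  if (is.null(fixed_dynamics)) {
    pop_a <- stats::rnorm(M, 0, config$intercept_scale)
    pop_k <- stats::rnorm(M, 0, config$slope_scale)
    layer_a <- matrix(stats::rnorm(M * L, pop_a, config$layer_sd), M, L)
    layer_k <- matrix(stats::rnorm(M * L, pop_k, config$layer_sd), M, L)
    if (config$n_null_measurements > 0) {
      null_idx <- config$n_measurements + seq_len(config$n_null_measurements)
      pop_k[null_idx] <- 0
      layer_k[null_idx, ] <- 0
    }
  } else {
    pop_a <- fixed_dynamics$population_a
    pop_k <- fixed_dynamics$population_k
    layer_a <- fixed_dynamics$layer_a
    layer_k <- fixed_dynamics$layer_k
    stopifnot(length(pop_a) == M, ncol(layer_a) == L)
  }

  td <- times[perm]
  eta <- outer(td, as.vector(layer_k)) +
    rep(as.vector(layer_a), each = D)
  rate <- exp(eta)
  if (max(rate) > 1e12)
    stop("degenerate simulation config: Poisson rate exceeds 1e12")
  counts <- array(stats::rpois(length(rate), rate), c(D, M, L))

  mask <- array(TRUE, c(D, M, L))
  if (config$missing_fraction > 0) {
    mask[] <- stats::runif(length(mask)) >= config$missing_fraction
    # keep the dataset invariants: each donor and each measurement retains at
    # least one observed cell (reinstate a deterministic cell if needed)
    for (d in which(rowSums(matrix(mask, D)) == 0)) mask[d, 1, 1] <- TRUE
    for (m in which(!apply(mask, 2, any))) mask[1, m, 1] <- TRUE
  }

  meas_names <- c(
    if (config$n_measurements > 0) paste0("meas_", seq_len(config$n_measurements)),
    if (config$n_null_measurements > 0)
      paste0("null_", seq_len(config$n_null_measurements)))
  dataset <- neuropath_dataset(
    counts, mask,
    donor_ids = sprintf("donor_%02d", seq_len(D)),
    measurement_names = meas_names,
    layer_names = paste0("L", seq_len(L)))
  truth <- list(
    true_times = times,
    true_permutation = perm,
    donor_times = td,
    true_dynamics = dynamics_params(pop_a, pop_k, layer_a, layer_k))
  list(dataset = dataset, truth = truth)
}

#' Write a dataset as a long-format CSV
#'
#' One row per observed cell with columns `donor_id,measurement,layer,value`;
#' masked cells are omitted (not written as zero). Round-trips losslessly
#' through [load_neuropath_table()].
#'
#' @param dataset a [neuropath_dataset()].
#' @param path output file path.
#' @param header_lines optional character vector of `#`-prefixed metadata
#'   lines written before the column header.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path, header_lines = NULL) {
  fl <- .flatten_dataset(dataset)
  dm <- dim(dataset$counts)
  long <- data.frame(
    donor_id = rep(dataset$donor_ids, dm[2] * dm[3]),
    measurement = rep(dataset$measurement_names[fl$meas_index], each = dm[1]),
    layer = rep(dataset$layer_names[fl$layer_index], each = dm[1]),
    value = as.vector(fl$X),
    stringsAsFactors = FALSE)
  long <- long[as.vector(fl$W), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.csv(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' Keys: `times`, `permutation`, `population_a`, `population_k`, `layer_a`,
#' `layer_k` (layer matrices as row-per-measurement lists).
#'
#' @param truth the `truth` element of [simulate_dataset()]'s result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(
    times = truth$true_times,
    permutation = truth$true_permutation,
    population_a = truth$true_dynamics$population_a,
    population_k = truth$true_dynamics$population_k,
    layer_a = truth$true_dynamics$layer_a,
    layer_k = truth$true_dynamics$layer_k)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
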