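#' Read a long-format quantitative neuropathology table
#'
#' Expects a CSV with header `donor_id,measurement,layer,value` (lines
#' starting with `#` are treated as metadata and skipped). Values are
#' coerced to nonnegative integers by rounding half up; a warning reports
#' how many cells were modified. Absent (donor, measurement, layer) rows
#' become masked cells.
#'
#' @param path CSV file path.
#' @return A [neuropath_dataset()].
#' @export
load_neuropath_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty neuropathology table: ", path)
  need <- c("donor_id", "measurement", "layer", "value")
  if (!all(need %in% names(df)))
    stop("table must have columns ", paste(need, collapse = ","))
  if (any(!is.finite(df$value))) stop("non-finite values in table")
  if (any(df$value < 0)) stop("negative values in table")
  key <- paste(df$donor_id, df$measurement, df$layer, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (donor, measurement, layer) rows in table")
  rounded <- floor(df$value + 0.5)  # round half up onto Poisson support
  n_mod <- sum(rounded != df$value)
  if (n_mod > 0)
    warning(sprintf("%d non-integer value(s) rounded half up", n_mod))
  donors <- unique(df$donor_id)
  meas <- unique(df$measurement)
  layers <- unique(df$layer)
  D <- length(donors); M <- length(meas); L <- length(layers)
  counts <- array(0, c(D, M, L))
  mask <- array(FALSE, c(D, M, L))
  idx <- cbind(match(df$donor_id, donors), match(df$measurement, meas),
               match(df$layer, layers))
  counts[idx] <- rounded
  mask[idx] <- TRUE
  neuropath_dataset(counts, mask, donor_ids = donors,
                    measurement_names = meas, layer_names = layers)
}

#' Z-score each variable across donors
#'
#' Centres and scales every column of a [variable_matrix()] over its observed
#' donors (sd with denominator n - 1). Variables with fewer than two observed
#' donors or zero variance are excluded with a warning rather than divided
#' by zero.
#'
#' @param matrix a [variable_matrix()].
#' @return A [variable_matrix()] whose retained columns have mean 0 and sd 1.
#' @export
zscore_variables <- function(matrix) {
  stopifnot(inherits(matrix, "variable_matrix"))
  vals <- matrix$values
  mu <- colMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 2, stats::sd, na.rm = TRUE)
  n_obs <- colSums(!is.na(vals))
  bad <- n_obs < 2 | !is.finite(sdv) | sdv == 0
  if (any(bad))
    warning("excluding ", sum(bad), " constant/under-observed variable(s): ",
            paste(matrix$variable_names[bad], collapse = ", "))
  keep <- which(!bad)
  out <- sweep(sweep(vals[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  structure(list(values = out, variable_names = matrix$variable_names[keep],
                 donor_ids = matrix$donor_ids,
                 donor_order = matrix$donor_order),
            class = "variable_matrix")
}

#' Moving-average smoothing along the donor ordering
#'
#' Reorders donors by `donor_order` (e.g. increasing CPS) and replaces each
#' value by the centred moving average of width `window` along that ordering.
#' At the edges the window truncates to the available donors; missing entries
#' are ignored within each window.
#'
#' @param matrix a [variable_matrix()] with `donor_order` set.
#' @param window odd positive integer window width (donors).
#' @return A [variable_matrix()] with rows in `donor_order` and smoothed
#'   values.
#' @export
moving_average_smooth <- function(matrix, window = 5L) {
  stopifnot(inherits(matrix, "variable_matrix"))
  if (is.null(matrix$donor_order))
    stop("`donor_order` must be set before smoothing (e.g. by CPS)")
  window <- as.integer(window)
  D <- nrow(matrix$values)
  if (window < 1L || window %% 2L == 0L) stop("`window` must be odd positive")
  if (window > 2L * D - 1L) stop("`window` larger than 2*D-1")
  vals <- matrix$values[matrix$donor_order, , drop = FALSE]
  half <- window %/% 2L
  out <- vals
  for (i in seq_len(D)) {
    rows <- max(1L, i - half):min(D, i + half)
    out[i, ] <- colMeans(vals[rows, , drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  structure(list(values = out, variable_names = matrix$variable_names,
                 donor_ids = matrix$donor_ids[matrix$donor_order],
                 donor_order = seq_len(D)),
            class = "variable_matrix")
}

#' Co-correlation hierarchical clustering of variables
#'
#' Computes the Pearson correlation matrix across variables on
#' pairwise-complete donors, clusters variables by average-linkage
#' agglomeration on the distance `1 - r`, and cuts the tree into
#' `n_clusters` groups. Pairs with fewer than 3 complete observations get
#' the maximal distance 2 (with a warning).
#'
#' @param matrix a [variable_matrix()].
#' @param n_clusters number of clusters to cut.
#' @return List: `labels` (named integer cluster per variable), `hclust`
#'   (the dendrogram), `correlation` (leaf-ordered correlation matrix),
#'   `order` (leaf order indices).
#' @export
cocorrelation_clusters <- function(matrix, n_clusters = 8L) {
  stopifnot(inherits(matrix, "variable_matrix"))
  vals <- matrix$values
  V <- ncol(vals)
  if (V < n_clusters) stop("fewer variables than requested clusters")
  r <- suppressWarnings(stats::cor(vals, use = "pairwise.complete.obs"))
  obs <- !is.na(vals)
  n_pair <- t(obs * 1) %*% (obs * 1)
  thin <- n_pair < 3 & upper.tri(n_pair)
  if (any(is.na(r[upper.tri(r)])) || any(thin))
    warning("variable pair(s) with insufficient overlap; distance set to 2")
  dmat <- 1 - r
  dmat[is.na(dmat)] <- 2
  dmat[n_pair < 3] <- 2
  diag(dmat) <- 0
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  labels <- stats::cutree(hc, k = n_clusters)
  names(labels) <- matrix$variable_names
  list(labels = labels, hclust = hc,
       correlation = r[hc$order, hc$order], order = hc$order)
}
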