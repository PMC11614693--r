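#' Construct a layer-resolved neuropathology count dataset
#'
#' Container for quantitative neuropathology panels: nonnegative integer
#' counts of stained objects per standardised area, indexed by donor,
#' measurement (stain/feature) and cortical layer. Cells that were not
#' measured are flagged in `mask`.
#'
#' @param counts numeric array of dimension D x M x L with nonnegative
#'   integer counts. Masked (unobserved) cells may hold any placeholder.
#' @param mask logical array of the same dimension; `TRUE` marks observed
#'   cells. Defaults to all observed.
#' @param donor_ids,measurement_names,layer_names label vectors matching the
#'   three dimensions; defaults are generated.
#' @return An object of class `neuropath_dataset`: a list with elements
#'   `counts`, `mask`, `donor_ids`, `measurement_names`, `layer_names`.
#' @examples
#' x <- array(rpois(2 * 3 * 2, 4), c(2, 3, 2))
#' neuropath_dataset(x)
#' @export
neuropath_dataset <- function(counts, mask = NULL, donor_ids = NULL,
                              measurement_names = NULL, layer_names = NULL) {
  if (length(dim(counts)) != 3L)
    stop("`counts` must be a 3-d array (donor x measurement x layer)")
  dm <- dim(counts)
  if (is.null(mask)) mask <- array(TRUE, dm)
  mask <- array(as.logical(mask), dm)
  if (!identical(dim(mask), dm)) stop("`mask` dimensions must match `counts`")
  donor_ids <- as.character(donor_ids %||% paste0("donor_", seq_len(dm[1])))
  measurement_names <- as.character(
    measurement_names %||% paste0("meas_", seq_len(dm[2])))
  layer_names <- as.character(layer_names %||% paste0("L", seq_len(dm[3])))
  if (length(donor_ids) != dm[1] || length(measurement_names) != dm[2] ||
      length(layer_names) != dm[3])
    stop("label lengths must match the array dimensions")
  obs <- counts[mask]
  if (any(!is.finite(obs)) || any(obs < 0) || any(obs != round(obs)))
    stop("observed counts must be finite nonnegative integers")
  if (any(mask)) {
    # a fully masked dataset is allowed (prior-only sampling); a partially
    # observed one must cover every donor and measurement
    if (any(rowSums(matrix(mask, dm[1])) == 0))
      stop("every donor needs at least one observed cell")
    if (any(!apply(mask, 2, any)))
      stop("every measurement needs at least one observed cell")
  }
  structure(
    list(counts = array(as.numeric(counts), dm, dimnames = list(
           donor_ids, measurement_names, layer_names)),
         mask = mask,
         donor_ids = donor_ids, measurement_names = measurement_names,
         layer_names = layer_names),
    class = "neuropath_dataset")
}

#' @export
print.neuropath_dataset <- function(x, ...) {
  dm <- dim(x$counts)
  cat(sprintf(
    "neuropath_dataset: %d donors x %d measurements x %d layers (%.1f%% observed)\n",
    dm[1], dm[2], dm[3], 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.neuropath_dataset <- function(x) dim(x$counts)

# Flatten to D x V matrices (V = M*L, layer fastest is FALSE: column v maps to
# (m, l) with m varying fastest, matching R's array layout when we aperm).
# Returns counts X, mask W, and per-cell lgamma(X + 1) with masked cells zeroed.
.flatten_dataset <- function(dataset) {
  dm <- dim(dataset$counts)
  X <- matrix(dataset$counts, dm[1], dm[2] * dm[3])
  W <- matrix(dataset$mask, dm[1], dm[2] * dm[3])
  X[!W] <- 0
  vn <- as.vector(outer(dataset$measurement_names, dataset$layer_names,
                        function(m, l) paste0(m, "@", l)))
  list(X = X, W = W, lgX = lgamma(X + 1) * W, variable_names = vn,
       meas_index = rep(seq_len(dm[2]), dm[3]),
       layer_index = rep(seq_len(dm[3]), each = dm[2]))
}

#' Flatten a dataset into a donor-by-variable matrix
#'
#' Each measurement-layer pair becomes one variable named
#' `"measurement@layer"`; masked cells become `NA`. This is the input shape
#' for z-scoring, smoothing and co-correlation clustering.
#'
#' @param dataset a [neuropath_dataset()].
#' @param donor_order optional permutation of donors (integer indices or
#'   donor ids), e.g. by increasing posterior-mean CPS; stored for smoothing.
#' @return An object of class `variable_matrix`: list with `values` (D x V,
#'   `NA` where masked), `variable_names`, `donor_ids`, `donor_order`.
#' @export
variable_matrix <- function(dataset, donor_order = NULL) {
  fl <- .flatten_dataset(dataset)
  vals <- fl$X
  vals[!fl$W] <- NA_real_
  dimnames(vals) <- list(dataset$donor_ids, fl$variable_names)
  if (!is.null(donor_order)) {
    if (is.character(donor_order))
      donor_order <- match(donor_order, dataset$donor_ids)
    if (anyNA(donor_order) || !setequal(donor_order, seq_len(nrow(vals))))
      stop("`donor_order` must be a permutation of the donors")
    donor_order <- as.integer(donor_order)
  }
  structure(list(values = vals, variable_names = fl$variable_names,
                 donor_ids = dataset$donor_ids, donor_order = donor_order),
            class = "variable_matrix")
}

#' @export
print.variable_matrix <- function(x, ...) {
  cat(sprintf("variable_matrix: %d donors x %d variables (%s donor order)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$donor_order)) "no" else "with"))
  invisible(x)
}
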