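#' Remove descriptors with (near-)zero variance
#'
#' Drops every numeric descriptor column whose sample variance is at or
#' below `tol`; column order is otherwise preserved. Mirrors the usual first
#' data-reduction step applied to a raw descriptor matrix before modelling.
#'
#' @param table Descriptor table (tibble with an `analyte` label column and
#'   numeric descriptor columns), or a bare numeric data frame.
#' @param tol Minimum variance retained (raw scale).
#' @return The table with low-variance columns removed.
#' @export
variance_filter <- function(table, tol = 1e-8) {
  stopifnot(tol >= 0)
  table <- tibble::as_tibble(table)
  num <- names(table)[vapply(table, is.numeric, TRUE)]
  v <- col_vars(as.matrix(table[num]))
  drop <- num[v <= tol]
  if (length(drop) == length(num)) {
    stop("variance_filter(): every descriptor column would be removed",
         call. = FALSE)
  }
  dplyr::select(table, -dplyr::all_of(drop))
}

#' Prune highly correlated descriptors
#'
#' Greedy single pass: walk the columns in order and drop any column whose
#' absolute Pearson correlation with an already-retained column exceeds
#' `r_max`, so exactly one representative survives from each block of
#' near-collinear descriptors. By default columns are visited in order of
#' decreasing variance, so the most informative member of a correlated block
#' is the one kept; `order = "given"` visits them in table order.
#'
#' @param table Descriptor table (label columns are carried through).
#' @param r_max Correlation threshold; a pair with `|r| > r_max` cannot both
#'   survive.
#' @param order `"variance"` (default) or `"given"`.
#' @return The pruned table, retained columns in their original order.
#' @export
correlation_prune <- function(table, r_max = 0.95,
                              order = c("variance", "given")) {
  order <- match.arg(order)
  table <- tibble::as_tibble(table)
  if (nrow(table) < 2L) {
    stop("correlation_prune(): need at least 2 rows", call. = FALSE)
  }
  num <- names(table)[vapply(table, is.numeric, TRUE)]
  m <- as.matrix(table[num])
  v <- col_vars(m)
  if (any(v == 0)) {
    stop("correlation_prune(): zero-variance column present (",
         paste(num[v == 0], collapse = ", "),
         "); run variance_filter() first", call. = FALSE)
  }
  visit <- if (order == "variance") order(v, decreasing = TRUE) else seq_along(num)
  cm <- abs(stats::cor(m))
  kept <- integer()
  for (k in visit) {
    if (!length(kept) || all(cm[k, kept] <= r_max)) kept <- c(kept, k)
  }
  keep_names <- num[sort(kept)]
  dplyr::select(table, -dplyr::all_of(setdiff(num, keep_names)))
}

#' Fit a column scaling on training data and apply it everywhere
#'
#' Mean-centering or autoscaling (unit variance), with the statistics always
#' estimated on the training matrix and reused verbatim for every other
#' matrix — validation and test rows are never scaled with their own means.
#'
#' @param train Numeric matrix or data frame of training predictors (or the
#'   response as a 1-column matrix).
#' @param others Optional named list of further matrices to scale with the
#'   training statistics.
#' @param mode `"autoscale"` (center and divide by the training standard
#'   deviation) or `"mean-center"`.
#' @return A list of class `qsrr_scaling` with elements `train` (scaled),
#'   `others` (list of scaled matrices), `center`, `scale`, `mode`.
#' @export
fit_apply_scaling <- function(train, others = list(),
                              mode = c("autoscale", "mean-center")) {
  mode <- match.arg(mode)
  train <- as.matrix(train)
  stopifnot(nrow(train) > 0L)
  ctr <- colMeans(train)
  scl <- rep(1, ncol(train))
  if (mode == "autoscale") {
    scl <- sqrt(col_vars(train))
    if (any(!is.finite(scl)) || any(scl == 0)) {
      stop("fit_apply_scaling(): zero-variance training column under autoscale",
           call. = FALSE)
    }
  }
  names(scl) <- names(ctr) <- colnames(train)
  apply_one <- function(m) {
    m <- as.matrix(m)
    sweep(sweep(m, 2L, ctr, "-"), 2L, scl, "/")
  }
  structure(list(
    train = apply_one(train),
    others = lapply(others, apply_one),
    center = ctr, scale = scl, mode = mode
  ), class = "qsrr_scaling")
}

#' Apply or invert a fitted scaling
#'
#' @param scaling A `qsrr_scaling` from [fit_apply_scaling()].
#' @param m Numeric matrix (or vector, treated as one column).
#' @return The scaled (`scale_apply`) or back-transformed (`scale_invert`)
#'   matrix.
#' @export
scale_apply <- function(scaling, m) {
  m <- as.matrix(m)
  sweep(sweep(m, 2L, scaling$center, "-"), 2L, scaling$scale, "/")
}

#' @rdname scale_apply
#' @export
scale_invert <- function(scaling, m) {
  m <- as.matrix(m)
  sweep(sweep(m, 2L, scaling$scale, "*"), 2L, scaling$center, "+")
}
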