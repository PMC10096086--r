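#' Three-level full-factorial design with cubic-subspace centre points
#'
#' Builds the chromatographic design: all 27 combinations of three levels of
#' flow rate `F` (mL/min), column temperature `T` (degrees C) and gradient
#' time `tg` (min), followed by the centres of the eight cubic subspaces the
#' three levels carve out of the factor cube — every combination of the two
#' midpoints between adjacent levels, 2^3 = 8 extra points, 35 conditions in
#' all. Row order is deterministic: factorial points first (lexicographic,
#' `tg` varying fastest), then centres (same order).
#'
#' @param F_levels,T_levels,tg_levels Exactly three strictly increasing
#'   numeric levels per factor. Defaults are the study domain: flow rate
#'   0.6-0.8 mL/min, temperature 25-35 C, gradient time 4-8 min.
#' @return A tibble with columns `F`, `T`, `tg` and a `point` column marking
#'   `"factorial"` or `"centre"` rows.
#' @examples
#' des <- chromatographic_design()
#' nrow(des)  # 35
#' @export
chromatographic_design <- function(F_levels = c(0.6, 0.7, 0.8),
                                   T_levels = c(25, 30, 35),
                                   tg_levels = c(4, 6, 8)) {
  check_levels <- function(lv, nm) {
    if (length(lv) != 3L || any(diff(lv) <= 0)) {
      stop(sprintf("chromatographic_design(): %s must be 3 strictly increasing levels",
                   nm), call. = FALSE)
    }
  }
  check_levels(F_levels, "F_levels")
  check_levels(T_levels, "T_levels")
  check_levels(tg_levels, "tg_levels")
  fact <- tidyr::expand_grid(F = F_levels, T = T_levels, tg = tg_levels)
  mid <- function(lv) (lv[-3L] + lv[-1L]) / 2
  ctr <- tidyr::expand_grid(F = mid(F_levels), T = mid(T_levels),
                            tg = mid(tg_levels))
  dplyr::bind_rows(
    dplyr::mutate(fact, point = "factorial"),
    dplyr::mutate(ctr, point = "centre")
  )
}

#' Assemble a QSRR modelling dataset
#'
#' Crosses every analyte with every chromatographic condition: one record per
#' (analyte, condition) pair, carrying the analyte's descriptor row plus the
#' condition's `F`, `T`, `tg` as predictors, and optionally a measured
#' retention time `tr` (min).
#'
#' @param descriptors A descriptor table as from [compute_descriptor_table()]
#'   (column `analyte` + numeric descriptor columns).
#' @param conditions A condition table as from [chromatographic_design()]
#'   (columns `F`, `T`, `tg`; extra columns dropped).
#' @param responses Optional long table with columns `analyte`, `F`, `T`,
#'   `tg`, `tr` covering every (analyte, condition) pair.
#' @return A tibble with columns `analyte`, `F`, `T`, `tg`, the descriptor
#'   columns, optionally `tr`, and a `split` column initialized to
#'   `"unassigned"`.
#' @export
assemble_dataset <- function(descriptors, conditions, responses = NULL) {
  stopifnot("analyte" %in% names(descriptors),
            all(c("F", "T", "tg") %in% names(conditions)))
  conditions <- dplyr::select(tibble::as_tibble(conditions), "F", "T", "tg")
  ds <- tidyr::expand_grid(
    analyte = descriptors$analyte,
    dplyr::distinct(conditions)
  )
  ds <- dplyr::left_join(ds, descriptors, by = "analyte")
  if (!is.null(responses)) {
    responses <- tibble::as_tibble(responses)
    stopifnot(all(c("analyte", "F", "T", "tg", "tr") %in% names(responses)))
    ds <- dplyr::left_join(ds, responses[, c("analyte", "F", "T", "tg", "tr")],
                           by = c("analyte", "F", "T", "tg"))
    if (anyNA(ds$tr)) {
      miss <- ds[is.na(ds$tr), c("analyte", "F", "T", "tg")]
      stop("assemble_dataset(): missing responses for ",
           nrow(miss), " (analyte, condition) pairs, e.g. ",
           paste(utils::head(paste(miss$analyte, miss$F, miss$T, miss$tg), 3L),
                 collapse = "; "), call. = FALSE)
    }
  }
  desc_cols <- setdiff(names(descriptors), "analyte")
  if (anyNA(ds[desc_cols])) {
    stop("assemble_dataset(): analytes missing from the descriptor table",
         call. = FALSE)
  }
  dplyr::mutate(ds, split = "unassigned")
}

#' Split a QSRR dataset by analyte into train/validation/test
#'
#' All records of the named test analytes become the external test set (the
#' models never see those molecules). The remaining records are split at
#' random, record-wise, into a validation fraction and a training remainder;
#' validation size is `round(val_fraction * n_remaining)`. Reproducible for a
#' fixed seed.
#'
#' @param ds Dataset from [assemble_dataset()].
#' @param test_analytes Character vector of analyte names held out entirely.
#' @param val_fraction Fraction of the non-test records used for validation,
#'   in (0, 1).
#' @param seed Integer seed for the record-wise partition.
#' @return `ds` with its `split` column set to `"train"`, `"validation"` or
#'   `"test"`.
#' @export
split_by_analyte <- function(ds, test_analytes, val_fraction = 0.20,
                             seed = 1L) {
  stopifnot(is.numeric(val_fraction), length(val_fraction) == 1L)
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("split_by_analyte(): val_fraction must be strictly inside (0, 1)",
         call. = FALSE)
  }
  missing <- setdiff(test_analytes, unique(ds$analyte))
  if (length(missing)) {
    stop("split_by_analyte(): unknown test analytes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  is_test <- ds$analyte %in% test_analytes
  if (all(is_test)) {
    stop("split_by_analyte(): test analytes cover the whole dataset",
         call. = FALSE)
  }
  rest <- which(!is_test)
  n_val <- round(val_fraction * length(rest))
  local_rng(seed)
  val_idx <- rest[sample.int(length(rest), n_val)]
  lab <- rep("train", nrow(ds))
  lab[is_test] <- "test"
  lab[val_idx] <- "validation"
  ds$split <- lab
  ds
}

#' Pick test analytes spanning the retention range
#'
#' Chooses `n` analytes stratified over the observed mean retention: analytes
#' are ranked by their mean `tr` and one is drawn per rank stratum, so the
#' held-out molecules cover the studied retention range rather than cluster
#' at one end.
#'
#' @param ds Dataset with `analyte` and `tr` columns.
#' @param n Number of test analytes.
#' @param seed Integer seed.
#' @return Character vector of `n` analyte names.
#' @export
pick_test_analytes <- function(ds, n = 3L, seed = 1L) {
  stopifnot(all(c("analyte", "tr") %in% names(ds)))
  means <- ds |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(m = mean(.data$tr), .groups = "drop") |>
    dplyr::arrange(.data$m)
  if (n >= nrow(means)) {
    stop("pick_test_analytes(): n must be smaller than the analyte count",
         call. = FALSE)
  }
  strata <- split(means$analyte, cut(seq_len(nrow(means)), n, labels = FALSE))
  local_rng(seed)
  unname(vapply(strata, function(a) a[sample.int(length(a), 1L)], ""))
}
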