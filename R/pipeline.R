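#' Run the full QSRR modelling pipeline on synthetic data
#'
#' Orchestrates the whole study in order: descriptor generation, factorial
#' design, dataset assembly, analyte-wise splitting, descriptor pruning,
#' variable selection, PLS and ANN model fitting, and reporting. Every
#' stochastic stage draws its seed deterministically from the single master
#' seed, so one number reproduces the entire run.
#'
#' The fitted models are: PLS on all pruned predictors under mean-centering
#' and under autoscaling; PLS on the VIP > 1 subset; PLS on the CovSel
#' subset; optionally PLS on the GA subset; and the backpropagation network
#' on the GA-selected descriptors (or, without a GA stage, the informative
#' defaults) plus the three chromatographic factors.
#'
#' @param sim_config A [synthetic_config()] describing the synthetic study.
#' @param design Condition table from [chromatographic_design()].
#' @param test_analytes Analytes held out entirely (default: 3 picked by
#'   [pick_test_analytes()] to span the retention range).
#' @param covsel_k Number of variables CovSel retains.
#' @param include_ga Run the GA-MLR selection stage (the most expensive
#'   stage).
#' @param ga_cfg A [ga_config()] for the GA stage.
#' @param ann_cfg An [ann_config()] for the network stage.
#' @param ann_hidden Hidden-layer size of the network.
#' @param A_max Largest PLS complexity tried in cross-validation.
#' @param seed Master seed.
#' @param out_dir Optional directory; when given, the dataset, comparison
#'   table and a JSON manifest (inputs, seeds, package version) are written
#'   there.
#' @return A list of class `qsrr_pipeline`: `dataset`, `test_analytes`,
#'   `reports` (named list of [model_report()]), `comparison` (tibble),
#'   `ga` (if run), `ann` (the ensemble), `seed`.
#' @export
run_pipeline <- function(sim_config = synthetic_config(),
                         design = chromatographic_design(),
                         test_analytes = NULL,
                         covsel_k = 11L,
                         include_ga = TRUE,
                         ga_cfg = ga_config(n_runs = 5L, seed = 1L),
                         ann_cfg = ann_config(n_restarts = 10L),
                         ann_hidden = 2L,
                         A_max = 10L,
                         seed = 1L,
                         out_dir = NULL) {
  sim_config$seed <- derive_seed(seed, "simulate")
  descriptors <- generate_descriptor_matrix(sim_config)
  ds <- generate_retention(descriptors, design, sim_config)
  if (is.null(test_analytes)) {
    test_analytes <- pick_test_analytes(ds, 3L, seed = derive_seed(seed, "test-analytes"))
  }
  ds <- split_by_analyte(ds, test_analytes, val_fraction = 0.20,
                         seed = derive_seed(seed, "split"))

  desc_cols <- setdiff(names(descriptors), "analyte")
  pruned <- ds[, c("analyte", desc_cols)] |>
    dplyr::distinct() |>
    variance_filter() |>
    correlation_prune()
  kept_desc <- setdiff(names(pruned), "analyte")
  pred_cols <- c(kept_desc, "F", "T", "tg")

  split_X <- function(s) as.matrix(ds[ds$split %in% s, pred_cols])
  split_y <- function(s) ds$tr[ds$split %in% s]
  # the PLS arm trains on every non-test record
  Xtr <- split_X(c("train", "validation")); ytr <- split_y(c("train", "validation"))
  Xte <- split_X("test"); yte <- split_y("test")

  make_pls_report <- function(name, prep, cols) {
    mode <- if (prep == "Mean-centering") "mean-center" else "autoscale"
    cv <- venetian_blinds_cv(Xtr[, cols, drop = FALSE], ytr,
                             A_max = min(A_max, length(cols)), scale = mode)
    m <- fit_pls(Xtr[, cols, drop = FALSE], ytr, cv$A_best, scale = mode)
    preds <- dplyr::bind_rows(
      tibble::tibble(split = "train", analyte = ds$analyte[ds$split != "test"],
                     tr = ytr, pred = predict(m, Xtr[, cols, drop = FALSE])),
      tibble::tibble(split = "test", analyte = ds$analyte[ds$split == "test"],
                     tr = yte, pred = predict(m, Xte[, cols, drop = FALSE]))
    )
    r <- model_report(name, prep, preds,
                      rmsecv = cv$metrics$RMSECV[cv$metrics$A == cv$A_best],
                      r2cv = cv$metrics$R2cv[cv$metrics$A == cv$A_best])
    r$model_fit <- m
    r$cv <- cv
    r
  }

  reports <- list()
  reports$pls_mc <- make_pls_report("PLS", "Mean-centering", pred_cols)
  reports$pls_auto <- make_pls_report("PLS", "Autoscaling", pred_cols)

  vip <- vip_scores(reports$pls_auto$model_fit)
  vip_cols <- names(vip)[vip > 1]
  if (length(vip_cols) >= 2L) {
    reports$pls_vip <- make_pls_report("PLS + VIP", "Autoscaling", vip_cols)
  }

  cs <- covsel(Xtr, ytr, k = min(covsel_k, ncol(Xtr)), scale = "autoscale")
  reports$pls_covsel <- make_pls_report("PLS + CovSel", "Autoscaling", cs$selected)

  ga <- NULL
  if (include_ga) {
    ga_cfg$seed <- derive_seed(seed, "ga")
    # GA searches the descriptor columns; the three factors always enter the
    # downstream models.
    ga <- ga_select(as.matrix(cbind(ds[ds$split != "test", kept_desc])),
                    ytr, config = ga_cfg)
    ga_cols <- c(ga$descriptors[[1L]], "F", "T", "tg")
    reports$pls_ga <- make_pls_report("PLS + GA", "Autoscaling", ga_cols)
  }

  ann_desc <- if (!is.null(ga)) ga$descriptors[[1L]] else {
    utils::head(kept_desc, 6L)
  }
  ann_cols <- c(ann_desc, "F", "T", "tg")
  ann_cfg$seed <- derive_seed(seed, "ann")
  ann <- ensemble_train_ann(
    as.matrix(ds[ds$split == "train", ann_cols]), ds$tr[ds$split == "train"],
    as.matrix(ds[ds$split == "validation", ann_cols]), ds$tr[ds$split == "validation"],
    as.matrix(ds[ds$split == "test", ann_cols]), ds$tr[ds$split == "test"],
    n_hidden = ann_hidden, config = ann_cfg
  )
  ann_preds <- dplyr::bind_rows(lapply(c("train", "validation", "test"), function(s) {
    tibble::tibble(split = s, analyte = ds$analyte[ds$split == s],
                   tr = ds$tr[ds$split == s],
                   pred = predict(ann, as.matrix(ds[ds$split == s, ann_cols]),
                                  type = "average"))
  }))
  reports$ann <- model_report("ANN", "Autoscaling", ann_preds)

  comparison <- comparison_table(reports)
  out <- structure(list(dataset = ds, test_analytes = test_analytes,
                        kept_descriptors = kept_desc, reports = reports,
                        comparison = comparison, ga = ga, ann = ann,
                        seed = seed),
                   class = "qsrr_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(ds, file.path(out_dir, "dataset.csv"), row.names = FALSE)
    write_comparison_csv(comparison, file.path(out_dir, "comparison.csv"))
    manifest <- list(
      seed = seed,
      stage_seeds = list(simulate = derive_seed(seed, "simulate"),
                         split = derive_seed(seed, "split"),
                         ga = derive_seed(seed, "ga"),
                         ann = derive_seed(seed, "ann")),
      test_analytes = test_analytes,
      n_records = nrow(ds),
      package_version = as.character(utils::packageVersion("qsrr"))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' @export
print.qsrr_pipeline <- function(x, ...) {
  cat(sprintf("<qsrr_pipeline> %d records, test analytes: %s\n",
              nrow(x$dataset), paste(x$test_analytes, collapse = ", ")))
  print(as.data.frame(x$comparison), digits = 3)
  invisible(x)
}
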