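#' Leave-one-out cross-validated R-squared of a multilinear model
#'
#' Fits ordinary least squares (with intercept) of `y` on the given
#' predictor columns and scores it by the leave-one-out determination
#' coefficient, `R2_loo = 1 - PRESS/TSS`. PRESS is computed by the exact
#' leverage shortcut of OLS, `e_i / (1 - h_ii)`, which equals refitting the
#' model n times with one record deleted.
#'
#' This is the fitness the genetic algorithm maximizes; rank-deficient or
#' over-saturated predictor subsets are scored `-Inf` rather than raising,
#' so the evolutionary search remains total.
#'
#' @param X Numeric predictor matrix (records x descriptors).
#' @param y Numeric response vector.
#' @return `R2_loo` in (-Inf, 1]; `-Inf` for infeasible subsets.
#' @export
loo_cv_r2 <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n != length(y)) stop("loo_cv_r2(): dimension mismatch", call. = FALSE)
  p <- ncol(X) + 1L
  if (n < p + 1L) return(-Inf)
  qx <- qr(cbind(1, X))
  if (qx$rank < p) return(-Inf)
  e <- qr.resid(qx, y)
  h <- rowSums(qr.Q(qx)^2)
  if (any(h >= 1 - 1e-12)) return(-Inf)
  press <- sum((e / (1 - h))^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(-Inf)
  1 - press / tss
}

#' Genetic-algorithm configuration
#'
#' Bundles the evolutionary-search parameters. The defaults follow the
#' V-PARVUS-style setup used for descriptor selection in QSRR work:
#' population of 100 binary chromosomes, uniform crossover, low per-gene
#' mutation, 2% elitism, subsets constrained to 5-7 descriptors, 50
#' independent runs of at most 10 cycles each, stopping a run early after 5
#' cycles without improvement.
#'
#' @param pop_size Population size (even).
#' @param p_mutation Per-gene mutation probability. The conventional presets
#'   are 0.01 (1%) and 0.001 (0.1%).
#' @param elitism Fraction of the population carried unchanged.
#' @param max_cycles Maximum generations per GA run.
#' @param patience Cycles without best-fitness improvement before a run stops.
#' @param n_runs Independent GA runs pooled into the final ranking.
#' @param size_window Inclusive (min, max) number of selected descriptors.
#' @param seed Master seed for the whole search.
#' @return A list of class `qsrr_ga_config`.
#' @export
ga_config <- function(pop_size = 100L, p_mutation = 0.01, elitism = 0.02,
                      max_cycles = 10L, patience = 5L, n_runs = 50L,
                      size_window = c(5L, 7L), seed = 1L) {
  stopifnot(pop_size %% 2L == 0L, p_mutation >= 0, p_mutation <= 1,
            elitism >= 0, elitism <= 1, max_cycles >= 1L, n_runs >= 1L,
            length(size_window) == 2L, size_window[1L] <= size_window[2L],
            size_window[1L] >= 1L)
  structure(list(pop_size = as.integer(pop_size), p_mutation = p_mutation,
                 elitism = elitism, max_cycles = as.integer(max_cycles),
                 patience = as.integer(patience), n_runs = as.integer(n_runs),
                 size_window = as.integer(size_window),
                 seed = as.integer(seed)),
            class = "qsrr_ga_config")
}

# Flip random bits until the chromosome's cardinality is inside the window.
repair_chromosome <- function(chr, window) {
  k <- sum(chr)
  while (k > window[2L]) {
    on <- which(chr)
    chr[on[sample.int(length(on), 1L)]] <- FALSE
    k <- k - 1L
  }
  while (k < window[1L]) {
    off <- which(!chr)
    chr[off[sample.int(length(off), 1L)]] <- TRUE
    k <- k + 1L
  }
  chr
}

#' Genetic-algorithm descriptor selection with MLR LOO-CV fitness
#'
#' Evolves populations of binary descriptor-inclusion chromosomes, scoring
#' each subset by [loo_cv_r2()] of the multilinear model on those columns.
#' Each generation keeps the elite unchanged, draws parents by
#' fitness-proportional (roulette) selection on rank-transformed fitness,
#' recombines them by uniform crossover (an independent coin flip per gene),
#' applies per-gene mutation, and repairs chromosomes back into the
#' descriptor-count window before evaluation. Runs stop after `max_cycles`
#' generations or `patience` generations without best-fitness improvement;
#' all subsets evaluated across all runs are pooled and ranked.
#'
#' @param X Candidate descriptor matrix (records x descriptors, named
#'   columns) or a data frame of numeric columns.
#' @param y Response vector (retention times).
#' @param config A [ga_config()].
#' @param top_k Number of top-ranked subsets returned.
#' @return A tibble of class `qsrr_ga` with columns `rank`, `fitness`
#'   (LOO-CV R2), `n_desc` and list-column `descriptors`; the attribute
#'   `"n_evaluated"` counts distinct subsets scored.
#' @export
ga_select <- function(X, y, config = ga_config(), top_k = 10L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  window <- config$size_window
  if (p < window[2L]) {
    stop("ga_select(): fewer candidate descriptors than the size window max",
         call. = FALSE)
  }
  if (nrow(X) < window[2L] + 3L) {
    stop("ga_select(): too few records for the largest allowed subset",
         call. = FALSE)
  }
  local_rng(config$seed)

  cache <- new.env(parent = emptyenv())
  evaluate <- function(chr) {
    key <- paste(which(chr), collapse = ",")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- loo_cv_r2(X[, chr, drop = FALSE], y)
      cache[[key]] <- val
    }
    val
  }

  n_elite <- max(1L, ceiling(config$elitism * config$pop_size))
  random_chromosome <- function() {
    k <- sample(seq.int(window[1L], window[2L]), 1L)
    chr <- rep(FALSE, p)
    chr[sample.int(p, k)] <- TRUE
    chr
  }

  for (run in seq_len(config$n_runs)) {
    pop <- replicate(config$pop_size, random_chromosome(), simplify = FALSE)
    fit <- vapply(pop, evaluate, numeric(1))
    best <- max(fit)
    stall <- 0L
    for (cycle in seq_len(config$max_cycles)) {
      ord <- order(fit, decreasing = TRUE)
      elite <- pop[ord[seq_len(n_elite)]]
      # roulette on rank-transformed fitness (robust to -Inf sentinels)
      w <- rank(fit, ties.method = "average")
      parents_idx <- sample.int(length(pop), size = config$pop_size,
                                replace = TRUE, prob = w / sum(w))
      children <- vector("list", config$pop_size)
      for (m in seq.int(1L, config$pop_size, by = 2L)) {
        pa <- pop[[parents_idx[m]]]
        pb <- pop[[parents_idx[m + 1L]]]
        mask <- stats::runif(p) < 0.5
        c1 <- ifelse(mask, pa, pb)
        c2 <- ifelse(mask, pb, pa)
        children[[m]] <- c1
        children[[m + 1L]] <- c2
      }
      children <- lapply(children, function(chr) {
        flip <- stats::runif(p) < config$p_mutation
        repair_chromosome(xor(chr, flip), window)
      })
      pop <- c(elite, children[seq_len(config$pop_size - n_elite)])
      fit <- vapply(pop, evaluate, numeric(1))
      new_best <- max(fit)
      if (new_best > best + 1e-12) {
        best <- new_best
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  }

  keys <- ls(cache)
  fits <- vapply(keys, function(k) cache[[k]], numeric(1))
  ord <- order(fits, decreasing = TRUE)
  keep <- ord[seq_len(min(top_k, length(ord)))]
  subsets <- lapply(keys[keep],
                    function(k) as.integer(strsplit(k, ",")[[1]]))
  out <- tibble::tibble(
    rank = seq_along(keep),
    fitness = unname(fits[keep]),
    n_desc = lengths(subsets),
    descriptors = lapply(subsets, function(ix) colnames(X)[ix]),
    indices = subsets
  )
  attr(out, "n_evaluated") <- length(keys)
  class(out) <- c("qsrr_ga", class(out))
  out
}

#' @export
print.qsrr_ga <- function(x, ...) {
  cat(sprintf("<qsrr_ga> %d distinct subsets evaluated; top fitness %.4f\n",
              attr(x, "n_evaluated"), x$fitness[1L]))
  cat("best subset:", paste(x$descriptors[[1L]], collapse = ", "), "\n")
  invisible(x)
}
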