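#' Configuration of the synthetic QSRR study generator
#'
#' Describes a synthetic dataset with the structure a descriptor-based
#' retention study assumes: a modest number of analytes described by a few
#' informative descriptor columns hidden among many correlated noise
#' columns, crossed with a factorial table of chromatographic conditions,
#' and a retention response that increases with a hydrophobicity score,
#' decreases with flow rate, increases with gradient time, decreases weakly
#' with temperature, and bends nonlinearly through a hydrophobicity-by-
#' gradient-time interaction.
#'
#' Default magnitudes keep the response physically plausible for a fast
#' gradient separation: retention spans roughly 1-9 min, measurement noise
#' 0.05 min.
#'
#' @param n_analytes Number of analytes (rows of the descriptor table).
#' @param k_informative Number of descriptor columns that actually drive
#'   retention.
#' @param n_noise Number of uninformative descriptor columns.
#' @param rho Pairwise correlation within each block of noise columns, in
#'   [0, 1).
#' @param block_size Noise columns per correlated block.
#' @param beta Coefficients of the informative columns in the
#'   hydrophobicity score (recycled to `k_informative`).
#' @param mu0 Baseline retention, min.
#' @param a_F,a_T,a_g Condition effects (min per unit of centred flow rate,
#'   temperature, gradient time); signs fixed to chromatographic behaviour
#'   (`a_F < 0`, `a_T <= 0`, `a_g > 0`).
#' @param b_h Retention gain per unit hydrophobicity score, min.
#' @param gamma Strength of the hydrophobicity x gradient-time interaction
#'   (the nonlinearity), min.
#' @param sigma Gaussian noise standard deviation, min.
#' @param seed Integer seed.
#' @return A list of class `qsrr_sim_config`.
#' @export
synthetic_config <- function(n_analytes = 16L, k_informative = 6L,
                             n_noise = 44L, rho = 0.7, block_size = 4L,
                             beta = c(1, 0.7, 0.5, 0.4, 0.3, 0.2),
                             mu0 = 5, a_F = -3, a_T = -0.02, a_g = 0.35,
                             b_h = 1.2, gamma = 0.3, sigma = 0.05,
                             seed = 1L) {
  stopifnot(sigma >= 0, rho >= 0, rho < 1, k_informative >= 1L,
            a_F < 0, a_T <= 0, a_g > 0)
  beta <- rep_len(beta, k_informative)
  structure(list(n_analytes = as.integer(n_analytes),
                 k_informative = as.integer(k_informative),
                 n_noise = as.integer(n_noise), rho = rho,
                 block_size = as.integer(block_size), beta = beta,
                 mu0 = mu0, a_F = a_F, a_T = a_T, a_g = a_g, b_h = b_h,
                 gamma = gamma, sigma = sigma, seed = as.integer(seed)),
            class = "qsrr_sim_config")
}

# Descriptor names used in the generated table: the field's familiar
# selected-descriptor names first, then generic filler names.
SYNTH_DESCRIPTOR_NAMES <- c(
  "MW", "nCIR", "nR10", "RDF090u", "RDF030m", "Mor07u", "RDF110u",
  "Mor20u", "Mor26u", "Mor30u", "SM09_AEA(dm)", "SpPosA_RG", "H7u"
)

#' Generate a synthetic descriptor table
#'
#' `k_informative` columns are drawn independently standard normal; noise
#' columns come in blocks sharing a latent factor so that every pair within
#' a block has correlation `rho`. The first columns reuse familiar
#' descriptor names (MW, nCIR, ..., H7u), the rest are generic `D##`; all
#' values are synthetic draws, not structure-derived.
#'
#' @param config A [synthetic_config()].
#' @return A descriptor tibble (column `analyte` + numeric columns), as
#'   consumed by [assemble_dataset()].
#' @export
generate_descriptor_matrix <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "qsrr_sim_config"))
  n <- config$n_analytes
  k <- config$k_informative
  p <- k + config$n_noise
  if (k > p) stop("generate_descriptor_matrix(): k exceeds total columns",
                  call. = FALSE)
  local_rng(derive_seed(config$seed, "descriptors"))
  inf <- matrix(stats::rnorm(n * k), n, k)
  noise <- matrix(0, n, config$n_noise)
  if (config$n_noise > 0L) {
    blocks <- split(seq_len(config$n_noise),
                    ceiling(seq_len(config$n_noise) / config$block_size))
    for (b in blocks) {
      z <- stats::rnorm(n)
      for (j in b) {
        noise[, j] <- sqrt(config$rho) * z +
          sqrt(1 - config$rho) * stats::rnorm(n)
      }
    }
  }
  m <- cbind(inf, noise)
  nm <- c(SYNTH_DESCRIPTOR_NAMES,
          sprintf("D%02d", seq_len(max(0L, p - length(SYNTH_DESCRIPTOR_NAMES)))))
  colnames(m) <- nm[seq_len(p)]
  dplyr::bind_cols(
    tibble::tibble(analyte = sprintf("PAH%02d", seq_len(n))),
    tibble::as_tibble(m)
  )
}

#' Generate synthetic retention times over a condition design
#'
#' Builds the hydrophobicity score `h` from the informative descriptor
#' columns (standardized, weighted by `beta`), then for every (analyte,
#' condition) record draws
#' `tr = mu0 + a_F (F - mean F) + a_T (T - mean T) + a_g (tg - mean tg)
#'  + b_h h + gamma h (tg - mean tg) + noise`.
#' If any record comes out non-positive the whole response is shifted up to
#' a 0.2 min floor (the surface stays affine in its terms).
#'
#' @param descriptors Descriptor table from [generate_descriptor_matrix()].
#' @param conditions Condition table from [chromatographic_design()].
#' @param config The same [synthetic_config()] used for the descriptors.
#' @return A dataset tibble as from [assemble_dataset()], with `tr` filled
#'   in and attribute `"truth"` carrying the noiseless surface and `h`.
#' @export
generate_retention <- function(descriptors,
                               conditions = chromatographic_design(),
                               config = synthetic_config()) {
  stopifnot(inherits(config, "qsrr_sim_config"))
  k <- config$k_informative
  desc_cols <- setdiff(names(descriptors), "analyte")
  if (length(desc_cols) < k) {
    stop("generate_retention(): descriptor table has fewer columns than k_informative",
         call. = FALSE)
  }
  inf <- as.matrix(descriptors[, desc_cols[seq_len(k)]])
  h_raw <- as.numeric(inf %*% config$beta)
  h <- as.numeric(base::scale(h_raw))
  names(h) <- descriptors$analyte
  ds <- assemble_dataset(descriptors, conditions)
  Fm <- mean(ds$F); Tm <- mean(ds$T); gm <- mean(ds$tg)
  hh <- h[ds$analyte]
  surface <- config$mu0 +
    config$a_F * (ds$F - Fm) + config$a_T * (ds$T - Tm) +
    config$a_g * (ds$tg - gm) + config$b_h * hh +
    config$gamma * hh * (ds$tg - gm)
  local_rng(derive_seed(config$seed, "retention"))
  tr <- surface + stats::rnorm(nrow(ds), sd = config$sigma)
  if (min(tr) <= 0) {
    shift <- 0.2 - min(tr)
    tr <- tr + shift
    surface <- surface + shift
  }
  ds$tr <- tr
  ds <- dplyr::relocate(ds, "tr", .before = "split")
  attr(ds, "truth") <- list(surface = surface, h = h, config = config)
  ds
}

#' Planted-subset benchmark for GA descriptor selection
#'
#' Generates a regression problem with a known answer: `k` informative
#' standard-normal columns with unit coefficients, `n_noise` independent
#' noise columns, and Gaussian response noise sized so the population R2 of
#' the true model is `target_r2`. Used to measure whether a selection
#' procedure recovers the planted support.
#'
#' @param n Number of records.
#' @param k Number of informative columns (named `inf1..infk`, positions
#'   1..k).
#' @param n_noise Number of pure-noise columns.
#' @param target_r2 Population R2 of the true linear model.
#' @param seed Integer seed.
#' @return A list with matrix `X`, response `y`, and `informative` (the
#'   planted column indices).
#' @export
simulate_planted <- function(n = 200L, k = 5L, n_noise = 45L,
                             target_r2 = 0.9, seed = 1L) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  local_rng(seed)
  X <- matrix(stats::rnorm(n * (k + n_noise)), n, k + n_noise)
  colnames(X) <- c(sprintf("inf%d", seq_len(k)),
                   sprintf("noise%d", seq_len(n_noise)))
  beta <- rep(1, k)
  signal_var <- sum(beta^2)  # columns are independent standard normal
  sigma <- sqrt(signal_var * (1 - target_r2) / target_r2)
  y <- as.numeric(X[, seq_len(k)] %*% beta) + stats::rnorm(n, sd = sigma)
  list(X = X, y = y, informative = seq_len(k), sigma = sigma)
}
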