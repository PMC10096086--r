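# Independent oracles used across the suite. Each reimplements an operation
# by a different route (brute force, closed form, explicit refits) and must
# never call the package function it checks.

# All simple cycles of the heavy-atom graph by brute force over EDGE
# subsets: an edge subset is a circuit iff every touched vertex has degree
# exactly 2 within the subset and the subset is connected. (Vertex-subset
# enumeration would miss circuits whose chord is present in the graph, e.g.
# the 10-circuit of a fused bicyclic.) Feasible for <= ~16 heavy-atom bonds.
oracle_circuit_sizes <- function(mol) {
  heavy <- which(mol$atoms$element != "H")
  keep <- mol$bonds$i %in% heavy & mol$bonds$j %in% heavy
  E <- as.matrix(mol$bonds[keep, c("i", "j")])
  m <- nrow(E)
  stopifnot(m <= 16L)
  sizes <- integer()
  for (mask in seq_len(2^m - 1L)) {
    es <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
    if (length(es) < 3L) next
    verts <- unique(as.vector(E[es, ]))
    deg <- table(factor(as.vector(E[es, ]), levels = verts))
    if (any(deg != 2L)) next
    # connectivity over the selected edges
    seen <- verts[1L]
    repeat {
      touch <- es[E[es, 1] %in% seen | E[es, 2] %in% seen]
      nxt <- setdiff(unique(as.vector(E[touch, , drop = FALSE])), seen)
      if (!length(nxt)) break
      seen <- c(seen, nxt)
    }
    if (length(seen) == length(verts)) sizes <- c(sizes, length(verts))
  }
  sort(sizes)
}

# O(N^2) reference loops for the geometric descriptors.
oracle_rdf <- function(mol, radius, weighting = "u", B = 100) {
  el <- mol$atoms$element
  mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)[el]
  w <- if (weighting == "m") unname(mass) / 12.011 else rep(1, length(el))
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  out <- 0
  for (i in seq_len(nrow(xyz) - 1L)) {
    for (j in seq.int(i + 1L, nrow(xyz))) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      out <- out + w[i] * w[j] * exp(-B * (radius - r)^2)
    }
  }
  out
}

oracle_morse <- function(mol, s, weighting = "u") {
  el <- mol$atoms$element
  mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)[el]
  w <- if (weighting == "m") unname(mass) / 12.011 else rep(1, length(el))
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  out <- 0
  for (i in seq_len(nrow(xyz) - 1L)) {
    for (j in seq.int(i + 1L, nrow(xyz))) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      k <- if (s == 0) 1 else sin(s * r) / (s * r)
      out <- out + w[i] * w[j] * k
    }
  }
  out
}

# Random point-cloud molecule (no bonds) for descriptor invariance checks.
random_cloud <- function(n, seed, elements = c("C", "H", "N", "O")) {
  set.seed(seed)
  molecule(data.frame(
    element = sample(elements, n, replace = TRUE),
    x = stats::runif(n, -4, 4), y = stats::runif(n, -4, 4),
    z = stats::runif(n, -4, 4)
  ), name = paste0("cloud", seed))
}

rotate_translate <- function(mol, seed) {
  set.seed(seed)
  # random rotation via QR of a Gaussian matrix
  qrd <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qrd)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- stats::rnorm(3, sd = 5)
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")]) %*% R
  xyz <- sweep(xyz, 2L, shift, "+")
  molecule(data.frame(element = mol$atoms$element, x = xyz[, 1],
                      y = xyz[, 2], z = xyz[, 3]), mol$bonds, mol$name)
}

# Explicit n-refit leave-one-out R2 (the slow route the leverage shortcut
# must reproduce).
oracle_loo_r2 <- function(X, y) {
  n <- length(y)
  press <- 0
  for (i in seq_len(n)) {
    fit <- stats::lm.fit(cbind(1, X[-i, , drop = FALSE]), y[-i])
    pred <- sum(c(1, X[i, ]) * fit$coefficients)
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

# Brute-force greedy covariance selection: residualize the raw (scaled)
# columns and response on the selected span by explicit least squares at
# every step, instead of iterative deflation.
oracle_covsel <- function(X, y, k) {
  Xs <- scale(X)
  ys <- as.numeric(scale(y))
  sel <- integer()
  for (step in seq_len(k)) {
    if (length(sel)) {
      S <- Xs[, sel, drop = FALSE]
      P <- function(v) v - S %*% solve(crossprod(S), crossprod(S, v))
      Xr <- apply(Xs, 2L, P)
      yr <- as.numeric(P(ys))
    } else {
      Xr <- Xs; yr <- ys
    }
    covs2 <- as.numeric(crossprod(Xr, yr))^2
    covs2[sel] <- -Inf
    sel <- c(sel, which.max(covs2))
  }
  sel
}

# 16 distinct fused-hexagon PAHs on the axial lattice, growing in size.
lattice_pah_set <- function() {
  cells <- list(
    "0,0",                       # benzene
    "0,0;1,0",                   # naphthalene
    "0,0;1,0;2,0",               # linear acene
    "0,0;1,0;1,-1",              # angular
    "0,0;1,0;0,1;1,-1",          # pyrene-like cluster
    "0,0;1,0;2,0;3,0",
    "0,0;1,0;2,0;2,-1",
    "0,0;1,0;2,0;3,0;4,0",
    "0,0;1,0;2,0;3,0;3,-1",
    "0,0;1,0;2,0;1,-1;2,-2",
    "0,0;1,0;2,0;3,0;4,0;5,0",
    "0,0;1,0;2,0;3,0;4,0;4,-1",
    "0,0;1,0;0,1;1,-1;2,-1",
    "0,0;1,0;2,0;3,0;4,0;5,0;6,0",
    "0,0;1,0;2,0;3,0;4,0;5,0;5,-1",
    "0,0;1,0;2,0;3,0;4,0;5,0;6,0;7,0"
  )
  mols <- lapply(seq_along(cells), function(i) {
    build_cata_pah(cells[[i]], name = sprintf("PAH%02d", i))
  })
  names(mols) <- vapply(mols, function(m) m$name, "")
  mols
}
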