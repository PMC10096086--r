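#' @keywords internal
# Standard atomic weights (amu) for the elements a PAH/QSRR workflow meets.
ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904, P = 30.974
)

atom_masses <- function(mol) {
  m <- ATOMIC_WEIGHTS[mol$atoms$element]
  if (anyNA(m)) {
    bad <- unique(mol$atoms$element[is.na(m)])
    stop("unknown element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(m)
}

#' Molecular weight
#'
#' Sum of standard atomic weights over all atoms, hydrogens included.
#'
#' @param mol A [molecule()].
#' @return Mass in amu.
#' @examples
#' molecular_weight(build_cata_pah("0,0;1,0"))  # naphthalene, 128.174
#' @export
molecular_weight <- function(mol) {
  stopifnot(inherits(mol, "qsrr_molecule"))
  if (n_atoms(mol) == 0L) stop("molecular_weight(): empty molecule", call. = FALSE)
  sum(atom_masses(mol))
}

# Adjacency list of the heavy-atom (non-hydrogen) graph, vertices renumbered
# 1..n_heavy. Returns list(adj = list of integer neighbour vectors, n = count).
heavy_graph <- function(mol) {
  heavy <- which(mol$atoms$element != "H")
  remap <- integer(n_atoms(mol)); remap[heavy] <- seq_along(heavy)
  adj <- vector("list", length(heavy))
  for (k in seq_along(adj)) adj[[k]] <- integer()
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$i[r]; b <- mol$bonds$j[r]
      if (remap[a] > 0L && remap[b] > 0L) {
        adj[[remap[a]]] <- c(adj[[remap[a]]], remap[b])
        adj[[remap[b]]] <- c(adj[[remap[b]]], remap[a])
      }
    }
  }
  list(adj = lapply(adj, function(v) sort(unique(v))), n = length(heavy))
}

# Enumerate all simple cycles (circuits) in an undirected graph by rooted DFS:
# for each root v, walk simple paths through vertices > v only, counting a
# cycle when the walk returns to v with length >= 3. Each cycle is reported
# once per orientation, i.e. exactly twice; returns one size per cycle.
count_circuits <- function(adj, max_size = 24L) {
  n <- length(adj)
  sizes <- integer()
  in_path <- logical(n)
  dfs <- function(root, v, depth) {
    in_path[v] <<- TRUE
    for (w in adj[[v]]) {
      if (w == root && depth >= 3L) {
        sizes <<- c(sizes, depth)
      } else if (w > root && !in_path[w] && depth < max_size) {
        dfs(root, w, depth + 1L)
      }
    }
    in_path[v] <<- FALSE
  }
  for (root in seq_len(n)) dfs(root, root, 1L)
  if (!length(sizes)) return(integer())
  stopifnot(length(sizes) %% 2L == 0L)
  sort(sizes)[c(TRUE, FALSE)]
}

#' Ring and circuit descriptors
#'
#' Counts circuits in the heavy-atom bond graph by exhaustive simple-cycle
#' enumeration. `nCIR` is the number of distinct simple cycles (rings and
#' larger circuits alike) up to `max_circuit`; `nR10` is the number of
#' 10-membered circuits, the signature of two fused six-membered rings.
#'
#' @param mol A [molecule()] with bonds (run [perceive_bonds()] on bare XYZ
#'   input first).
#' @param max_circuit Largest circuit size enumerated.
#' @param max_heavy Refuse molecules with more heavy atoms than this
#'   (exhaustive enumeration grows exponentially).
#' @return A named list with integer `nCIR` and `nR10`.
#' @examples
#' ring_descriptors(build_cata_pah("0,0;1,0"))  # naphthalene: nCIR 3, nR10 1
#' @export
ring_descriptors <- function(mol, max_circuit = 24L, max_heavy = 60L) {
  stopifnot(inherits(mol, "qsrr_molecule"))
  g <- heavy_graph(mol)
  if (g$n > max_heavy) {
    stop(sprintf(paste0("ring_descriptors(): %d heavy atoms exceeds the ",
                        "enumeration cap of %d (raise max_heavy at your own ",
                        "expense)"), g$n, max_heavy), call. = FALSE)
  }
  sizes <- count_circuits(g$adj, max_size = as.integer(max_circuit))
  list(nCIR = length(sizes), nR10 = sum(sizes == 10L))
}

#' Descriptor specification
#'
#' Parses Dragon-style descriptor names into family/index/weighting triples.
#' Recognized: `MW`, `nCIR`, `nR10`, `RDF<code><w>` with a 3-digit radius
#' code (multiple of 5 in 000..155, radius = code/10 Angstrom) and weighting
#' letter `u` (unweighted) or `m` (mass), and `Mor<signal><w>` with a 2-digit
#' signal number in 01..32.
#'
#' @param name Descriptor name, e.g. `"RDF030m"`, `"Mor07u"`, `"MW"`.
#' @return A list with `name`, `family` (one of MW, RING, RDF, MORSE),
#'   `index` (integer or NA) and `weighting` (`"u"`, `"m"` or NA).
#' @export
descriptor_spec <- function(name) {
  if (name == "MW") {
    return(list(name = name, family = "MW", index = NA_integer_,
                weighting = NA_character_))
  }
  if (name %in% c("nCIR", "nR10")) {
    return(list(name = name, family = "RING", index = NA_integer_,
                weighting = NA_character_))
  }
  if (grepl("^RDF[0-9]{3}[um]$", name)) {
    code <- as.integer(substr(name, 4L, 6L))
    if (code %% 5L != 0L || code > 155L) {
      stop("descriptor_spec(): RDF code must be a multiple of 5 in 000..155: ",
           name, call. = FALSE)
    }
    return(list(name = name, family = "RDF", index = code,
                weighting = substr(name, 7L, 7L)))
  }
  if (grepl("^Mor[0-9]{2}[um]$", name)) {
    sig <- as.integer(substr(name, 4L, 5L))
    if (sig < 1L || sig > 32L) {
      stop("descriptor_spec(): MoRSE signal must be in 01..32: ", name,
           call. = FALSE)
    }
    return(list(name = name, family = "MORSE", index = sig,
                weighting = substr(name, 6L, 6L)))
  }
  stop("descriptor_spec(): unrecognized descriptor name: ", name,
       call. = FALSE)
}

pair_weights <- function(mol, weighting) {
  if (identical(weighting, "m")) atom_masses(mol) / ATOMIC_WEIGHTS[["C"]]
  else rep(1, n_atoms(mol))
}

#' Radial distribution function (RDF) descriptor
#'
#' Gaussian-smoothed pair-distance distribution evaluated at a fixed radius:
#' \deqn{RDF(R) = \sum_{i<j} w_i w_j \exp(-B (R - r_{ij})^2)}
#' with R = code/10 Angstrom and w the atomic weighting (1 for `u`; atomic
#' mass relative to carbon for `m`, so `m` and `u` coincide on pure-carbon
#' frameworks).
#'
#' @param mol A [molecule()] with at least 2 atoms.
#' @param code Radius code (e.g. `30` or `"030"` for 3.0 Angstrom); multiples
#'   of 5 in 0..155.
#' @param weighting `"u"` or `"m"`.
#' @param B Gaussian smoothing parameter, 1/Angstrom^2.
#' @param include_h Include hydrogens in the pair sum.
#' @return Dimensionless descriptor value.
#' @export
rdf_descriptor <- function(mol, code, weighting = "u", B = 100,
                           include_h = TRUE) {
  stopifnot(inherits(mol, "qsrr_molecule"), B > 0)
  code <- as.integer(code)
  if (is.na(code) || code < 0L || code > 155L || code %% 5L != 0L) {
    stop("rdf_descriptor(): invalid radius code", call. = FALSE)
  }
  sub <- mol
  if (!include_h) {
    keep <- mol$atoms$element != "H"
    sub <- molecule(mol$atoms[keep, ], NULL, mol$name)
  }
  if (n_atoms(sub) < 2L) {
    warning("rdf_descriptor(): fewer than 2 atoms; returning 0")
    return(0)
  }
  w <- pair_weights(sub, weighting)
  d <- stats::dist(coords_matrix(sub))
  R <- code / 10
  # pair products w_i * w_j in the same ordering as dist()
  n <- length(w)
  wp <- unlist(lapply(seq_len(n - 1L), function(i) w[i] * w[(i + 1L):n]))
  sum(wp * exp(-B * (R - as.numeric(d))^2))
}

#' 3D-MoRSE descriptor
#'
#' Electron-diffraction-style pair sum
#' \deqn{Mor(s) = \sum_{i<j} w_i w_j \, \mathrm{sin}(s\,r_{ij})/(s\,r_{ij})}
#' with the kernel equal to 1 at s = 0 by continuity. The scattering
#' parameter s (1/Angstrom) is mapped from the two-digit signal number by the
#' Dragon convention s = signal - 1 (so Mor01 has s = 0); the literal mapping
#' s = signal is available via `convention = "signal"`.
#'
#' @param mol A [molecule()] with at least 2 atoms.
#' @param signal Signal number in 1..32.
#' @param weighting `"u"` or `"m"`.
#' @param convention `"signal_minus_1"` (default) or `"signal"`.
#' @param include_h Include hydrogens in the pair sum.
#' @return Dimensionless descriptor value.
#' @export
morse_descriptor <- function(mol, signal, weighting = "u",
                             convention = c("signal_minus_1", "signal"),
                             include_h = TRUE) {
  stopifnot(inherits(mol, "qsrr_molecule"))
  convention <- match.arg(convention)
  signal <- as.integer(signal)
  if (is.na(signal) || signal < 1L || signal > 32L) {
    stop("morse_descriptor(): signal number must be in 1..32", call. = FALSE)
  }
  s <- if (convention == "signal_minus_1") signal - 1 else signal
  sub <- mol
  if (!include_h) {
    keep <- mol$atoms$element != "H"
    sub <- molecule(mol$atoms[keep, ], NULL, mol$name)
  }
  if (n_atoms(sub) < 2L) {
    stop("morse_descriptor(): need at least 2 atoms", call. = FALSE)
  }
  w <- pair_weights(sub, weighting)
  n <- length(w)
  wp <- unlist(lapply(seq_len(n - 1L), function(i) w[i] * w[(i + 1L):n]))
  r <- as.numeric(stats::dist(coords_matrix(sub)))
  kern <- if (s == 0) rep(1, length(r)) else sin(s * r) / (s * r)
  sum(wp * kern)
}

#' Compute a descriptor table for a set of molecules
#'
#' One row per molecule, one column per descriptor name, evaluated by
#' [molecular_weight()], [ring_descriptors()], [rdf_descriptor()] and
#' [morse_descriptor()] according to the parsed [descriptor_spec()].
#'
#' @param mols A list of [molecule()]s (named, or carrying `name` labels).
#' @param specs Character vector of descriptor names, e.g.
#'   `c("MW", "nCIR", "nR10", "RDF030m", "RDF090u", "Mor07u")`.
#' @param B RDF smoothing parameter, passed through.
#' @param morse_convention MoRSE signal convention, passed through.
#' @return A tibble with column `analyte` followed by one numeric column per
#'   descriptor.
#' @export
compute_descriptor_table <- function(mols, specs, B = 100,
                                     morse_convention = "signal_minus_1") {
  stopifnot(length(specs) > 0, length(mols) > 0)
  if (anyDuplicated(specs)) {
    stop("compute_descriptor_table(): duplicate descriptor names", call. = FALSE)
  }
  parsed <- lapply(specs, descriptor_spec)
  labels <- names(mols)
  if (is.null(labels)) labels <- vapply(mols, function(m) m$name, "")
  if (any(!nzchar(labels))) labels <- paste0("mol", seq_along(mols))
  rows <- lapply(seq_along(mols), function(k) {
    m <- mols[[k]]
    vals <- vapply(parsed, function(sp) {
      tryCatch(
        switch(sp$family,
          MW = molecular_weight(m),
          RING = {
            rd <- ring_descriptors(m)
            if (sp$name == "nCIR") rd$nCIR else rd$nR10
          },
          RDF = rdf_descriptor(m, sp$index, sp$weighting, B = B),
          MORSE = morse_descriptor(m, sp$index, sp$weighting,
                                   convention = morse_convention)
        ),
        error = function(e) {
          stop(sprintf("descriptor %s failed for molecule '%s': %s",
                       sp$name, labels[k], conditionMessage(e)), call. = FALSE)
        })
    }, numeric(1))
    names(vals) <- specs
    tibble::as_tibble(as.list(vals))
  })
  dplyr::bind_cols(tibble::tibble(analyte = labels), dplyr::bind_rows(rows))
}
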