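#' Molecular geometry container
#'
#' A `qsrr_molecule` bundles an element-labelled 3D point set with an
#' (optional) bond list. It is the substrate every descriptor in this package
#' is computed from. Coordinates are always in Angstrom.
#'
#' @param atoms A data frame with columns `element` (character symbol),
#'   `x`, `y`, `z` (numeric, Angstrom).
#' @param bonds A data frame with integer columns `i`, `j` (1-based atom
#'   indices, unordered pairs). May have zero rows.
#' @param name Text label for the molecule.
#'
#' @return An object of class `qsrr_molecule` with elements `atoms` (tibble),
#'   `bonds` (tibble, normalized so `i < j`, deduplicated) and `name`.
#' @examples
#' mol <- molecule(
#'   atoms = data.frame(element = c("C", "C"), x = c(0, 1.4), y = 0, z = 0),
#'   bonds = data.frame(i = 1L, j = 2L)
#' )
#' n_atoms(mol)
#' @export
molecule <- function(atoms, bonds = NULL, name = "") {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  atoms <- atoms[, c("element", "x", "y", "z")]
  atoms$element <- as.character(atoms$element)
  for (cc in c("x", "y", "z")) atoms[[cc]] <- as.numeric(atoms[[cc]])
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("molecule(): all coordinates must be finite", call. = FALSE)
  }
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- tibble::tibble(i = integer(), j = integer())
  } else {
    bonds <- tibble::as_tibble(bonds)[, c("i", "j")]
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    n <- nrow(atoms)
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n)) {
      stop("molecule(): bond index out of range 1..", n, call. = FALSE)
    }
    if (any(bonds$i == bonds$j)) {
      stop("molecule(): self-bonds are not allowed", call. = FALSE)
    }
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    bonds <- dplyr::distinct(bonds)
  }
  structure(list(atoms = atoms, bonds = bonds, name = name),
            class = "qsrr_molecule")
}

#' @export
print.qsrr_molecule <- function(x, ...) {
  cat(sprintf("<qsrr_molecule> %s: %d atoms (%s), %d bonds\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$atoms),
              paste(names(sort(table(x$atoms$element), decreasing = TRUE)),
                    sort(table(x$atoms$element), decreasing = TRUE),
                    sep = "", collapse = " "),
              nrow(x$bonds)))
  invisible(x)
}

#' @rdname molecule
#' @param mol A `qsrr_molecule`.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

coords_matrix <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ convention: first line atom count, second line a free-form
#' comment (used as the molecule name), then one `element x y z` line per
#' atom. No bonds are read; use [perceive_bonds()] afterwards.
#'
#' @param path Path to an XYZ file.
#' @return A [molecule()] with zero bonds.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("read_xyz(): file too short: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("read_xyz(): line 1 is not an atom count", call. = FALSE)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    stop(sprintf("read_xyz(): declared %d atoms but only %d atom lines found",
                 n, length(body)), call. = FALSE)
  }
  rows <- lapply(seq_len(n), function(k) {
    tok <- strsplit(trimws(body[k]), "\\s+")[[1]]
    if (length(tok) < 4L) {
      stop(sprintf("read_xyz(): atom line %d has fewer than 4 fields", k + 2L),
           call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) {
      stop(sprintf("read_xyz(): non-numeric coordinate on atom line %d", k + 2L),
           call. = FALSE)
    }
    tibble::tibble(element = tok[1L], x = xyz[1L], y = xyz[2L], z = xyz[3L])
  })
  molecule(dplyr::bind_rows(rows), name = trimws(lines[2L]))
}

#' Write a molecule to an XYZ file
#'
#' @param mol A [molecule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path) {
  hdr <- c(as.character(n_atoms(mol)), mol$name)
  body <- sprintf("%-3s %18.10f %18.10f %18.10f",
                  mol$atoms$element, mol$atoms$x, mol$atoms$y, mol$atoms$z)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a molecule from an SDF/MOL V2000 connection table
#'
#' Reads the first record: header (3 lines, line 1 used as the name), counts
#' line, atom block and bond block.
#'
#' @param path Path to a MOL/SDF file (V2000).
#' @return A [molecule()] with atoms and bonds populated.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) stop("read_sdf(): file too short: ", path, call. = FALSE)
  counts <- lines[4L]
  natom <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbond <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natom) || is.na(nbond) || natom < 0L || nbond < 0L) {
    stop("read_sdf(): malformed counts line (line 4)", call. = FALSE)
  }
  if (length(lines) < 4L + natom + nbond) {
    stop("read_sdf(): file ends before the declared atom/bond blocks",
         call. = FALSE)
  }
  atom_lines <- lines[4L + seq_len(natom)]
  atoms <- dplyr::bind_rows(lapply(atom_lines, function(ln) {
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 1, 10), substr(ln, 11, 20),
                                         substr(ln, 21, 30))))
    el <- trimws(substr(ln, 32, 34))
    if (anyNA(xyz) || !nzchar(el)) {
      stop("read_sdf(): malformed atom line: ", ln, call. = FALSE)
    }
    tibble::tibble(element = el, x = xyz[1], y = xyz[2], z = xyz[3])
  }))
  bonds <- NULL
  if (nbond > 0L) {
    bond_lines <- lines[4L + natom + seq_len(nbond)]
    bonds <- dplyr::bind_rows(lapply(bond_lines, function(ln) {
      ij <- suppressWarnings(as.integer(c(substr(ln, 1, 3), substr(ln, 4, 6))))
      if (anyNA(ij)) stop("read_sdf(): malformed bond line: ", ln, call. = FALSE)
      if (any(ij < 1L) || any(ij > natom)) {
        stop("read_sdf(): bond references atom outside 1..", natom, call. = FALSE)
      }
      tibble::tibble(i = ij[1], j = ij[2])
    }))
  }
  molecule(atoms, bonds, name = trimws(lines[1L]))
}

# Axial (q, r) hexagon centre -> cartesian, flat-top hexagons with side `a`.
hex_centre <- function(q, r, a) {
  c(x = 1.5 * a * q, y = sqrt(3) * a * (r + q / 2))
}

# Six vertices of a flat-top hexagon centred at `ctr` with side `a`.
hex_vertices <- function(ctr, a) {
  ang <- pi / 3 * (0:5)
  cbind(x = ctr["x"] + a * cos(ang), y = ctr["y"] + a * sin(ang))
}

#' Build an idealized cata-/peri-fused PAH on a hexagonal lattice
#'
#' Places one benzene hexagon per axial lattice cell (flat-top convention),
#' merges vertices shared between fused hexagons, and caps every carbon with
#' fewer than three carbon neighbours with a hydrogen on the external
#' bisector. The result is a planar, idealized polycyclic aromatic
#' hydrocarbon: all C-C bonds exactly 1.40 Angstrom, all C-H bonds 1.09
#' Angstrom, all atoms at z = 0. Intended as a deterministic stand-in for
#' force-field-optimized geometries, which for planar PAHs deviate only
#' slightly from the ideal lattice.
#'
#' @param hexagons Hexagon cells as a two-column matrix/data frame of axial
#'   `(q, r)` coordinates, or a string `"q1,r1;q2,r2;..."`.
#' @param name Molecule name.
#' @param cc Carbon-carbon bond length, Angstrom.
#' @param ch Carbon-hydrogen bond length, Angstrom.
#' @return A [molecule()] with C and H atoms and all C-C and C-H bonds.
#' @examples
#' benzene <- build_cata_pah("0,0")
#' naphthalene <- build_cata_pah("0,0;1,0", name = "naphthalene")
#' @export
build_cata_pah <- function(hexagons, name = "", cc = 1.40, ch = 1.09) {
  if (is.character(hexagons)) {
    parts <- strsplit(strsplit(hexagons, ";")[[1]], ",")
    hexagons <- do.call(rbind, lapply(parts, function(p) as.numeric(trimws(p))))
  }
  hexagons <- as.matrix(hexagons)
  if (ncol(hexagons) != 2L || anyNA(hexagons)) {
    stop("build_cata_pah(): hexagons must be (q, r) axial pairs", call. = FALSE)
  }
  nh <- nrow(hexagons)
  # connectivity of the hexagon set on the axial lattice (6 neighbours)
  if (nh > 1L) {
    nb_offsets <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))
    adj <- matrix(FALSE, nh, nh)
    for (a_ in seq_len(nh)) for (b_ in seq_len(nh)) {
      d <- hexagons[b_, ] - hexagons[a_, ]
      if (any(apply(nb_offsets, 1L, function(o) all(o == d)))) adj[a_, b_] <- TRUE
    }
    seen <- rep(FALSE, nh); queue <- 1L; seen[1L] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nx <- which(adj[v, ] & !seen)
      seen[nx] <- TRUE; queue <- c(queue, nx)
    }
    if (!all(seen)) {
      stop("build_cata_pah(): hexagon set is disconnected", call. = FALSE)
    }
  }
  # collect vertices, merge duplicates shared by fused rings
  verts <- NULL
  edges <- NULL  # rows of (global vertex a, global vertex b)
  key_of <- function(v) NULL
  tol <- 1e-6
  for (h in seq_len(nh)) {
    ctr <- hex_centre(hexagons[h, 1L], hexagons[h, 2L], cc)
    vv <- hex_vertices(ctr, cc)
    idx <- integer(6)
    for (k in 1:6) {
      if (is.null(verts)) {
        verts <- vv[k, , drop = FALSE]; idx[k] <- 1L
      } else {
        d2 <- (verts[, 1] - vv[k, 1])^2 + (verts[, 2] - vv[k, 2])^2
        hit <- which(d2 < tol^2)
        if (length(hit)) {
          idx[k] <- hit[1L]
        } else {
          verts <- rbind(verts, vv[k, ]); idx[k] <- nrow(verts)
        }
      }
    }
    edges <- rbind(edges, cbind(idx, idx[c(2:6, 1L)]))
  }
  edges <- t(apply(edges, 1L, sort))
  edges <- unique(edges)
  nc <- nrow(verts)
  # carbon neighbour counts -> hydrogen placement on the external bisector
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nc)
  h_xy <- NULL
  for (v in which(deg < 3L)) {
    nbrs <- unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
    dir <- verts[v, ] - colMeans(verts[nbrs, , drop = FALSE])
    dir <- dir / sqrt(sum(dir^2))
    h_xy <- rbind(h_xy, verts[v, ] + ch * dir)
  }
  nH <- if (is.null(h_xy)) 0L else nrow(h_xy)
  atoms <- tibble::tibble(
    element = c(rep("C", nc), rep("H", nH)),
    x = c(verts[, 1], if (nH) h_xy[, 1]),
    y = c(verts[, 2], if (nH) h_xy[, 2]),
    z = 0
  )
  ch_bonds <- if (nH) cbind(which(deg < 3L), nc + seq_len(nH)) else NULL
  bonds <- tibble::tibble(
    i = c(edges[, 1], if (nH) ch_bonds[, 1]),
    j = c(edges[, 2], if (nH) ch_bonds[, 2])
  )
  molecule(atoms, bonds, name = name)
}

#' Perceive bonds from interatomic distances
#'
#' Adds a bond for every atom pair closer than the distance cutoff for that
#' element pair. Cutoffs are symmetric in the element order; pairs without a
#' cutoff entry fall back to `default`.
#'
#' @param mol A [molecule()]; existing bonds are replaced.
#' @param cutoffs Named numeric vector of per-element-pair cutoffs in
#'   Angstrom, names like `"C-C"`, `"C-H"`. Defaults separate bonded from
#'   non-bonded distances on the ideal PAH lattice by a wide margin.
#' @param default Cutoff for element pairs not listed, Angstrom.
#' @return The molecule with perceived bonds.
#' @export
perceive_bonds <- function(mol, cutoffs = c("C-C" = 1.75, "C-H" = 1.20),
                           default = 1.6) {
  stopifnot(inherits(mol, "qsrr_molecule"))
  if (any(cutoffs <= 0) || default <= 0) {
    stop("perceive_bonds(): cutoffs must be positive", call. = FALSE)
  }
  n <- n_atoms(mol)
  if (n < 2L) return(molecule(mol$atoms, NULL, mol$name))
  xyz <- coords_matrix(mol)
  el <- mol$atoms$element
  cut_for <- function(e1, e2) {
    k1 <- paste0(e1, "-", e2); k2 <- paste0(e2, "-", e1)
    if (k1 %in% names(cutoffs)) cutoffs[[k1]]
    else if (k2 %in% names(cutoffs)) cutoffs[[k2]]
    else default
  }
  d <- as.matrix(stats::dist(xyz))
  ii <- jj <- integer()
  for (a_ in seq_len(n - 1L)) {
    for (b_ in seq.int(a_ + 1L, n)) {
      if (d[a_, b_] < cut_for(el[a_], el[b_])) {
        ii <- c(ii, a_); jj <- c(jj, b_)
      }
    }
  }
  molecule(mol$atoms, tibble::tibble(i = ii, j = jj), mol$name)
}
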