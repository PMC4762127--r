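#' Assemble a coarse-grained 3D scaffold from a secondary structure
#'
#' Builds one P/C4' coordinate pair per nucleotide from a secondary
#' structure: helices as ideal A-form virtual-bond duplexes, loops as
#' self-avoiding virtual-bond walks on the diamond lattice bridging their
#' helix anchor points (helix pseudo-atoms act as excluded volume).
#' Helices connected by loops of at most 1 nt are placed coaxially on a
#' common axis, which is what makes the hairpin-hairpin kissing complex a
#' continuous H1-H2-H3 stack.
#'
#' Supported topologies at this coarse-grained level: the empty structure,
#' an unpaired chain, a single hairpin (stem + loop), a two-strand duplex
#' covering both strands, and a kissing complex (two hairpin stems joined
#' by one intermolecular kissing helix with l2, l4 <= 1). A loop too short
#' to bridge its anchors on the lattice is reported as infeasible, never
#' silently dropped.
#'
#' @param structure A [kf_structure()].
#' @param geom A [helix_geometry()].
#' @param vbond Virtual-bond length in Angstrom (default 3.9).
#' @param clash Minimum allowed distance between non-bonded pseudo-atoms
#'   (default 3.5 Angstrom); loop conformations violating it are skipped.
#' @return A `kf_scaffold` tibble: chain, residue, atom, x, y, z, source
#'   (`"helix"` or `"loop"`), resid (base letter).
#' @export
assemble_scaffold <- function(structure, geom = helix_geometry(),
                              vbond = 3.9, clash = 3.5) {
  stopifnot(inherits(structure, "kf_structure"))
  total <- sum(structure$n)
  if (total == 0) return(empty_scaffold())
  pm <- as.matrix(structure$pairs[, c("i", "j")])
  bases <- strsplit(paste0(structure$sequences, collapse = ""), "")[[1]]
  n1 <- structure$n[1]
  helices <- pairs_to_helices(pm)
  n_strands <- length(structure$sequences)
  scaffold <- if (nrow(pm) == 0) {
    coil_scaffold(structure$n, vbond)
  } else if (length(helices) == 1 && n_strands == 1) {
    hairpin_scaffold(structure, helices[[1]], geom, vbond, clash)
  } else if (length(helices) == 1 && n_strands == 2) {
    duplex_scaffold(structure, helices[[1]], geom, vbond)
  } else if (is_kissing_layout(structure, helices, n1)) {
    kissing_scaffold(structure, helices, geom, vbond, clash)
  } else {
    abort("unsupported topology for coarse-grained scaffold assembly")
  }
  scaffold$resid <- bases[global_index(scaffold, structure$n)]
  mind <- scaffold_min_nonbonded(scaffold)
  if (mind < clash) {
    abort(sprintf(
      "scaffold has a steric clash (%.2f A < %.2f A); structure reported infeasible",
      mind, clash))
  }
  scaffold
}

global_index <- function(scaffold, n) {
  offs <- c(0, cumsum(n))
  chain_no <- match(scaffold$chain, LETTERS)
  offs[chain_no] + scaffold$residue
}

coil_scaffold <- function(n, vbond) {
  # unpaired chains laid out as non-overlapping zig-zag lattice walks
  rows <- list()
  offset <- c(0L, 0L, 0L)
  for (k in seq_along(n)) {
    sites <- zigzag_sites(2L * n[k], offset)
    xyz <- lattice_to_cartesian(sites, vbond)
    rows[[k]] <- tibble(
      chain = LETTERS[k], residue = rep(seq_len(n[k]), each = 2),
      atom = rep(c("P", "C4'"), n[k]),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], source = "loop")
    offset <- offset + c(0L, 4L, 4L)
  }
  new_scaffold(dplyr::bind_rows(rows))
}

zigzag_sites <- function(n_sites, offset = c(0L, 0L, 0L)) {
  site <- offset
  out <- matrix(0L, nrow = n_sites, ncol = 3)
  for (s in seq_len(n_sites)) {
    step <- if (s %% 2 == 1) c(1L, 1L, 1L) else c(1L, -1L, -1L)
    site <- site + step
    out[s, ] <- site
  }
  out
}

# Bridge a backbone gap of `l` nt between a donor C4' atom and an acceptor
# P atom with a lattice walk of 2l + 1 steps; returns the 2l interior
# coordinates (P, C4' alternating) or NULL if infeasible.
bridge_loop <- function(donor, acceptor, l, placed_xyz, vbond, clash) {
  start <- snap_to_lattice(donor, vbond)
  want <- if ((2 * l + 1) %% 2 == 1) {
    setdiff(c("A", "B"), lattice_sublattice(start))
  } else {
    lattice_sublattice(start)
  }
  end <- snap_to_lattice(acceptor, vbond, sublattice = want)
  obst <- unique(t(apply(placed_xyz, 1, snap_to_lattice,
                         bond_length = vbond)))
  keys <- site_key(obst)
  obst <- obst[!keys %in% c(site_key(rbind(start)), site_key(rbind(end))),
               , drop = FALSE]
  walks <- enumerate_anchored_walks(start, end, 2L * l + 1L, obst)
  for (w in walks) {
    interior <- w[seq(2, nrow(w) - 1), , drop = FALSE]
    if (nrow(interior) == 0) return(matrix(numeric(), ncol = 3))
    xyz <- lattice_to_cartesian(interior, vbond)
    d <- fields_min_dist(xyz, placed_xyz)
    if (d >= clash) return(xyz)
  }
  NULL
}

fields_min_dist <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  min(vapply(seq_len(nrow(a)), function(r) {
    sqrt(min((b[, 1] - a[r, 1])^2 + (b[, 2] - a[r, 2])^2 +
               (b[, 3] - a[r, 3])^2))
  }, numeric(1)))
}

duplex_atom_lookup <- function(atoms) {
  function(strand, level, atom) {
    row <- atoms[atoms$strand == strand & atoms$level == level &
                   atoms$atom == atom, ]
    c(row$x[1], row$y[1], row$z[1])
  }
}

loop_rows <- function(chain, residues, xyz) {
  if (length(residues) == 0) {
    return(tibble(chain = character(), residue = integer(),
                  atom = character(), x = double(), y = double(),
                  z = double(), source = character()))
  }
  tibble(chain = chain, residue = rep(residues, each = 2),
         atom = rep(c("P", "C4'"), length(residues)),
         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], source = "loop")
}

helix_rows <- function(atoms, strand, levels, chain, residues) {
  # levels in backbone order for this chain segment
  out <- lapply(seq_along(levels), function(k) {
    sub <- atoms[atoms$strand == strand & atoms$level == levels[k], ]
    sub <- sub[order(sub$atom != "P"), ]
    tibble(chain = chain, residue = residues[k], atom = sub$atom,
           x = sub$x, y = sub$y, z = sub$z, source = "helix")
  })
  dplyr::bind_rows(out)
}

hairpin_scaffold <- function(structure, helix, geom, vbond, clash) {
  n_bp <- nrow(helix)
  p <- helix[n_bp, 1]
  q <- helix[n_bp, 2]
  l <- q - p - 1
  if (helix[1, 1] != 1 || helix[1, 2] != sum(structure$n)) {
    abort("hairpin scaffold requires the stem to close the full chain")
  }
  atoms <- aform_duplex_atoms(n_bp, geom, vbond, 2.1468)
  at <- duplex_atom_lookup(atoms)
  stem5 <- helix_rows(atoms, 1, 0:(n_bp - 1), "A", seq_len(n_bp))
  stem3 <- helix_rows(atoms, 2, (n_bp - 1):0, "A",
                      seq(q, helix[1, 2]))
  placed <- as.matrix(dplyr::bind_rows(stem5, stem3)[, c("x", "y", "z")])
  lp <- bridge_loop(at(1, n_bp - 1, "C4'"), at(2, n_bp - 1, "P"), l,
                    placed, vbond, clash)
  if (is.null(lp)) {
    abort(sprintf("loop of %d nt cannot bridge its stem anchors: infeasible",
                  l))
  }
  new_scaffold(dplyr::bind_rows(stem5, loop_rows("A", seq(p + 1, q - 1), lp),
                                stem3) |>
                 dplyr::arrange(.data$residue,
                                dplyr::desc(.data$atom == "P")))
}

duplex_scaffold <- function(structure, helix, geom, vbond) {
  n_bp <- nrow(helix)
  n <- structure$n
  if (n_bp != n[1] || n_bp != n[2]) {
    abort("duplex scaffold requires both strands fully paired")
  }
  sc <- build_aform_helix(n_bp, geom, vbond = vbond)
  sc
}

is_kissing_layout <- function(structure, helices, n1) {
  if (length(structure$sequences) != 2 || length(helices) != 3) return(FALSE)
  inter <- vapply(helices, function(h) h[1, 1] <= n1 && h[1, 2] > n1, TRUE)
  sum(inter) == 1 && any(structure$pairs$kissing)
}

kissing_scaffold <- function(structure, helices, geom, vbond, clash) {
  n1 <- structure$n[1]
  inter <- vapply(helices, function(h) h[1, 1] <= n1 && h[1, 2] > n1, TRUE)
  K <- helices[inter][[1]]
  H1 <- helices[!inter][[which(vapply(helices[!inter],
                                      function(h) h[1, 1] <= n1, TRUE))]]
  H3 <- helices[!inter][[which(vapply(helices[!inter],
                                      function(h) h[1, 1] > n1, TRUE))]]
  h1 <- nrow(H1)
  h2 <- nrow(K)
  h3 <- nrow(H3)
  # loop lengths from sequence gaps (global numbering)
  l1 <- min(K[, 1]) - H1[h1, 1] - 1
  l2 <- H1[h1, 2] - max(K[, 1]) - 1
  l3 <- min(K[, 2]) - H3[h3, 1] - 1
  l4 <- H3[h3, 2] - max(K[, 2]) - 1
  if (l2 > 1 || l4 > 1) {
    abort("kissing scaffold requires l2 and l4 <= 1 (coaxial stacking)")
  }
  n <- h1 + h2 + h3
  atoms <- aform_duplex_atoms(n, geom, vbond, 2.1468)
  at <- duplex_atom_lookup(atoms)
  # chain A: H1 up | l1 | H2 (descending strand) | l2 | H1 down
  a_h1_up <- helix_rows(atoms, 1, 0:(h1 - 1), "A", H1[, 1])
  a_h2 <- helix_rows(atoms, 2, (h1 + h2 - 1):h1, "A", K[, 1])
  a_h1_dn <- helix_rows(atoms, 2, (h1 - 1):0, "A", rev(H1[, 2]))
  # chain B: H3 down-entry | l3 | H2 (ascending strand) | l4 | H3 up
  b_h3_in <- helix_rows(atoms, 2, (n - 1):(h1 + h2), "B", H3[, 1] - n1)
  b_h2 <- helix_rows(atoms, 1, h1:(h1 + h2 - 1), "B", K[, 2] - n1)
  b_h3_out <- helix_rows(atoms, 1, (h1 + h2):(n - 1), "B",
                         rev(H3[, 2]) - n1)
  placed <- dplyr::bind_rows(a_h1_up, a_h2, a_h1_dn, b_h3_in, b_h2,
                             b_h3_out)
  placed_xyz <- as.matrix(placed[, c("x", "y", "z")])
  add_gap <- function(donor, acceptor, l, chain, residues) {
    if (l == 0) return(NULL)
    lp <- bridge_loop(donor, acceptor, l, placed_xyz, vbond, clash)
    if (is.null(lp)) {
      abort(sprintf(
        "loop of %d nt cannot bridge its anchors: infeasible", l))
    }
    loop_rows(chain, residues, lp)
  }
  g1 <- add_gap(at(1, h1 - 1, "C4'"), at(2, h1 + h2 - 1, "P"), l1, "A",
                seq(H1[h1, 1] + 1, length.out = l1))
  g2 <- add_gap(at(2, h1, "C4'"), at(2, h1 - 1, "P"), l2, "A",
                seq(max(K[, 1]) + 1, length.out = l2))
  g3 <- add_gap(at(2, h1 + h2, "C4'"), at(1, h1, "P"), l3, "B",
                seq(H3[h3, 1] + 1, length.out = l3) - n1)
  g4 <- add_gap(at(1, h1 + h2 - 1, "C4'"), at(1, h1 + h2, "P"), l4, "B",
                seq(max(K[, 2]) + 1, length.out = l4) - n1)
  out <- dplyr::bind_rows(a_h1_up, g1, a_h2, g2, a_h1_dn,
                          b_h3_in, g3, b_h2, g4, b_h3_out) |>
    dplyr::arrange(.data$chain, .data$residue,
                   dplyr::desc(.data$atom == "P"))
  new_scaffold(out)
}
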