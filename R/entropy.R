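#' Kissing-complex topology
#'
#' Stem/loop decomposition of a hairpin-hairpin kissing complex: the
#' kissing stem H2 of `h2_len` base pairs flanked by hairpin stems H1 and
#' H3, with four connecting loops l1..l4. The entropy pipeline assumes l2
#' and l4 are at most 1 nt, which favours coaxial stacking of H1 on H2 and
#' H2 on H3 and makes the kissing entropy a function of (H2, l1, l3) only.
#'
#' @param h2_len Kissing-stem length in bp (>= 1).
#' @param l1_len,l3_len Lengths of the two bridging loops in nt (>= 0).
#' @param l2_len,l4_len Lengths of the two short loops (0 or 1 nt).
#' @param h1_len,h3_len Flanking hairpin stem lengths in bp (>= 1).
#' @return An object of class `kissing_topology`.
#' @examples
#' kissing_topology(6, 2, 2)
#' @export
kissing_topology <- function(h2_len, l1_len, l3_len, l2_len = 0, l4_len = 0,
                             h1_len = 2, h3_len = 2) {
  vals <- c(h2_len, l1_len, l3_len, l2_len, l4_len, h1_len, h3_len)
  stopifnot(is.numeric(vals), all(vals == round(vals)), all(vals >= 0))
  if (h2_len < 1) abort("`h2_len` must be >= 1 bp.")
  if (h1_len < 1 || h3_len < 1) abort("flanking stems must be >= 1 bp.")
  if (l2_len > 1 || l4_len > 1) {
    abort("l2 and l4 must be <= 1 nt for the coaxial-stacking pipeline.")
  }
  structure(list(h2_len = as.integer(h2_len), l1_len = as.integer(l1_len),
                 l3_len = as.integer(l3_len), l2_len = as.integer(l2_len),
                 l4_len = as.integer(l4_len), h1_len = as.integer(h1_len),
                 h3_len = as.integer(h3_len)),
            class = "kissing_topology")
}

#' @export
print.kissing_topology <- function(x, ...) {
  cat(sprintf(
    "<kissing_topology> H2 = %d bp, loops l1/l2/l3/l4 = %d/%d/%d/%d nt, H1 = %d bp, H3 = %d bp\n",
    x$h2_len, x$l1_len, x$l2_len, x$l3_len, x$l4_len, x$h1_len, x$h3_len))
  invisible(x)
}

#' Anchor frame of a kissing complex
#'
#' Places the eight anchor nucleotides of the bridging loops l1 and l3
#' (start/end phosphates a_i, a_j and b_i, b_j, plus their pairing partners
#' a_i', a_j', b_i', b_j') from ideal coaxially stacked A-form geometry:
#' H1, H2 and H3 are built as one continuous duplex on a common axis, and
#' the anchors are read off the stem ends that the loops connect. The
#' placement is fully deterministic and regenerated from the geometry, not
#' taken from an experimental template, so entropies computed from it are
#' Vfold-like rather than bit-identical to published tables.
#'
#' Loop l1 runs from the top of the H1 strand that ascends the stack
#' (level h1-1) to the 5' end of the H2 strand it feeds (level h1+h2-1);
#' loop l3 runs from the bottom of the descending H3 strand (level h1+h2)
#' to the entry of the other H2 strand (level h1). The a_i - b_i
#' separation therefore grows by exactly one helical step per added H2
#' base pair.
#'
#' @param h2_len Kissing-stem length in bp (1..`max_h2`).
#' @param h1_len,h3_len Flanking stem lengths in bp.
#' @param geom A [helix_geometry()].
#' @param vbond Virtual-bond length in Angstrom.
#' @param max_h2 Largest supported kissing-stem length (default 8, the
#'   range of the shipped entropy table).
#' @return A list of class `anchor_frame`: `anchors` (8 x 3 matrix, rows
#'   a_i, a_i', a_j, a_j', b_i, b_i', b_j, b_j'), `helix_atoms` (matrix of
#'   all stack pseudo-atom coordinates), and the lengths used.
#' @export
generate_anchor_frame <- function(h2_len, h1_len = 2, h3_len = 2,
                                  geom = helix_geometry(), vbond = 3.9,
                                  max_h2 = 8L) {
  stopifnot(h2_len >= 1, h1_len >= 1, h3_len >= 1)
  if (h2_len > max_h2) {
    abort(sprintf("h2_len = %d exceeds the supported maximum of %d bp",
                  h2_len, max_h2))
  }
  n <- h1_len + h2_len + h3_len
  atoms <- aform_duplex_atoms(n, geom, vbond, groove_phase = 2.1468)
  p_at <- function(strand, level) {
    row <- atoms[atoms$strand == strand & atoms$level == level &
                   atoms$atom == "P", ]
    c(row$x[1], row$y[1], row$z[1])
  }
  anchors <- rbind(
    a_i = p_at(1, h1_len - 1),
    a_i_p = p_at(2, h1_len - 1),
    a_j = p_at(2, h1_len + h2_len - 1),
    a_j_p = p_at(1, h1_len + h2_len - 1),
    b_i = p_at(2, h1_len + h2_len),
    b_i_p = p_at(1, h1_len + h2_len),
    b_j = p_at(1, h1_len),
    b_j_p = p_at(2, h1_len))
  colnames(anchors) <- c("x", "y", "z")
  structure(list(anchors = anchors,
                 helix_atoms = as.matrix(atoms[, c("x", "y", "z")]),
                 h2_len = h2_len, h1_len = h1_len, h3_len = h3_len,
                 geom = geom, vbond = vbond),
            class = "anchor_frame")
}

#' Linear coil-entropy model
#'
#' `ln(omega_coil) = slope * l + intercept` for a free chain of `l` nt, the
#' polymer-theory reference against which loop entropies are measured.
#'
#' @param l Chain length in nucleotides.
#' @param slope,intercept Model constants (defaults 2.05 and 0.1 per nt).
#' @return `ln(omega_coil)` in `k_B`, vectorised over `l`.
#' @examples
#' coil_ln_omega(2)
#' @export
coil_ln_omega <- function(l, slope = 2.05, intercept = 0.1) {
  stopifnot(all(l >= 0))
  slope * l + intercept
}

#' Conformational entropy of loop-loop kissing
#'
#' The three-step computation of the entropic cost of forming a
#' hairpin-hairpin kissing interface S(H2, l1, l3):
#' (1) the relative orientation of the flanking stems H1 and H3 is fixed by
#' the length of the kissing stem H2 through ideal coaxial stacking, giving
#' the loop anchor coordinates ([generate_anchor_frame()]);
#' (2) each bridging loop is modelled as self-avoiding virtual-bond walks
#' on the diamond lattice between its snapped anchors;
#' (3) excluded volume is enforced by disallowing walks through any helix
#' pseudo-atom site. A loop of `l` nt anchored between two helix phosphates
#' is a walk of `2 * (l + 1)` virtual-bond steps (two bonds per nucleotide
#' plus the two bonds joining the anchor phosphates).
#'
#' The loop count is the product of the two independent anchored counts,
#' and the entropy change is measured against the linear coil model:
#' `dS = ln(count_l1 * count_l3) - (ln omega_coil(l1) + ln omega_coil(l3))`
#' in `k_B`. Zero feasible conformations is reported as status
#' `"infeasible"` with `delta_S = -Inf`, distinct from any numeric value.
#'
#' @param topology A [kissing_topology()].
#' @param bond_length Lattice virtual-bond length in Angstrom.
#' @param cap Enumeration cap (nt) passed to the lattice engine.
#' @param coil_slope,coil_intercept Coil model constants.
#' @param geom A [helix_geometry()].
#' @return A one-row tibble: `h2_len`, `l1_len`, `l3_len`, `count_l1`,
#'   `count_l3`, `ln_omega_loop`, `ln_omega_coil`, `delta_S` (k_B),
#'   `status` (`"ok"` or `"infeasible"`).
#' @export
kissing_entropy <- function(topology, bond_length = 3.9, cap = 12L,
                            coil_slope = 2.05, coil_intercept = 0.1,
                            geom = helix_geometry()) {
  stopifnot(inherits(topology, "kissing_topology"))
  if (topology$l1_len + 1 > cap || topology$l3_len + 1 > cap) {
    abort("loop lengths exceed the lattice enumeration cap")
  }
  frame <- generate_anchor_frame(topology$h2_len, topology$h1_len,
                                 topology$h3_len, geom = geom,
                                 vbond = bond_length)
  counts <- vapply(list(c("a_i", "a_j"), c("b_i", "b_j")), function(nm) {
    anchored_count_between(frame, nm[1], nm[2],
                           n_nt_between = topology[[
                             if (nm[1] == "a_i") "l1_len" else "l3_len"]],
                           bond_length = bond_length)
  }, numeric(1))
  ln_loop <- if (all(counts > 0)) sum(log(counts)) else -Inf
  ln_coil <- coil_ln_omega(topology$l1_len, coil_slope, coil_intercept) +
    coil_ln_omega(topology$l3_len, coil_slope, coil_intercept)
  tibble(
    h2_len = topology$h2_len, l1_len = topology$l1_len,
    l3_len = topology$l3_len,
    count_l1 = counts[1], count_l3 = counts[2],
    ln_omega_loop = ln_loop, ln_omega_coil = ln_coil,
    delta_S = ln_loop - ln_coil,
    status = if (is.finite(ln_loop)) "ok" else "infeasible")
}

# Snap two anchor phosphates and the helix obstacle set to the lattice and
# count walks of 2 * (n_nt_between + 1) steps between them.
anchored_count_between <- function(frame, from, to, n_nt_between,
                                   bond_length) {
  start <- snap_to_lattice(frame$anchors[from, ], bond_length)
  sub <- lattice_sublattice(start)  # even step count: same sublattice
  end <- snap_to_lattice(frame$anchors[to, ], bond_length,
                         sublattice = sub)
  obst <- unique(t(apply(frame$helix_atoms, 1, snap_to_lattice,
                         bond_length = bond_length)))
  keys <- site_key(obst)
  drop <- keys %in% c(site_key(rbind(start)), site_key(rbind(end)))
  obst <- obst[!drop, , drop = FALSE]
  saw_anchored_count(start, end, 2L * (as.integer(n_nt_between) + 1L),
                     normalize_obstacles(obst))
}

#' Load an entropy table
#'
#' Reads a kissing-entropy table (columns `h2_len`, `l1_len`, `l3_len`,
#' `ln_omega`, optional `note`) from TSV. Missing cells (infeasible
#' combinations printed as dashes in the source) are explicit `NA`s, never
#' silently interpolated. The default file is the transcription of the
#' published Vfold-derived table shipped with the package.
#'
#' @param path TSV path; `NULL` for the shipped table.
#' @return A tibble of class `entropy_table`.
#' @export
load_entropy_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "entropy_table_vfold.tsv",
                        package = "kisfold")
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  stopifnot(all(c("h2_len", "l1_len", "l3_len", "ln_omega") %in% names(tab)))
  if (is.null(tab$note)) tab$note <- ""
  tab$note[is.na(tab$note)] <- ""
  tab <- as_tibble(tab)
  class(tab) <- c("entropy_table", class(tab))
  tab
}

#' Write an entropy table to TSV
#'
#' Inverse of [load_entropy_table()]; missing cells are written as empty
#' fields so that a load/write cycle is the identity.
#'
#' @param table An `entropy_table` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_entropy_table <- function(table, path) {
  df <- as.data.frame(table[, c("h2_len", "l1_len", "l3_len", "ln_omega",
                                "note")])
  suppressWarnings(utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = ""))
  invisible(path)
}

#' Look up a kissing-entropy cell
#'
#' Exact cell access with explicit missing-value semantics: a cell printed
#' as infeasible returns `NA` (with `missing = TRUE` in the result), an
#' out-of-range index is an error naming the offending axis. No
#' interpolation or extrapolation is ever performed.
#'
#' @param table An `entropy_table`.
#' @param h2_len,l1_len,l3_len Cell indices.
#' @return One-row tibble with `ln_omega` and `missing`.
#' @examples
#' table_lookup(load_entropy_table(), 6, 2, 2)
#' @export
table_lookup <- function(table, h2_len, l1_len, l3_len) {
  stopifnot(inherits(table, "entropy_table"))
  for (ax in c("h2_len", "l1_len", "l3_len")) {
    val <- get(ax)
    if (!val %in% table[[ax]]) {
      abort(sprintf("%s = %s is outside the table range [%d, %d]",
                    ax, format(val), min(table[[ax]]), max(table[[ax]])))
    }
  }
  row <- table[table$h2_len == h2_len & table$l1_len == l1_len &
                 table$l3_len == l3_len, ]
  if (nrow(row) == 0) {
    abort(sprintf(
      "no cell at (h2_len = %d, l1_len = %d, l3_len = %d): l1_len outside the block tabulated for this stem length",
      h2_len, l1_len, l3_len))
  }
  tibble(ln_omega = row$ln_omega[1], missing = is.na(row$ln_omega[1]))
}

#' Kissing entropy penalty from a table cell
#'
#' `-T dS` in `k_B T` units for a (H2, l1, l3) topology using a tabulated
#' `ln omega` and the linear coil model:
#' `-T dS / k_B T = ln omega_coil(l1) + ln omega_coil(l3) - ln omega`.
#'
#' @inheritParams table_lookup
#' @param coil_slope,coil_intercept Coil model constants.
#' @return Penalty in `k_B T` (positive = destabilising), or `NA` for a
#'   missing cell.
#' @examples
#' table_entropy_penalty(load_entropy_table(), 6, 2, 2)  # 8.4 k_B
#' @export
table_entropy_penalty <- function(table, h2_len, l1_len, l3_len,
                                  coil_slope = 2.05, coil_intercept = 0.1) {
  cell <- table_lookup(table, h2_len, l1_len, l3_len)
  if (cell$missing) return(NA_real_)
  coil_ln_omega(l1_len, coil_slope, coil_intercept) +
    coil_ln_omega(l3_len, coil_slope, coil_intercept) - cell$ln_omega
}

#' Effective loop lengths with stem-loop substructures
#'
#' A stem-loop substructure embedded in a kissing-complex loop is
#' approximated by replacing its terminal base pair by a single nucleotide:
#' each loop's effective length is the number of unpaired nucleotides plus
#' the number of stem-loop substructures it carries.
#'
#' @param topology A [kissing_topology()] whose loop lengths count unpaired
#'   nucleotides only.
#' @param substructures Named integer vector giving the number of stem-loop
#'   substructures in each loop, e.g. `c(l1 = 1)`; loops not named carry
#'   none.
#' @return A new [kissing_topology()] with effective loop lengths.
#' @examples
#' effective_loop_lengths(kissing_topology(6, 3, 2), c(l1 = 1))
#' @export
effective_loop_lengths <- function(topology, substructures = integer()) {
  stopifnot(inherits(topology, "kissing_topology"))
  extra <- function(nm) {
    if (nm %in% names(substructures)) as.integer(substructures[[nm]]) else 0L
  }
  kissing_topology(
    h2_len = topology$h2_len,
    l1_len = topology$l1_len + extra("l1"),
    l3_len = topology$l3_len + extra("l3"),
    l2_len = topology$l2_len + extra("l2"),
    l4_len = topology$l4_len + extra("l4"),
    h1_len = topology$h1_len, h3_len = topology$h3_len)
}
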