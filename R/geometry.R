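#' A-form helix geometry at virtual-bond resolution
#'
#' Bundles the parameters of an ideal A-form RNA helix used by the scaffold
#' builder and the closed-form end-to-end distance: the rise per base pair
#' `h`, the helical radius `r` of the backbone phosphate wheel, and the
#' number of base pairs per turn. The period is fixed at 11 bp/turn, the
#' canonical A-form value that sets the phase 2*pi*s/11 of the end-to-end
#' formula; changing it would change the model, so it is not an argument.
#'
#' @param rise Rise per base pair in Angstrom (default 2.7).
#' @param radius Helical radius of the P wheel in Angstrom (default 9.9).
#' @return An object of class `helix_geometry`.
#' @examples
#' helix_geometry()
#' @export
helix_geometry <- function(rise = 2.7, radius = 9.9) {
  stopifnot(is.numeric(rise), length(rise) == 1, is.finite(rise),
            is.numeric(radius), length(radius) == 1, is.finite(radius))
  if (rise <= 0) abort("`rise` must be positive (Angstrom per base pair).")
  if (radius <= 0) abort("`radius` must be positive (Angstrom).")
  structure(list(rise = rise, radius = radius, bp_per_turn = 11L),
            class = "helix_geometry")
}

#' @export
print.helix_geometry <- function(x, ...) {
  cat(sprintf(
    "<helix_geometry> A-form: rise %.3g A/bp, radius %.3g A, %d bp/turn\n",
    x$rise, x$radius, x$bp_per_turn))
  invisible(x)
}

#' End-to-end distance of an A-form helix strand
#'
#' Closed-form distance between the terminal backbone phosphates of one
#' strand of an A-form helix spanning `s` base-pair steps (s + 1 base
#' pairs). A strand point at step s sits at angle 2*pi*s/11 on a wheel of
#' radius r at height h*s, so the end-to-end distance is
#'
#'   z(s) = sqrt((h s)^2 + r^2 (1 - cos(2 pi s/11))^2 + r^2 sin^2(2 pi s/11))
#'        = sqrt((h s)^2 + 4 r^2 sin^2(pi s/11)),
#'
#' the chord identity (1 - cos t)^2 + sin^2 t = 4 sin^2(t/2) collapsing the
#' three-term form to two terms. Both forms are implemented and agree to
#' machine precision; `form` exists so tests can assert the identity.
#'
#' @param s Number of base-pair steps spanned (>= 0, real-valued allowed).
#' @param geom A [helix_geometry()].
#' @param form `"reduced"` (two-term) or `"expanded"` (three-term); they are
#'   algebraically identical.
#' @return Distance(s) in Angstrom, vectorised over `s`.
#' @examples
#' helix_end_to_end(11)   # one full turn: chord vanishes, z = 11 * 2.7
#' @export
helix_end_to_end <- function(s, geom = helix_geometry(),
                             form = c("reduced", "expanded")) {
  form <- match.arg(form)
  stopifnot(is.numeric(s), inherits(geom, "helix_geometry"))
  if (any(!is.finite(s)) || any(s < 0)) {
    abort("`s` must be finite and >= 0 (base-pair steps).")
  }
  h <- geom$rise
  r <- geom$radius
  t <- 2 * pi * s / geom$bp_per_turn
  if (form == "reduced") {
    sqrt((h * s)^2 + 4 * r^2 * sin(t / 2)^2)
  } else {
    sqrt((h * s)^2 + r^2 * (1 - cos(t))^2 + r^2 * sin(t)^2)
  }
}

# Radius of the C4' wheel that makes both virtual bonds (P-C4' and C4'-P)
# have exactly length `vbond`, given that C4' sits half a step (omega/2,
# h/2) beyond P. Root of r_c^2 - 2 r cos(omega/2) r_c + (r^2 + h^2/4 -
# vbond^2) = 0; the inner root is taken.
c4_radius <- function(geom, vbond) {
  half <- pi / geom$bp_per_turn
  disc <- (geom$radius * cos(half))^2 -
    (geom$radius^2 + geom$rise^2 / 4 - vbond^2)
  if (disc < 0) {
    abort(sprintf(
      "virtual bond length %.3g A is too short for this helix geometry", vbond))
  }
  geom$radius * cos(half) - sqrt(disc)
}

new_scaffold <- function(df) {
  df <- as_tibble(df)
  class(df) <- c("kf_scaffold", class(df))
  df
}

empty_scaffold <- function() {
  new_scaffold(tibble(
    chain = character(), residue = integer(), atom = character(),
    x = double(), y = double(), z = double(), source = character()))
}

apply_frame <- function(df, frame) {
  if (is.null(frame)) return(df)
  stopifnot(is.list(frame), !is.null(frame$rotation), !is.null(frame$origin))
  R <- frame$rotation
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
  df$x <- xyz[, 1] + frame$origin[1]
  df$y <- xyz[, 2] + frame$origin[2]
  df$z <- xyz[, 3] + frame$origin[3]
  df
}

# Internal duplex generator on the local frame (+z axis). Returns one row
# per pseudo-atom. Strand 1 ascends bp levels 0..n-1 (5'->3'); strand 2 is
# the antiparallel partner winding with the same handedness at a fixed
# groove phase, its residue k pairing with strand-1 residue n-1-k.
# `level_offset` shifts the bp levels (used to stack blocks coaxially).
aform_duplex_atoms <- function(n_bp, geom, vbond, groove_phase,
                               level_offset = 0) {
  om <- 2 * pi / geom$bp_per_turn
  h <- geom$rise
  rP <- geom$radius
  rC <- c4_radius(geom, vbond)
  j <- seq_len(n_bp) - 1 + level_offset
  s1 <- tibble(
    strand = 1L, residue = seq_len(n_bp), level = j,
    pa = om * j, pz = h * j,
    ca = om * j + om / 2, cz = h * j + h / 2)
  k <- seq_len(n_bp) - 1
  jl <- rev(j)  # strand-2 residue k sits at bp level n-1-k (+offset)
  s2 <- tibble(
    strand = 2L, residue = seq_len(n_bp), level = jl,
    pa = om * jl + groove_phase, pz = h * jl,
    ca = om * jl + groove_phase - om / 2, cz = h * jl - h / 2)
  both <- dplyr::bind_rows(s1, s2)
  p <- both |>
    dplyr::transmute(.data$strand, .data$residue, .data$level, atom = "P",
                     x = rP * cos(.data$pa), y = rP * sin(.data$pa),
                     z = .data$pz)
  c4 <- both |>
    dplyr::transmute(.data$strand, .data$residue, .data$level, atom = "C4'",
                     x = rC * cos(.data$ca), y = rC * sin(.data$ca),
                     z = .data$cz)
  dplyr::bind_rows(p, c4) |>
    dplyr::arrange(.data$strand, .data$residue,
                   dplyr::desc(.data$atom == "P"))
}

#' Build a coarse-grained A-form helix
#'
#' Generates the two antiparallel strands of an ideal A-form duplex as P and
#' C4' pseudo-atoms (two per nucleotide) on helical wheels of the given
#' geometry. The C4' wheel radius is solved so that both virtual bonds,
#' P-C4' and C4'-P, have exactly length `vbond`. The distance between the
#' terminal P atoms of a strand over s steps equals [helix_end_to_end()].
#'
#' @param n_bp Number of base pairs (>= 1).
#' @param geom A [helix_geometry()].
#' @param frame Optional rigid transform, `list(rotation = 3x3 matrix,
#'   origin = length-3 vector)`, applied to the local frame (helix axis =
#'   +z, right-handed, Angstrom).
#' @param chains Two chain identifiers, default `c("A", "B")`.
#' @param vbond Virtual-bond length in Angstrom (default 3.9).
#' @param groove_phase Angular offset (radians) between paired phosphates
#'   across the duplex; default 2.147 rad puts the cross-strand P-P distance
#'   near the A-form value of ~17.4 A.
#' @return A `kf_scaffold` tibble with columns chain, residue, atom, x, y,
#'   z, source. Residues are numbered 1-based 5'->3' within each chain.
#' @examples
#' h <- build_aform_helix(12)
#' dim(h)  # 12 bp x 2 strands x 2 pseudo-atoms
#' @export
build_aform_helix <- function(n_bp, geom = helix_geometry(), frame = NULL,
                              chains = c("A", "B"), vbond = 3.9,
                              groove_phase = 2.1468) {
  stopifnot(is.numeric(n_bp), length(n_bp) == 1)
  if (n_bp < 1 || n_bp != round(n_bp)) {
    abort("`n_bp` must be an integer >= 1.")
  }
  n_bp <- as.integer(n_bp)
  atoms <- aform_duplex_atoms(n_bp, geom, vbond, groove_phase)
  df <- tibble(
    chain = chains[atoms$strand],
    residue = atoms$residue,
    atom = atoms$atom,
    x = atoms$x, y = atoms$y, z = atoms$z,
    source = "helix")
  new_scaffold(apply_frame(df, frame))
}

scaffold_check_bonds <- function(scaffold, vbond = 3.9, tol = 1e-6) {
  ok <- TRUE
  for (ch in unique(scaffold$chain)) {
    sub <- scaffold[scaffold$chain == ch & scaffold$source == "helix", ]
    if (nrow(sub) < 2) next
    d <- sqrt(diff(sub$x)^2 + diff(sub$y)^2 + diff(sub$z)^2)
    ok <- ok && all(abs(d - vbond) < tol)
  }
  ok
}

# Minimum distance between pseudo-atoms more than `skip` positions apart in
# the backbone (non-bonded), across all chains.
scaffold_min_nonbonded <- function(scaffold, skip = 1) {
  xyz <- as.matrix(scaffold[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 2) return(Inf)
  d <- as.matrix(stats::dist(xyz))
  same_chain <- outer(scaffold$chain, scaffold$chain, "==")
  pos <- stats::ave(seq_len(n), scaffold$chain, FUN = seq_along)
  near <- same_chain & abs(outer(pos, pos, "-")) <= skip
  d[near] <- Inf
  diag(d) <- Inf
  min(d)
}
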