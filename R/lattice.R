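#' @name diamond-lattice
#' @title The diamond lattice used for virtual-bond enumeration
#'
#' @description
#' Loop conformations are modelled as self-avoiding walks of virtual bonds
#' on the diamond (tetrahedral) lattice, whose 109.5-degree bond angles
#' approximate nucleic-acid virtual-bond geometry. Sites are encoded as
#' integer triples: the A sublattice has all-even coordinates with
#' x + y + z = 0 (mod 4), the B sublattice all-odd coordinates with
#' x + y + z = 3 (mod 4). From an A site the four neighbour displacements
#' are (1,1,1), (1,-1,-1), (-1,1,-1), (-1,-1,1); from a B site their
#' negatives. One lattice bond has length sqrt(3) in these units and maps
#' to one physical virtual bond of `bond_length` Angstrom.
NULL

# Neighbour displacement matrix for the A sublattice (rows sorted so that
# enumeration order is deterministic).
.lattice_steps <- matrix(c(
  -1, -1,  1,
  -1,  1, -1,
   1, -1, -1,
   1,  1,  1), ncol = 3, byrow = TRUE)

#' Test and classify diamond-lattice sites
#'
#' @param site Integer length-3 vector, or a matrix with one site per row.
#' @return `is_lattice_site()` returns logical; `lattice_sublattice()`
#'   returns `"A"`, `"B"` or `NA` for off-lattice points.
#' @examples
#' is_lattice_site(c(0, 0, 0))
#' lattice_sublattice(c(1, 1, 1))
#' @export
is_lattice_site <- function(site) {
  m <- rbind(site)
  all_even <- rowSums(m %% 2) == 0
  all_odd <- rowSums(m %% 2) == 3
  s4 <- ((rowSums(m) %% 4) + 4) %% 4
  (all_even & s4 == 0) | (all_odd & s4 == 3)
}

#' @rdname is_lattice_site
#' @export
lattice_sublattice <- function(site) {
  m <- rbind(site)
  out <- rep(NA_character_, nrow(m))
  ok <- is_lattice_site(m)
  even <- rowSums(m %% 2) == 0
  out[ok & even] <- "A"
  out[ok & !even] <- "B"
  if (is.null(dim(site))) out[1] else out
}

#' Neighbours of a diamond-lattice site
#'
#' @param site Integer length-3 lattice site.
#' @return 4 x 3 integer matrix of neighbour sites, in deterministic
#'   (lexicographic) order.
#' @examples
#' lattice_neighbors(c(0, 0, 0))
#' @export
lattice_neighbors <- function(site) {
  sub <- lattice_sublattice(site)
  if (is.na(sub)) abort("`site` is not a diamond-lattice site.")
  sgn <- if (sub == "A") 1L else -1L
  nb <- sweep(sgn * .lattice_steps, 2, as.integer(site), "+")
  nb[order(nb[, 1], nb[, 2], nb[, 3]), , drop = FALSE]
}

#' Count free-coil conformations on the diamond lattice
#'
#' Exhaustively counts self-avoiding walks of `2 * n_nt` virtual-bond steps
#' from a fixed origin -- the free-coil reference for loop entropies, two
#' virtual bonds (P-C4' and C4'-P) per nucleotide. The count is exact: the
#' depth-first search fixes the first bond (factor 4, the lattice
#' coordination number) and, for walks of two or more steps, the second
#' bond (factor 3, the three-fold symmetry about a lattice bond), and the
#' recorded `symmetry_factor` restores the absolute count.
#'
#' @param n_nt Chain length in nucleotides (1 to `cap`).
#' @param cap Enumeration cap in nucleotides (default 12). Longer chains
#'   must use tabulated values; the cap is enforced, never silently
#'   truncated.
#' @return A tibble with columns `n_nt`, `n_steps`, `count`, `ln_omega`,
#'   `symmetry_factor`, one row per chain length `1..n_nt`.
#' @examples
#' enumerate_free_coil(4)
#' @export
enumerate_free_coil <- function(n_nt, cap = 12L) {
  stopifnot(is.numeric(n_nt), length(n_nt) == 1, n_nt == round(n_nt))
  if (n_nt < 1) abort("`n_nt` must be >= 1.")
  if (n_nt > cap) {
    abort(sprintf(
      "chain of %d nt exceeds the exhaustive-enumeration cap of %d nt; use the entropy-table interface for longer loops",
      n_nt, cap))
  }
  counts <- saw_coil_counts(2L * as.integer(n_nt))
  steps <- seq_along(counts)
  keep <- steps %% 2 == 0
  tibble(
    n_nt = steps[keep] / 2,
    n_steps = steps[keep],
    count = counts[keep],
    ln_omega = log(counts[keep]),
    symmetry_factor = ifelse(steps[keep] >= 2, 12, 4))
}

#' Count walks of a given number of steps from the origin
#'
#' Lower-level access to the free-coil counter in steps rather than
#' nucleotides; exposes the degenerate 1-step case (4 walks, the lattice
#' coordination number).
#'
#' @param n_steps Number of virtual-bond steps (>= 1).
#' @return Exact count of self-avoiding walks of `n_steps` steps.
#' @examples
#' count_free_walks(1)  # 4
#' count_free_walks(2)  # 12: no immediate reversal is self-avoiding
#' @export
count_free_walks <- function(n_steps) {
  stopifnot(is.numeric(n_steps), length(n_steps) == 1, n_steps >= 1)
  saw_coil_counts(as.integer(n_steps))[as.integer(n_steps)]
}

#' Count anchored loop conformations with obstacles
#'
#' Exact number of self-avoiding walks of exactly `2 * n_nt` virtual-bond
#' steps from `anchor_start` to `anchor_end` on the diamond lattice,
#' avoiding the `obstacles` sites (hard-sphere excluded volume at site
#' resolution). Anchored counts are absolute: no symmetry reduction is
#' applied. A count of zero is a legal result (infeasible loop);
#' parity-incompatible anchors give zero with a diagnostic message rather
#' than an error.
#'
#' @param anchor_start,anchor_end Integer length-3 lattice sites.
#' @param n_nt Loop length in nucleotides; the walk has `2 * n_nt` steps.
#'   `n_steps` may be given instead for step-resolution control.
#' @param obstacles Integer matrix of excluded sites (one per row), or
#'   `NULL`.
#' @param n_steps Optional explicit step count overriding `2 * n_nt`.
#' @param cap Enumeration cap in nucleotides (default 12).
#' @return A one-row tibble with `n_conformations` and `ln_omega`
#'   (`-Inf` when the count is 0).
#' @examples
#' enumerate_anchored_loop(c(0, 0, 0), c(0, 0, 0), n_nt = 1)  # 0: cannot return
#' @export
enumerate_anchored_loop <- function(anchor_start, anchor_end, n_nt = NULL,
                                    obstacles = NULL, n_steps = NULL,
                                    cap = 12L) {
  if (is.null(n_steps)) {
    stopifnot(!is.null(n_nt))
    if (n_nt > cap) {
      abort(sprintf(
        "loop of %g nt exceeds the exhaustive-enumeration cap of %d nt",
        n_nt, cap))
    }
    n_steps <- 2L * as.integer(n_nt)
  }
  if (n_steps > 2L * cap + 2L) {
    abort(sprintf("%d steps exceeds the enumeration cap", n_steps))
  }
  for (a in list(anchor_start, anchor_end)) {
    if (!is_lattice_site(a)) abort("anchors must be diamond-lattice sites.")
  }
  obstacles <- normalize_obstacles(obstacles)
  same <- lattice_sublattice(anchor_start) == lattice_sublattice(anchor_end)
  if ((n_steps %% 2 == 0) != same) {
    rlang::inform(
      "anchors on incompatible sublattices for this walk length; count is 0")
    return(tibble(n_conformations = 0, ln_omega = -Inf))
  }
  cnt <- saw_anchored_count(as.integer(anchor_start), as.integer(anchor_end),
                            as.integer(n_steps), obstacles)
  tibble(n_conformations = cnt,
         ln_omega = if (cnt > 0) log(cnt) else -Inf)
}

normalize_obstacles <- function(obstacles) {
  if (is.null(obstacles) || (is.matrix(obstacles) && nrow(obstacles) == 0)) {
    return(matrix(integer(), ncol = 3))
  }
  m <- rbind(obstacles)
  storage.mode(m) <- "integer"
  stopifnot(ncol(m) == 3)
  m
}

#' Enumerate anchored walks explicitly (breadth-first)
#'
#' Returns the actual self-avoiding walks, not just their count, by
#' level-wise expansion. Used to realise loop conformations for scaffold
#' assembly and as an independent cross-check of the depth-first counter.
#' Exponential in `n_steps`; intended for short loops only.
#'
#' @inheritParams enumerate_anchored_loop
#' @param n_steps Number of steps.
#' @param max_walks Abort if the number of partial walks exceeds this bound.
#' @return List of integer matrices, each `(n_steps + 1) x 3`, rows = sites
#'   visited in order; deterministic (lexicographic) order.
#' @export
enumerate_anchored_walks <- function(anchor_start, anchor_end, n_steps,
                                     obstacles = NULL, max_walks = 2e6) {
  stopifnot(is_lattice_site(anchor_start))
  obstacles <- normalize_obstacles(obstacles)
  okey <- site_key(obstacles)
  # paths: list of matrices grown level by level
  paths <- list(matrix(as.integer(anchor_start), ncol = 3))
  for (step in seq_len(n_steps)) {
    nxt <- list()
    for (p in paths) {
      cur <- p[nrow(p), ]
      nb <- lattice_neighbors(cur)
      pk <- site_key(p)
      for (i in seq_len(nrow(nb))) {
        k <- site_key(nb[i, , drop = FALSE])
        if (k %in% pk || k %in% okey) next
        # reachability pruning against the end anchor
        rem <- n_steps - step
        if (max(abs(nb[i, ] - anchor_end)) > rem) next
        nxt[[length(nxt) + 1]] <- rbind(p, nb[i, ])
      }
    }
    if (length(nxt) > max_walks) abort("too many walks; reduce n_steps")
    paths <- nxt
    if (length(paths) == 0) break
  }
  keep <- vapply(paths, function(p) all(p[nrow(p), ] == anchor_end), TRUE)
  paths[keep]
}

site_key <- function(m) {
  m <- rbind(m)
  if (nrow(m) == 0) return(character())
  paste(m[, 1], m[, 2], m[, 3], sep = ",")
}

#' Snap a 3D point to the nearest diamond-lattice site
#'
#' Maps a physical coordinate (Angstrom) to the nearest lattice site under
#' the scaling in which one lattice bond (length sqrt(3) in site units)
#' equals `bond_length` Angstrom. Ties are broken deterministically toward
#' the lexicographically smallest site. Optionally restricts to one
#' sublattice so that walk parity constraints can be honoured.
#'
#' @param point Numeric length-3 coordinate in Angstrom.
#' @param bond_length Physical virtual-bond length in Angstrom (default 3.9).
#' @param sublattice `"any"`, `"A"` or `"B"`.
#' @return Integer length-3 lattice site.
#' @examples
#' snap_to_lattice(c(0, 0, 0))
#' @export
snap_to_lattice <- function(point, bond_length = 3.9,
                            sublattice = c("any", "A", "B")) {
  sublattice <- match.arg(sublattice)
  stopifnot(is.numeric(point), length(point) == 3, all(is.finite(point)))
  scale <- bond_length / sqrt(3)  # Angstrom per site unit
  p <- point / scale
  ctr <- round(p)
  # search a local box; sublattice sites have spacing 2 in these units so a
  # +-3 box always contains the optimum of either sublattice
  rng <- -3:3
  cand <- as.matrix(expand.grid(x = ctr[1] + rng, y = ctr[2] + rng,
                                z = ctr[3] + rng))
  ok <- is_lattice_site(cand)
  if (sublattice != "any") {
    ok <- ok & (lattice_sublattice(cand) %in% sublattice)
  }
  cand <- cand[ok, , drop = FALSE]
  d2 <- (cand[, 1] - p[1])^2 + (cand[, 2] - p[2])^2 + (cand[, 3] - p[3])^2
  best <- which(d2 < min(d2) + 1e-9)
  cand <- cand[best, , drop = FALSE]
  o <- order(cand[, 1], cand[, 2], cand[, 3])
  as.integer(cand[o[1], ])
}

#' Convert lattice sites to physical coordinates
#'
#' @param sites Integer matrix of lattice sites (one per row).
#' @param bond_length Virtual-bond length in Angstrom.
#' @return Numeric matrix of coordinates in Angstrom.
#' @export
lattice_to_cartesian <- function(sites, bond_length = 3.9) {
  rbind(sites) * (bond_length / sqrt(3))
}

#' Fit the coil-entropy slope from exhaustive enumeration
#'
#' Least-squares fit of ln(count) versus chain length in nucleotides for
#' free coils, over an exhaustively enumerable window. The slope is the
#' per-nucleotide coil entropy (in k_B) and should approximate the linear
#' coil model ln(omega_coil) = 2.05 l + 0.1.
#'
#' @param n_range Integer vector of chain lengths (default 4:12).
#' @param cap Enumeration cap passed through.
#' @return A one-row tibble: `slope`, `intercept`, `n_min`, `n_max`.
#' @export
coil_slope <- function(n_range = 4:12, cap = 12L) {
  tab <- enumerate_free_coil(max(n_range), cap = cap)
  tab <- tab[tab$n_nt %in% n_range, ]
  fit <- lm(ln_omega ~ n_nt, data = tab)
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n_min = min(n_range), n_max = max(n_range))
}
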