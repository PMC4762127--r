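#' Ensemble parameters for a two-strand system
#'
#' @param temperature Temperature in K (default 310.15).
#' @param ct Total strand concentration in mol/L (default 1e-6). Each
#'   strand is present at `ct / 2`; the association entropy uses the
#'   printed `ct / 4` convention.
#' @param dg_init Association initiation free energy in kcal/mol
#'   (default 4.1, the experimental value).
#' @return An object of class `ensemble_params`.
#' @export
ensemble_params <- function(temperature = 310.15, ct = 1e-6,
                            dg_init = 4.1) {
  stopifnot(temperature > 0, ct > 0, is.finite(dg_init))
  structure(list(temperature = temperature, ct = ct, dg_init = dg_init),
            class = "ensemble_params")
}

#' Concentration-dependent association free energy
#'
#' `dG_associate = dG_init - k_B T ln(C_T / 4)`: the free-energy cost of
#' bringing two strands together at total strand concentration `C_T`. More
#' dilute solutions pay a larger penalty.
#'
#' @param params An [ensemble_params()], or `NULL` to pass `ct`,
#'   `temperature`, `dg_init` directly.
#' @param ct,temperature,dg_init Used when `params` is `NULL`.
#' @return Free energy in kcal/mol.
#' @examples
#' associate_free_energy(ct = 4)     # = dg_init exactly
#' associate_free_energy(ct = 4e-6)  # dilution penalty of ~8.5 kcal/mol
#' @export
associate_free_energy <- function(params = NULL, ct = 1e-6,
                                  temperature = 310.15, dg_init = 4.1) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "ensemble_params"))
    ct <- params$ct
    temperature <- params$temperature
    dg_init <- params$dg_init
  }
  stopifnot(all(ct > 0))
  dg_init - .kB * temperature * log(ct / 4)
}

# ---------------------------------------------------------------------------
# loop entropies for ensemble scoring, cached by (kind, length)

.loop_cache <- new.env(parent = emptyenv())

# Conformational entropy change (k_B, <= 0) of closing a loop of `l`
# unpaired nt, from exhaustive anchored lattice enumeration relative to
# the linear coil model. Two anchor geometries: "hairpin" (anchors across
# the duplex end, ~17.4 A apart, duplex atoms as obstacles) and
# "internal" (anchors one helix step apart). Beyond `cap_l` nt the
# enumerated value is extended with the standard logarithmic tail
# dS(l) = dS(cap) - 1.75 ln(l / cap).
loop_entropy_ds <- function(l, kind = c("hairpin", "internal"),
                            bond_length = 3.9, cap_l = 8L) {
  kind <- match.arg(kind)
  if (l <= 0) return(0)
  key <- sprintf("%s_%d_%g", kind, min(l, cap_l), bond_length)
  if (is.null(.loop_cache[[key]])) {
    .loop_cache[[key]] <- compute_loop_ds(min(l, cap_l), kind, bond_length)
  }
  ds <- .loop_cache[[key]]
  if (l > cap_l && is.finite(ds)) ds <- ds - 1.75 * log(l / cap_l)
  ds
}

compute_loop_ds <- function(l, kind, bond_length) {
  geom <- helix_geometry()
  if (kind == "hairpin") {
    atoms <- aform_duplex_atoms(2, geom, bond_length, groove_phase = 2.1468)
    a1 <- unlist(atoms[atoms$strand == 1 & atoms$level == 1 &
                         atoms$atom == "P", c("x", "y", "z")])
    a2 <- unlist(atoms[atoms$strand == 2 & atoms$level == 1 &
                         atoms$atom == "P", c("x", "y", "z")])
    start <- snap_to_lattice(a1, bond_length)
    end <- snap_to_lattice(a2, bond_length,
                           sublattice = lattice_sublattice(start))
    obst <- unique(t(apply(as.matrix(atoms[, c("x", "y", "z")]), 1,
                           snap_to_lattice, bond_length = bond_length)))
    keys <- site_key(obst)
    obst <- obst[!keys %in% c(site_key(rbind(start)), site_key(rbind(end))),
                 , drop = FALSE]
  } else {
    start <- snap_to_lattice(c(0, 0, 0), bond_length)
    end <- snap_to_lattice(c(6.2, 0, 0), bond_length,
                           sublattice = lattice_sublattice(start))
    obst <- matrix(integer(), ncol = 3)
  }
  cnt <- saw_anchored_count(start, end, 2L * (as.integer(l) + 1L),
                            normalize_obstacles(obst))
  if (cnt == 0) return(-Inf)
  log(cnt) - coil_ln_omega(l)
}

# ---------------------------------------------------------------------------
# exhaustive structure enumeration

#' Exhaustively enumerate secondary structures of one or two strands
#'
#' Enumerates every secondary structure (intra- and intermolecular pairs,
#' one kissing interaction allowed) satisfying the constraints, and scores
#' each with the nearest-neighbour stack parameters plus lattice-derived
#' loop entropies. Pairs must form helices of at least `min_helix` stacked
#' pairs (default 3: shorter frayed registers are below the stability
#' threshold and only blur the landscape at toy scale); hairpin loops have
#' at least `min_hairpin` nt; pairs are
#' non-crossing except that at most `max_kissing` intermolecular helix may
#' cross intramolecular stems (a kissing interaction). Exhaustive
#' enumeration is capped at `cap` nt combined length.
#'
#' Scoring: helix stacking enthalpies/entropies from the NN table (no
#' per-helix initiation -- strand association is priced separately by
#' [associate_free_energy()]); hairpin, internal and multibranch loops pay
#' a conformational-entropy penalty from exhaustive anchored lattice
#' enumeration; a kissing interface with short outer loops (l2, l4 <= 1)
#' uses the kissing-entropy table when its cell is present, an infeasible
#' (dash) cell excludes the structure, and out-of-range topologies fall
#' back to the generic lattice loop penalties.
#'
#' @param seq1 First strand (5'->3').
#' @param seq2 Optional second strand; `NULL` for a single-strand system.
#' @param min_helix Minimum stacked pairs per helix (default 3).
#' @param min_hairpin Minimum hairpin loop length in nt (default 3).
#' @param max_kissing Maximum number of kissing helices (default 1).
#' @param cap Maximum combined length for exhaustive enumeration
#'   (default 30 nt).
#' @param nn Nearest-neighbour table from [nn_parameters()].
#' @param entropy_table Kissing-entropy table from [load_entropy_table()].
#' @return A `kf_ensemble`: tibble with one row per structure and columns
#'   `system` (`"strand1"`, `"strand2"`, `"dimer"`), `n_pairs`, `n_inter`,
#'   `kissing`, `dh` (kcal/mol), `ds` (kcal/mol/K), `dg37` (kcal/mol),
#'   and `pairs` (list of pair matrices in global numbering). Sequences
#'   and settings are kept as attributes. Single-strand systems include
#'   the open chain at energy zero; the dimer system contains only
#'   structures with at least one intermolecular pair.
#' @export
enumerate_structures <- function(seq1, seq2 = NULL, min_helix = 3L,
                                 min_hairpin = 3L, max_kissing = 1L,
                                 cap = 30L, nn = nn_parameters(),
                                 entropy_table = load_entropy_table()) {
  seq1 <- normalize_rna(seq1)
  if (!is.null(seq2)) seq2 <- normalize_rna(seq2)
  total <- nchar(seq1) + if (is.null(seq2)) 0L else nchar(seq2)
  if (total > cap) {
    abort(sprintf(
      "combined length %d nt exceeds the exhaustive enumeration cap (%d nt); reduce the input",
      total, cap))
  }
  opts <- list(min_helix = as.integer(min_helix),
               min_hairpin = as.integer(min_hairpin),
               max_kissing = as.integer(max_kissing),
               nn = nn, entropy_table = entropy_table)
  out <- list()
  out[[1]] <- enumerate_system(seq1, NULL, "strand1", opts)
  if (!is.null(seq2)) {
    out[[2]] <- enumerate_system(seq2, NULL, "strand2", opts)
    out[[3]] <- enumerate_system(seq1, seq2, "dimer", opts)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "seq1") <- seq1
  attr(res, "seq2") <- seq2
  attr(res, "opts") <- opts[c("min_helix", "min_hairpin", "max_kissing")]
  class(res) <- c("kf_ensemble", class(res))
  res
}

enumerate_system <- function(s1, s2, system, opts) {
  bases <- strsplit(paste0(s1, s2), "")[[1]]
  n1 <- nchar(s1)
  n <- length(bases)
  sets <- enumerate_pair_sets(bases, n1, opts)
  rows <- lapply(sets, function(pm) {
    n_inter <- if (nrow(pm)) sum(pm[, 1] <= n1 & pm[, 2] > n1) else 0L
    th <- structure_thermo(pm, bases, n1, opts)
    tibble(system = system, n_pairs = nrow(pm), n_inter = n_inter,
           kissing = th$kissing, dh = th$dh, ds = th$ds,
           dg37 = th$dh - 310.15 * th$ds, pairs = list(pm),
           feasible = th$feasible)
  })
  res <- dplyr::bind_rows(rows)
  res <- res[res$feasible, , drop = FALSE]
  res$feasible <- NULL
  if (system == "dimer") res <- res[res$n_inter >= 1, , drop = FALSE]
  res
}

# All pair sets: subsets of stackable-run selections, kept when crossing
# constraints hold. Returns a list of pair matrices (possibly empty).
enumerate_pair_sets <- function(bases, n1, opts) {
  n <- length(bases)
  cand <- candidate_pairs(bases, n1, opts$min_hairpin)
  runs <- maximal_runs(cand, n1)
  masks <- lapply(runs, function(r) run_masks(nrow(r), opts$min_helix))
  # visit runs with many selections first so conflicts prune early
  ord <- order(vapply(masks, length, 1L), decreasing = TRUE)
  runs <- runs[ord]
  masks <- masks[ord]
  acc <- list()
  occupied <- rep(FALSE, n)
  sel <- vector("list", length(runs))
  recurse <- function(k, acc_pm) {
    if (k > length(runs)) {
      if (kissing_count_ok(acc_pm, n1, opts$max_kissing)) {
        acc[[length(acc) + 1]] <<- acc_pm
      }
      return(invisible())
    }
    for (m in masks[[k]]) {
      if (length(m) == 0) {
        recurse(k + 1, acc_pm)
        next
      }
      pm <- runs[[k]][m, , drop = FALSE]
      pos <- c(pm)
      if (any(occupied[pos])) next
      if (!crossing_legal_increment(acc_pm, pm, n1)) next
      occupied[pos] <<- TRUE
      recurse(k + 1, rbind(acc_pm, pm))
      occupied[pos] <<- FALSE
    }
  }
  recurse(1, matrix(integer(), ncol = 2))
  acc
}

# Crossing legality between the accumulated pair set and a newly added
# run selection: intra pairs may not cross intra pairs, inter may not
# cross inter (pairs within one run never cross each other).
crossing_legal_increment <- function(acc_pm, pm, n1) {
  if (nrow(acc_pm) == 0) return(TRUE)
  new_inter <- pm[1, 1] <= n1 & pm[1, 2] > n1
  acc_inter <- acc_pm[, 1] <= n1 & acc_pm[, 2] > n1
  same <- which(acc_inter == new_inter)
  if (length(same) == 0) return(TRUE)
  for (r in seq_len(nrow(pm))) {
    i <- pm[r, 1]
    j <- pm[r, 2]
    a <- acc_pm[same, 1]
    b <- acc_pm[same, 2]
    if (any((a < i & i < b & b < j) | (i < a & a < j & j < b))) {
      return(FALSE)
    }
  }
  TRUE
}

# Final check: number of distinct kissing helices (inter helices that
# cross an intra pair) within the allowance.
kissing_count_ok <- function(pm, n1, max_kissing) {
  k <- nrow(pm)
  if (k < 2) return(TRUE)
  inter <- pm[, 1] <= n1 & pm[, 2] > n1
  if (!any(inter) || all(inter)) return(TRUE)
  helix_id <- helix_membership(pm)
  intra <- pm[!inter, , drop = FALSE]
  kiss <- unique(vapply(which(inter), function(r) {
    i <- pm[r, 1]
    j <- pm[r, 2]
    if (any((intra[, 1] < i & i < intra[, 2] & intra[, 2] < j) |
              (i < intra[, 1] & intra[, 1] < j & j < intra[, 2]))) {
      helix_id[r]
    } else NA_integer_
  }, integer(1)))
  sum(!is.na(kiss)) <= max_kissing
}

candidate_pairs <- function(bases, n1, min_hairpin) {
  n <- length(bases)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same <- (i <= n1) == (j <= n1)
      if (same && (j - i) <= min_hairpin) next
      if (is_canonical_pair(bases[i], bases[j])) {
        out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  do.call(rbind, c(list(matrix(integer(), ncol = 2)), out))
}

# Maximal stackable runs: consecutive pairs (i, j), (i+1, j-1) along one
# anti-diagonal, not crossing a strand boundary and keeping i < j.
maximal_runs <- function(cand, n1) {
  if (nrow(cand) == 0) return(list())
  key <- paste(cand[, 1], cand[, 2])
  strand <- function(p) p <= n1
  runs <- list()
  seen <- character()
  for (a in seq_len(nrow(cand))) {
    i <- cand[a, 1]
    j <- cand[a, 2]
    prev <- paste(i - 1, j + 1)
    prev_ok <- prev %in% key &&
      strand(i - 1) == strand(i) && strand(j + 1) == strand(j)
    if (prev_ok) next  # not a run start
    run <- matrix(c(i, j), ncol = 2)
    repeat {
      ni <- run[nrow(run), 1] + 1L
      nj <- run[nrow(run), 2] - 1L
      if (ni >= nj) break
      if (!(paste(ni, nj) %in% key)) break
      if (strand(ni) != strand(ni - 1L) || strand(nj) != strand(nj + 1L)) break
      run <- rbind(run, c(ni, nj))
    }
    runs[[length(runs) + 1]] <- run
  }
  runs
}

# All index subsets of 1..L whose chosen positions form runs of at least
# `min_helix` consecutive indices; includes the empty selection.
run_masks <- function(L, min_helix) {
  masks <- list(integer())
  build <- function(start, current) {
    if (start > L) return(invisible())
    for (s in start:L) {
      max_len <- L - s + 1
      if (max_len < min_helix) break
      for (len in min_helix:max_len) {
        chosen <- c(current, s:(s + len - 1))
        masks[[length(masks) + 1]] <<- chosen
        build(s + len + 1, chosen)  # gap of >= 1 before the next run
      }
    }
  }
  build(1, integer())
  masks
}

helix_membership <- function(pm) {
  id <- integer(nrow(pm))
  helices <- pairs_to_helices(pm)
  key <- paste(pm[, 1], pm[, 2])
  for (h in seq_along(helices)) {
    id[match(paste(helices[[h]][, 1], helices[[h]][, 2]), key)] <- h
  }
  id
}

# ---------------------------------------------------------------------------
# structure scoring

structure_thermo <- function(pm, bases, n1, opts) {
  res <- list(dh = 0, ds = 0, kissing = FALSE, feasible = TRUE)
  if (nrow(pm) == 0) return(res)
  helices <- pairs_to_helices(pm)
  inter_pair <- pm[, 1] <= n1 & pm[, 2] > n1
  key <- paste(pm[, 1], pm[, 2])
  h_inter <- vapply(helices, function(h) h[1, 1] <= n1 && h[1, 2] > n1, TRUE)
  h_kissing <- vapply(seq_along(helices), function(hi) {
    if (!h_inter[hi]) return(FALSE)
    h <- helices[[hi]]
    intra <- pm[!inter_pair, , drop = FALSE]
    if (nrow(intra) == 0) return(FALSE)
    any(vapply(seq_len(nrow(h)), function(r) {
      i <- h[r, 1]
      j <- h[r, 2]
      any((intra[, 1] < i & i < intra[, 2] & intra[, 2] < j) |
            (i < intra[, 1] & intra[, 1] < j & j < intra[, 2]))
    }, TRUE))
  }, TRUE)
  res$kissing <- any(h_kissing)
  # stacking terms
  for (h in helices) {
    if (nrow(h) < 2) next
    for (r in seq_len(nrow(h) - 1)) {
      i <- h[r, 1]
      j <- h[r, 2]
      stack <- paste0(bases[i], bases[i + 1], "/", bases[j], bases[j - 1])
      row <- which(opts$nn$stack == stack)
      if (length(row) == 0) {
        abort(sprintf("stack `%s` missing from the NN table", stack))
      }
      dg37 <- opts$nn$dg37[row[1]]
      dh <- opts$nn$dh[row[1]]
      res$dh <- res$dh + dh
      res$ds <- res$ds + (dh - dg37) / 310.15
    }
  }
  # loop terms on the non-kissing pair set
  kiss_pairs <- do.call(rbind, c(list(matrix(integer(), ncol = 2)),
                                 helices[h_kissing]))
  rest <- helices[!h_kissing]
  paired <- logical(length(bases))
  paired[c(pm)] <- TRUE
  kiss_gaps <- list()
  for (h in rest) {
    p <- h[nrow(h), 1]
    q <- h[nrow(h), 2]
    if (q - p < 2) next
    inside <- (p + 1):(q - 1)
    # positions not covered by nested helices of `rest`; the strand break
    # is open (no closure penalty) unless a nested helix spans it
    covered <- rep(FALSE, length(inside))
    nick_in_child <- FALSE
    for (h2 in rest) {
      a <- h2[1, 1]
      b <- h2[1, 2]
      if (a > p && b < q) {
        covered[inside >= a & inside <= b] <- TRUE
        if (a <= n1 && n1 + 1 <= b) nick_in_child <- TRUE
      }
    }
    face <- inside[!covered]
    if (length(face) == 0) next
    has_nick <- length(bases) > n1 && p <= n1 && n1 < q && !nick_in_child
    in_kiss <- face[face %in% c(kiss_pairs)]
    free <- face[!paired[face]]
    if (length(in_kiss) > 0) {
      # kissing face: unpaired gaps before/after the kissing block
      blk <- range(in_kiss)
      gap5 <- sum(free < blk[1])
      gap3 <- sum(free > blk[2])
      kiss_gaps[[length(kiss_gaps) + 1]] <- c(gap5, gap3)
    } else if (!has_nick) {
      kind <- if (any(covered)) "internal" else "hairpin"
      res$ds <- res$ds + .kB * loop_entropy_ds(length(free), kind)
    }
  }
  if (res$kissing) {
    res <- add_kissing_entropy(res, kiss_pairs, kiss_gaps, opts)
  }
  if (!is.finite(res$ds)) res$feasible <- FALSE
  res
}

# Entropy of the kissing interface: table cell when the coaxial pipeline
# applies, generic lattice loop penalties otherwise; an infeasible (dash)
# cell makes the structure infeasible.
add_kissing_entropy <- function(res, kiss_pairs, kiss_gaps, opts) {
  h2 <- nrow(kiss_pairs)
  gaps <- unlist(kiss_gaps)
  if (length(kiss_gaps) == 2) {
    g1 <- sort(kiss_gaps[[1]], decreasing = TRUE)  # long loop first
    g2 <- sort(kiss_gaps[[2]], decreasing = TRUE)
    tab <- opts$entropy_table
    in_range <- g1[2] <= 1 && g2[2] <= 1 &&
      h2 %in% tab$h2_len && g1[1] %in% tab$l1_len && g2[1] %in% tab$l3_len
    if (in_range) {
      cell <- try(table_lookup(tab, h2, g1[1], g2[1]), silent = TRUE)
      if (!inherits(cell, "try-error") && nrow(cell) == 1) {
        if (cell$missing) {
          res$ds <- -Inf
          return(res)
        }
        penalty <- coil_ln_omega(g1[1]) + coil_ln_omega(g2[1]) -
          cell$ln_omega
        res$ds <- res$ds - .kB * penalty
        return(res)
      }
    }
  }
  for (g in gaps) res$ds <- res$ds + .kB * loop_entropy_ds(g, "internal")
  res
}

# ---------------------------------------------------------------------------
# partition functions

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

ensemble_log_q <- function(tab, temperature) {
  if (nrow(tab) == 0) return(-Inf)
  dg <- tab$dh - temperature * tab$ds
  logsumexp(-dg / (.kB * temperature))
}

#' Two-strand partition functions and bound fraction
#'
#' Boltzmann sums over the unbound single-strand ensembles (`Q1`, `Q2`,
#' each including the open chain at energy zero) and the bound dimer
#' ensemble (`Q12`), combined as
#' `Q = Q1 * Q2 + exp(-dG_associate / k_B T) * Q12`.
#' Sums are accumulated in log space, so energies of a few hundred
#' kcal/mol do not overflow.
#'
#' @param ensemble A `kf_ensemble` from [enumerate_structures()] (with
#'   `seq2` supplied).
#' @param params An [ensemble_params()].
#' @param include_unpaired_bound Include the associated-but-unpaired state
#'   in `Q12` at energy zero (default TRUE).
#' @return A `kf_partition` list: `q1`, `q2`, `q12`, `log_q1`, `log_q2`,
#'   `log_q12`, `dg_associate`, `q_total`, `bound_fraction`,
#'   `temperature`. Has [tidy()] and [glance()] methods.
#' @export
partition_functions <- function(ensemble, params = ensemble_params(),
                                include_unpaired_bound = TRUE) {
  stopifnot(inherits(ensemble, "kf_ensemble"),
            inherits(params, "ensemble_params"))
  kT <- .kB * params$temperature
  lq1 <- ensemble_log_q(ensemble[ensemble$system == "strand1", ],
                        params$temperature)
  lq2 <- if (any(ensemble$system == "strand2")) {
    ensemble_log_q(ensemble[ensemble$system == "strand2", ],
                   params$temperature)
  } else 0
  dimer <- ensemble[ensemble$system == "dimer", ]
  lq12_structs <- ensemble_log_q(dimer, params$temperature)
  lq12 <- if (include_unpaired_bound) {
    logsumexp(c(0, lq12_structs))
  } else {
    lq12_structs
  }
  dga <- associate_free_energy(params)
  l_unbound <- lq1 + lq2
  l_bound <- -dga / kT + lq12
  l_total <- logsumexp(c(l_unbound, l_bound))
  structure(list(
    q1 = exp(lq1), q2 = exp(lq2), q12 = exp(lq12),
    log_q1 = lq1, log_q2 = lq2, log_q12 = lq12,
    dg_associate = dga,
    q_total = exp(l_total),
    bound_fraction = exp(l_bound - l_total),
    temperature = params$temperature,
    include_unpaired_bound = include_unpaired_bound),
    class = "kf_partition")
}

#' @export
print.kf_partition <- function(x, ...) {
  cat("<kf_partition> two-strand system\n")
  cat(sprintf("  Q1 = %.4g, Q2 = %.4g, Q12 = %.4g\n", x$q1, x$q2, x$q12))
  cat(sprintf("  dG_associate = %.3f kcal/mol at %.5g K\n",
              x$dg_associate, x$temperature))
  cat(sprintf("  bound fraction = %.4g\n", x$bound_fraction))
  invisible(x)
}

# ---------------------------------------------------------------------------
# free-energy landscape over (native, non-native) base-pair counts

#' Free-energy landscape over native/non-native pair counts
#'
#' Bins every bound (dimer) structure by the number of native base pairs
#' (pairs shared with the reference structure) and non-native pairs (pairs
#' absent from the reference, intramolecular ones included), accumulates
#' Boltzmann mass per bin, and reports bin free energies
#' `F = -k_B T ln(mass)` and local minima (bins below all 8 neighbours,
#' absent bins counting as empty).
#'
#' @param ensemble A `kf_ensemble` with a dimer system.
#' @param reference A [kf_structure()] (or pair matrix) defining native
#'   pairs, drawn from the same sequence pair.
#' @param params An [ensemble_params()].
#' @return A `kf_landscape` tibble: `native`, `nonnative`, `mass`,
#'   `probability`, `free_energy` (kcal/mol), `minimum` (logical). The
#'   total mass equals `exp(-dG_assoc/kT) * (Q12 - 1)` contribution of the
#'   paired bound ensemble; probabilities are normalised over bins.
#' @export
landscape <- function(ensemble, reference, params = ensemble_params()) {
  stopifnot(inherits(ensemble, "kf_ensemble"))
  ref <- if (inherits(reference, "kf_structure")) {
    as.matrix(reference$pairs[, c("i", "j")])
  } else {
    as.matrix(reference)[, 1:2, drop = FALSE]
  }
  ref_key <- paste(ref[, 1], ref[, 2])
  dimer <- ensemble[ensemble$system == "dimer", ]
  if (nrow(dimer) == 0) abort("ensemble has no bound structures")
  kT <- .kB * params$temperature
  dga <- associate_free_energy(params)
  dg <- dimer$dh - params$temperature * dimer$ds
  logw <- -(dg + dga) / kT
  nat <- vapply(dimer$pairs, function(pm) {
    if (nrow(pm) == 0) return(0L)
    sum(paste(pm[, 1], pm[, 2]) %in% ref_key)
  }, integer(1))
  nn <- dimer$n_pairs - nat
  df <- tibble(native = nat, nonnative = nn, logw = logw) |>
    dplyr::group_by(.data$native, .data$nonnative) |>
    dplyr::summarise(log_mass = logsumexp(.data$logw), .groups = "drop")
  total <- logsumexp(df$log_mass)
  df$mass <- exp(df$log_mass)
  df$probability <- exp(df$log_mass - total)
  df$free_energy <- -kT * df$log_mass
  df$minimum <- landscape_minima(df)
  df$log_mass <- NULL
  attr(df, "temperature") <- params$temperature
  attr(df, "dg_associate") <- dga
  class(df) <- c("kf_landscape", class(df))
  df
}

landscape_minima <- function(df) {
  vapply(seq_len(nrow(df)), function(r) {
    nb <- df$native %in% (df$native[r] + -1:1) &
      df$nonnative %in% (df$nonnative[r] + -1:1) &
      !(df$native == df$native[r] & df$nonnative == df$nonnative[r])
    nb <- nb & abs(df$native - df$native[r]) <= 1 &
      abs(df$nonnative - df$nonnative[r]) <= 1
    all(df$free_energy[nb] > df$free_energy[r])
  }, logical(1))
}

# ---------------------------------------------------------------------------
# melting profile

#' Bound fraction and species populations across temperature
#'
#' Recomputes the two-strand partition functions on a temperature grid
#' (stack entropies from the NN table, lattice loop entropies temperature
#' independent) and reports the population of each species class:
#' `kissing` (bound structures containing a kissing helix),
#' `extended_duplex` (bound, intermolecular pairs, no kissing helix),
#' `unbound` (the `Q1 * Q2` term, plus the associated-unpaired state when
#' enabled). The classes partition the ensemble, so populations sum to 1.
#'
#' @param ensemble A `kf_ensemble` with a dimer system.
#' @param params An [ensemble_params()]; its temperature field is ignored
#'   in favour of `t_grid`.
#' @param t_grid Increasing vector of temperatures in K.
#' @param include_unpaired_bound As in [partition_functions()]; the
#'   associated-unpaired state is counted as `unbound` in the species
#'   split.
#' @return A tibble of class `kf_melting`: `temperature`,
#'   `bound_fraction`, `p_kissing`, `p_extended_duplex`, `p_unbound`.
#' @export
melting_profile <- function(ensemble, params = ensemble_params(),
                            t_grid = seq(273.15, 373.15, by = 2.5),
                            include_unpaired_bound = TRUE) {
  stopifnot(all(diff(t_grid) > 0))
  dimer <- ensemble[ensemble$system == "dimer", ]
  rows <- lapply(t_grid, function(Tk) {
    p <- ensemble_params(temperature = Tk, ct = params$ct,
                         dg_init = params$dg_init)
    kT <- .kB * Tk
    pf <- partition_functions(ensemble, p, include_unpaired_bound)
    dg <- dimer$dh - Tk * dimer$ds
    logw <- -(dg + pf$dg_associate) / kT - log(pf$q_total)
    lk <- logsumexp(logw[dimer$kissing])
    ld <- logsumexp(logw[!dimer$kissing])
    p_k <- exp(lk)
    p_d <- exp(ld)
    tibble(temperature = Tk, bound_fraction = pf$bound_fraction,
           p_kissing = p_k, p_extended_duplex = p_d,
           p_unbound = 1 - p_k - p_d)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("kf_melting", class(out))
  out
}
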