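test_that("lattice encoding: 4 neighbours, alternating sublattice", {
  expect_true(is_lattice_site(c(0, 0, 0)))
  expect_true(is_lattice_site(c(1, 1, 1)))
  expect_false(is_lattice_site(c(1, 0, 0)))
  nb <- lattice_neighbors(c(0, 0, 0))
  expect_equal(nrow(nb), 4)
  expect_true(all(is_lattice_site(nb)))
  expect_true(all(lattice_sublattice(nb) == "B"))
  # equal bond lengths
  expect_equal(sqrt(rowSums(nb^2)), rep(sqrt(3), 4))
  # neighbours of a B site are A sites, including the origin
  nb2 <- lattice_neighbors(c(1, 1, 1))
  expect_true(all(lattice_sublattice(nb2) == "A"))
  expect_true("0,0,0" %in% kisfold:::site_key(nb2))
})

test_that("free-coil counts: coordination number and first lengths match a brute-force oracle", {
  expect_equal(count_free_walks(1), 4)   # coordination number
  expect_equal(count_free_walks(2), 12)  # no immediate reversal
  tab <- enumerate_free_coil(3)
  far <- c(40, 40, 40)  # unreachable end: oracle counts all walks
  for (steps in 1:6) {
    brute <- 0
    # count all SAWs of `steps` steps by summing anchored counts over all
    # reachable endpoints of a bounded box
    rng <- -steps:steps
    ends <- as.matrix(expand.grid(rng, rng, rng))
    ends <- ends[is_lattice_site(ends), , drop = FALSE]
    for (r in seq_len(nrow(ends))) {
      brute <- brute + oracle_saw_count(c(0, 0, 0), ends[r, ], steps)
    }
    got <- count_free_walks(steps)
    expect_equal(got, brute, info = paste("steps", steps))
  }
  expect_equal(tab$count, c(12, 108, 948))
  expect_equal(tab$ln_omega, log(tab$count))
})

test_that("enumeration cap is an explicit error, never a truncation", {
  expect_error(enumerate_free_coil(13), "cap")
  expect_error(enumerate_free_coil(20, cap = 12), "cap")
  expect_silent(enumerate_free_coil(4, cap = 12))
})

test_that("anchored loops: degenerate cases and parity diagnostics", {
  # cannot return to the origin in 2 self-avoiding steps
  r <- enumerate_anchored_loop(c(0, 0, 0), c(0, 0, 0), n_nt = 1)
  expect_equal(r$n_conformations, 0)
  expect_identical(r$ln_omega, -Inf)
  # adjacent anchors, single-step walk
  r1 <- enumerate_anchored_loop(c(0, 0, 0), c(1, 1, 1), n_steps = 1)
  expect_equal(r1$n_conformations, 1)
  # parity-incompatible anchors: diagnostic message, zero count
  expect_message(
    r2 <- enumerate_anchored_loop(c(0, 0, 0), c(1, 1, 1), n_nt = 1),
    "sublattice")
  expect_equal(r2$n_conformations, 0)
})

test_that("optimized anchored counts equal the independent oracle on random cases", {
  set.seed(7)
  for (case in 1:40) {
    n <- sample(1:5, 1)
    start <- random_site(sample(0:3, 1))
    end <- random_site_offset(start, 2 * n)
    obst <- unique(t(replicate(sample(0:8, 1),
                               random_site_offset(start, sample(1:4, 1)))))
    obst <- obst[!apply(obst, 1, function(s) {
      all(s == start) || all(s == end)
    }), , drop = FALSE]
    got <- enumerate_anchored_loop(start, end, n_nt = n,
                                   obstacles = obst)$n_conformations
    want <- oracle_saw_count(start, end, 2 * n, obst)
    expect_equal(got, want, info = paste("case", case))
  }
})

test_that("adding obstacles never increases anchored counts", {
  set.seed(21)
  for (case in 1:20) {
    n <- sample(2:5, 1)
    start <- c(0L, 0L, 0L)
    end <- random_site_offset(start, 2 * n)
    base <- enumerate_anchored_loop(start, end, n_nt = n)$n_conformations
    obst <- t(replicate(3, random_site_offset(start, sample(1:3, 1))))
    obst <- obst[!apply(obst, 1, function(s) {
      all(s == start) || all(s == end)
    }), , drop = FALSE]
    with_obst <- enumerate_anchored_loop(start, end, n_nt = n,
                                         obstacles = obst)$n_conformations
    expect_lte(with_obst, base)
  }
})

test_that("counts are invariant under lattice point-group operations", {
  # cyclic coordinate permutation and a coordinate swap both map the
  # diamond lattice onto itself (inversion about a site does not: the
  # diamond lattice is not site-centrosymmetric)
  perm <- function(m) rbind(m)[, c(2, 3, 1), drop = FALSE]
  inv <- function(m) rbind(m)[, c(2, 1, 3), drop = FALSE]
  set.seed(13)
  for (case in 1:10) {
    n <- sample(2:4, 1)
    start <- c(0L, 0L, 0L)
    end <- random_site_offset(start, 2 * n)
    obst <- t(replicate(4, random_site_offset(start, 2)))
    base <- enumerate_anchored_loop(start, end, n_nt = n,
                                    obstacles = obst)$n_conformations
    for (op in list(perm, inv)) {
      mapped <- enumerate_anchored_loop(
        drop(op(start)), drop(op(end)), n_nt = n,
        obstacles = op(obst))$n_conformations
      expect_equal(mapped, base)
    }
  }
})

test_that("explicit walk enumeration agrees with the counter and is deterministic", {
  start <- c(0L, 0L, 0L)
  end <- random_site_offset(start, 4)
  w1 <- enumerate_anchored_walks(start, end, 4)
  w2 <- enumerate_anchored_walks(start, end, 4)
  expect_identical(w1, w2)
  expect_equal(length(w1),
               enumerate_anchored_loop(start, end,
                                       n_steps = 4)$n_conformations)
  for (w in w1) {
    steps <- diff(w)
    expect_true(all(abs(steps) == 1))
    expect_equal(anyDuplicated(kisfold:::site_key(w)), 0)
  }
})

test_that("snap_to_lattice: exact hits, deterministic ties, local optimality", {
  scale <- 3.9 / sqrt(3)
  expect_equal(snap_to_lattice(c(2, 2, 0) * scale), c(2L, 2L, 0L))
  # midpoint of a bond snaps to the lexicographically smaller site
  mid <- c(0.5, 0.5, 0.5) * scale
  expect_equal(snap_to_lattice(mid), c(0L, 0L, 0L))
  set.seed(5)
  for (case in 1:200) {
    p <- runif(3, -12, 12)
    site <- snap_to_lattice(p)
    # exhaustive search over a generous neighbourhood
    rng <- -6:6
    cand <- as.matrix(expand.grid(round(p / scale)[1] + rng,
                                  round(p / scale)[2] + rng,
                                  round(p / scale)[3] + rng))
    cand <- cand[is_lattice_site(cand), , drop = FALSE]
    d2 <- colSums((t(cand) * scale - p)^2)
    expect_lt(sum((site * scale - p)^2), min(d2) + 1e-9)
  }
  # sublattice restriction is honoured
  expect_equal(lattice_sublattice(snap_to_lattice(c(0.1, 0, 0),
                                                  sublattice = "B")), "B")
})

test_that("coil growth is near-linear with a stable fitted slope", {
  fit_lo <- coil_slope(4:8)
  fit_hi <- coil_slope(6:10)
  expect_lt(abs(fit_lo$slope - fit_hi$slope), 0.05)
})
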