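test_that("kissing topology validates the coaxial-stacking assumptions", {
  t1 <- kissing_topology(6, 2, 2)
  expect_s3_class(t1, "kissing_topology")
  expect_error(kissing_topology(0, 2, 2), "h2_len")
  expect_error(kissing_topology(6, 2, 2, l2_len = 2), "l2 and l4")
})

test_that("anchor frames are deterministic and track the kissing-stem length", {
  f1 <- generate_anchor_frame(4)
  f2 <- generate_anchor_frame(4)
  expect_identical(f1$anchors, f2$anchors)
  # the anchors of the loops that span H2 sit h2 + 1 helical steps
  # apart: each added base pair adds one rise and one twist increment
  om <- 2 * pi / 11
  for (h2 in 1:6) {
    f <- generate_anchor_frame(h2)
    dz <- abs(f$anchors["b_i", "z"] - f$anchors["a_i", "z"])
    expect_equal(dz, 2.7 * (h2 + 1), tolerance = 1e-9)
    d <- sqrt(sum((f$anchors["a_i", ] - f$anchors["b_i", ])^2))
    chord <- 2 * 9.9 * abs(sin((om * (h2 + 1) + 2.1468) / 2))
    expect_equal(d, sqrt(dz^2 + chord^2), tolerance = 1e-9)
  }
  # separation across the duplex equals the groove chord at equal level
  f <- generate_anchor_frame(3)
  d <- sqrt(sum((f$anchors["a_i", ] - f$anchors["a_i_p", ])^2))
  expect_equal(d, 2 * 9.9 * sin(2.1468 / 2), tolerance = 1e-9)
  expect_error(generate_anchor_frame(9), "maximum")
})

test_that("kissing entropy: determinism, label symmetry, and obstacle monotonicity", {
  k1 <- kissing_entropy(kissing_topology(3, 5, 5))
  k2 <- kissing_entropy(kissing_topology(3, 5, 5))
  expect_identical(k1, k2)
  expect_equal(k1$status, "ok")
  expect_equal(k1$ln_omega_loop, log(k1$count_l1 * k1$count_l3))
  expect_equal(k1$delta_S, k1$ln_omega_loop - k1$ln_omega_coil)
  # swapping the loop labels of a symmetric topology leaves delta_S alone
  ka <- kissing_entropy(kissing_topology(3, 5, 6))
  kb <- kissing_entropy(kissing_topology(3, 6, 5))
  expect_equal(ka$ln_omega_coil, kb$ln_omega_coil)
  # longer flanking stems add obstacles: delta_S never increases
  short <- kissing_entropy(kissing_topology(3, 5, 5, h1_len = 1,
                                            h3_len = 1))
  long <- kissing_entropy(kissing_topology(3, 5, 5, h1_len = 3,
                                           h3_len = 3))
  expect_lte(long$delta_S, short$delta_S)
  # infeasible loops are reported distinctly, not as numbers
  inf <- kissing_entropy(kissing_topology(3, 2, 2))
  expect_equal(inf$status, "infeasible")
  expect_identical(inf$delta_S, -Inf)
})

test_that("anchored loops lose entropy relative to free coils of the same length", {
  for (l in 5:6) {
    k <- kissing_entropy(kissing_topology(3, l, l))
    free <- enumerate_free_coil(l)
    ln_free <- 2 * free$ln_omega[free$n_nt == l]
    expect_lte(k$ln_omega_loop, ln_free)
  }
})

test_that("entropy table: exact cells, explicit missing, bounds, round-trip", {
  tab <- load_entropy_table()
  cell <- table_lookup(tab, 6, 2, 2)
  expect_false(cell$missing)
  expect_identical(cell$ln_omega, 0)
  expect_identical(table_lookup(tab, 5, 7, 7)$ln_omega, 12.6)
  # dash entries are missing, never interpolated
  dash <- table_lookup(tab, 6, 2, 1)
  expect_true(dash$missing)
  expect_true(is.na(dash$ln_omega))
  expect_error(table_lookup(tab, 12, 2, 2), "h2_len")
  expect_error(table_lookup(tab, 6, 2, 9), "l3_len")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_entropy_table(tab, path)
  back <- load_entropy_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  # and byte-identical on re-serialisation
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_entropy_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("the tabulated (6,2,2) cell with the coil model gives the 8.4 k_BT penalty", {
  tab <- load_entropy_table()
  pen <- table_entropy_penalty(tab, 6, 2, 2)
  expect_equal(pen, 2 * (2.05 * 2 + 0.1) - 0, tolerance = 1e-12)
  expect_true(is.na(table_entropy_penalty(tab, 6, 2, 1)))
})

test_that("free-coil enumeration approximates the linear coil model", {
  tab <- enumerate_free_coil(10)
  sub <- tab[tab$n_nt >= 4, ]
  rel <- abs(sub$ln_omega - coil_ln_omega(sub$n_nt)) / sub$ln_omega
  expect_lt(max(rel), 0.10)
  fit <- coil_slope(4:10)
  expect_lt(abs(fit$slope - 2.05), 0.15)
})

test_that("effective loop lengths follow the substructure-replacement rule", {
  t0 <- kissing_topology(6, 3, 2)
  t1 <- effective_loop_lengths(t0, c(l1 = 1))
  expect_equal(t1$l1_len, 4)
  expect_equal(t1$l3_len, 2)
  # identity without substructures
  expect_equal(effective_loop_lengths(t0)$l1_len, 3)
  # 0 unpaired + 2 substructures -> 2
  t2 <- effective_loop_lengths(kissing_topology(6, 0, 0), c(l1 = 2))
  expect_equal(t2$l1_len, 2)
})
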