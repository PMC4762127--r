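test_that("pseudoknot penalty is affine with the stated coefficients", {
  p <- pseudoknot_params(1.0, 0.5, 0.1)
  expect_equal(pseudoknot_energy(0, 0, p), 1.0)
  expect_equal(pseudoknot_energy(4, 7, p), 3.7)
  p0 <- pseudoknot_params(2.5, 0, 0)
  expect_equal(pseudoknot_energy(9, 13, p0), 2.5)
  # finite-difference slopes recover beta2 and beta3 exactly
  expect_equal(pseudoknot_energy(5, 3, p) - pseudoknot_energy(4, 3, p), 0.5)
  expect_equal(pseudoknot_energy(5, 4, p) - pseudoknot_energy(5, 3, p), 0.1)
  expect_error(pseudoknot_energy(-1, 0, p))
})

test_that("Flory radius: single-segment limits and scaling", {
  expect_equal(flory_radius(1, 0), 6.2)
  expect_equal(flory_radius(0, 1), 15)
  expect_equal(flory_radius(2, 0), 2^(3 / 5) * 6.2, tolerance = 1e-12)
  expect_error(flory_radius(0, 0), "N \\+ M")
  p <- fjc_params(a = 5, b = 10)
  expect_equal(flory_radius(1, 1, p), sqrt(25 + 100))
})

test_that("FJC stretching energy: value and cancellation at z = R_F", {
  rf <- flory_radius(2, 0)
  expect_equal(fjc_stretch_free_energy(2, 0, rf) , 3 * log(rf),
               tolerance = 1e-12)
  expect_equal(3 * log(rf), 6.718, tolerance = 1e-3)
  set.seed(3)
  for (case in 1:100) {
    N <- sample(0:6, 1)
    M <- sample(0:3, 1)
    if (N + M < 2) N <- N + 2
    rf <- flory_radius(N, M)
    bg <- fjc_stretch_free_energy(N, M, rf)
    expect_equal(bg, 3 * log(rf), tolerance = 1e-9)
  }
})

test_that("FJC slope at R_F equals 5/(2 R_F) after the log-term cancellation", {
  # the z-derivative of the two log terms at R_F cancels the matching
  # pieces of the linear coefficient, leaving 5 / (2 R_F)
  for (nm in list(c(3, 0), c(2, 1), c(4, 2))) {
    rf <- flory_radius(nm[1], nm[2])
    h <- 1e-6
    fd <- (fjc_stretch_free_energy(nm[1], nm[2], rf + h) -
             fjc_stretch_free_energy(nm[1], nm[2], rf - h)) / (2 * h)
    expect_equal(fd, 5 / (2 * rf), tolerance = 1e-4)
  }
})

test_that("FJC energy is continuous, single-welled, and domain-guarded", {
  N <- 3
  M <- 1
  rf <- flory_radius(N, M)
  lmax <- N * 6.2 + M * 15
  z <- seq(3.5, lmax - 0.5, length.out = 400)
  bg <- vapply(z, function(zz) fjc_stretch_free_energy(N, M, zz), 1)
  expect_true(all(is.finite(bg)))
  expect_lt(max(abs(diff(bg))), 1)  # no jumps on a fine grid
  # the log terms diverge at both domain edges, so there is a single
  # interior well; its floor lies at or below the value at R_F, where
  # the slope is +5/(2 R_F)
  zmin <- z[which.min(bg)]
  expect_gt(zmin, 2.4)
  expect_lt(zmin, rf)
  expect_lte(min(bg), fjc_stretch_free_energy(N, M, rf))
  d <- diff(bg)
  expect_equal(sum(diff(sign(d)) != 0), 1)  # one slope sign change
  expect_error(fjc_stretch_free_energy(N, M, 2.0), "2.4")
  expect_error(fjc_stretch_free_energy(N, M, lmax + 1), "contour")
  # C0 enters as beta * C0
  kT <- kb_kcal_mol() * 310.15
  expect_equal(fjc_stretch_free_energy(N, M, rf, fjc_params(C0 = 1)),
               fjc_stretch_free_energy(N, M, rf) + 1 / kT)
})

test_that("kissing-complex free energy combines stems and entropy in kcal/mol", {
  e <- kissing_complex_free_energy(c(-15.7, -15.7, -14.2), 8.62)
  expect_equal(e$total,
               -45.6 + 8.62 * kb_kcal_mol() * 310.15, tolerance = 1e-12)
  expect_equal(e$total, -40.2, tolerance = 0.15)
  # zero entropy: pure sum
  expect_equal(kissing_complex_free_energy(c(-1, -1, -1), 0)$total, -3)
  # linearity in the stem terms
  e1 <- kissing_complex_free_energy(c(-2, -3), 5)
  e2 <- kissing_complex_free_energy(c(-4, -6), 5)
  expect_equal(e2$total - e2$entropy_kcal,
               2 * (e1$total - e1$entropy_kcal))
  # infeasible entropy propagates to +Inf with a warning
  expect_warning(ei <- kissing_complex_free_energy(c(-1), Inf),
                 "infeasible")
  expect_identical(ei$total, Inf)
  # tidy/glance views
  td <- tidy(e)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$kcal_mol), e$total)
  expect_equal(glance(e)$temperature, 310.15)
})

test_that("nearest-neighbour stem energies sum shipped stack parameters", {
  nn <- nn_parameters()
  init <- nn$dg37[nn$stack == "init"]
  term_au <- nn$dg37[nn$stack == "terminal_au"]
  # single base pair: initiation + terminal penalties only
  expect_equal(stem_free_energy("G", "C", nn), init)
  expect_equal(stem_free_energy("A", "U", nn), init + 2 * term_au)
  # a 3-stack helix, hand-summed from the file
  v <- function(k) nn$dg37[nn$stack == k]
  expect_equal(
    stem_free_energy("GGAC", "CCUG", nn),
    v("GG/CC") + v("GA/CU") + v("AC/UG") + init)
  # reading the duplex from the other strand's 5' end is the same
  # molecule: E(s5, s3) == E(rev(s3), rev(s5))
  rev_str <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  for (dup in list(c("GGAC", "CCUG"), c("GGCC", "CCGG"),
                   c("GAUC", "CUAG"))) {
    expect_equal(stem_free_energy(dup[1], dup[2]),
                 stem_free_energy(rev_str(dup[2]), rev_str(dup[1])))
  }
  expect_error(stem_free_energy("GA", "CA"), "non-canonical .* position 2")
  # G-U wobble pairs are accepted and carry the terminal penalty
  expect_equal(stem_free_energy("G", "U", nn), init + 2 * term_au)
})

test_that("temperature dependence uses dH and the 37 C entropy split", {
  nn <- nn_parameters()
  g37 <- stem_free_energy("GGG", "CCC", nn, temperature = 310.15)
  g50 <- stem_free_energy("GGG", "CCC", nn, temperature = 323.15)
  expect_gt(g50, g37)  # stacking is enthalpy-driven: less stable when hot
  # reconstruct one stack by hand
  row <- nn[nn$stack == "GG/CC", ]
  ds <- (row$dh - row$dg37) / 310.15
  expect_equal(stem_free_energy("GG", "CC", nn, initiation = FALSE,
                                temperature = 300) ,
               row$dh - 300 * ds, tolerance = 1e-12)
})
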