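kT_at <- function(Tk) kb_kcal_mol() * Tk

test_that("association free energy follows the concentration law", {
  expect_equal(associate_free_energy(ct = 4), 4.1)
  expect_equal(associate_free_energy(ct = 4e-6, temperature = 310.15),
               4.1 - kT_at(310.15) * log(1e-6), tolerance = 1e-12)
  expect_equal(4.1 - kT_at(310.15) * log(1e-6), 12.62, tolerance = 0.01)
  cts <- 10^seq(-9, 0, length.out = 30)
  dg <- vapply(cts, function(ct) associate_free_energy(ct = ct), 1)
  expect_true(all(diff(dg) < 0))  # more dilute -> larger penalty
})

test_that("strands without a pairable stretch give a structure-free bound ensemble", {
  ens <- enumerate_structures("AAAA", "AAAA")
  expect_equal(sum(ens$system == "dimer"), 0)
  pf <- partition_functions(ens, ensemble_params())
  expect_equal(pf$q1, 1)
  expect_equal(pf$q12, 1)  # the associated-unpaired state only
  x <- exp(-pf$dg_associate / kT_at(310.15))
  expect_equal(pf$bound_fraction, x / (1 + x), tolerance = 1e-12)
  pf0 <- partition_functions(ens, ensemble_params(),
                             include_unpaired_bound = FALSE)
  expect_equal(pf0$bound_fraction, 0)
})

test_that("a single-duplex toy matches the analytic two-state closed form", {
  # GGG + CCC: complementary only along one register (>= 3 bp)
  ens <- enumerate_structures("GGG", "CCC")
  dimer <- ens[ens$system == "dimer", ]
  expect_equal(nrow(dimer), 1)
  expect_equal(dimer$n_pairs, 3)
  nn <- nn_parameters()
  v <- function(k) nn$dg37[nn$stack == k]
  expect_equal(dimer$dg37, 2 * v("GG/CC"))  # two stacks, no initiation
  for (Tk in c(290, 310.15, 340)) {
    p <- ensemble_params(temperature = Tk, ct = 1e-5)
    pf <- partition_functions(ens, p, include_unpaired_bound = FALSE)
    dg_d <- dimer$dh - Tk * dimer$ds
    w <- exp(-(dg_d + pf$dg_associate) / kT_at(Tk))
    expect_equal(pf$bound_fraction, w / (1 + w), tolerance = 1e-9)
  }
  # melting: raising T lowers the bound fraction
  prof <- melting_profile(ens, ensemble_params(ct = 1e-5),
                          t_grid = seq(280, 370, by = 10))
  expect_true(all(diff(prof$bound_fraction) < 0))
  expect_equal(prof$p_kissing + prof$p_extended_duplex + prof$p_unbound,
               rep(1, nrow(prof)), tolerance = 1e-9)
})

test_that("the melting midpoint matches the analytic Tm from the same parameters", {
  ens <- enumerate_structures("GGG", "CCC")
  dimer <- ens[ens$system == "dimer", ]
  ct <- 1e-5
  # bound fraction = 1/2 when dG_d + dG_associate = 0:
  # dH + dG_init - T (dS + kB ln(ct/4)) = 0
  tm <- (dimer$dh + 4.1) / (dimer$ds + kb_kcal_mol() * log(ct / 4))
  prof <- melting_profile(ens, ensemble_params(ct = ct),
                          t_grid = seq(tm - 15, tm + 15, by = 0.05),
                          include_unpaired_bound = FALSE)
  crossing <- prof$temperature[which.min(abs(prof$bound_fraction - 0.5))]
  expect_equal(crossing, tm, tolerance = 0.1)
})

test_that("exhaustive enumeration equals the independent pair-level oracle", {
  cases <- list(c("GGAC", "GUCC"), c("GGGAAACCC", NA),
                c("GCGAAU", "AUUCGC"), c("GGACA", "UGUCC"))
  for (cs in cases) {
    s1 <- cs[1]
    s2 <- if (is.na(cs[2])) NULL else cs[2]
    ens <- enumerate_structures(s1, s2)
    sys <- if (is.null(s2)) "strand1" else "dimer"
    got <- vapply(ens$pairs[ens$system == sys], pairs_key, "")
    want <- oracle_structures(s1, if (is.null(s2)) "" else s2)
    if (sys == "dimer") {
      n1 <- nchar(s1)
      keep <- vapply(strsplit(want, ","), function(ps) {
        any(vapply(ps, function(p) {
          ij <- as.integer(strsplit(p, ":")[[1]])
          length(ij) == 2 && ij[1] <= n1 && ij[2] > n1
        }, TRUE))
      }, TRUE)
      want <- want[keep & want != ""]
    }
    expect_setequal(got, want)
    expect_equal(length(got), length(unique(got)))  # no duplicates
  }
})

test_that("enumeration cap errors instead of truncating", {
  expect_error(enumerate_structures(strrep("AC", 20)), "cap")
})

test_that("landscape: reference binning, conservation, and minima", {
  # one-structure ensemble: all mass in a single native bin
  ens <- enumerate_structures("GGG", "CCC")
  ref <- kf_structure(c("GGG", "CCC"), cbind(1:3, 6:4))
  land <- landscape(ens, ref)
  expect_equal(nrow(land), 1)
  expect_equal(land$native, 3)
  expect_equal(land$nonnative, 0)
  expect_equal(land$probability, 1)
  expect_true(land$minimum)
  # conservation against the partition functions on a richer system
  tm <- cached_two_minimum()
  p <- ensemble_params()
  land2 <- landscape(tm$ens, tm$fx$reference, p)
  expect_equal(sum(land2$probability), 1, tolerance = 1e-9)
  pf <- partition_functions(tm$ens, p, include_unpaired_bound = FALSE)
  expect_equal(sum(land2$mass),
               exp(-pf$dg_associate / kT_at(p$temperature)) * pf$q12,
               tolerance = 1e-9 * sum(land2$mass))
  # minima are invariant under a global energy shift
  land3 <- landscape(tm$ens, tm$fx$reference,
                     ensemble_params(ct = 1e-2))
  expect_equal(land3$minimum, land2$minimum)
})

test_that("the engineered two-minimum dimer shows two coexisting folds", {
  tm <- cached_two_minimum()
  land <- landscape(tm$ens, tm$fx$reference)
  expect_equal(sum(land$minimum), 2)
  mins <- land[land$minimum, ]
  nref <- nrow(tm$fx$reference$pairs)
  # one basin is the native kissing fold, the other the extended duplex
  expect_true(any(mins$native == nref & mins$nonnative == 0))
  expect_true(any(mins$native < nref & mins$nonnative > 0))
  # the kissing structure and the extended duplex both exist in the
  # ensemble as distinct classes
  dimer <- tm$ens[tm$ens$system == "dimer", ]
  expect_true(any(dimer$kissing))
  expect_true(any(!dimer$kissing & dimer$n_inter > 0))
})

test_that("species classes partition the bound ensemble at every temperature", {
  tm <- cached_two_minimum()
  prof <- melting_profile(tm$ens, ensemble_params(),
                          t_grid = seq(283.15, 363.15, by = 20))
  expect_equal(prof$p_kissing + prof$p_extended_duplex + prof$p_unbound,
               rep(1, nrow(prof)), tolerance = 1e-9)
  expect_true(all(prof$bound_fraction >= 0 & prof$bound_fraction <= 1))
  # partition views
  pf <- partition_functions(tm$ens)
  expect_equal(tidy(pf)$value[4], pf$q_total)
  expect_s3_class(glance(pf), "tbl_df")
})

test_that("fixture generation is deterministic and seed-sensitive", {
  f1 <- generate_fixture("kissing_dimer", seed = 5)
  f2 <- generate_fixture("kissing_dimer", seed = 5)
  expect_identical(f1$sequences, f2$sequences)
  f3 <- generate_fixture("kissing_dimer", seed = 6)
  expect_false(identical(f1$sequences, f3$sequences))
  # loops are reverse-complementary by construction
  loops <- substr(f1$sequences, 4, 8)
  expect_identical(kisfold:::revcomp_rna(loops[[1]]), loops[[2]])
})
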