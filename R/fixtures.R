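#' Generate toy fixtures for dimer thermodynamics
#'
#' Deterministic (seeded) generators for the engineered toy systems used
#' throughout the package, standing in for viral kissing-dimer sequences
#' that are not part of the package:
#'
#' * `"hairpin"`: one strand folding into a single stem-loop.
#' * `"kissing_dimer"`: two hairpins whose loops are reverse-complementary,
#'   so they can pair loop-to-loop into a kissing complex.
#' * `"two_minimum_dimer"`: a kissing dimer whose strands are additionally
#'   full reverse complements of each other, so the kissing fold competes
#'   with a fully zipped extended duplex; the generator verifies by
#'   exhaustive enumeration that the (native, non-native) free-energy
#'   landscape has exactly two local minima, retrying with fresh random
#'   sequences up to `max_tries` times.
#'
#' @param kind One of `"hairpin"`, `"kissing_dimer"`,
#'   `"two_minimum_dimer"`.
#' @param seed Integer seed; the same seed always returns the same
#'   fixture.
#' @param stem_len Hairpin stem length in bp (default 3).
#' @param loop_len Loop length in nt (default 5).
#' @param max_tries Attempts before giving up on the landscape check.
#' @return A list: `sequences` (character vector), `reference` (a
#'   [kf_structure()]; the kissing fold for dimers), `kind`, `seed`.
#' @export
generate_fixture <- function(kind = c("hairpin", "kissing_dimer",
                                      "two_minimum_dimer"),
                             seed = 1L, stem_len = 3L, loop_len = 5L,
                             max_tries = 60L) {
  kind <- match.arg(kind)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  switch(kind,
         hairpin = fixture_hairpin(seed, stem_len, loop_len),
         kissing_dimer = fixture_kissing(seed, stem_len, loop_len,
                                         identical_stems = FALSE),
         two_minimum_dimer = fixture_two_minimum(seed, stem_len, loop_len,
                                                 max_tries))
}

rand_rna <- function(n) {
  paste0(sample(c("A", "U", "G", "C"), n, replace = TRUE), collapse = "")
}

revcomp_rna <- function(s) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  paste0(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# A stem with at least one G-C pair at the closing end, so toy hairpins do
# not fray into non-structures under the NN parameters.
rand_stem <- function(n) {
  paste0(c(sample(c("G", "C"), 1), strsplit(rand_rna(n - 1), "")[[1]]),
         collapse = "")
}

hairpin_pairs <- function(stem_len, loop_len, offset = 0L) {
  n <- 2L * stem_len + loop_len
  cbind(offset + seq_len(stem_len), offset + n + 1L - seq_len(stem_len))
}

fixture_hairpin <- function(seed, stem_len, loop_len) {
  stem <- rand_stem(stem_len)
  loop <- rand_rna(loop_len)
  s <- paste0(stem, loop, revcomp_rna(stem))
  ref <- kf_structure(s, hairpin_pairs(stem_len, loop_len))
  list(sequences = c(hp = s), reference = ref, kind = "hairpin",
       seed = seed)
}

kissing_reference <- function(stem_len, loop_len, s1, s2) {
  n1 <- nchar(s1)
  stems <- rbind(hairpin_pairs(stem_len, loop_len, 0L),
                 hairpin_pairs(stem_len, loop_len, n1))
  kiss <- cbind(stem_len + seq_len(loop_len),
                n1 + stem_len + loop_len + 1L - seq_len(loop_len))
  kf_structure(c(s1, s2), rbind(stems, kiss))
}

fixture_kissing <- function(seed, stem_len, loop_len, identical_stems) {
  repeat {
    stem_a <- rand_stem(stem_len)
    stem_b <- if (identical_stems) stem_a else rand_stem(stem_len)
    loop_a <- rand_rna(loop_len)
    s1 <- paste0(stem_a, loop_a, revcomp_rna(stem_a))
    s2 <- paste0(stem_b, revcomp_rna(loop_a), revcomp_rna(stem_b))
    ref <- try(kissing_reference(stem_len, loop_len, s1, s2),
               silent = TRUE)
    if (!inherits(ref, "try-error")) {
      return(list(sequences = c(hp1 = s1, hp2 = s2), reference = ref,
                  kind = "kissing_dimer", seed = seed))
    }
  }
}

fixture_two_minimum <- function(seed, stem_len, loop_len, max_tries) {
  for (try_i in seq_len(max_tries)) {
    stem_a <- rand_stem(stem_len)
    loop_a <- rand_rna(loop_len)
    s1 <- paste0(stem_a, loop_a, revcomp_rna(stem_a))
    s2 <- revcomp_rna(s1)  # extended duplex is the full zip of s1 with s2
    ref <- try(kissing_reference(stem_len, loop_len, s1, s2),
               silent = TRUE)
    if (inherits(ref, "try-error")) next
    ens <- try(enumerate_structures(s1, s2), silent = TRUE)
    if (inherits(ens, "try-error")) next
    if (!any(ens$system == "dimer")) next
    land <- landscape(ens, ref)
    if (sum(land$minimum) == 2L) {
      return(list(sequences = c(hp1 = s1, hp2 = s2), reference = ref,
                  kind = "two_minimum_dimer", seed = seed))
    }
  }
  abort(sprintf(
    "no two-minimum fixture found in %d attempts for seed %d",
    max_tries, seed))
}
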