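#' Pseudoknot penalty parameters
#'
#' Coefficients of the affine H-type pseudoknot penalty
#' `G = beta1 + beta2 * B + beta3 * U`, where `beta1` is the cost of
#' introducing a pseudoknot, `beta2` the cost per base pair bordering the
#' pseudoknot interior and `beta3` the cost per unpaired base inside it.
#' The coefficients are experimental data, not model output, so they have
#' no defaults.
#'
#' @param beta1,beta2,beta3 Penalties in kcal/mol.
#' @return An object of class `pseudoknot_params`.
#' @export
pseudoknot_params <- function(beta1, beta2, beta3) {
  vals <- c(beta1, beta2, beta3)
  stopifnot(is.numeric(vals), length(vals) == 3, all(is.finite(vals)))
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3),
            class = "pseudoknot_params")
}

#' Affine pseudoknot free-energy penalty
#'
#' @param n_border_pairs Number of base pairs bordering the pseudoknot
#'   interior (non-negative integer).
#' @param n_unpaired Number of unpaired bases inside the pseudoknot.
#' @param params A [pseudoknot_params()].
#' @return Penalty in kcal/mol: `beta1 + beta2 * n_border_pairs +
#'   beta3 * n_unpaired`.
#' @examples
#' pseudoknot_energy(4, 7, pseudoknot_params(1, 0.5, 0.1))
#' @export
pseudoknot_energy <- function(n_border_pairs, n_unpaired, params) {
  stopifnot(inherits(params, "pseudoknot_params"),
            n_border_pairs >= 0, n_unpaired >= 0,
            n_border_pairs == round(n_border_pairs),
            n_unpaired == round(n_unpaired))
  params$beta1 + params$beta2 * n_border_pairs + params$beta3 * n_unpaired
}

#' Freely-jointed-chain loop parameters
#'
#' Segment lengths of the freely jointed chain used for loop stretching:
#' single-stranded backbone segments of length `a` and helix-crossing
#' segments of length `b`, plus the experimental reference constant `C0`
#' (kcal/mol, default 0).
#'
#' @param a Single-stranded segment length in Angstrom (default 6.2).
#' @param b Helix-crossing segment length in Angstrom (default 15).
#' @param C0 Reference constant in kcal/mol (default 0).
#' @return An object of class `fjc_params`.
#' @export
fjc_params <- function(a = 6.2, b = 15, C0 = 0) {
  stopifnot(is.numeric(a), a > 0, is.numeric(b), b > 0,
            is.numeric(C0), is.finite(C0))
  structure(list(a = a, b = b, C0 = C0), class = "fjc_params")
}

#' Flory radius of a mixed single-strand/helix chain
#'
#' Characteristic end-to-end separation of a self-avoiding chain of `N`
#' single-stranded segments and `M` helix-crossing segments:
#' `R_F = sqrt(N^(6/5) a^2 + M^(6/5) b^2)`.
#'
#' @param N Number of single-stranded segments (>= 0).
#' @param M Number of helix-crossing segments (>= 0); `N + M >= 1`.
#' @param params An [fjc_params()].
#' @return Length in Angstrom, vectorised over `N` and `M`.
#' @examples
#' flory_radius(1, 0)  # = a
#' @export
flory_radius <- function(N, M, params = fjc_params()) {
  stopifnot(inherits(params, "fjc_params"), all(N >= 0), all(M >= 0))
  if (any(N + M < 1)) abort("`N + M` must be >= 1.")
  sqrt(N^(6 / 5) * params$a^2 + M^(6 / 5) * params$b^2)
}

#' Loop-stretching free energy of a freely jointed chain
#'
#' Dimensionless free energy `beta * G(N, M, z)` of stretching a loop of
#' `N` single-stranded and `M` helix-crossing segments to end-to-end
#' separation `z`:
#'
#' \deqn{\beta G = \frac{3}{2}\ln(N^{6/5}a^2 + M^{6/5}b^2) + \beta C_0
#'   - \frac{5}{18}\ln\frac{z - 2.4}{R_F - 2.4}
#'   - (N + M - 2)\ln\frac{Na + Mb - z}{Na + Mb - R_F}
#'   + \Big(\frac{5}{2R_F} + \frac{5}{18(R_F - 2.4)}
#'   - \frac{N + M - 2}{Na + Mb - R_F}\Big)(z - R_F)}
#'
#' The three z-dependent terms vanish identically at `z = R_F`, where
#' `beta G - beta C0 = 3 ln(R_F)`. The constant 2.4 Angstrom is a fixed
#' model constant (the short-distance cutoff of the log term). `beta` is
#' `1/(k_B T)`: the expression is dimensionless only under that reading.
#'
#' @param N,M Segment counts; `N + M >= 2` so the fourth term's prefactor
#'   is meaningful.
#' @param z End-to-end separation in Angstrom; must satisfy
#'   `2.4 < z < N*a + M*b`.
#' @param params An [fjc_params()].
#' @param temperature Temperature in K used to convert `C0` to
#'   dimensionless form (default 310.15).
#' @return Dimensionless `beta * G`.
#' @examples
#' fjc_stretch_free_energy(2, 0, z = flory_radius(2, 0))
#' @export
fjc_stretch_free_energy <- function(N, M, z, params = fjc_params(),
                                    temperature = 310.15) {
  stopifnot(inherits(params, "fjc_params"))
  if (N + M < 2) abort("`N + M` must be >= 2 for the stretching form.")
  a <- params$a
  b <- params$b
  rf <- flory_radius(N, M, params)
  lmax <- N * a + M * b
  if (any(z <= 2.4)) {
    abort("`z` must exceed 2.4 Angstrom (short-distance bound of the log term).")
  }
  if (any(z >= lmax)) {
    abort(sprintf(
      "`z` must be below the contour length N*a + M*b = %.3g Angstrom", lmax))
  }
  beta_c0 <- params$C0 / (.kB * temperature)
  (3 / 2) * log(N^(6 / 5) * a^2 + M^(6 / 5) * b^2) + beta_c0 -
    (5 / 18) * log((z - 2.4) / (rf - 2.4)) -
    (N + M - 2) * log((lmax - z) / (lmax - rf)) +
    (5 / (2 * rf) + 5 / (18 * (rf - 2.4)) - (N + M - 2) / (lmax - rf)) *
      (z - rf)
}

#' Total free energy of a kissing complex
#'
#' Combines the stem free energies with the kissing-loop entropy penalty:
#' `dG = sum(stems) - T * dS`, where the entropy term is supplied as
#' `-T dS` in units of `k_B T` (a positive value is a penalty) and
#' converted to kcal/mol at the stated temperature.
#'
#' @param stem_energies Numeric vector of stem free energies in kcal/mol
#'   (e.g. stem 1, stem 2, kissing stem).
#' @param entropy_term_kBT The entropic penalty `-T dS` in `k_B T` units.
#'   `Inf` (infeasible loop) is propagated to a `+Inf` total.
#' @param temperature Temperature in K (default 310.15, i.e. 37 C).
#' @return An object of class `kf_energy`: a list with `stem_terms`,
#'   `entropy_term_kBT`, `entropy_kcal`, `total` (kcal/mol) and
#'   `temperature`. Has [tidy()] and [glance()] methods.
#' @examples
#' kissing_complex_free_energy(c(-15.7, -15.7, -14.2), 8.62)
#' @export
kissing_complex_free_energy <- function(stem_energies, entropy_term_kBT,
                                        temperature = 310.15) {
  stopifnot(is.numeric(stem_energies), length(stem_energies) >= 1,
            all(is.finite(stem_energies)),
            is.numeric(entropy_term_kBT), length(entropy_term_kBT) == 1)
  entropy_kcal <- entropy_term_kBT * .kB * temperature
  total <- sum(stem_energies) + entropy_kcal
  if (!is.finite(entropy_term_kBT)) {
    warn("entropy term is infinite (infeasible loop); total is +Inf")
    total <- Inf
  }
  structure(list(stem_terms = stem_energies,
                 entropy_term_kBT = entropy_term_kBT,
                 entropy_kcal = entropy_kcal,
                 total = total,
                 temperature = temperature),
            class = "kf_energy")
}

#' @export
print.kf_energy <- function(x, ...) {
  cat("<kf_energy> kissing-complex free energy\n")
  cat("  stems:", paste(sprintf("%.2f", x$stem_terms), collapse = ", "),
      "kcal/mol\n")
  cat(sprintf("  -T dS: %.3g k_BT = %.3g kcal/mol at %.5g K\n",
              x$entropy_term_kBT, x$entropy_kcal, x$temperature))
  cat(sprintf("  total: %.3f kcal/mol\n", x$total))
  invisible(x)
}

#' Nearest-neighbour helix parameters
#'
#' Loads the stacking free-energy/enthalpy table (Turner 2004 set) shipped
#' with the package, or a user file in the same TSV dialect. Stacks are
#' keyed `XW/YZ`, meaning 5'-X W-3' paired with 3'-Y Z-5'; `init` is the
#' duplex initiation term and `terminal_au` the penalty per helix end
#' closed by A-U or G-U.
#'
#' @param path Optional path to a TSV with columns `stack`, `dg37`, `dh`.
#' @return A tibble of class `nn_table`.
#' @export
nn_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_stacks.tsv", package = "kisfold")
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("stack", "dg37", "dh") %in% names(tab)))
  tab <- as_tibble(tab)
  class(tab) <- c("nn_table", class(tab))
  tab
}

.canonical_pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")

is_canonical_pair <- function(x, y) paste0(x, y) %in% .canonical_pairs

nn_value <- function(nn, key, what, temperature) {
  row <- which(nn$stack == key)
  if (length(row) == 0) {
    abort(sprintf("stack `%s` is not in the nearest-neighbour table", key))
  }
  dg37 <- nn$dg37[row[1]]
  dh <- nn$dh[row[1]]
  # dS from dH and dG37; dG(T) = dH - T * dS
  ds <- (dh - dg37) / 310.15
  dh - temperature * ds
}

#' Nearest-neighbour free energy of a helix
#'
#' Sums stacking terms over consecutive base pairs of a duplex, plus the
#' configured initiation and terminal A-U/G-U penalties. Temperatures other
#' than 37 C use the enthalpy column: `dG(T) = dH - T * dS` with `dS`
#' recovered from the 37 C values.
#'
#' @param seq5 Top strand, 5' to 3'.
#' @param seq3 Bottom strand, 3' to 5' (aligned so `seq5[i]` pairs
#'   `seq3[i]`).
#' @param nn An [nn_parameters()] table.
#' @param initiation Include the duplex initiation term (default TRUE).
#' @param terminal_penalty Include terminal A-U/G-U penalties (default TRUE).
#' @param temperature Temperature in K.
#' @return Free energy in kcal/mol.
#' @examples
#' stem_free_energy("GGAC", "CCUG")
#' @export
stem_free_energy <- function(seq5, seq3, nn = nn_parameters(),
                             initiation = TRUE, terminal_penalty = TRUE,
                             temperature = 310.15) {
  s5 <- strsplit(toupper(seq5), "")[[1]]
  s3 <- strsplit(toupper(seq3), "")[[1]]
  if (length(s5) != length(s3)) abort("strands must have equal length")
  n <- length(s5)
  if (n < 1) abort("empty duplex")
  for (i in seq_len(n)) {
    if (!is_canonical_pair(s5[i], s3[i])) {
      abort(sprintf("non-canonical pair %s-%s at position %d",
                    s5[i], s3[i], i))
    }
  }
  e <- 0
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      key <- paste0(s5[i], s5[i + 1], "/", s3[i], s3[i + 1])
      e <- e + nn_value(nn, key, "dg", temperature)
    }
  }
  if (initiation) e <- e + nn_value(nn, "init", "dg", temperature)
  if (terminal_penalty) {
    for (i in c(1, n)) {
      if (paste0(s5[i], s3[i]) %in% c("AU", "UA", "GU", "UG")) {
        e <- e + nn_value(nn, "terminal_au", "dg", temperature)
      }
    }
  }
  e
}
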