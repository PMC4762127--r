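#' Tidy a two-strand partition result
#'
#' @param x A `kf_partition` from [partition_functions()].
#' @param ... Unused.
#' @return A tibble with one row per partition-function component.
#' @export
tidy.kf_partition <- function(x, ...) {
  tibble(component = c("q1", "q2", "q12", "q_total"),
         value = c(x$q1, x$q2, x$q12, x$q_total),
         log_value = c(x$log_q1, x$log_q2, x$log_q12, log(x$q_total)))
}

#' @rdname tidy.kf_partition
#' @export
glance.kf_partition <- function(x, ...) {
  tibble(temperature = x$temperature,
         dg_associate = x$dg_associate,
         bound_fraction = x$bound_fraction,
         q_total = x$q_total)
}

#' Tidy a kissing-complex free-energy breakdown
#'
#' @param x A `kf_energy` from [kissing_complex_free_energy()].
#' @param ... Unused.
#' @return A tibble with one row per free-energy term (kcal/mol).
#' @export
tidy.kf_energy <- function(x, ...) {
  tibble(
    term = c(paste0("stem", seq_along(x$stem_terms)), "entropy"),
    kcal_mol = c(x$stem_terms, x$entropy_kcal))
}

#' @rdname tidy.kf_energy
#' @export
glance.kf_energy <- function(x, ...) {
  tibble(total = x$total, temperature = x$temperature,
         entropy_term_kBT = x$entropy_term_kBT)
}
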