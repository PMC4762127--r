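#' Read RNA sequences from FASTA
#'
#' Wraps `Biostrings::readBStringSet()` and normalises to the uppercase
#' RNA alphabet (T is mapped to U with a warning). Illegal characters are
#' reported with the file line on which they occur.
#'
#' @param path FASTA file path.
#' @return Named character vector of RNA sequences.
#' @export
parse_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    abort(sprintf("cannot parse FASTA %s: %s", path,
                                  conditionMessage(e)))
                  })
  if (length(set) == 0) abort(sprintf("empty FASTA file: %s", path))
  seqs <- as.character(set)
  bad <- grepl("[^AUGCaugcTt]", seqs)
  if (any(bad)) {
    lines <- readLines(path)
    ln <- which(grepl("[^AUGCaugcTt>]", lines) & !startsWith(lines, ">"))[1]
    abort(sprintf("illegal sequence character in %s at line %d", path,
                  if (is.na(ln)) -1L else ln))
  }
  setNames(normalize_rna(seqs), names(set))
}

#' Write RNA sequences to FASTA
#'
#' @param sequences Named (or unnamed) character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a coarse-grained scaffold as PDB
#'
#' One ATOM record per pseudo-atom (names `P` and `C4'`), one chain per
#' strand, TER between chains. Coordinates are written at the standard
#' 1e-3 Angstrom PDB precision.
#'
#' @param scaffold A `kf_scaffold` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scaffold_pdb <- function(scaffold, path) {
  resid <- if (is.null(scaffold$resid)) rep("N", nrow(scaffold)) else scaffold$resid
  con <- file(path, "w")
  on.exit(close(con))
  eleno <- 0
  chains <- unique(scaffold$chain)
  for (ch in chains) {
    sub <- scaffold[scaffold$chain == ch, ]
    rs <- resid[scaffold$chain == ch]
    for (r in seq_len(nrow(sub))) {
      eleno <- eleno + 1
      name <- sub$atom[r]
      padded <- sprintf("%-4s", name)
      writeLines(sprintf(
        "ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        eleno, padded, rs[r], ch, sub$residue[r],
        sub$x[r], sub$y[r], sub$z[r], 1, 0,
        substr(name, 1, 1)), con)
    }
    writeLines(sprintf("TER   %5d      %3s %s%4d", eleno + 1,
                       rs[nrow(sub)], ch, sub$residue[nrow(sub)]), con)
    eleno <- eleno + 1
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a coarse-grained scaffold from PDB
#'
#' Uses `bio3d::read.pdb()` and returns the `kf_scaffold` tibble form.
#'
#' @param path PDB file path.
#' @return A `kf_scaffold` tibble.
#' @export
read_scaffold_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  new_scaffold(tibble(
    chain = a$chain, residue = as.integer(a$resno), atom = a$elety,
    x = a$x, y = a$y, z = a$z, source = NA_character_,
    resid = a$resid))
}

#' Write a free-energy landscape as TSV
#'
#' @param x A `kf_landscape` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landscape_tsv <- function(x, path) {
  df <- as.data.frame(x[, c("native", "nonnative", "free_energy",
                            "probability")])
  names(df) <- c("N", "NN", "free_energy_kcal_mol", "probability")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write lattice site sets as TSV
#'
#' Obstacle and walk site sets are integer triples, one site per row,
#' columns `x`, `y`, `z`.
#'
#' @param sites Integer matrix of sites.
#' @param path File path.
#' @return `write_sites_tsv()`: `path` invisibly; `read_sites_tsv()`: an
#'   integer matrix.
#' @export
write_sites_tsv <- function(sites, path) {
  df <- as.data.frame(rbind(sites))
  names(df) <- c("x", "y", "z")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_tsv
#' @export
read_sites_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path))
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' Default run configuration
#'
#' All tunable model parameters with their defaults, as a nested list:
#' lattice (bond length, enumeration cap), geometry (virtual-bond length,
#' clash distance, helix rise/radius/period), energetics (temperature,
#' FJC constants, C0), ensemble (concentration, initiation, enumeration
#' constraints) and the fixture-generation seed (the only use of
#' randomness in the package).
#'
#' @return Nested list of class `kf_config`.
#' @export
kisfold_config <- function() {
  structure(list(
    lattice = list(bond_length = 3.9, cap = 12L),
    geometry = list(virtual_bond_length = 3.9, clash_distance = 3.5,
                    helix = list(rise = 2.7, radius = 9.9,
                                 bp_per_turn = 11L)),
    energetics = list(temperature = 310.15, c0 = 0,
                      fjc = list(a = 6.2, b = 15)),
    ensemble = list(ct = 1e-6, dg_init = 4.1, min_helix = 3L,
                    min_hairpin = 3L, max_kissing = 1L, cap = 30L),
    seed = 1L), class = "kf_config")
}

#' Load a configuration file
#'
#' Reads a YAML configuration and merges it over the defaults from
#' [kisfold_config()]. Unknown keys are rejected, so typos cannot silently
#' fall back to defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A `kf_config` list.
#' @export
load_config <- function(path = NULL) {
  base <- kisfold_config()
  if (is.null(path)) return(base)
  user <- yaml::read_yaml(path)
  merged <- merge_config(unclass(base), user, prefix = "")
  class(merged) <- "kf_config"
  merged
}

merge_config <- function(base, user, prefix) {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(base)) {
      abort(sprintf("unknown configuration key `%s`", full))
    }
    if (is.list(base[[key]]) && is.list(user[[key]])) {
      base[[key]] <- merge_config(base[[key]], user[[key]],
                                  paste0(full, "."))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' @export
print.kf_config <- function(x, ...) {
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
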