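#' Secondary structure with tertiary (crossing) pairs
#'
#' A secondary structure over one or two RNA strands: an ordered set of
#' base pairs in a global 5'->3' numbering (strand 1 first, then strand 2),
#' each base in at most one pair, pairs restricted to the canonical set
#' A-U, G-C and G-U. Crossing pairs (pseudoknots, kissing interactions)
#' are permitted and flagged rather than forbidden.
#'
#' @param sequences Character vector of 1 or 2 RNA sequences (AUGC; T is
#'   accepted and mapped to U with a warning).
#' @param pairs Two-column matrix or data frame of paired positions in
#'   global 1-based numbering; may have zero rows.
#' @return A `kf_structure`: list with `sequences`, `n` (strand lengths),
#'   and a tibble `pairs` with columns `i`, `j`, `strand_i`, `strand_j`,
#'   `type` (`"intra"`/`"inter"`), `crossing`, `kissing`.
#' @export
kf_structure <- function(sequences, pairs = NULL) {
  sequences <- normalize_rna(sequences)
  if (!length(sequences) %in% 1:2) abort("1 or 2 strands are supported.")
  n <- nchar(sequences)
  total <- sum(n)
  if (is.null(pairs) || NROW(pairs) == 0) {
    pm <- matrix(integer(), ncol = 2)
  } else {
    pm <- as.matrix(as.data.frame(pairs)[, 1:2])
  }
  storage.mode(pm) <- "integer"
  pm <- pm[order(pm[, 1]), , drop = FALSE]
  if (nrow(pm)) {
    if (any(pm < 1) || any(pm > total)) abort("pair index out of range.")
    if (any(pm[, 1] >= pm[, 2])) abort("pairs must satisfy i < j.")
    if (anyDuplicated(c(pm))) abort("a base may appear in at most one pair.")
    bases <- strsplit(paste0(sequences, collapse = ""), "")[[1]]
    bad <- !is_canonical_pair(bases[pm[, 1]], bases[pm[, 2]])
    if (any(bad)) {
      k <- which(bad)[1]
      abort(sprintf("non-canonical pair %s-%s at (%d, %d)",
                    bases[pm[k, 1]], bases[pm[k, 2]], pm[k, 1], pm[k, 2]))
    }
  }
  strand_of <- function(p) ifelse(p <= n[1], 1L, 2L)
  tab <- tibble(
    i = pm[, 1], j = pm[, 2],
    strand_i = strand_of(pm[, 1]), strand_j = strand_of(pm[, 2]))
  tab$type <- ifelse(tab$strand_i == tab$strand_j, "intra", "inter")
  tab$crossing <- pairs_crossing_flags(pm)
  if (nrow(tab) > 0) {
    tab$kissing <- tab$type == "inter" & vapply(seq_len(nrow(tab)),
      function(k) {
        i <- tab$i[k]
        j <- tab$j[k]
        any(tab$type == "intra" & ((tab$i < i & i < tab$j & tab$j < j) |
                                     (i < tab$i & tab$i < j & j < tab$j)))
      }, logical(1))
  } else {
    tab$kissing <- logical(0)
  }
  structure(list(sequences = sequences, n = n, pairs = tab),
            class = "kf_structure")
}

pairs_crossing_flags <- function(pm) {
  k <- nrow(pm)
  if (k == 0) return(logical(0))
  out <- logical(k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      if (pm[a, 1] < pm[b, 1] && pm[b, 1] < pm[a, 2] && pm[a, 2] < pm[b, 2]) {
        out[a] <- TRUE
        out[b] <- TRUE
      }
    }
  }
  out
}

#' @export
print.kf_structure <- function(x, ...) {
  cat(sprintf("<kf_structure> %d strand(s), %s nt, %d pair(s)",
              length(x$sequences), paste(x$n, collapse = "+"),
              nrow(x$pairs)))
  if (any(x$pairs$kissing)) cat(" [kissing]")
  else if (any(x$pairs$crossing)) cat(" [pseudoknot]")
  cat("\n")
  cat(write_dotbracket(x), sep = "\n")
  invisible(x)
}

normalize_rna <- function(sequences) {
  out <- toupper(sequences)
  if (any(grepl("T", out))) {
    warn("T found in input; interpreting as DNA alphabet and mapping T -> U")
    out <- gsub("T", "U", out)
  }
  bad <- grepl("[^AUGC]", out)
  if (any(bad)) {
    pos <- regexpr("[^AUGC]", out[bad][1])
    abort(sprintf("illegal character `%s` in sequence (position %d)",
                  substr(out[bad][1], pos, pos), pos))
  }
  out
}

.bracket_pairs <- c("(" = ")", "[" = "]", "{" = "}", "<" = ">")

#' Parse an extended dot-bracket string
#'
#' Dot-bracket notation with up to four bracket tiers `()`, `[]`, `{}`,
#' `<>` for crossing (pseudoknot/kissing) pairs and `&` separating the
#' strands of a dimer. The bracket string must match the total sequence
#' length; unbalanced brackets are reported with their position.
#'
#' @param dotbracket The structure string, e.g. `"((..[[..))..&..]]"`.
#' @param sequences One or two sequences (character vector, or a single
#'   string containing `&`). If omitted, an all-A placeholder is used
#'   (pair canonicity is then not meaningful, so it is not checked).
#' @return A [kf_structure()].
#' @examples
#' parse_dotbracket("((...))", "GGAAACC")
#' @export
parse_dotbracket <- function(dotbracket, sequences = NULL) {
  parts <- strsplit(dotbracket, "&", fixed = TRUE)[[1]]
  lens <- nchar(parts)
  flat <- paste0(parts, collapse = "")
  if (is.null(sequences)) {
    sequences <- vapply(lens, function(l) strrep("A", l), "")
    check_canonical <- FALSE
  } else {
    if (length(sequences) == 1 && grepl("&", sequences, fixed = TRUE)) {
      sequences <- strsplit(sequences, "&", fixed = TRUE)[[1]]
    }
    check_canonical <- TRUE
    if (!identical(unname(nchar(sequences)), unname(lens))) {
      abort("bracket string length must equal total sequence length (per strand)")
    }
  }
  chars <- strsplit(flat, "")[[1]]
  stacks <- lapply(.bracket_pairs, function(x) integer())
  pm <- matrix(integer(), ncol = 2)
  for (pos in seq_along(chars)) {
    ch <- chars[pos]
    if (ch == ".") next
    if (ch %in% names(.bracket_pairs)) {
      stacks[[ch]] <- c(stacks[[ch]], pos)
    } else if (ch %in% .bracket_pairs) {
      lvl <- names(.bracket_pairs)[match(ch, .bracket_pairs)]
      st <- stacks[[lvl]]
      if (length(st) == 0) {
        abort(sprintf("unbalanced `%s` at position %d", ch, pos))
      }
      pm <- rbind(pm, c(st[length(st)], pos))
      stacks[[lvl]] <- st[-length(st)]
    } else {
      abort(sprintf("illegal structure character `%s` at position %d",
                    ch, pos))
    }
  }
  open <- vapply(stacks, length, 1L)
  if (any(open > 0)) {
    lvl <- names(open)[open > 0][1]
    abort(sprintf("unbalanced `%s`: %d unclosed at end of string",
                  lvl, open[[lvl]]))
  }
  if (!check_canonical && nrow(pm)) {
    # placeholder sequence: substitute a pairable alphabet
    seqs <- sequences
    bases <- strsplit(paste0(seqs, collapse = ""), "")[[1]]
    bases[pm[, 1]] <- "G"
    bases[pm[, 2]] <- "C"
    sequences <- regroup_bases(bases, lens)
  }
  kf_structure(sequences, pm)
}

regroup_bases <- function(bases, lens) {
  stops <- cumsum(lens)
  starts <- c(1, head(stops, -1) + 1)
  vapply(seq_along(lens), function(k) {
    paste0(bases[starts[k]:stops[k]], collapse = "")
  }, "")
}

#' Write an extended dot-bracket string
#'
#' Inverse of [parse_dotbracket()]: assigns each pair the lowest bracket
#' tier on which it crosses no other pair already placed there (greedy in
#' 5'->3' order), and joins strands with `&`.
#'
#' @param structure A [kf_structure()].
#' @return Character vector: the sequence line and the structure line.
#' @export
write_dotbracket <- function(structure) {
  stopifnot(inherits(structure, "kf_structure"))
  total <- sum(structure$n)
  chars <- rep(".", total)
  pm <- as.matrix(structure$pairs[, c("i", "j")])
  lvl_of <- integer(nrow(pm))
  if (nrow(pm)) {
    for (a in seq_len(nrow(pm))) {
      for (lvl in seq_along(.bracket_pairs)) {
        placed <- which(lvl_of == lvl)
        cross <- any(
          (pm[placed, 1] < pm[a, 1] & pm[a, 1] < pm[placed, 2] &
             pm[placed, 2] < pm[a, 2]) |
            (pm[a, 1] < pm[placed, 1] & pm[placed, 1] < pm[a, 2] &
               pm[a, 2] < pm[placed, 2]))
        if (!cross) {
          lvl_of[a] <- lvl
          break
        }
      }
      if (lvl_of[a] == 0) abort("structure needs more than 4 bracket tiers")
      chars[pm[a, 1]] <- names(.bracket_pairs)[lvl_of[a]]
      chars[pm[a, 2]] <- .bracket_pairs[[lvl_of[a]]]
    }
  }
  split_at <- cumsum(structure$n)
  starts <- c(1, head(split_at, -1) + 1)
  db <- paste(vapply(seq_along(starts), function(k) {
    paste0(chars[starts[k]:split_at[k]], collapse = "")
  }, ""), collapse = "&")
  seqline <- paste(structure$sequences, collapse = "&")
  c(seqline, db)
}

# Decompose a pair matrix into helices: maximal runs of stacked pairs
# ((i, j), (i+1, j-1), ...). Returns a list of integer matrices.
pairs_to_helices <- function(pm) {
  if (nrow(pm) == 0) return(list())
  pm <- pm[order(pm[, 1]), , drop = FALSE]
  key <- paste(pm[, 1], pm[, 2])
  used <- logical(nrow(pm))
  helices <- list()
  for (a in seq_len(nrow(pm))) {
    if (used[a]) next
    # walk outward: is (i-1, j+1) present? if so this is not a helix start
    if (paste(pm[a, 1] - 1, pm[a, 2] + 1) %in% key) next
    run <- a
    used[a] <- TRUE
    repeat {
      last <- run[length(run)]
      nxt <- match(paste(pm[last, 1] + 1, pm[last, 2] - 1), key)
      if (is.na(nxt) || used[nxt]) break
      run <- c(run, nxt)
      used[nxt] <- TRUE
    }
    helices[[length(helices) + 1]] <- pm[run, , drop = FALSE]
  }
  helices
}
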