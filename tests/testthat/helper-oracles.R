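# Independent oracles, written against the lattice definition rather than
# the package implementation: plain-R depth-first counters over a flat
# visited vector with an arithmetic site encoding.

oracle_steps <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1),
                       ncol = 3, byrow = TRUE)

oracle_on_A <- function(s) {
  all(s %% 2 == 0) && ((s[1] + s[2] + s[3]) %% 4 + 4) %% 4 == 0
}

oracle_encode <- function(s, L = 45L) {
  (s[1] + L) + (2L * L + 1L) * (s[2] + L) + (2L * L + 1L)^2 * (s[3] + L)
}

# Count self-avoiding walks from `start` to `end` of exactly `n_steps`
# steps avoiding `obstacles` (matrix, one site per row).
oracle_saw_count <- function(start, end, n_steps, obstacles = NULL) {
  visited <- new.env(parent = emptyenv())
  if (!is.null(obstacles) && nrow(rbind(obstacles)) > 0) {
    ob <- rbind(obstacles)
    for (r in seq_len(nrow(ob))) {
      visited[[as.character(oracle_encode(ob[r, ]))]] <- TRUE
    }
  }
  count <- 0L
  rec <- function(site, depth) {
    if (depth == n_steps) {
      if (all(site == end)) count <<- count + 1L
      return(invisible())
    }
    rem <- n_steps - depth
    if (max(abs(end - site)) > rem) return(invisible())
    sgn <- if (oracle_on_A(site)) 1 else -1
    for (k in 1:4) {
      nb <- site + sgn * oracle_steps[k, ]
      key <- as.character(oracle_encode(nb))
      if (isTRUE(visited[[key]])) next
      visited[[key]] <- TRUE
      rec(nb, depth + 1L)
      rm(list = key, envir = visited)
    }
  }
  skey <- as.character(oracle_encode(start))
  visited[[skey]] <- TRUE
  rec(start, 0L)
  count
}

# Random lattice site reached by a short random walk (guarantees a valid
# site of known parity relative to the start).
random_site_offset <- function(start, n_steps) {
  site <- as.integer(start)
  for (k in seq_len(n_steps)) {
    sgn <- if (oracle_on_A(site)) 1L else -1L
    site <- site + sgn * oracle_steps[sample(4, 1), ]
  }
  site
}

random_site <- function(n_steps) random_site_offset(c(0L, 0L, 0L), n_steps)

# Independent pair-level structure enumerator: depth-first over positions
# (each unpaired or paired with a later canonical partner), then filtered
# by the constraint set. Returns a character vector of canonical structure
# keys ("i:j,i:j,...").
oracle_structures <- function(s1, s2, min_helix = 3, min_hairpin = 3,
                              max_kissing = 1) {
  bases <- strsplit(paste0(s1, s2), "")[[1]]
  n1 <- nchar(s1)
  n <- length(bases)
  can <- function(i, j) {
    paste0(bases[i], bases[j]) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  out <- character()
  emit <- function(pairs) {
    if (!oracle_valid(pairs, n1, min_helix, min_hairpin, max_kissing)) {
      return(invisible())
    }
    key <- if (length(pairs) == 0) "" else {
      pm <- do.call(rbind, pairs)
      pm <- pm[order(pm[, 1]), , drop = FALSE]
      paste(paste(pm[, 1], pm[, 2], sep = ":"), collapse = ",")
    }
    out[[length(out) + 1L]] <<- key
  }
  rec <- function(pos, used, pairs) {
    if (pos > n) {
      emit(pairs)
      return(invisible())
    }
    if (used[pos]) {
      rec(pos + 1L, used, pairs)
      return(invisible())
    }
    rec(pos + 1L, used, pairs)  # pos unpaired
    for (j in seq_len(n)) {
      if (j <= pos || used[j] || !can(pos, j)) next
      same <- (pos <= n1) == (j <= n1)
      if (same && (j - pos) <= min_hairpin) next
      used2 <- used
      used2[c(pos, j)] <- TRUE
      rec(pos + 1L, used2, c(pairs, list(c(pos, j))))
    }
  }
  rec(1L, rep(FALSE, n), list())
  unique(out)
}

oracle_valid <- function(pairs, n1, min_helix, min_hairpin, max_kissing) {
  k <- length(pairs)
  if (k == 0) return(TRUE)
  pm <- do.call(rbind, pairs)
  pm <- pm[order(pm[, 1]), , drop = FALSE]
  key <- paste(pm[, 1], pm[, 2])
  strand <- function(p) p <= n1
  # helix decomposition by stacked runs
  run_len <- integer(nrow(pm))
  helix_of <- integer(nrow(pm))
  hid <- 0L
  for (r in seq_len(nrow(pm))) {
    prev <- paste(pm[r, 1] - 1, pm[r, 2] + 1)
    prev_ok <- prev %in% key &&
      strand(pm[r, 1] - 1) == strand(pm[r, 1]) &&
      strand(pm[r, 2] + 1) == strand(pm[r, 2])
    if (!prev_ok) hid <- hid + 1L
    helix_of[r] <- if (prev_ok) helix_of[match(prev, key)] else hid
  }
  for (h in unique(helix_of)) {
    if (sum(helix_of == h) < min_helix) return(FALSE)
  }
  inter <- pm[, 1] <= n1 & pm[, 2] > n1
  kiss <- rep(FALSE, max(helix_of))
  for (a in seq_len(nrow(pm))) {
    for (b in seq_len(nrow(pm))) {
      if (a == b) next
      cross <- pm[a, 1] < pm[b, 1] && pm[b, 1] < pm[a, 2] &&
        pm[a, 2] < pm[b, 2]
      if (!cross) next
      if (inter[a] == inter[b]) return(FALSE)
      kiss[helix_of[if (inter[a]) a else b]] <- TRUE
    }
  }
  sum(kiss) <= max_kissing
}

# Canonical key for a pair matrix, matching oracle_structures().
pairs_key <- function(pm) {
  if (nrow(pm) == 0) return("")
  pm <- pm[order(pm[, 1]), , drop = FALSE]
  paste(paste(pm[, 1], pm[, 2], sep = ":"), collapse = ",")
}

xyz_matrix <- function(scaffold) {
  as.matrix(scaffold[, c("x", "y", "z")])
}

# cached fixture + ensemble shared across test files
fixture_cache <- new.env(parent = emptyenv())

cached_two_minimum <- function() {
  if (is.null(fixture_cache$fx)) {
    fixture_cache$fx <- generate_fixture("two_minimum_dimer", seed = 1)
    fx <- fixture_cache$fx
    fixture_cache$ens <- enumerate_structures(fx$sequences[1],
                                              fx$sequences[2])
  }
  list(fx = fixture_cache$fx, ens = fixture_cache$ens)
}
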