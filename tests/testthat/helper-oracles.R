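# Independent brute-force oracles used to check the dynamic-programming
# folding engine and the exact test. They enumerate candidate solutions
# explicitly and score them with the structure evaluator, never calling the
# DP code paths they validate.

# all non-crossing structures on seq (min hairpin 3), as 1-based partner
# vectors; positions where blocked[i] is TRUE may not pair
enumerate_structures <- function(n, pairable, blocked = logical(n)) {
  # pairable: n x n logical matrix of legal base pairs
  rec <- function(i, j) {
    if (j - i < 4L) return(list(integer(0)))   # too short for any pair
    out <- lapply(rec(i, j - 1L), identity)    # j unpaired
    if (!blocked[j]) {
      for (k in i:(j - 4L)) {
        if (blocked[k] || !pairable[k, j]) next
        left <- rec(i, k - 1L)
        right <- rec(k + 1L, j - 1L)
        for (L in left) for (R in right)
          out[[length(out) + 1L]] <- rbind(matrix(c(k, j), ncol = 2),
                                           if (length(L)) L, if (length(R)) R)
      }
    }
    out
  }
  rec(1L, n)
}

pairable_matrix <- function(chars) {
  ok <- c("AU", "UA", "CG", "GC", "GU", "UG")
  n <- length(chars)
  outer(seq_len(n), seq_len(n),
        Vectorize(function(i, j) paste0(chars[i], chars[j]) %in% ok))
}

# exhaustive minimum free energy; returns list(energy, pairs)
oracle_mfe <- function(seq, model = default_energy_model(),
                       blocked = NULL) {
  chars <- strsplit(toupper(chartr("tT", "uU", as.character(seq))), "")[[1]]
  n <- length(chars)
  if (is.null(blocked)) blocked <- logical(n)
  structs <- enumerate_structures(n, pairable_matrix(chars), blocked)
  best_e <- 0; best <- rep(NA_integer_, n)
  for (st in structs) {
    pr <- rep(NA_integer_, n)
    if (length(st)) {
      pr[st[, 1]] <- st[, 2]
      pr[st[, 2]] <- st[, 1]
    }
    e <- structure_energy(paste(chars, collapse = ""), pr, model)
    if (e < best_e - 1e-12) { best_e <- e; best <- pr }
  }
  list(energy = best_e, pairs = best)
}

# brute-force duplex: enumerate all antiparallel pair chains between two
# strands with per-side gaps <= loop_cap, scored by an independent
# chain-energy evaluator
oracle_duplex <- function(mirna, site, model = default_energy_model(),
                          loop_cap = 4L) {
  m <- strsplit(toupper(chartr("tT", "uU", as.character(mirna))), "")[[1]]
  s <- strsplit(toupper(chartr("tT", "uU", as.character(site))), "")[[1]]
  ok <- c("AU", "UA", "CG", "GC", "GU", "UG")
  auset <- c("AU", "UA", "GU", "UG")
  au <- function(a, b) if (paste0(a, b) %in% auset) model$au_end else 0
  lookup <- function(tab, x) if (x <= length(tab)) tab[x] else tab[length(tab)]

  chain_energy <- function(ii, jj) {
    e <- model$duplex_init + au(m[ii[1]], s[jj[1]])
    k <- length(ii)
    if (k > 1) for (t in 2:k) {
      g1 <- ii[t] - ii[t - 1] - 1L
      g2 <- jj[t - 1] - jj[t] - 1L
      if (g1 == 0L && g2 == 0L) {
        e <- e + model$stack[paste0(m[ii[t - 1]], s[jj[t - 1]]),
                             paste0(m[ii[t]], s[jj[t]])]
      } else {
        lp <- if (g1 == 0L || g2 == 0L) lookup(model$bulge, g1 + g2)
              else lookup(model$internal, g1 + g2)
        e <- e + lp + au(m[ii[t - 1]], s[jj[t - 1]]) + au(m[ii[t]], s[jj[t]])
      }
    }
    e + au(m[ii[k]], s[jj[k]])
  }

  best <- 0   # no binding
  grow <- function(ii, jj) {
    e <- chain_energy(ii, jj)
    if (e < best) best <<- e
    i0 <- ii[length(ii)]; j0 <- jj[length(jj)]
    if (i0 < length(m) && j0 > 1) {
      for (i in (i0 + 1):min(length(m), i0 + 1 + loop_cap))
        for (j in (j0 - 1):max(1, j0 - 1 - loop_cap))
          if (paste0(m[i], s[j]) %in% ok) grow(c(ii, i), c(jj, j))
    }
  }
  for (i in seq_along(m)) for (j in seq_along(s))
    if (paste0(m[i], s[j]) %in% ok) grow(i, j)
  best
}

# two-sided Fisher p by direct factorial enumeration (no dhyper)
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  lprob <- function(x) {
    # log P(table with cell a = x | margins), via lchoose
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  lp <- vapply(support, lprob, numeric(1))
  p <- exp(lp)
  sum(p[p <= exp(lprob(a)) * (1 + 1e-7)])
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                     replace = TRUE), collapse = "")
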