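# Independent reference implementations used as oracles. These deliberately
# re-derive each quantity from its definition by direct loops/enumeration and
# never call the package functions they check.

# adjusted Tanimoto by per-cell scan
tanimoto_oracle <- function(va, vb, std, zero_tol = 1e-12) {
  a <- 0L; b <- 0L; cc <- 0L
  for (i in seq_along(va)) {
    nza <- abs(va[i]) > zero_tol
    nzb <- abs(vb[i]) > zero_tol
    if (nza) a <- a + 1L
    if (nzb) b <- b + 1L
    if (nza && nzb) {
      sim <- if (std[i] > 0) abs(va[i] - vb[i]) < std[i] else va[i] == vb[i]
      if (sim) cc <- cc + 1L
    }
  }
  cc / (a + b - cc)
}

# S(Tc) via the complementary error function (pracma), not via pnorm
s_oracle <- function(tc, mu, sigma, tc0 = mu) {
  sf <- function(x) pracma::erfc((x - mu) / (sigma * sqrt(2))) / 2
  log(sf(tc) / sf(tc0))
}

# mutual-best matching by exhaustive scan of every candidate pair: (i, j) is
# matched iff s[i, j] beats every other entry of row i and of column j under
# the (s asc, raw tc desc, partner name asc) order, and s[i, j] < cutoff
mutual_best_oracle <- function(smat, tmat, names_a, names_b, cutoff) {
  beats <- function(s1, t1, n1, s2, t2, n2) {
    if (s1 != s2) return(s1 < s2)
    if (!identical(t1, t2) && !(is.na(t1) && is.na(t2))) return(t1 > t2)
    n1 < n2
  }
  out <- list()
  for (i in seq_len(nrow(smat))) {
    for (j in seq_len(ncol(smat))) {
      if (!is.finite(smat[i, j]) || smat[i, j] >= cutoff) next
      ok <- TRUE
      for (jj in seq_len(ncol(smat))[-j]) {
        if (is.finite(smat[i, jj]) &&
            !beats(smat[i, j], tmat[i, j], names_b[j],
                   smat[i, jj], tmat[i, jj], names_b[jj])) { ok <- FALSE; break }
      }
      if (ok) for (ii in seq_len(nrow(smat))[-i]) {
        if (is.finite(smat[ii, j]) &&
            !beats(smat[i, j], tmat[i, j], names_a[i],
                   smat[ii, j], tmat[ii, j], names_a[ii])) { ok <- FALSE; break }
      }
      if (ok) out[[length(out) + 1L]] <- c(i = i, j = j)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  as.data.frame(do.call(rbind, out))
}

# AUC by the O(n^2) pairwise comparison definition (more negative = positive)
auc_oracle <- function(scores, positive) {
  ps <- scores[positive]
  ns <- scores[!positive]
  total <- 0
  for (p in ps) {
    for (q in ns) {
      total <- total + if (p < q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(ps) * length(ns))
}

# upper-tail hypergeometric by direct summation of binomial-coefficient
# terms; exact in double precision whenever choose(N, n) < 2^53 (every term
# and the total are bounded by choose(N, n) via the Vandermonde identity),
# otherwise summed on the log scale
hyper_tail_oracle <- function(N, K, n, k) {
  j <- seq.int(max(k, 0, n - (N - K)), min(K, n))
  if (length(j) == 0L) return(0)
  if (choose(N, n) < 2^53) {
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
  } else {
    lt <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
    m <- max(lt)
    exp(m) * sum(exp(lt - m))
  }
}

# random microenvironment set with the given tags: sparse positive vectors
random_mset <- function(tags, n_cells, site_id = "s",
                        support_frac = 0.6) {
  n <- length(tags)
  v <- matrix(0, n, n_cells)
  for (i in seq_len(n)) {
    sup <- sample.int(n_cells, max(2L, round(support_frac * n_cells)))
    v[i, sup] <- 5 + abs(rnorm(length(sup), sd = 2))
  }
  microenvironment_set(v, tags, sprintf("m%d%s/%s", seq_len(n), tags, site_id),
                       site_id = site_id)
}

# lattice-valued microenvironment sets whose cross-pair Tc distribution is
# binomial by construction: fixed support of m cells, values on the odd
# lattice {1, 3, ..., 2K-1}; under unit STDs two cells are similar iff equal,
# with probability 1/K, so c ~ Binomial(m, 1/K) and Tc = c / (2m - c)
lattice_msets <- function(n_sites, m, K, n_cells, tag = "S") {
  support <- seq_len(m)
  lapply(seq_len(n_sites), function(s) {
    v <- matrix(0, 1, n_cells)
    v[1, support] <- 2 * sample.int(K, m, replace = TRUE) - 1
    microenvironment_set(v, tag, sprintf("m1%s/site%d", tag, s),
                         site_id = sprintf("site%d", s))
  })
}
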