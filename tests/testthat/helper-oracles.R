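# Independent oracles, kept deliberately naive: direct substitution into the
# Bernoulli likelihood products (0^0 = 1), explicit threshold loops, and
# exhaustive label enumeration. None of them share code with the package.

pow0 <- function(p, k) if (k == 0) 1 else p^k

oracle_lrt_plain <- function(T_A, T_U, m, l) {
  pA <- T_A / m; pU <- T_U / l; p <- (T_A + T_U) / (m + l)
  num <- pow0(pA, T_A) * pow0(1 - pA, m - T_A) *
         pow0(pU, T_U) * pow0(1 - pU, l - T_U)
  den <- pow0(p, T_A + T_U) * pow0(1 - p, m + l - T_A - T_U)
  log(num / den)
}

oracle_lrt_swapped <- function(T_A, T_U, m, l) {
  pA <- T_A / m; pU <- T_U / l; p <- (T_A + T_U) / (m + l)
  num <- pow0(pU, T_A) * pow0(1 - pU, m - T_A) *
         pow0(pA, T_U) * pow0(1 - pA, l - T_U)
  den <- pow0(p, T_A + T_U) * pow0(1 - p, m + l - T_A - T_U)
  log(num / den)
}

# direction-adjusted form exactly as printed: plain branch when pA > pU
oracle_lrt_adjusted <- function(T_A, T_U, m, l) {
  if (T_A / m > T_U / l) oracle_lrt_plain(T_A, T_U, m, l)
  else oracle_lrt_swapped(T_A, T_U, m, l)
}

# naive threshold maximization (strict exceedance, unique observed values)
oracle_max_lrt <- function(scores, status, adjusted = FALSE) {
  status <- as.logical(status)
  m <- sum(status); l <- sum(!status)
  best <- -Inf
  for (t in sort(unique(scores))) {
    T_A <- sum(scores[status] > t)
    T_U <- sum(scores[!status] > t)
    lam <- if (adjusted) oracle_lrt_adjusted(T_A, T_U, m, l)
           else oracle_lrt_plain(T_A, T_U, m, l)
    if (lam > best) best <- lam
  }
  best
}

# exact permutation p-value by enumeration of all case-index subsets
oracle_perm_p <- function(stat_fn, status, tol = 1e-9) {
  n <- length(status); m <- sum(status == 1L)
  obs <- stat_fn(as.integer(status))
  combs <- utils::combn(n, m)
  hits <- apply(combs, 2, function(idx) {
    st <- integer(n); st[idx] <- 1L
    stat_fn(st) >= obs - tol
  })
  mean(hits)
}

# naive C-alpha statistic
oracle_calpha_T <- function(dos, status) {
  status <- as.logical(status)
  p0 <- mean(status)
  tot <- 0
  for (i in seq_len(ncol(dos))) {
    n_i <- sum(dos[, i])
    y_i <- sum(dos[status, i])
    tot <- tot + (y_i - n_i * p0)^2 - n_i * p0 * (1 - p0)
  }
  tot
}

toy_unit <- function(dosages, gene = "TOY", ...) {
  gene_unit(gene, as.matrix(dosages), ...)
}
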