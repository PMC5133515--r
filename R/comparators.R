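#' CMC (combined multivariate and collapsing) test
#'
#' Classic collapsing comparator: variants with sample MAF below `maf_cut`
#' are collapsed to a single carrier indicator (1 if the sample carries at
#' least one rare minor allele), common variants keep their own dosage
#' columns, constant columns are dropped, and the case/control mean vectors
#' of the resulting design are compared by Hotelling's T². The p-value comes
#' from the same two-stage permutation engine as the LRT methods, so all
#' methods share one null-calibration footing.
#'
#' @param unit a [gene_unit()].
#' @param ph a [phenotype_vector()] or 0/1 vector.
#' @param maf_cut rare/common MAF partition (default 0.01).
#' @param B1,B2,gate,seed,exact see [permute_gene()].
#' @return a `perm_result`.
#' @export
cmc_test <- function(unit, ph, maf_cut = 0.01, B1 = 1000L, B2 = 10000L,
                     gate = 0.1, seed = 1L, exact = FALSE) {
  stopifnot(maf_cut > 0, maf_cut <= 0.5)
  permute_gene(unit, ph, method = "cmc", B1 = B1, B2 = B2, gate = gate,
               seed = seed, maf_cut = maf_cut, exact = exact)
}

#' C-alpha test
#'
#' Variance-component comparator: writing `n_i` for the total minor-allele
#' copies of variant `i`, `y_i` for the copies found in cases, and
#' `p0 = m/(m+l)` for the null case proportion, the statistic is
#' \deqn{T = \sum_i (y_i - n_i p_0)^2 - n_i p_0 (1 - p_0),}
#' which detects overdispersion of per-variant case fractions in either
#' direction (mixtures of protective and deleterious variants). The primary
#' p-value permutes labels and recomputes every `y_i` per replicate; the
#' one-sided normal approximation `Z = T / sqrt(c)` with the binomial
#' variance term
#' \deqn{c = \sum_n k_n \sum_{u=0}^{n} [(u - n p_0)^2 - n p_0 (1-p_0)]^2
#'   \mathrm{Bin}(u; n, p_0)}
#' (`k_n` = number of variants with copy total `n`) is reported for
#' reference only.
#'
#' @inheritParams cmc_test
#' @return a `perm_result` with extras `z`, `p_normal`, `c_variance`.
#' @export
calpha_test <- function(unit, ph, B1 = 1000L, B2 = 10000L, gate = 0.1,
                        seed = 1L, exact = FALSE) {
  permute_gene(unit, ph, method = "calpha", B1 = B1, B2 = B2, gate = gate,
               seed = seed, exact = exact)
}

# rare-collapse + common-dosage design; NULL if everything is constant
cmc_design <- function(dos, maf_cut) {
  n <- nrow(dos)
  maf <- colSums(dos) / (2 * n)
  rare <- maf < maf_cut
  cols <- list()
  if (any(rare))
    cols$carrier <- as.numeric(rowSums(dos[, rare, drop = FALSE]) > 0)
  if (any(!rare))
    cols <- c(cols, as.data.frame(dos[, !rare, drop = FALSE]))
  X <- as.matrix(as.data.frame(cols))
  keep <- apply(X, 2L, function(x) length(unique(x)) > 1L)
  if (!any(keep)) return(NULL)
  X[, keep, drop = FALSE]
}

# Hotelling's T^2 with pooled covariance; pseudo-inverse fallback for
# rank-deficient designs (tiny groups, collinear columns)
hotelling_t2 <- function(X, st) {
  case <- st == 1L
  m <- sum(case); l <- sum(!case)
  if (m < 1L || l < 1L) stop("need both groups")
  d <- colMeans(X[case, , drop = FALSE]) - colMeans(X[!case, , drop = FALSE])
  if (m + l <= 2L) return(sum(d^2))
  Sa <- if (m > 1L) stats::cov(X[case, , drop = FALSE]) else 0 * diag(ncol(X))
  Su <- if (l > 1L) stats::cov(X[!case, , drop = FALSE]) else 0 * diag(ncol(X))
  Sp <- ((m - 1) * Sa + (l - 1) * Su) / (m + l - 2)
  sol <- tryCatch(solve(Sp, d), error = function(e) NULL)
  if (is.null(sol)) {
    sol <- drop(MASS::ginv(Sp) %*% d)
    # mean difference outside the covariance column space: perfect
    # separation along some direction, infinitely large T^2
    if (max(abs(drop(Sp %*% sol) - d)) > 1e-8 * max(1, max(abs(d))))
      return(Inf)
  }
  as.numeric((m * l / (m + l)) * sum(d * sol))
}

calpha_T <- function(dos, st, n_i, p0) {
  y <- colSums(dos[st == 1L, , drop = FALSE])
  sum((y - n_i * p0)^2 - n_i * p0 * (1 - p0))
}

calpha_c <- function(n_i, p0) {
  q0 <- 1 - p0
  total <- 0
  tab <- table(n_i[n_i > 0])
  for (nm in names(tab)) {
    n <- as.integer(nm)
    u <- 0:n
    term <- ((u - n * p0)^2 - n * p0 * q0)^2 * stats::dbinom(u, n, p0)
    total <- total + as.integer(tab[[nm]]) * sum(term)
  }
  total
}
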