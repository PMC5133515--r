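#' Bernoulli likelihood ratio statistic at a fixed threshold
#'
#' Evaluates the gene-level burden LRT statistic from exceedance counts at one
#' threshold. Writing `T_A` and `T_U` for the numbers of cases and controls
#' whose burden score exceeds the threshold, `m` and `l` for the group sizes,
#' and `pA = T_A/m`, `pU = T_U/l`, `p = (T_A+T_U)/(m+l)`, the plain statistic
#' is the log ratio of the two-group Bernoulli likelihood (each group at its
#' own MLE) to the pooled single-Bernoulli likelihood:
#'
#' \deqn{\Lambda = T_A \log pA + (m-T_A)\log(1-pA) + T_U \log pU +
#'   (l-T_U)\log(1-pU) - T \log p - (m+l-T)\log(1-p)}
#'
#' In `"direction-adjusted"` mode the plain form is used when `pA > pU`; when
#' `pA <= pU` the group estimates in the numerator are swapped (cases
#' evaluated at `pU`, controls at `pA`), which yields a non-positive value.
#' All logarithms are natural; the convention `0 * log 0 = 0` applies to
#' every factor. A strictly positive count paired with a zero swapped
#' estimate gives `-Inf`, which is representable and simply never wins a
#' threshold maximization.
#'
#' @param counts list (or [threshold_counts()] result) with elements `T_A`,
#'   `T_U`, `m`, `l`.
#' @param mode `"plain"` (two-group MLE numerator at every configuration) or
#'   `"direction-adjusted"` (swap the group estimates when `pA <= pU`).
#' @return list with `statistic` (finite or `-Inf`) and `branch`
#'   (`"plain"` or `"swapped"`).
#' @examples
#' lrt_at_threshold(list(T_A = 2, T_U = 0, m = 2, l = 2))$statistic # log(16)
#' @export
lrt_at_threshold <- function(counts, mode = c("plain", "direction-adjusted")) {
  mode <- match.arg(mode)
  T_A <- counts$T_A; T_U <- counts$T_U; m <- counts$m; l <- counts$l
  stopifnot(m >= 1, l >= 1, T_A >= 0, T_U >= 0, T_A <= m, T_U <= l)
  if (T_A + T_U > m + l) stop("inconsistent exceedance counts: T > m + l")
  pA <- T_A / m
  pU <- T_U / l
  swapped <- (mode == "direction-adjusted") && (pA <= pU)
  lam <- lrt_lambda(T_A, T_U, m, l, swapped = swapped)
  list(statistic = lam, branch = if (swapped) "swapped" else "plain")
}

#' Exceedance counts at a threshold
#'
#' Counts cases and controls whose burden score strictly exceeds `t`.
#'
#' @param scores numeric burden scores, one per sample.
#' @param status integer/logical case indicator aligned to `scores`.
#' @param t threshold.
#' @return list with `t`, `T_A`, `T_U`, `T`, `m`, `l`, `p_A`, `p_U`, `p`.
#' @export
threshold_counts <- function(scores, status, t) {
  status <- as.logical(status)
  m <- sum(status); l <- sum(!status)
  T_A <- sum(scores[status] > t)
  T_U <- sum(scores[!status] > t)
  list(t = t, T_A = T_A, T_U = T_U, T = T_A + T_U, m = m, l = l,
       p_A = T_A / m, p_U = T_U / l, p = (T_A + T_U) / (m + l))
}

# vectorized log-ratio over threshold grids; 0*log(0) = 0 per factor,
# positive count with zero swapped estimate -> -Inf (never wins the max)
lrt_lambda <- function(T_A, T_U, m, l, swapped = FALSE) {
  tt <- T_A + T_U
  n <- m + l
  pA <- T_A / m
  pU <- T_U / l
  p <- tt / n
  den <- xlogy(tt, p) + xlogy(n - tt, 1 - p)
  if (!swapped) {
    xlogy(T_A, pA) + xlogy(m - T_A, 1 - pA) +
      xlogy(T_U, pU) + xlogy(l - T_U, 1 - pU) - den
  } else {
    xlogy(T_A, pU) + xlogy(m - T_A, 1 - pU) +
      xlogy(T_U, pA) + xlogy(l - T_U, 1 - pA) - den
  }
}

#' Maximize the burden LRT over a threshold grid
#'
#' Evaluates the LRT statistic of [lrt_at_threshold()] at every unique
#' observed burden-score value (thresholding by strict inequality, so these
#' are the only informative grid points) and returns the maximizing
#' configuration. Grid points where nobody or everybody exceeds give
#' `Lambda = 0` by construction, so the maximized plain statistic is always
#' `>= 0`. Ties are broken toward the smallest threshold. Only the ordering
#' and ties of the scores matter: any strictly increasing transform of the
#' scores yields the same result.
#'
#' @param scores numeric burden scores, one per sample.
#' @param status case indicator (1/TRUE = case) aligned to `scores`, or a
#'   `phenotype_vector`.
#' @param mode passed to the statistic: `"plain"` or `"direction-adjusted"`.
#' @return an object of class `lrt_result`: list with `statistic`, `t_star`,
#'   `counts` (exceedance counts at `t_star`), `branch`, `degenerate`.
#' @examples
#' maximize_lrt(c(3, 3, 0, 0), c(1, 1, 0, 0))$statistic # log(16)
#' @export
maximize_lrt <- function(scores, status, mode = c("plain", "direction-adjusted")) {
  mode <- match.arg(mode)
  if (inherits(status, "phenotype_vector")) status <- status$status
  status <- as.integer(as.logical(status))
  stopifnot(length(scores) == length(status))
  m <- sum(status == 1L)
  l <- sum(status == 0L)
  if (m < 1L || l < 1L) stop("need at least one case and one control")
  us <- sort(unique(scores))
  if (length(us) == 1L) {
    cnt <- threshold_counts(scores, status, us[1L])
    res <- list(statistic = 0, t_star = us[1L], counts = cnt,
                branch = "plain", degenerate = TRUE)
    class(res) <- "lrt_result"
    return(res)
  }
  lev <- match(scores, us)
  cc <- tabulate(lev[status == 1L], nbins = length(us))
  ac <- tabulate(lev, nbins = length(us))
  T_A <- m - cumsum(cc)                 # cases with score > us[k]
  T_all <- (m + l) - cumsum(ac)
  T_U <- T_all - T_A
  lam2 <- lrt_lambda(T_A, T_U, m, l, swapped = FALSE)
  if (mode == "plain") {
    lam <- lam2
    branch <- rep("plain", length(us))
  } else {
    swap <- (T_A / m) <= (T_U / l)
    lam4 <- lrt_lambda(T_A, T_U, m, l, swapped = TRUE)
    lam <- ifelse(swap, lam4, lam2)
    branch <- ifelse(swap, "swapped", "plain")
  }
  k <- which.max(lam)                   # first (= smallest t) maximizer
  res <- list(statistic = lam[k],
              t_star = us[k],
              counts = list(t = us[k], T_A = T_A[k], T_U = T_U[k],
                            T = T_A[k] + T_U[k], m = m, l = l,
                            p_A = T_A[k] / m, p_U = T_U[k] / l,
                            p = (T_A[k] + T_U[k]) / (m + l)),
              branch = branch[k],
              degenerate = FALSE)
  class(res) <- "lrt_result"
  res
}

#' @method print lrt_result
#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Burden LRT: Lambda = %.6g at t* = %g (branch %s%s)\n",
              x$statistic, x$t_star, x$branch,
              if (x$degenerate) ", degenerate" else ""))
  cat(sprintf("  exceedance: T_A = %d/%d cases, T_U = %d/%d controls\n",
              x$counts$T_A, x$counts$m, x$counts$T_U, x$counts$l))
  invisible(x)
}

# x * log(y) with 0 * log(0) = 0 (vectorized)
xlogy <- function(x, y) {
  r <- x * log(y)
  r[x == 0] <- 0
  r
}
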