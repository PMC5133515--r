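#' Gene-specific permutation p-value with two-stage early stopping
#'
#' Computes the empirical p-value of a gene-level statistic by permuting
#' case/control labels over all samples and re-running the full pipeline for
#' the chosen method in every replicate: for `"lrt-dir"` the direction
#' weights are refit from the permuted labels (required for type-I error
#' control, since the signs are fitted to the labels); for `"lrt-bs"` the
#' annotation weights are fixed; threshold maximization is redone every
#' replicate. Label permutation preserves the genotype correlation structure
#' within the gene, so dependence among variants is accommodated.
#'
#' The p-value uses the add-one estimator `(1 + #\{Lambda_perm >= Lambda_obs\})
#' / (1 + B)`, with ties counting toward the numerator. Permutation stops
#' after `B1` replicates unless the interim empirical p-value is below
#' `gate` (default 0.1), in which case it continues to `B2` total replicates;
#' the stage-1 replicates are the prefix of the stage-2 stream, so a gene
#' that reaches stage 2 reports exactly the single-stage p-value at `B2`
#' under the same seed.
#'
#' @param unit a [gene_unit()].
#' @param ph a [phenotype_vector()] (or a bare 0/1 vector) aligned to the
#'   unit's samples.
#' @param method one of `"lrt"`, `"lrt-dir"`, `"lrt-bs"`, `"cmc"`,
#'   `"calpha"`.
#' @param B1,B2 stage-1 and total stage-2 replicate counts (`B2 >= B1`).
#' @param gate interim p-value below which stage 2 is entered.
#' @param seed integer seed for this gene's permutation stream.
#' @param scheme annotation weight scheme for `"lrt-bs"` (see
#'   [annotation_weights()]).
#' @param mode LRT statistic form for the weighted methods: `"plain"`
#'   (label-symmetric form at every threshold; default) or
#'   `"direction-adjusted"` (swapped-estimate branch when `p_A <= p_U`,
#'   exactly as printed in the source formulation; see the vignette for why
#'   it is not the default).
#' @param maf_cut rare/common MAF partition for `"cmc"`.
#' @param exact if `TRUE`, enumerate all distinct label assignments
#'   (`choose(n, m)` of them) instead of sampling; the p-value is then the
#'   exact proportion of assignments with a statistic `>= ` observed
#'   (feasible only for small cohorts).
#' @return object of class `perm_result`: `p_value`, `B_used`, `stage`,
#'   `observed`, `t_star` (LRT methods), `degenerate`, `seed`, plus
#'   method-specific extras (`z`, `p_normal` for C-alpha).
#' @export
permute_gene <- function(unit, ph,
                         method = c("lrt", "lrt-dir", "lrt-bs", "cmc", "calpha"),
                         B1 = 1000L, B2 = 10000L, gate = 0.1, seed = 1L,
                         scheme = "bs-10-5-1",
                         mode = c("plain", "direction-adjusted"),
                         maf_cut = 0.01, exact = FALSE) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  stopifnot(B1 >= 1L, B2 >= B1, gate > 0, gate < 1)
  status <- if (inherits(ph, "phenotype_vector")) ph$status else as.integer(ph)
  if (length(status) != nrow(unit$dosages))
    stop("phenotype length does not match unit samples")
  sf <- stat_factory(unit, method, scheme = scheme, mode = mode,
                     maf_cut = maf_cut, status = status)
  if (sf$degenerate) {
    res <- list(p_value = 1, B_used = 0L, stage = 1L,
                observed = 0, t_star = NA_real_, degenerate = TRUE,
                seed = seed, method = method)
    class(res) <- "perm_result"
    return(res)
  }
  res <- perm_engine(sf$stat, status, B1 = B1, B2 = B2, gate = gate,
                     seed = seed, exact = exact)
  res$t_star <- sf$t_star
  res$degenerate <- FALSE
  res$method <- method
  res <- c(res, sf$extras)
  class(res) <- "perm_result"
  res
}

#' @method print perm_result
#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (stage %d, B = %d%s)\n",
              toupper(x$method), x$observed, x$p_value, x$stage, x$B_used,
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}

# Builds the per-replicate statistic closure for a method. Returns the
# closure, the observed t* where defined, a degeneracy flag and extras.
stat_factory <- function(unit, method, scheme, mode, maf_cut, status) {
  dos <- unit$dosages
  if (all(apply(dos, 2L, function(x) length(unique(x)) == 1L)))
    return(list(degenerate = TRUE))
  t_star <- NA_real_
  extras <- NULL
  if (method %in% c("lrt", "lrt-bs")) {
    w <- if (method == "lrt") unit_weights(unit)
         else annotation_weights(unit, scheme)
    scores <- burden_scores(unit, w)
    lmode <- if (method == "lrt") "plain" else mode
    stat <- make_threshold_stat(scores, lmode)
    obs <- maximize_lrt(scores, status, mode = lmode)
    if (obs$degenerate) return(list(degenerate = TRUE))
    t_star <- obs$t_star
  } else if (method == "lrt-dir") {
    stat <- function(st) {
      w <- direction_weights_raw(dos, st)
      max_lrt_stat(drop(dos %*% w), st, mode)
    }
    obsw <- direction_weights(unit, status)
    obs <- maximize_lrt(burden_scores(unit, obsw), status, mode = mode)
    t_star <- obs$t_star
  } else if (method == "cmc") {
    X <- cmc_design(dos, maf_cut)
    if (is.null(X)) return(list(degenerate = TRUE))
    stat <- function(st) hotelling_t2(X, st)
  } else { # calpha
    n_i <- colSums(dos)
    if (all(n_i == 0)) return(list(degenerate = TRUE))
    m <- sum(status == 1L)
    p0 <- m / length(status)
    stat <- function(st) calpha_T(dos, st, n_i, p0)
    cvar <- calpha_c(n_i, p0)
    Tobs <- calpha_T(dos, status, n_i, p0)
    z <- Tobs / sqrt(cvar)
    extras <- list(z = z, p_normal = stats::pnorm(z, lower.tail = FALSE),
                   c_variance = cvar)
  }
  list(stat = stat, degenerate = FALSE, t_star = t_star, extras = extras)
}

# Shared engine: two-stage Monte-Carlo or exhaustive enumeration.
perm_engine <- function(stat_fn, status, B1, B2, gate, seed, exact = FALSE,
                        tol = 1e-9) {
  obs <- stat_fn(status)
  n <- length(status)
  if (exact) {
    m <- sum(status == 1L)
    combs <- utils::combn(n, m)
    vals <- apply(combs, 2L, function(idx) {
      st <- integer(n); st[idx] <- 1L; stat_fn(st)
    })
    return(list(p_value = mean(vals >= obs - tol), B_used = ncol(combs),
                stage = 1L, observed = obs, seed = NA_integer_))
  }
  set.seed(seed)
  count <- 0L
  for (b in seq_len(B1))
    if (stat_fn(sample(status)) >= obs - tol) count <- count + 1L
  p1 <- (1 + count) / (1 + B1)
  if (p1 >= gate || B2 == B1)
    return(list(p_value = p1, B_used = B1, stage = 1L, observed = obs,
                seed = seed))
  for (b in seq_len(B2 - B1))
    if (stat_fn(sample(status)) >= obs - tol) count <- count + 1L
  list(p_value = (1 + count) / (1 + B2), B_used = B2, stage = 2L,
       observed = obs, seed = seed)
}

# Fast maximized-LRT closure for scores that are fixed across replicates:
# the score-level encoding is precomputed, each call only re-tabulates
# case counts per level.
make_threshold_stat <- function(scores, mode) {
  us <- sort(unique(scores))
  nlev <- length(us)
  lev <- match(scores, us)
  ac_cum <- cumsum(tabulate(lev, nbins = nlev))
  n <- length(scores)
  directional <- mode == "direction-adjusted"
  function(st) {
    case <- st == 1L
    m <- sum(case); l <- n - m
    T_A <- m - cumsum(tabulate(lev[case], nbins = nlev))
    T_U <- (n - ac_cum) - T_A
    lam <- lrt_lambda(T_A, T_U, m, l, swapped = FALSE)
    if (directional) {
      swap <- (T_A / m) <= (T_U / l)
      if (any(swap))
        lam[swap] <- lrt_lambda(T_A[swap], T_U[swap], m, l, swapped = TRUE)
    }
    max(lam)
  }
}

max_lrt_stat <- function(scores, st, mode) {
  make_threshold_stat(scores, mode)(st)
}

# direction signs without gene_unit overhead (hot path of lrt-dir)
direction_weights_raw <- function(dos, st) {
  case <- st == 1L
  f_case <- colSums(dos[case, , drop = FALSE]) / (2 * sum(case))
  f_ctrl <- colSums(dos[!case, , drop = FALSE]) / (2 * sum(!case))
  ifelse(f_case <= f_ctrl, 1, -1)
}

#' Run a method over all gene units
#'
#' Batch driver: applies [permute_gene()] to every unit with a per-gene seed
#' derived reproducibly from the master seed and the gene symbol, so results
#' do not depend on processing order and the comparator methods consume the
#' identical per-gene permutation streams as the LRT methods.
#'
#' @param units named list of [gene_unit()] objects.
#' @param ph a [phenotype_vector()] aligned to the units.
#' @param method,B1,B2,gate,scheme,mode,maf_cut,exact see [permute_gene()].
#' @param seed master integer seed.
#' @return data.frame with columns `gene`, `statistic`, `p_value`, `stage`,
#'   `b_used`, `t_star`, `n_variants`, `degenerate`.
#' @export
run_all_genes <- function(units, ph, method = "lrt", B1 = 1000L, B2 = 10000L,
                          gate = 0.1, seed = 1L, scheme = "bs-10-5-1",
                          mode = "plain", maf_cut = 0.01, exact = FALSE) {
  if (length(units) == 0L)
    return(data.frame(gene = character(0), statistic = numeric(0),
                      p_value = numeric(0), stage = integer(0),
                      b_used = integer(0), t_star = numeric(0),
                      n_variants = integer(0), degenerate = logical(0)))
  rows <- lapply(units, function(u) {
    r <- permute_gene(u, ph, method = method, B1 = B1, B2 = B2, gate = gate,
                      seed = derive_seed(seed, u$gene), scheme = scheme,
                      mode = mode, maf_cut = maf_cut, exact = exact)
    data.frame(gene = u$gene, statistic = r$observed, p_value = r$p_value,
               stage = r$stage, b_used = r$B_used, t_star = r$t_star,
               n_variants = ncol(u$dosages), degenerate = r$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Folds the label's characters into a 31-bit polynomial hash combined with
#' the master seed; used for per-gene and per-replicate streams.
#'
#' @param seed master integer seed.
#' @param label character label (e.g. a gene symbol).
#' @return integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (code in utf8ToInt(as.character(label)))
    h <- (h * 31 + code) %% mod
  as.integer((h %% (mod - 1)) + 1)
}
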