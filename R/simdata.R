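#' Gene specification for the cohort simulator
#'
#' Describes one simulated gene: its variant count, minor-allele-frequency
#' spectrum, and causal architecture. Archetypes mirror the qualitative gene
#' types used to evaluate weighting schemes: a strong protective gene, a weak
#' gene, a strong deleterious gene, a null gene, and a "cancellation" gene
#' carrying balanced protective and deleterious variants of equal magnitude
#' (the configuration that defeats unweighted burden collapsing). Default
#' effect magnitudes are `log(3)` per minor allele for strong effects and
#' `log(1.3)` for weak ones, on the log-odds scale.
#'
#' Causal variants occupy the first `n_causal` positions of the gene, and the
#' first `n_annotated` of them (by position) are marked `"functional"` in the
#' annotation table — everything else is `"rest"` — emulating incomplete
#' functional annotation.
#'
#' @param name gene symbol.
#' @param archetype one of `"protective-strong"`, `"weak"`,
#'   `"deleterious-strong"`, `"cancellation"`, `"null"`.
#' @param n_variants number of variants on the gene.
#' @param n_causal number of causal variants (0 for `"null"`).
#' @param beta per-causal log-odds effects; defaults by archetype (recycled
#'   if scalar). For `"cancellation"` the default is half `-log(3)`, half
#'   `+log(3)`.
#' @param n_annotated causal variants marked as annotated (default
#'   `min(10, n_causal)`).
#' @param maf_alpha,maf_beta,maf_range Beta(`maf_alpha`, `maf_beta`) MAF
#'   spectrum truncated to `maf_range` (default a rare spectrum on
#'   (0.001, 0.05)).
#' @return object of class `gene_spec`.
#' @export
gene_spec <- function(name,
                      archetype = c("null", "protective-strong", "weak",
                                    "deleterious-strong", "cancellation"),
                      n_variants = 30L,
                      n_causal = if (archetype == "null") 0L else 15L,
                      beta = NULL,
                      n_annotated = min(10L, n_causal),
                      maf_alpha = 0.5, maf_beta = 8,
                      maf_range = c(0.001, 0.05)) {
  archetype <- match.arg(archetype)
  stopifnot(n_causal <= n_variants, n_annotated <= max(n_causal, 0L),
            maf_range[1] > 0, maf_range[2] < 0.5)
  if (is.null(beta)) {
    beta <- switch(archetype,
                   "null" = numeric(0),
                   "protective-strong" = rep(-log(3), n_causal),
                   "weak" = rep(log(1.3), n_causal),
                   "deleterious-strong" = rep(log(3), n_causal),
                   "cancellation" = rep(c(-log(3), log(3)),
                                        length.out = n_causal))
  }
  beta <- rep_len(as.numeric(beta), n_causal)
  structure(list(name = name, archetype = archetype,
                 n_variants = as.integer(n_variants),
                 n_causal = as.integer(n_causal), beta = beta,
                 n_annotated = as.integer(n_annotated),
                 maf_alpha = maf_alpha, maf_beta = maf_beta,
                 maf_range = maf_range),
            class = "gene_spec")
}

#' Simulation configuration
#'
#' @param genes list of [gene_spec()] objects.
#' @param n_samples cohort size (default 2000, echoing an exome cohort of
#'   order 10^3 with a few hundred cases).
#' @param case_fraction target case proportion; the logistic intercept is
#'   calibrated on the realized genetic scores so the expected case fraction
#'   matches (default 0.17).
#' @param intercept fixed logistic intercept, overriding `case_fraction`.
#' @param seed master seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(genes, n_samples = 2000L, case_fraction = 0.17,
                       intercept = NULL, seed = 1L) {
  stopifnot(length(genes) >= 1L, n_samples >= 2L)
  if (is.null(intercept))
    stopifnot(case_fraction > 0, case_fraction < 1)
  structure(list(genes = genes, n_samples = as.integer(n_samples),
                 case_fraction = case_fraction, intercept = intercept,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a case-control exome cohort
#'
#' Per variant, a MAF is drawn from the gene's truncated Beta spectrum and
#' dosages are Binomial(2, MAF) under Hardy-Weinberg equilibrium, with
#' variants in linkage equilibrium. Disease status is Bernoulli with
#' `logit P(case) = intercept + sum_i beta_i x_i` over causal variants. The
#' annotation table marks the first `n_annotated` causal variants of each
#' gene `"functional"` and all remaining variants `"rest"`. Deterministic
#' given `(cfg, replicate)`.
#'
#' @param cfg a [sim_config()].
#' @param replicate replicate index (distinct replicates give independent
#'   cohorts under one master seed).
#' @return list with `genotypes` ([genotype_matrix()]), `phenotype`
#'   ([phenotype_vector()]), `annotation` (data.frame `variant_id`,
#'   `category`), `maf` (drawn frequencies), `intercept`.
#' @export
simulate_cohort <- function(cfg, replicate = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, paste0("cohort:", replicate)))
  n <- cfg$n_samples
  dos_all <- list(); meta_all <- list(); ann_all <- list()
  maf_all <- numeric(0)
  eta <- numeric(n)
  pos0 <- 0L
  for (g in cfg$genes) {
    lo <- stats::pbeta(g$maf_range[1], g$maf_alpha, g$maf_beta)
    hi <- stats::pbeta(g$maf_range[2], g$maf_alpha, g$maf_beta)
    if (hi <= lo) stop("degenerate MAF spectrum for gene ", g$name)
    maf <- stats::qbeta(stats::runif(g$n_variants, lo, hi),
                        g$maf_alpha, g$maf_beta)
    dos <- matrix(stats::rbinom(n * g$n_variants, 2L, rep(maf, each = n)),
                  nrow = n)
    vid <- sprintf("%s:v%03d", g$name, seq_len(g$n_variants))
    if (g$n_causal > 0L)
      eta <- eta + drop(dos[, seq_len(g$n_causal), drop = FALSE] %*% g$beta)
    cat_g <- rep("rest", g$n_variants)
    if (g$n_annotated > 0L) cat_g[seq_len(g$n_annotated)] <- "functional"
    dos_all[[g$name]] <- dos
    meta_all[[g$name]] <- data.frame(
      variant_id = vid, chrom = "1",
      pos = pos0 + seq_len(g$n_variants) * 100L,
      ref = "A", alt = "T", gene = g$name, stringsAsFactors = FALSE)
    ann_all[[g$name]] <- data.frame(variant_id = vid, category = cat_g,
                                    stringsAsFactors = FALSE)
    maf_all <- c(maf_all, maf)
    pos0 <- pos0 + g$n_variants * 100L + 10000L
  }
  intercept <- if (!is.null(cfg$intercept)) cfg$intercept else
    stats::uniroot(function(c0) mean(stats::plogis(c0 + eta)) - cfg$case_fraction,
                   c(-30, 30), tol = 1e-10)$root
  status <- stats::rbinom(n, 1L, stats::plogis(intercept + eta))
  ids <- sprintf("S%04d", seq_len(n))
  gm <- genotype_matrix(do.call(cbind, dos_all), ids, do.call(rbind, meta_all))
  list(genotypes = gm,
       phenotype = phenotype_vector(ids, status),
       annotation = do.call(rbind, c(ann_all, list(make.row.names = FALSE))),
       maf = maf_all, intercept = intercept)
}

#' The evaluated annotation weight-scheme grid
#'
#' The six (functional, rest) weight combinations
#' \{2, 5, 10\} x \{1, -1\}, optionally preceded by the unweighted baseline.
#'
#' @param include_baseline prepend the unweighted scheme.
#' @return named list of schemes (named numeric vectors
#'   `c(functional = , rest = )`).
#' @export
weight_scheme_grid <- function(include_baseline = TRUE) {
  grid <- list()
  if (include_baseline)
    grid[["unweighted"]] <- c(functional = 1, rest = 1)
  for (f in c(2, 5, 10))
    for (r in c(1, -1))
      grid[[sprintf("f%g-r%g", f, r)]] <- c(functional = f, rest = r)
  grid
}

#' Power / type-I-error study over methods and weight schemes
#'
#' For each replicate, simulates a fresh cohort from `cfg`, runs every
#' requested method (and, for `"lrt-bs"`, every weight scheme) on every gene
#' through the two-stage permutation engine, and tallies rejections at level
#' `alpha`. On null-archetype genes the estimated "power" is the empirical
#' type-I error. All methods and schemes share identical per-gene permutation
#' seed streams within a replicate.
#'
#' @param cfg a [sim_config()].
#' @param methods character vector of methods (see [permute_gene()]).
#' @param schemes named list of annotation weight schemes, used by
#'   `"lrt-bs"` only (default the built-in grid with baseline).
#' @param alpha significance level.
#' @param R number of replicates.
#' @param B1,B2,gate permutation parameters (study-scale defaults 99/999).
#' @param seed master seed for cohorts and permutations.
#' @param mode LRT statistic form (see [permute_gene()]).
#' @return data.frame (`PowerTable`) with columns `gene`, `archetype`,
#'   `method`, `scheme`, `alpha`, `power`, `mc_se`, `replicates`.
#' @export
power_study <- function(cfg, methods = c("lrt", "lrt-dir", "lrt-bs"),
                        schemes = weight_scheme_grid(), alpha = 0.05,
                        R = 100L, B1 = 99L, B2 = 999L, gate = 0.1,
                        seed = 1L, mode = "plain") {
  stopifnot(R >= 1L, alpha > 0, alpha < 1)
  cfg$seed <- as.integer(seed)
  arms <- list()
  for (mth in methods) {
    if (mth == "lrt-bs") {
      for (sn in names(schemes))
        arms[[paste(mth, sn)]] <- list(method = mth, scheme_name = sn,
                                       scheme = schemes[[sn]])
    } else {
      arms[[mth]] <- list(method = mth, scheme_name = NA_character_,
                          scheme = NULL)
    }
  }
  genes <- vapply(cfg$genes, `[[`, "", "name")
  arche <- vapply(cfg$genes, `[[`, "", "archetype")
  rej <- array(0L, dim = c(length(genes), length(arms)),
               dimnames = list(genes, names(arms)))
  for (r in seq_len(R)) {
    coh <- simulate_cohort(cfg, replicate = r)
    units <- build_gene_units(coh$genotypes, coh$phenotype, coh$annotation)
    for (g in genes) {
      gseed <- derive_seed(seed, paste0("perm:", r, ":", g))
      for (an in names(arms)) {
        a <- arms[[an]]
        res <- permute_gene(units[[g]], coh$phenotype, method = a$method,
                            B1 = B1, B2 = B2, gate = gate, seed = gseed,
                            scheme = if (is.null(a$scheme)) "bs-10-5-1" else a$scheme,
                            mode = mode)
        if (res$p_value <= alpha) rej[g, an] <- rej[g, an] + 1L
      }
    }
  }
  rows <- list()
  for (g in seq_along(genes))
    for (an in names(arms)) {
      p <- rej[g, an] / R
      rows[[length(rows) + 1L]] <- data.frame(
        gene = genes[g], archetype = arche[g],
        method = arms[[an]]$method, scheme = arms[[an]]$scheme_name,
        alpha = alpha, power = p, mc_se = sqrt(p * (1 - p) / R),
        replicates = R, stringsAsFactors = FALSE)
    }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
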