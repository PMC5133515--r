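#' Weighted burden scores for one gene
#'
#' Collapses a gene's variants into one score per sample:
#' `S_k = sum_i s_i * x_ik`, where `x_ik` is the minor-allele dosage of
#' variant `i` in sample `k` and `s_i` the per-variant weight. With unit
#' weights this is the classic burden score (row sum of the dosage
#' sub-matrix); direction signs or annotation magnitudes plug in as `s_i`.
#'
#' @param unit a `gene_unit` (see [build_gene_units()]).
#' @param w numeric weight vector aligned to the unit's variant order
#'   (typically from [unit_weights()], [direction_weights()] or
#'   [annotation_weights()]). Defaults to unit weights.
#' @return numeric vector of per-sample scores.
#' @examples
#' u <- gene_unit("G", matrix(c(1, 0, 2), 1, 3))
#' burden_scores(u, c(10, 5, 1)) # 12
#' @export
burden_scores <- function(unit, w = unit_weights(unit)) {
  if (length(w) != ncol(unit$dosages))
    stop("weight vector length ", length(w), " does not match n_j = ",
         ncol(unit$dosages))
  drop(unit$dosages %*% as.numeric(w))
}

#' Unit weights (plain burden)
#'
#' @param unit a `gene_unit`.
#' @return weight vector of ones, provenance `"UNIT"`.
#' @export
unit_weights <- function(unit) {
  weight_vector(rep(1, ncol(unit$dosages)), "UNIT")
}

#' Effect-direction weights
#'
#' Assigns each variant a sign from the comparison of its minor-allele
#' frequency in cases (`f_A = case allele count / 2m`) against controls
#' (`f_U`): `s_i = +1` if `f_A <= f_U` (control-enriched or tied, including
#' monomorphic variants where both frequencies are 0) and `s_i = -1`
#' otherwise. This flips all apparent effect directions to one side so that
#' protective and deleterious variants no longer cancel in the burden sum.
#' Because the signs are fitted to the labels, they must be recomputed from
#' the permuted labels inside every permutation replicate (the permutation
#' engine does this for method `"lrt-dir"`).
#'
#' @param unit a `gene_unit`.
#' @param status case indicator aligned to the unit's samples, or a
#'   `phenotype_vector`.
#' @return numeric vector of +1/-1 weights, provenance `"DIRECTION"`.
#' @export
direction_weights <- function(unit, status) {
  if (inherits(status, "phenotype_vector")) status <- status$status
  status <- as.logical(status)
  m <- sum(status); l <- sum(!status)
  if (m < 1L || l < 1L) stop("need at least one case and one control")
  dos <- unit$dosages
  f_case <- colSums(dos[status, , drop = FALSE]) / (2 * m)
  f_ctrl <- colSums(dos[!status, , drop = FALSE]) / (2 * l)
  weight_vector(ifelse(f_case <= f_ctrl, 1, -1), "DIRECTION")
}

#' Annotation-based weights
#'
#' Maps each variant's annotation category to a numeric multiplier. The
#' built-in scheme `"bs-10-5-1"` assigns 10 to non-synonymous variants in a
#' predicted protein-binding site (`BS`), 5 to non-synonymous variants
#' outside binding sites (`NSSNV_NONBS`) and 1 to everything else (`OTHER`).
#' Arbitrary schemes are named numeric vectors (category -> weight), e.g.
#' `c(functional = 10, rest = 1)`. An explicit per-variant weight stored in
#' the unit overrides the scheme for that variant.
#'
#' @param unit a `gene_unit` carrying annotation categories.
#' @param scheme named numeric vector, or the name of a built-in scheme
#'   (currently `"bs-10-5-1"`).
#' @return numeric weight vector, provenance `"ANNOTATION"`.
#' @examples
#' u <- gene_unit("G", matrix(0, 1, 3),
#'                categories = c("BS", "NSSNV_NONBS", "OTHER"))
#' annotation_weights(u) # 10 5 1
#' @export
annotation_weights <- function(unit, scheme = "bs-10-5-1") {
  if (is.character(scheme) && length(scheme) == 1L) {
    scheme <- switch(scheme,
                     "bs-10-5-1" = c(BS = 10, NSSNV_NONBS = 5, OTHER = 1),
                     stop("unknown named weight scheme: ", scheme))
  }
  if (is.null(names(scheme)) || !is.numeric(scheme))
    stop("a weight scheme is a named numeric vector (category -> weight)")
  cat_w <- scheme[unit$categories]
  unknown <- unit$categories[is.na(cat_w)]
  explicit <- unit$weights
  if (!is.null(explicit)) cat_w[!is.na(explicit)] <- explicit[!is.na(explicit)]
  if (anyNA(cat_w))
    stop("categories without a weight in the scheme: ",
         paste(unique(unknown), collapse = ", "))
  weight_vector(unname(cat_w), "ANNOTATION")
}

weight_vector <- function(w, provenance) {
  structure(as.numeric(w), provenance = provenance)
}
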