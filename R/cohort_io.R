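#' Construct a genotype matrix
#'
#' Container for per-sample minor-allele dosages with per-variant metadata.
#' Dosages are integers in \{0, 1, 2\} (copies of the minor allele) with `NA`
#' marking missing genotypes.
#'
#' @param dosages integer matrix, samples in rows, variants in columns.
#' @param sample_ids character vector of row identifiers.
#' @param variant_meta data.frame with one row per variant column:
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `gene` (gene may be `NA`).
#' @param log list of parsing bookkeeping (missing counts, flipped variants).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids, variant_meta,
                            log = list(n_missing = sum(is.na(dosages)),
                                       flipped = character(0))) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) == length(sample_ids),
            ncol(dosages) == nrow(variant_meta))
  ok <- is.na(dosages) | dosages %in% c(0L, 1L, 2L)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(variant_meta$variant_id))
    stop("variant_ids must be unique")
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variant_meta$variant_id
  structure(list(dosages = dosages, sample_ids = sample_ids,
                 variant_meta = variant_meta, log = log),
            class = "genotype_matrix")
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d genes, %d missing calls)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(stats::na.omit(x$variant_meta$gene))),
              x$log$n_missing))
  invisible(x)
}

#' Read genotypes from VCF or the variant-by-sample TSV dialect
#'
#' For VCF input only the GT field is used; multi-allelic records are split
#' into one dosage column per alternate allele, each keyed
#' `chrom:pos:ref:alt`. After parsing, any variant whose alternate-allele
#' sample frequency exceeds 0.5 is flipped (`2 - x`) so that dosages always
#' count the minor allele; flipped keys are recorded in the parse log, as is
#' the number of missing genotype calls.
#'
#' The TSV dialect has header `variant_id chrom pos ref alt gene s1 s2 ...`,
#' one row per variant, dosage cells in `{0, 1, 2, .}` (`.` = missing).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param gene_map optional variant-to-gene map for VCF input (which carries
#'   no gene column): a data.frame or TSV path with columns
#'   `variant_id, gene` or `chrom, pos, ref, alt, gene`. A variant mapped to
#'   two genes appears as two columns, one per gene, with the gene appended
#'   to the key.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           gene_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  gm <- if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
  if (!is.null(gene_map)) gm <- apply_gene_map(gm, gene_map)
  gm
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("variant_id", "chrom", "pos", "ref", "alt", "gene")
  if (!identical(names(df)[seq_along(need)], need))
    stop("tsv-matrix header must start with: ", paste(need, collapse = " "))
  sample_ids <- names(df)[-seq_along(need)]
  if (length(sample_ids) == 0L) stop("tsv-matrix has zero sample columns")
  cells <- as.matrix(df[, sample_ids, drop = FALSE])
  bad <- !(cells %in% c("0", "1", "2", "."))
  dim(bad) <- dim(cells)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed dosage cell at data line %d, sample %s: '%s'",
                 idx[1], sample_ids[idx[2]], cells[idx[1], idx[2]]))
  }
  dos <- suppressWarnings(matrix(as.integer(cells), nrow = nrow(cells)))
  meta <- data.frame(variant_id = df$variant_id, chrom = df$chrom,
                     pos = as.integer(df$pos), ref = df$ref, alt = df$alt,
                     gene = ifelse(df$gene == "" | df$gene == ".", NA, df$gene),
                     stringsAsFactors = FALSE)
  genotype_matrix(t(dos), sample_ids, meta)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) stop("VCF has no sample GT fields")
  sample_ids <- colnames(gt)
  cols <- list(); meta <- list()
  for (r in seq_len(nrow(gt))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gt[r, ], "[/|]")
    for (a in seq_along(alts)) {
      dos <- vapply(alleles, function(al) {
        if (length(al) == 0L || anyNA(al) || any(al == "."))
          return(NA_integer_)
        if (!all(grepl("^[0-9]+$", al)))
          stop("malformed GT at VCF record ", r)
        sum(al == as.character(a))
      }, integer(1))
      cols[[length(cols) + 1L]] <- dos
      meta[[length(meta) + 1L]] <- data.frame(
        variant_id = paste(fix[r, "CHROM"], fix[r, "POS"],
                           fix[r, "REF"], alts[a], sep = ":"),
        chrom = fix[r, "CHROM"], pos = as.integer(fix[r, "POS"]),
        ref = fix[r, "REF"], alt = alts[a], gene = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  dosages <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  # orient to the minor allele
  flipped <- character(0)
  for (j in seq_len(ncol(dosages))) {
    x <- dosages[, j]
    f <- sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))
    if (is.finite(f) && f > 0.5) {
      dosages[, j] <- 2L - x
      flipped <- c(flipped, meta$variant_id[j])
    }
  }
  genotype_matrix(dosages, sample_ids, meta,
                  log = list(n_missing = sum(is.na(dosages)),
                             flipped = flipped))
}

apply_gene_map <- function(gm, gene_map) {
  if (is.character(gene_map) && length(gene_map) == 1L)
    gene_map <- utils::read.delim(gene_map, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  if (!"gene" %in% names(gene_map)) stop("gene map needs a 'gene' column")
  key <- if ("variant_id" %in% names(gene_map)) gene_map$variant_id
         else paste(gene_map$chrom, gene_map$pos, gene_map$ref,
                    gene_map$alt, sep = ":")
  hit <- lapply(gm$variant_meta$variant_id, function(v) which(key == v))
  keep <- integer(0); genes <- character(0)
  for (j in seq_along(hit)) {
    if (length(hit[[j]]) == 0L) { keep <- c(keep, j); genes <- c(genes, NA) }
    else { keep <- c(keep, rep(j, length(hit[[j]])))
           genes <- c(genes, gene_map$gene[hit[[j]]]) }
  }
  meta <- gm$variant_meta[keep, , drop = FALSE]
  meta$gene <- genes
  dup <- duplicated(meta$variant_id)
  meta$variant_id[dup] <- paste(meta$variant_id[dup], meta$gene[dup], sep = ":")
  genotype_matrix(gm$dosages[, keep, drop = FALSE], gm$sample_ids, meta,
                  log = gm$log)
}

#' Write a genotype matrix in the TSV dialect
#'
#' Inverse of [read_genotypes()] for the `tsv` format; missing dosages are
#' written as `.`. Round-trips dosages, sample order and variant keys.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @export
write_genotypes <- function(gm, path) {
  cells <- t(gm$dosages)
  cells[is.na(cells)] <- "."
  df <- cbind(gm$variant_meta[, c("variant_id", "chrom", "pos", "ref", "alt")],
              gene = ifelse(is.na(gm$variant_meta$gene), ".",
                            gm$variant_meta$gene),
              as.data.frame(cells, stringsAsFactors = FALSE))
  names(df)[-(1:6)] <- gm$sample_ids
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a phenotype vector
#'
#' @param sample_ids character identifiers.
#' @param status binary case indicator (1 = case, 0 = control).
#' @return object of class `phenotype_vector` with `m` cases, `l` controls.
#' @export
phenotype_vector <- function(sample_ids, status) {
  status <- as.integer(status)
  stopifnot(length(sample_ids) == length(status))
  if (!all(status %in% c(0L, 1L))) stop("status must be binary 0/1")
  structure(list(sample_ids = sample_ids, status = status,
                 m = sum(status == 1L), l = sum(status == 0L)),
            class = "phenotype_vector")
}

#' @method print phenotype_vector
#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("phenotype_vector: %d cases, %d controls\n", x$m, x$l))
  invisible(x)
}

#' Read a binary phenotype table
#'
#' Accepts a TSV with columns `sample_id status`, or `sample_id SBP DBP`
#' together with `derive_bp = TRUE`, in which case hypertension case status
#' is derived by the standard rule SBP >= 140 or DBP >= 90.
#'
#' @param path file path.
#' @param derive_bp derive status from blood-pressure columns.
#' @return a [phenotype_vector()].
#' @export
read_phenotypes <- function(path, derive_bp = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("phenotype TSV needs a sample_id column")
  if (derive_bp) {
    if (!all(c("SBP", "DBP") %in% names(df)))
      stop("derive_bp = TRUE needs SBP and DBP columns")
    status <- as.integer(df$SBP >= 140 | df$DBP >= 90)
  } else {
    if (!"status" %in% names(df)) stop("phenotype TSV needs a status column")
    status <- as.integer(df$status)
  }
  phenotype_vector(df$sample_id, status)
}

#' Align genotype and phenotype samples
#'
#' Restricts both objects to their common samples, in genotype order.
#' Samples present in only one input are dropped with a warning.
#'
#' @param gm a `genotype_matrix`.
#' @param ph a `phenotype_vector`.
#' @return list with aligned `genotypes` and `phenotype`.
#' @export
align_samples <- function(gm, ph) {
  keep <- gm$sample_ids %in% ph$sample_ids
  n_drop_g <- sum(!keep)
  n_drop_p <- sum(!ph$sample_ids %in% gm$sample_ids)
  if (n_drop_g + n_drop_p > 0L)
    warning(sprintf("dropping %d genotype-only and %d phenotype-only samples",
                    n_drop_g, n_drop_p))
  ids <- gm$sample_ids[keep]
  gm2 <- genotype_matrix(gm$dosages[keep, , drop = FALSE], ids,
                         gm$variant_meta, log = gm$log)
  st <- ph$status[match(ids, ph$sample_ids)]
  if (sum(st == 1L) == 0L || sum(st == 0L) == 0L)
    stop("alignment left zero cases or zero controls")
  list(genotypes = gm2, phenotype = phenotype_vector(ids, st))
}

#' Construct a gene unit
#'
#' One gene's analysis block: the dosage sub-matrix plus aligned annotation
#' slots. Missing dosages must already be resolved.
#'
#' @param gene gene symbol.
#' @param dosages numeric matrix, samples x variants.
#' @param categories per-variant annotation category (default `"OTHER"`).
#' @param weights optional explicit per-variant weights (`NA` = none).
#' @param variant_ids optional column identifiers.
#' @param sample_ids optional row identifiers.
#' @return object of class `gene_unit`.
#' @export
gene_unit <- function(gene, dosages, categories = NULL, weights = NULL,
                      variant_ids = colnames(dosages),
                      sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) < 1L) stop("gene unit needs at least one variant")
  if (is.null(categories)) categories <- rep("OTHER", ncol(dosages))
  stopifnot(length(categories) == ncol(dosages))
  if (!is.null(weights)) stopifnot(length(weights) == ncol(dosages))
  structure(list(gene = gene, dosages = dosages, categories = categories,
                 weights = weights, variant_ids = variant_ids,
                 sample_ids = sample_ids),
            class = "gene_unit")
}

#' @method print gene_unit
#' @export
print.gene_unit <- function(x, ...) {
  cat(sprintf("gene_unit %s: %d samples x %d variants\n",
              x$gene, nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Assemble per-gene analysis units
#'
#' Groups genotype columns by gene symbol and attaches annotation categories
#' and explicit weights. Variants without a gene assignment are skipped (with
#' a message); variants without an annotation row get category `"OTHER"`.
#' Missing dosages are resolved by policy: `"as-ref"` (missing counts as 0
#' minor alleles; conservative for burden scores) or `"mean-impute"`
#' (per-variant mean of observed dosages).
#'
#' @param gm a `genotype_matrix`, sample-aligned with `ph`.
#' @param ph a `phenotype_vector` (used only to check alignment).
#' @param ann optional annotation table: data.frame with columns
#'   `variant_id` or `chrom,pos,ref,alt`, a `category`, and optionally a
#'   numeric `weight` that overrides the category. Also accepts a TSV path.
#' @param missing missing-genotype policy.
#' @return named list of [gene_unit()] objects.
#' @export
build_gene_units <- function(gm, ph, ann = NULL,
                             missing = c("as-ref", "mean-impute")) {
  missing <- match.arg(missing)
  if (!identical(gm$sample_ids, ph$sample_ids))
    stop("genotypes and phenotype are not sample-aligned; see align_samples()")
  dos <- gm$dosages
  if (anyNA(dos)) {
    if (missing == "as-ref") {
      dos[is.na(dos)] <- 0
    } else {
      for (j in which(colSums(is.na(dos)) > 0L)) {
        mu <- mean(dos[, j], na.rm = TRUE)
        dos[is.na(dos[, j]), j] <- if (is.nan(mu)) 0 else mu
      }
    }
  }
  meta <- gm$variant_meta
  cat_of <- rep("OTHER", nrow(meta))
  wt_of <- rep(NA_real_, nrow(meta))
  if (!is.null(ann)) {
    if (is.character(ann) && length(ann) == 1L)
      ann <- utils::read.delim(ann, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    akey <- if ("variant_id" %in% names(ann)) ann$variant_id
            else paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
    if (anyDuplicated(akey)) stop("annotation table has duplicate variants")
    vkey <- paste(meta$chrom, meta$pos, meta$ref, meta$alt, sep = ":")
    i <- match(meta$variant_id, akey)
    i[is.na(i)] <- match(vkey, akey)[is.na(i)]
    hit <- !is.na(i)
    cat_of[hit] <- ann$category[i[hit]]
    if ("weight" %in% names(ann)) wt_of[hit] <- ann$weight[i[hit]]
  }
  has_gene <- !is.na(meta$gene)
  if (any(!has_gene))
    message(sum(!has_gene), " variant(s) without gene assignment skipped")
  units <- list()
  for (g in unique(meta$gene[has_gene])) {
    j <- which(has_gene & meta$gene == g)
    units[[g]] <- gene_unit(g, dos[, j, drop = FALSE],
                            categories = cat_of[j],
                            weights = if (all(is.na(wt_of[j]))) NULL else wt_of[j],
                            variant_ids = meta$variant_id[j],
                            sample_ids = gm$sample_ids)
  }
  units
}
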