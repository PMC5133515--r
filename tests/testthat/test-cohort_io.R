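write_lines <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3")

test_that("VCF GT fields map to minor-allele dosages", {
  path <- write_lines(c(vcf_header,
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"), ".vcf")
  gm <- read_genotypes(path)
  expect_equal(unname(gm$dosages[, 1]), c(0, 1, 2))
  expect_equal(gm$variant_meta$variant_id, "1:100:A:G")
  expect_equal(gm$log$n_missing, 0)
})

test_that("multi-allelic records split into one column per alt allele", {
  path <- write_lines(c(vcf_header,
    "1\t200\t.\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t1/2\t2/2"), ".vcf")
  gm <- read_genotypes(path)
  expect_equal(ncol(gm$dosages), 2)
  expect_setequal(gm$variant_meta$variant_id, c("1:200:G:A", "1:200:G:C"))
  # independent per-allele recount from the GT strings
  gts <- c("0/1", "1/2", "2/2")
  for (a in 1:2) {
    recount <- vapply(strsplit(gts, "/"),
                      function(al) sum(al == as.character(a)), numeric(1))
    col <- gm$dosages[, gm$variant_meta$alt == c("A", "C")[a]]
    expect_equal(unname(col), recount)
  }
})

test_that("major-oriented VCF alleles are flipped to minor with a log entry", {
  path <- write_lines(c(vcf_header,
    "1\t300\t.\tT\tC\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1"), ".vcf")
  gm <- read_genotypes(path)
  expect_equal(unname(gm$dosages[, 1]), c(0, 0, 1))
  expect_equal(gm$log$flipped, "1:300:T:C")
})

test_that("missing GT calls and malformed records are handled", {
  path <- write_lines(c(vcf_header,
    "1\t400\t.\tA\tG\t.\tPASS\t.\tGT\t./.\t0/1\t0/0"), ".vcf")
  gm <- read_genotypes(path)
  expect_true(is.na(gm$dosages[1, 1]))
  expect_equal(gm$log$n_missing, 1)
})

test_that("the TSV dialect round-trips exactly", {
  path <- write_lines(c(
    "variant_id\tchrom\tpos\tref\talt\tgene\ta\tb\tc",
    "v1\t1\t100\tA\tG\tGENEA\t0\t1\t2",
    "v2\t1\t150\tC\tT\tGENEA\t.\t0\t1",
    "v3\t2\t900\tG\tA\tGENEB\t2\t2\t0"), ".tsv")
  gm <- read_genotypes(path)
  expect_equal(gm$sample_ids, c("a", "b", "c"))
  expect_true(is.na(gm$dosages["a", "v2"]))
  expect_equal(gm$log$n_missing, 1)
  out <- tempfile(fileext = ".tsv")
  write_genotypes(gm, out)
  gm2 <- read_genotypes(out)
  expect_identical(gm2$dosages, gm$dosages)
  expect_identical(gm2$sample_ids, gm$sample_ids)
  expect_identical(gm2$variant_meta$variant_id, gm$variant_meta$variant_id)
  # re-reading the same file yields identical keys
  expect_identical(read_genotypes(path)$variant_meta, gm$variant_meta)
})

test_that("malformed TSV cells raise an error naming the location", {
  path <- write_lines(c(
    "variant_id\tchrom\tpos\tref\talt\tgene\ta\tb",
    "v1\t1\t100\tA\tG\tG1\t0\t3"), ".tsv")
  expect_error(read_genotypes(path), "malformed dosage cell")
})

test_that("phenotypes read directly or derived from blood pressure", {
  p1 <- write_lines(c("sample_id\tstatus", "a\t1", "b\t1", "c\t0"), ".tsv")
  ph <- read_phenotypes(p1)
  expect_equal(ph$m, 2)
  expect_equal(ph$l, 1)
  p2 <- write_lines(c("sample_id\tSBP\tDBP",
                      "a\t140\t80",   # SBP at the cutoff: case
                      "b\t139\t89",   # both strictly below: control
                      "c\t120\t90"),  # DBP at the cutoff: case
                    ".tsv")
  ph2 <- read_phenotypes(p2, derive_bp = TRUE)
  expect_equal(ph2$status, c(1, 0, 1))
})

test_that("sample alignment drops unmatched samples and keeps genotype order", {
  meta <- data.frame(variant_id = "v1", chrom = "1", pos = 1L,
                     ref = "A", alt = "G", gene = "G1")
  gm <- genotype_matrix(matrix(c(0L, 1L, 2L), 3, 1), c("a", "b", "c"), meta)
  ph <- phenotype_vector(c("c", "b", "x"), c(0, 1, 1))
  expect_warning(al <- align_samples(gm, ph), "dropping")
  expect_equal(al$genotypes$sample_ids, c("b", "c"))
  expect_equal(al$phenotype$status, c(1, 0))
  ph_bad <- phenotype_vector(c("b", "c"), c(1, 1))
  expect_error(suppressWarnings(align_samples(gm, ph_bad)), "zero cases or zero controls")
})

test_that("gene units partition variants and default to category OTHER", {
  meta <- data.frame(variant_id = paste0("v", 1:5), chrom = "1",
                     pos = 1:5, ref = "A", alt = "G",
                     gene = c("A", "A", "A", "B", "B"))
  gm <- genotype_matrix(matrix(0L, 4, 5, dimnames = list(NULL, meta$variant_id)),
                        c("s1", "s2", "s3", "s4"), meta)
  ph <- phenotype_vector(gm$sample_ids, c(1, 1, 0, 0))
  ann <- data.frame(variant_id = c("v1", "v4"),
                    category = c("BS", "NSSNV_NONBS"))
  units <- build_gene_units(gm, ph, ann)
  expect_named(units, c("A", "B"))
  expect_equal(ncol(units$A$dosages), 3)
  expect_equal(ncol(units$B$dosages), 2)
  expect_equal(units$A$categories, c("BS", "OTHER", "OTHER"))
  # n_j sums to the number of gene-assigned variants
  expect_equal(sum(vapply(units, function(u) ncol(u$dosages), numeric(1))),
               sum(!is.na(meta$gene)))
})

test_that("missing dosages resolve by policy", {
  meta <- data.frame(variant_id = "v1", chrom = "1", pos = 1L,
                     ref = "A", alt = "G", gene = "G1")
  gm <- genotype_matrix(matrix(c(NA, 1L, 1L, 2L), 4, 1), paste0("s", 1:4), meta)
  ph <- phenotype_vector(gm$sample_ids, c(1, 1, 0, 0))
  u_ref <- build_gene_units(gm, ph)$G1
  expect_equal(unname(u_ref$dosages[1, 1]), 0)       # as-ref: contributes 0
  u_imp <- build_gene_units(gm, ph, missing = "mean-impute")$G1
  expect_equal(unname(u_imp$dosages[1, 1]), mean(c(1, 1, 2)))
})

test_that("a variant mapped to two genes appears once per gene unit", {
  path <- write_lines(c(vcf_header,
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0"), ".vcf")
  map <- data.frame(variant_id = c("1:100:A:G", "1:100:A:G", "1:200:C:T"),
                    gene = c("GA", "GB", "GA"))
  gm <- read_genotypes(path, gene_map = map)
  expect_equal(ncol(gm$dosages), 3)
  ph <- phenotype_vector(gm$sample_ids, c(1, 0, 0))
  units <- build_gene_units(gm, ph)
  expect_equal(ncol(units$GA$dosages), 2)
  expect_equal(ncol(units$GB$dosages), 1)
})
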