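# File parsing and writing: summary statistics, genotypes, weights, regions.

test_that("summary statistics parse, derive z/p, and drop bad rows", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = 1,
                   BP = c(100, 200, 300), A1 = "A", A2 = "G",
                   BETA = c(0.1, -0.2, 0.0), SE = c(0.05, 0.1, 0.1),
                   N = 5000)
  ss <- read_sumstats(write_tsv(df))
  expect_s3_class(ss, "sumstats")
  expect_equal(ss$z, c(2, -2, 0))
  expect_equal(ss$p, 2 * pnorm(-abs(ss$z)))

  # se = 0 row is dropped and counted
  df$SE[2] <- 0
  ss2 <- read_sumstats(write_tsv(df))
  expect_equal(nrow(ss2), 2)
  expect_equal(attr(ss2, "parse_log")$n_dropped, 1L)

  # z-only tables are legal; beta/se stay absent
  df3 <- data.frame(SNP = c("rs1", "rs2"), CHR = 1, BP = c(100, 200),
                    A1 = "A", A2 = "G", Z = c(1.5, -0.5),
                    P = 2 * pnorm(-abs(c(1.5, -0.5))))
  ss3 <- read_sumstats(write_tsv(df3))
  expect_true(all(is.na(ss3$beta)))
  expect_equal(ss3$z, c(1.5, -0.5))

  # a missing required column is a named error
  expect_error(read_sumstats(write_tsv(df[, setdiff(names(df), "A2")])),
               "a2")
})

test_that("p inconsistent with z is recomputed from z (z authoritative)", {
  df <- data.frame(SNP = "rs1", CHR = 1, BP = 100, A1 = "A", A2 = "G",
                   BETA = 0.2, SE = 0.1, P = 0.5)
  expect_message(ss <- read_sumstats(write_tsv(df)), "inconsistent")
  expect_equal(ss$p, 2 * pnorm(-2), tolerance = 1e-12)
  expect_equal(attr(ss, "parse_log")$p_z_inconsistent, 1L)
})

test_that("sumstats and weights round-trip through TSV", {
  set.seed(1)
  ss <- toy_sumstats(beta = rnorm(5), se = runif(5, 0.01, 0.2))
  back <- read_sumstats(write_sumstats(ss, tempfile(fileext = ".tsv")))
  for (col in c("beta", "se", "z", "p"))
    expect_equal(back[[col]], ss[[col]], tolerance = 1e-10)

  w <- weight_matrix(toy_variants(4), matrix(rnorm(8), 4,
                                             dimnames = list(NULL, c("t1", "t2"))))
  wback <- read_weights(write_weights(w, tempfile(fileext = ".tsv")))
  expect_equal(wback$weights, w$weights, tolerance = 1e-10)
  expect_equal(wback$variants, w$variants)
})

test_that("parsing is independent of input row order", {
  set.seed(2)
  df <- data.frame(SNP = paste0("rs", 1:20), CHR = rep(c(2, 1), 10),
                   BP = sample(1e5, 20), A1 = "T", A2 = "C",
                   BETA = rnorm(20), SE = runif(20, 0.05, 0.2))
  a <- read_sumstats(write_tsv(df))
  b <- read_sumstats(write_tsv(df[sample(20), ]))
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("PLINK bed triplets decode to the documented dosages", {
  # 2 individuals x 2 variants, hand-encoded SNP-major .bed:
  # variant 1: ind1 hom A2 (code 11 -> dosage 0), ind2 het (10 -> 1)
  #   byte = 11 | 10<<2 = 0x0b
  # variant 2: ind1 het (10 -> 1), ind2 hom A1 (00 -> 2)
  #   byte = 10 | 00<<2 = 0x02
  prefix <- tempfile()
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x0b, 0x02)), paste0(prefix, ".bed"))
  writeLines(c("1\trs1\t0\t100\tA\tG", "1\trs2\t0\t200\tT\tC"),
             paste0(prefix, ".bim"))
  writeLines(c("f1\ti1\t0\t0\t0\t-9", "f2\ti2\t0\t0\t0\t-9"),
             paste0(prefix, ".fam"))
  p <- read_plink(prefix)
  expect_equal(unname(p$dosages), matrix(c(0, 1, 1, 2), 2))
  expect_equal(p$variants$a1, c("A", "T"))

  # corrupted length is a format error
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x0b)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "mismatch")
})

test_that("PLINK writer and reader are inverse, including missing calls", {
  set.seed(3)
  v <- toy_variants(7, a1 = c("A", "T", "G", "C", "A", "T", "G"),
                    a2 = c("G", "C", "A", "T", "C", "G", "T"))
  d <- matrix(sample(0:2, 7 * 9, replace = TRUE), nrow = 9)
  d[2, 3] <- NA; d[5, 1] <- NA
  panel <- genotype_panel(v, d)
  prefix <- tempfile()
  write_plink(panel, prefix)
  back <- read_plink(prefix)
  expect_equal(unname(back$dosages), unname(d))
  expect_equal(back$variants[c("chrom", "pos", "a1", "a2")],
               panel$variants[c("chrom", "pos", "a1", "a2")])
})

test_that("VCF genotypes map to ALT dosages and multi-allelics are skipped", {
  skip_if_not_installed("VariantAnnotation")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t./.\t1|1",
    "1\t300\trs3\tA\tC,G\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2"), vcf)
  expect_message(p <- read_genotypes(vcf, "vcf"), "multi-allelic")
  expect_equal(nrow(p$variants), 2)
  expect_equal(unname(p$dosages[, 1]), c(0, 1, 2))
  expect_equal(unname(p$dosages[, 2]), c(1, NA, 2))
  expect_equal(p$variants$a1, c("A", "T"))   # ALT is the counted allele
})

test_that("dosage-matrix TSV parses and flags non-numeric cells", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("iid\t1:100:A:G\t1:200:T:C", "i1\t0\t1.5", "i2\t2\t0"), path)
  p <- read_genotypes(path, "matrix-tsv")
  expect_equal(unname(p$dosages), matrix(c(0, 2, 1.5, 0), 2))
  expect_equal(p$variants$pos, c(100, 200))

  writeLines(c("iid\t1:100:A:G\t1:200:T:C", "i1\t0\toops", "i2\t2\t0"), path)
  expect_error(read_genotypes(path, "matrix-tsv"), "row 1.*1:200:T:C")
})

test_that("weight tables fill absent entries with zero and reject duplicates", {
  path <- write_tsv(data.frame(id = c("rs1", "rs2"), chrom = 1,
                               pos = c(100, 200), a1 = "A", a2 = "G",
                               height = c(0.5, NA), bmi = c(NA, -0.2)))
  expect_warning(w <- read_weights(path), "NA weight")
  expect_equal(unname(w$weights), matrix(c(0.5, 0, 0, -0.2), 2))
  expect_equal(w$trait_ids, c("height", "bmi"))

  dup <- write_tsv(data.frame(id = c("rs1", "rs1"), chrom = 1, pos = 100,
                              a1 = "A", a2 = "G", t1 = c(1, 2)))
  expect_error(read_weights(dup), "ambiguous")
})

test_that("regions parse from inline strings and BED with exact coordinates", {
  r <- read_regions("19:45,147,340-45,594,595")
  expect_equal(as.data.frame(r),
               data.frame(chrom = "19", start = 45147340, end = 45594595))

  bed <- tempfile(fileext = ".bed")
  writeLines("19\t45147339\t45594595", bed)
  rb <- read_regions(bed)
  expect_equal(rb$start, 45147340)   # 0-based half-open -> 1-based inclusive
  expect_equal(rb$end, 45594595)

  empty <- tempfile(fileext = ".bed"); file.create(empty)
  expect_equal(nrow(read_regions(empty)), 0)

  expect_error(read_regions("1:500-100"), "end < start")
})
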