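# File readers/writers for the formats the scan consumes and emits.
# All tables come back in the package's canonical (chrom, pos, a1, a2) sort
# so parsing is independent of input row order.

# recognised header aliases, lower-cased, per canonical column
.SS_ALIASES <- list(
  id    = c("id", "snp", "rsid", "snpid", "variant_id", "markername", "marker"),
  chrom = c("chrom", "chr", "chromosome", "#chrom"),
  pos   = c("pos", "bp", "position", "base_pair_location", "pos_b37", "pos_hg19"),
  a1    = c("a1", "effect_allele", "allele1", "ea", "alt", "effect_allele_a1"),
  a2    = c("a2", "other_allele", "allele2", "oa", "ref", "non_effect_allele"),
  beta  = c("beta", "b", "effect", "effect_size", "log_odds"),
  se    = c("se", "stderr", "standard_error", "sebeta"),
  z     = c("z", "zscore", "z_score", "tstat", "stat"),
  p     = c("p", "pval", "p_value", "pvalue", "p.value"),
  n     = c("n", "nsample", "n_total", "samplesize", "n_complete_samples")
)

.map_columns <- function(header, column_map) {
  lh <- tolower(header)
  out <- character(0)
  for (canon in names(.SS_ALIASES)) {
    cand <- if (!is.null(column_map) && canon %in% names(column_map)) {
      tolower(column_map[[canon]])
    } else .SS_ALIASES[[canon]]
    hit <- which(lh %in% cand)
    if (length(hit)) out[canon] <- header[hit[1]]
  }
  out
}

#' Read a GWAS summary-statistics table
#'
#' Accepts tab- or whitespace-delimited text with a header. Required columns:
#' variant id, chromosome, position, effect allele, other allele, and at least
#' two of beta / se / z / p. Common header dialects are recognised
#' automatically; `column_map` overrides the mapping (canonical name ->
#' file column name).
#'
#' Missing z is derived as beta/se; missing p from z (two-sided normal).
#' z is authoritative: when a supplied p disagrees with the p implied by z
#' beyond 1e-4 relative tolerance the p is recomputed and the row counted in
#' the parse log. Rows with non-finite required values, non-positive se,
#' non-ACGT single-nucleotide alleles, or duplicated (chrom, pos, allele
#' pair) are dropped and counted.
#'
#' @param path file path
#' @param column_map optional named character vector, canonical -> file column
#' @return a [sumstats] table; `attr(, "parse_log")` holds drop counts
#' @export
read_sumstats <- function(path, column_map = NULL) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", "", "."))
  if (nrow(dt) == 0) stop("no rows parsed from ", path)
  cmap <- .map_columns(names(dt), column_map)
  for (req in VARIANT_COLS) {
    if (!req %in% names(cmap))
      stop("missing required column: ", req, " (in ", path, ")")
  }
  stat_cols <- intersect(c("beta", "se", "z", "p"), names(cmap))
  if (length(stat_cols) < 2)
    stop("need at least two of beta/se/z/p columns; found: ",
         paste(stat_cols, collapse = ", "))
  getcol <- function(canon, default = NA_real_) {
    if (canon %in% names(cmap)) dt[[cmap[[canon]]]] else rep(default, nrow(dt))
  }
  v <- data.frame(id = as.character(getcol("id")),
                  chrom = norm_chrom(getcol("chrom")),
                  pos = suppressWarnings(as.numeric(getcol("pos"))),
                  a1 = toupper(as.character(getcol("a1"))),
                  a2 = toupper(as.character(getcol("a2"))),
                  stringsAsFactors = FALSE)
  beta <- suppressWarnings(as.numeric(getcol("beta")))
  se   <- suppressWarnings(as.numeric(getcol("se")))
  zz   <- suppressWarnings(as.numeric(getcol("z")))
  pp   <- suppressWarnings(as.numeric(getcol("p")))
  nn   <- suppressWarnings(as.numeric(getcol("n")))

  drop <- rep(FALSE, nrow(dt)); reason <- rep(NA_character_, nrow(dt))
  flag <- function(bad, why) {
    new <- bad & !drop
    reason[new] <<- why; drop <<- drop | bad
  }
  flag(!v$a1 %in% c("A", "C", "G", "T") | !v$a2 %in% c("A", "C", "G", "T") |
         v$a1 == v$a2, "allele")
  flag(!is.finite(v$pos) | v$pos < 1, "position")
  has_beta_se <- "beta" %in% stat_cols && "se" %in% stat_cols
  if (has_beta_se) {
    flag(!is.finite(beta) | !is.finite(se), "nonfinite")
    flag(is.finite(se) & se <= 0, "se_nonpositive")
  }
  if ("z" %in% stat_cols) flag(!is.finite(zz), "nonfinite")
  key_full <- paste(v$chrom, v$pos, pmin(v$a1, v$a2), pmax(v$a1, v$a2))
  flag(key_full %in% key_full[duplicated(key_full)], "duplicate")

  keep <- !drop
  if (!any(keep)) stop("all rows dropped while parsing ", path)
  v <- v[keep, , drop = FALSE]
  beta <- beta[keep]; se <- se[keep]; zz <- zz[keep]; pp <- pp[keep]
  nn <- nn[keep]

  # reconstruct the missing members of (beta, se, z, p); beta/se are
  # authoritative for z when both are present
  z_incons <- 0L
  if (has_beta_se) {
    z_bs <- beta / se
    if ("z" %in% stat_cols) z_incons <- sum(abs(zz - z_bs) > 1e-6, na.rm = TRUE)
    zz <- z_bs
  } else if (all(!is.finite(zz))) {
    if ("beta" %in% stat_cols && "p" %in% stat_cols) {
      zz <- sign(beta) * qnorm(pp / 2, lower.tail = FALSE)
      se <- beta / zz
    } else stop("cannot reconstruct z-scores from available columns")
  }
  p_incons <- 0L
  p_implied <- p_from_z(zz)
  if ("p" %in% stat_cols && any(is.finite(pp))) {
    rel <- abs(pp - p_implied) / pmax(p_implied, .Machine$double.xmin)
    bad <- is.finite(pp) & rel > 1e-4
    p_incons <- sum(bad)
    pp[bad | !is.finite(pp)] <- p_implied[bad | !is.finite(pp)]
  } else pp <- p_implied
  log <- list(n_input = nrow(dt), n_kept = nrow(v),
              n_dropped = sum(drop),
              drop_reasons = table(reason[drop]),
              z_beta_se_inconsistent = z_incons,
              p_z_inconsistent = p_incons)
  if (p_incons > 0)
    message(p_incons, " p-values inconsistent with z; recomputed from z")
  sumstats(v, beta = beta, se = se, z = zz, p = pp, n = nn, parse_log = log)
}

#' Write a summary-statistics table as TSV
#' @param ss a [sumstats] table
#' @param path output path
#' @export
write_sumstats <- function(ss, path) {
  data.table::fwrite(as.data.frame(ss), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

# ---- genotypes --------------------------------------------------------------

#' Read a reference genotype panel
#'
#' Supported formats: PLINK 1 binary (`.bed`/`.bim`/`.fam` triplet, pass the
#' prefix or the `.bed` path), VCF 4.x with GT or DS fields (biallelic records
#' only; multi-allelic sites are skipped and logged), or a plain dosage matrix
#' TSV whose first column is the individual id and whose remaining column
#' names are `chrom:pos:a1:a2` tokens.
#'
#' Dosages always count the effect allele recorded in the returned variant
#' table (`a1`): PLINK A1, VCF ALT. Missing genotypes are preserved as NA;
#' see [fill_missing_dosages()].
#'
#' @param path file path or PLINK prefix
#' @param format one of "auto", "plink-bed", "vcf", "matrix-tsv"
#' @return a [genotype_panel]
#' @export
read_genotypes <- function(path, format = c("auto", "plink-bed", "vcf",
                                            "matrix-tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path) || file.exists(paste0(path, ".bed")))
      "plink-bed"
    else if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
    else "matrix-tsv"
  }
  switch(format,
         "plink-bed" = read_plink(path),
         "vcf" = read_vcf_panel(path),
         "matrix-tsv" = read_matrix_panel(path))
}

#' Read a PLINK 1 binary triplet
#' @param prefix path prefix, or the .bed path
#' @return a [genotype_panel]; dosages count the bim A1 allele
#' @export
read_plink <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  bed_path <- paste0(prefix, ".bed")
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE,
                           data.table = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE,
                           data.table = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic): ", bed_path)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bpv <- ceiling(n / 4)                      # bytes per variant
  if (length(raw) - 3 != bpv * m)
    stop(sprintf(".bed size mismatch: %d data bytes, expected %d (n=%d, m=%d)",
                 length(raw) - 3, bpv * m, n, m))
  # 2-bit codes, little-endian within each byte:
  # 00 -> 2 copies of A1, 01 -> missing, 10 -> het, 11 -> 0 copies of A1
  code_map <- c(2, NA, 1, 0)
  byte_lut <- matrix(0, nrow = 256, ncol = 4)
  for (b in 0:255)
    byte_lut[b + 1, ] <- code_map[bitwAnd(bitwShiftR(b, c(0, 2, 4, 6)), 3L) + 1L]
  body <- as.integer(raw[-(1:3)])
  geno <- matrix(NA_real_, nrow = n, ncol = m)
  idx <- seq_len(n)
  for (j in seq_len(m)) {
    bytes <- body[((j - 1) * bpv + 1):(j * bpv)]
    vals <- t(byte_lut[bytes + 1, , drop = FALSE])  # 4 x bpv, sample-ordered
    geno[, j] <- as.vector(vals)[idx]
  }
  variants <- data.frame(id = as.character(bim$id), chrom = norm_chrom(bim$chrom),
                         pos = as.numeric(bim$pos),
                         a1 = toupper(as.character(bim$a1)),
                         a2 = toupper(as.character(bim$a2)),
                         stringsAsFactors = FALSE)
  genotype_panel(variants, geno)
}

#' Write a genotype panel as a PLINK 1 binary triplet
#' @param panel a [genotype_panel]; non-integer dosages are rounded
#' @param prefix output path prefix
#' @export
write_plink <- function(panel, prefix) {
  v <- panel$variants
  n <- panel$n_individuals
  data.table::fwrite(data.frame(v$chrom, v$id, 0, v$pos, v$a1, v$a2),
                     paste0(prefix, ".bim"), sep = "\t", col.names = FALSE,
                     quote = FALSE)
  fam <- data.frame(fid = paste0("F", seq_len(n)), iid = paste0("I", seq_len(n)),
                    pat = 0, mat = 0, sex = 0, phe = -9)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  # dosage (A1 count) -> 2-bit code
  enc <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  bpv <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  shift <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(ncol(panel$dosages))) {
    codes <- enc(round(panel$dosages[, j]))
    length(codes) <- bpv * 4            # pad with NA -> treated as code 0
    codes[is.na(codes)] <- 0L
    bytes <- colSums(matrix(codes * shift, nrow = 4))
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

read_vcf_panel <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required to read VCF panels")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt != 1
  if (any(multi))
    message(sum(multi), " multi-allelic site(s) skipped")
  keep <- which(!multi)
  if (!length(keep)) stop("no biallelic sites in ", path)
  g <- VariantAnnotation::geno(vcf)
  if ("GT" %in% names(g)) {
    gt <- g$GT[keep, , drop = FALSE]
    dos <- matrix(vapply(gt, function(x) {
      alleles <- strsplit(x, "[/|]")[[1]]
      if (any(alleles == ".")) NA_real_ else sum(alleles == "1")
    }, numeric(1)), nrow = nrow(gt))
  } else if ("DS" %in% names(g)) {
    dos <- matrix(as.numeric(g$DS[keep, , drop = FALSE]), nrow = length(keep))
  } else stop("VCF has neither GT nor DS genotype fields")
  ref <- as.character(VariantAnnotation::ref(vcf))[keep]
  alt1 <- as.character(unlist(alt[keep]))
  variants <- data.frame(
    id = names(rr)[keep],
    chrom = norm_chrom(as.character(GenomicRanges::seqnames(rr)[keep])),
    pos = as.numeric(GenomicRanges::start(rr)[keep]),
    a1 = toupper(alt1), a2 = toupper(ref), stringsAsFactors = FALSE)
  genotype_panel(variants, t(dos))
}

read_matrix_panel <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  if (ncol(dt) < 2) stop("dosage matrix needs an id column plus variants")
  tokens <- names(dt)[-1]
  parts <- strsplit(tokens, ":", fixed = TRUE)
  if (any(lengths(parts) != 4))
    stop("variant headers must be chrom:pos:a1:a2 tokens")
  pm <- do.call(rbind, parts)
  variants <- data.frame(id = tokens, chrom = norm_chrom(pm[, 1]),
                         pos = as.numeric(pm[, 2]),
                         a1 = toupper(pm[, 3]), a2 = toupper(pm[, 4]),
                         stringsAsFactors = FALSE)
  cells <- as.matrix(dt[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !(is.na(cells) | cells %in% c("NA", "", ".")),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric dosage '%s' at row %d, column '%s'",
                 cells[bad[1, 1], bad[1, 2]], bad[1, 1], tokens[bad[1, 2]]))
  genotype_panel(variants, num)
}

# ---- weights ----------------------------------------------------------------

#' Read a SNP-weight table (one or more traits)
#'
#' Expects variant identity columns (id, chrom, pos, effect allele a1, other
#' allele a2, with the usual header aliases) followed by one numeric column
#' per trait. NA weights become exact zeros with a warning; a duplicated
#' variant within one table is an error (ambiguous weight).
#'
#' @param path file path
#' @return a [weight_matrix]
#' @export
read_weights <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", "", "."))
  if (nrow(dt) == 0) stop("no rows parsed from ", path)
  cmap <- .map_columns(names(dt), NULL)
  for (req in VARIANT_COLS)
    if (!req %in% names(cmap)) stop("missing required column: ", req)
  trait_cols <- setdiff(names(dt), unname(cmap[VARIANT_COLS]))
  if (!length(trait_cols)) stop("no weight columns found in ", path)
  v <- data.frame(id = as.character(dt[[cmap["id"]]]),
                  chrom = norm_chrom(dt[[cmap["chrom"]]]),
                  pos = as.numeric(dt[[cmap["pos"]]]),
                  a1 = toupper(as.character(dt[[cmap["a1"]]])),
                  a2 = toupper(as.character(dt[[cmap["a2"]]])),
                  stringsAsFactors = FALSE)
  key <- variant_key(v)
  if (anyDuplicated(key))
    stop("duplicated variant within weight table (ambiguous weight): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  w <- as.matrix(dt[, trait_cols, drop = FALSE])
  storage.mode(w) <- "double"
  if (anyNA(w)) {
    warning(sum(is.na(w)), " NA weight(s) treated as zero")
    w[is.na(w)] <- 0
  }
  weight_matrix(v, w, trait_cols)
}

#' Write a weight matrix as TSV
#' @param w a [weight_matrix]
#' @param path output path
#' @export
write_weights <- function(w, path) {
  df <- cbind(w$variants,
              as.data.frame(w$weights, row.names = NULL))
  names(df) <- c(VARIANT_COLS, w$trait_ids)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# ---- regions ----------------------------------------------------------------

#' Read genomic regions from BED or inline strings
#'
#' BED input (0-based half-open) is converted to the package's internal
#' 1-based inclusive convention (start+1 .. end). Inline strings use
#' `"chr:start-end"` with 1-based inclusive coordinates (commas allowed).
#'
#' @param x a BED file path, or a character vector of inline region strings
#' @return a [region_set]
#' @export
read_regions <- function(x) {
  if (length(x) == 1 && file.exists(x)) {
    if (file.size(x) == 0) return(region_set())
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      gr <- rtracklayer::import(x, format = "BED")
      return(region_set(as.character(GenomicRanges::seqnames(gr)),
                        GenomicRanges::start(gr), GenomicRanges::end(gr)))
    }
    bed <- data.table::fread(x, header = FALSE, data.table = FALSE)
    return(region_set(bed[[1]], as.numeric(bed[[2]]) + 1, as.numeric(bed[[3]])))
  }
  x <- gsub(",", "", x)
  m <- regmatches(x, regexec("^(chr)?([^:]+):([0-9]+)-([0-9]+)$", x))
  if (any(lengths(m) == 0))
    stop("cannot parse region string(s): ",
         paste(x[lengths(m) == 0], collapse = ", "))
  region_set(vapply(m, `[`, "", 3), as.numeric(vapply(m, `[`, "", 4)),
             as.numeric(vapply(m, `[`, "", 5)))
}

#' Write an association results table as TSV
#' @param results data.frame of association results
#' @param path output path
#' @export
write_results <- function(results, path) {
  data.table::fwrite(as.data.frame(results), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}
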