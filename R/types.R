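#' @importFrom stats cor cov cutree dist hclust median p.adjust phyper pnorm qbinom qnorm rbinom rnorm runif sd var
#' @importFrom utils head modifyList tail
NULL

# Canonical variant identity columns shared by all tabular types.
VARIANT_COLS <- c("id", "chrom", "pos", "a1", "a2")

#' Positional key (chrom:pos) used for matching across sources
#' @param x data.frame with chrom and pos columns
#' @return character vector
#' @keywords internal
variant_key <- function(x) paste(x$chrom, x$pos, sep = ":")

# chrom normalisation: strip leading "chr", keep as character so "X" works
norm_chrom <- function(chrom) sub("^chr", "", as.character(chrom), ignore.case = TRUE)

canonical_order <- function(variants) {
  order(variants$chrom, variants$pos, variants$a1, variants$a2, method = "radix")
}

#' Construct a GWAS summary-statistics table
#'
#' One row per biallelic SNV with effect estimate `beta`, its standard error
#' `se`, z-score `z` (= beta/se), two-sided p-value `p` and GWAS sample size
#' `n`. `a1` is the effect (counted) allele. Any of beta/se/n may be NA
#' (z-only tables are legal); `z` and `p` are always populated.
#'
#' @param variants data.frame with columns id, chrom, pos, a1, a2
#' @param beta,se,z,p,n per-variant numeric vectors (NA allowed for beta/se/n)
#' @param parse_log optional list recording rows dropped during parsing
#' @return object of class `sumstats` (a data.frame)
#' @export
sumstats <- function(variants, beta = NA_real_, se = NA_real_, z, p = NULL,
                     n = NA_real_, parse_log = NULL) {
  stopifnot(all(VARIANT_COLS %in% names(variants)))
  m <- nrow(variants)
  if (is.null(p)) p <- p_from_z(z)
  df <- data.frame(variants[VARIANT_COLS],
                   beta = rep_len(as.numeric(beta), m),
                   se = rep_len(as.numeric(se), m),
                   z = as.numeric(z), p = as.numeric(p),
                   n = rep_len(as.numeric(n), m),
                   stringsAsFactors = FALSE, row.names = NULL)
  df <- df[canonical_order(df), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("sumstats", "data.frame"),
            parse_log = parse_log)
}

#' Construct a reference genotype panel
#'
#' @param variants data.frame with columns id, chrom, pos, a1, a2; `a1` is the
#'   counted (dosage) allele
#' @param dosages numeric matrix, individuals x variants, entries in [0, 2]
#'   or NA for missing
#' @return object of class `genotype_panel`
#' @export
genotype_panel <- function(variants, dosages) {
  stopifnot(all(VARIANT_COLS %in% names(variants)),
            is.matrix(dosages), ncol(dosages) == nrow(variants))
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2]")
  colnames(dosages) <- variants$id
  structure(list(variants = as.data.frame(variants[VARIANT_COLS],
                                          stringsAsFactors = FALSE),
                 dosages = dosages,
                 n_individuals = nrow(dosages)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d variants (%d missing calls)\n",
              x$n_individuals, nrow(x$variants), sum(is.na(x$dosages))))
  invisible(x)
}

#' Construct a SNP-by-trait weight matrix
#'
#' Columns of the weight matrix are linear trait-imputation models
#' (polygenic scores): the imputed trait is the dosage matrix times the
#' weight column. Absent variant-trait weights are exact zeros.
#'
#' @param variants data.frame with columns id, chrom, pos, a1, a2 (a1 is the
#'   weighted allele)
#' @param weights numeric matrix, variants x traits, finite
#' @param trait_ids character vector of trait (column) names
#' @return object of class `weight_matrix`
#' @export
weight_matrix <- function(variants, weights, trait_ids = colnames(weights)) {
  weights <- as.matrix(weights)
  stopifnot(all(VARIANT_COLS %in% names(variants)),
            nrow(weights) == nrow(variants))
  if (is.null(trait_ids)) trait_ids <- paste0("trait", seq_len(ncol(weights)))
  if (any(!is.finite(weights))) stop("weight entries must be finite")
  ord <- canonical_order(variants)
  variants <- as.data.frame(variants[VARIANT_COLS], stringsAsFactors = FALSE)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  weights <- weights[ord, , drop = FALSE]
  dimnames(weights) <- list(variants$id, trait_ids)
  structure(list(variants = variants, weights = weights,
                 trait_ids = as.character(trait_ids)),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> %d variants x %d traits (%d nonzero weights)\n",
              nrow(x$variants), length(x$trait_ids), sum(x$weights != 0)))
  invisible(x)
}

#' Construct a set of genomic regions (1-based, both ends inclusive)
#'
#' @param chrom,start,end vectors of equal length; coordinates are 1-based
#'   inclusive on both ends. Overlapping intervals are allowed (union
#'   semantics).
#' @return object of class `region_set` (a data.frame)
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer()) {
  chrom <- norm_chrom(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(end < start)) stop("region end < start after normalisation")
  if (any(start < 1)) stop("region start must be >= 1")
  structure(data.frame(chrom = chrom, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("region_set", "data.frame"))
}

#' Test which positions fall inside a region set
#' @param regions a region_set
#' @param chrom,pos vectors of positions to test
#' @return logical vector, TRUE where (chrom, pos) lies in any interval
#'   (both ends inclusive)
#' @export
in_regions <- function(regions, chrom, pos) {
  chrom <- norm_chrom(chrom)
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chrom == regions$chrom[i] &
                  pos >= regions$start[i] & pos <= regions$end[i])
  }
  hit
}

# two-sided normal p from z, computed in log space so large |z| keeps a
# subnormal p instead of overflowing the tail computation
p_from_z <- function(z) {
  p <- exp(pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# -log10 two-sided p, exact in log space for |z| far beyond double underflow
neglog10p_from_z <- function(z) {
  -(pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
}
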