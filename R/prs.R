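# Polygenic-score construction: p-value thresholding, greedy LD clumping
# against a reference panel, genomic region exclusion, and panel scoring.

#' Filter a summary-statistics table on association p-value
#'
#' Retains rows with p <= threshold (boundary inclusive: "removed SNPs with
#' p greater than the threshold" keeps equality). An empty result is a
#' warning, not an error.
#'
#' @param ss a [sumstats] table
#' @param threshold p-value cutoff in (0, 1]; default 0.01
#' @return the filtered [sumstats] table
#' @export
pvalue_filter <- function(ss, threshold = 0.01) {
  stopifnot(threshold > 0, threshold <= 1)
  keep <- ss$p <= threshold
  if (!any(keep)) warning("no variants pass p <= ", threshold)
  out <- as.data.frame(ss)[keep, , drop = FALSE]
  sumstats(out[VARIANT_COLS], beta = out$beta, se = out$se, z = out$z,
           p = out$p, n = out$n)
}

#' Greedy LD clumping
#'
#' PLINK-style clumping: repeatedly take the most significant unprocessed
#' variant as an index, then remove every unprocessed variant on the same
#' chromosome within `radius_bp` whose squared Pearson correlation of panel
#' dosages with the index exceeds `r2_cutoff`. r2 is always computed against
#' the index variant (not transitively). Ties on p are broken by ascending
#' (chrom, pos). Pairs where either variant has zero dosage variance count
#' as r2 = 0.
#'
#' @param ss a [sumstats] table; all its variants must be in the panel
#' @param panel a [genotype_panel] providing LD (missing dosages are
#'   mean-imputed for the correlation)
#' @param r2_cutoff squared-correlation cutoff in (0, 1); default 0.1
#' @param radius_bp clumping radius in base pairs; default 1e6 (1 Mb)
#' @return a `clump_result`: list with `index_variants` (ordered as selected)
#'   and `removed` (named character vector, removed id -> absorbing index id)
#' @export
ld_clump <- function(ss, panel, r2_cutoff = 0.1, radius_bp = 1e6) {
  stopifnot(r2_cutoff > 0, r2_cutoff < 1, radius_bp > 0)
  key_ss <- variant_key(ss)
  key_p <- variant_key(panel$variants)
  pidx <- match(key_ss, key_p)
  if (anyNA(pidx))
    stop("variant(s) absent from panel: ",
         paste(head(ss$id[is.na(pidx)], 5), collapse = ", "),
         if (sum(is.na(pidx)) > 5) " ...")
  d <- panel$dosages[, pidx, drop = FALSE]
  if (anyNA(d)) d <- fill_missing_dosages(genotype_panel(ss[VARIANT_COLS], d))$dosages
  m <- nrow(ss)
  ord <- order(ss$p, ss$chrom, ss$pos, method = "radix")
  state <- rep("open", m)                 # open | index | removed
  removed_by <- rep(NA_character_, m)
  sds <- apply(d, 2, sd)
  for (i in ord) {
    if (state[i] != "open") next
    state[i] <- "index"
    cand <- which(state == "open" & ss$chrom == ss$chrom[i] &
                    abs(ss$pos - ss$pos[i]) <= radius_bp)
    if (!length(cand)) next
    ok <- sds[cand] > 0 & sds[i] > 0
    r2 <- rep(0, length(cand))
    if (any(ok))
      r2[ok] <- drop(cor(d[, i], d[, cand[ok], drop = FALSE]))^2
    hit <- cand[r2 > r2_cutoff]
    state[hit] <- "removed"
    removed_by[hit] <- ss$id[i]
  }
  sel <- ord[state[ord] == "index"]
  structure(list(index_variants = as.data.frame(ss)[sel, , drop = FALSE],
                 removed = structure(removed_by[state == "removed"],
                                     names = ss$id[state == "removed"])),
            class = "clump_result")
}

#' Build a single-trait PRS weight table from summary statistics
#'
#' Pipeline: [pvalue_filter()] then [ld_clump()]; the weights of the
#' surviving index variants are their marginal effect sizes (beta). For
#' z-only tables the z-scores are used instead and the result carries
#' `attr(, "standardized_weight") = TRUE`.
#'
#' @param ss a [sumstats] table
#' @param panel a [genotype_panel] for LD
#' @param p_threshold p-value cutoff (default 0.01)
#' @param r2_cutoff LD r2 cutoff (default 0.1)
#' @param radius_bp clumping radius (default 1 Mb)
#' @param trait_id name for the weight column
#' @return a [weight_matrix] with one column (possibly zero rows)
#' @export
build_prs <- function(ss, panel, p_threshold = 0.01, r2_cutoff = 0.1,
                      radius_bp = 1e6, trait_id = "trait") {
  kept <- suppressWarnings(pvalue_filter(ss, p_threshold))
  if (nrow(kept) == 0) {
    warning("no variants pass the p-value threshold; empty weight table")
    w <- weight_matrix(kept[VARIANT_COLS],
                       matrix(0, 0, 1, dimnames = list(NULL, trait_id)))
    return(w)
  }
  cl <- ld_clump(kept, panel, r2_cutoff, radius_bp)
  iv <- cl$index_variants
  standardized <- all(!is.finite(iv$beta))
  wvals <- if (standardized) iv$z else iv$beta
  w <- weight_matrix(iv[VARIANT_COLS],
                     matrix(wvals, ncol = 1, dimnames = list(NULL, trait_id)))
  attr(w, "standardized_weight") <- standardized
  w
}

#' Remove variants inside genomic regions from a weight table
#'
#' Variants whose position falls inside any interval (1-based, both ends
#' inclusive) are removed from every trait column. Used for sensitivity
#' analyses that exclude a dominant locus, e.g. the extended APOE region
#' chr19:45,147,340-45,594,595 (hg19) in Alzheimer's studies.
#'
#' @param w a [weight_matrix]
#' @param regions a [region_set]
#' @return the filtered [weight_matrix]
#' @export
exclude_region <- function(w, regions) {
  if (nrow(regions) == 0 || nrow(w$variants) == 0) return(w)
  drop <- in_regions(regions, w$variants$chrom, w$variants$pos)
  if (!any(drop)) return(w)
  weight_matrix(w$variants[!drop, , drop = FALSE],
                w$weights[!drop, , drop = FALSE], w$trait_ids)
}

#' Impute (score) traits on a genotype panel
#'
#' Computes the linear imputation T = X W over the variants shared between
#' the weight table and the panel, orienting dosages to the weight table's
#' effect alleles. Traits with zero overlapping variants are flagged
#' unusable.
#'
#' @param w a [weight_matrix]
#' @param panel a [genotype_panel] without missing dosages (see
#'   [fill_missing_dosages()])
#' @return individuals x traits matrix of scores; attributes
#'   `n_variants_used` (per trait) and `unusable_traits`
#' @export
score_panel <- function(w, panel) {
  if (anyNA(panel$dosages))
    stop("panel has missing dosages; run fill_missing_dosages() first")
  key_w <- variant_key(w$variants)
  key_p <- variant_key(panel$variants)
  pidx <- match(key_w, key_p)
  use <- !is.na(pidx)
  flip <- allele_orientation(w$variants$a1[use], w$variants$a2[use],
                             panel$variants$a1[pidx[use]],
                             panel$variants$a2[pidx[use]])
  if (anyNA(flip))
    stop("allele mismatch between weights and panel; run harmonize() first")
  ww <- w$weights[use, , drop = FALSE] * flip
  d <- panel$dosages[, pidx[use], drop = FALSE]
  # a panel column whose counted allele is the weight's other allele
  # contributes weight * (2 - dosage): negate the weight and add the
  # constant 2 * weight once per flipped variant
  scores <- d %*% ww
  if (any(flip == -1)) {
    offset <- 2 * colSums(w$weights[use, , drop = FALSE][flip == -1, ,
                                                         drop = FALSE])
    scores <- sweep(scores, 2, offset, `+`)
  }
  colnames(scores) <- w$trait_ids
  n_used <- colSums(w$weights[use, , drop = FALSE] != 0)
  unusable <- w$trait_ids[n_used == 0]
  if (length(unusable))
    warning("trait(s) with no usable variants: ",
            paste(unusable, collapse = ", "))
  structure(scores, n_variants_used = n_used, unusable_traits = unusable)
}
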