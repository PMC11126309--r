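# Variant/allele harmonisation across summary statistics, weight tables and
# genotype panels. All downstream algebra assumes one shared variant universe
# with one effect-allele orientation; this module builds it.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) unname(COMPLEMENT[a1] == a2)

# Classify a source allele pair (b1, b2) against a reference pair (a1, a2).
# Returns +1 (same orientation), -1 (effect allele swapped, effect sign must
# flip), or NA (mismatch). Strand flips are resolved by complementing first.
allele_orientation <- function(a1, a2, b1, b2) {
  out <- rep(NA_real_, length(a1))
  out[b1 == a1 & b2 == a2] <- 1
  swap <- is.na(out) & b1 == a2 & b2 == a1
  out[swap] <- -1
  cb1 <- unname(COMPLEMENT[b1]); cb2 <- unname(COMPLEMENT[b2])
  comp_same <- is.na(out) & cb1 == a1 & cb2 == a2
  out[comp_same] <- 1
  comp_swap <- is.na(out) & cb1 == a2 & cb2 == a1
  out[comp_swap] <- -1
  out
}

variants_of <- function(x) {
  if (inherits(x, "sumstats")) x[VARIANT_COLS]
  else if (inherits(x, c("genotype_panel", "weight_matrix"))) x$variants
  else stop("unsupported source type: ", paste(class(x), collapse = "/"))
}

# restrict a source to row indices `idx` (in its own variant order), applying
# per-variant sign flips and rewriting alleles to the reference orientation
.apply_orientation <- function(x, idx, flip, ref_variants) {
  if (inherits(x, "sumstats")) {
    out <- as.data.frame(x)[idx, , drop = FALSE]
    out$beta <- out$beta * flip
    out$z <- out$z * flip
    out[c("chrom", "pos", "a1", "a2")] <- ref_variants[c("chrom", "pos", "a1", "a2")]
    sumstats(out[VARIANT_COLS], beta = out$beta, se = out$se, z = out$z,
             p = out$p, n = out$n)
  } else if (inherits(x, "weight_matrix")) {
    w <- x$weights[idx, , drop = FALSE] * flip
    weight_matrix(ref_variants, w, x$trait_ids)
  } else if (inherits(x, "genotype_panel")) {
    d <- x$dosages[, idx, drop = FALSE]
    neg <- which(flip == -1)
    if (length(neg)) d[, neg] <- 2 - d[, neg, drop = FALSE]
    genotype_panel(ref_variants, d)
  }
}

#' Harmonise variants and effect alleles across data sources
#'
#' Matches variants on (chromosome, position), verifies allele pairs against
#' the first source's orientation, and returns every source restricted to the
#' shared universe with effect signs flipped where the effect allele was
#' swapped. Strand flips are resolved by complementing alleles before
#' matching; strand-ambiguous (A/T, C/G) variants are dropped when
#' `strict_ambiguous` is set because their orientation cannot be decided
#' without allele frequencies. Variants duplicated within a source, absent
#' from any source, or with irreconcilable alleles are dropped with a reason.
#'
#' @param sources named list of [sumstats], [weight_matrix] and/or
#'   [genotype_panel] objects (at least two)
#' @param strict_ambiguous drop strand-ambiguous variants (default TRUE)
#' @return a `harmonized_set`: list with `sources` (aligned, flips applied,
#'   identical variant order), `variants`, `sign_flips` (variants x sources),
#'   and `report` (per-variant action/reason table)
#' @export
harmonize <- function(sources, strict_ambiguous = TRUE) {
  stopifnot(is.list(sources), length(sources) >= 2)
  if (is.null(names(sources)) || any(names(sources) == ""))
    names(sources) <- paste0("source", seq_along(sources))
  vs <- lapply(sources, variants_of)
  keys <- lapply(vs, variant_key)

  dropped <- list()
  # duplicates within each source leave the matching universe entirely
  for (s in names(sources)) {
    k <- keys[[s]]
    dup <- unique(k[duplicated(k)])
    if (length(dup))
      dropped[[length(dropped) + 1L]] <-
        data.frame(key = dup, reason = "duplicate", source = s)
  }
  dup_keys <- unique(unlist(lapply(dropped, `[[`, "key")))
  usable <- lapply(keys, function(k) setdiff(k, dup_keys))
  shared <- Reduce(intersect, usable)
  all_keys <- unique(unlist(keys))
  missing_keys <- setdiff(setdiff(all_keys, dup_keys), shared)
  if (length(missing_keys))
    dropped[[length(dropped) + 1L]] <-
      data.frame(key = missing_keys, reason = "missing", source = NA)
  if (!length(shared))
    stop("no shared variants across sources (counts: ",
         paste(sprintf("%s=%d", names(sources), vapply(keys, length, 0L)),
               collapse = ", "), ")")

  ref_idx <- match(shared, keys[[1]])
  ref <- vs[[1]][ref_idx, , drop = FALSE]

  flips <- matrix(1, nrow = length(shared), ncol = length(sources),
                  dimnames = list(shared, names(sources)))
  keep <- rep(TRUE, length(shared))
  reason <- rep(NA_character_, length(shared))
  for (s in seq_along(sources)[-1]) {
    si <- match(shared, keys[[s]])
    b <- vs[[s]][si, , drop = FALSE]
    ori <- allele_orientation(ref$a1, ref$a2, b$a1, b$a2)
    bad <- is.na(ori)
    reason[bad & keep] <- "mismatch"
    keep <- keep & !bad
    flips[, s] <- ifelse(bad, NA, ori)
  }
  if (strict_ambiguous) {
    amb <- is_palindromic(ref$a1, ref$a2)
    reason[amb & keep] <- "ambiguous"
    keep <- keep & !amb
  }
  if (any(!keep))
    dropped[[length(dropped) + 1L]] <-
      data.frame(key = shared[!keep], reason = reason[!keep], source = NA)
  if (!any(keep))
    stop("no variants retained after allele harmonisation")

  shared <- shared[keep]
  ref <- ref[keep, , drop = FALSE]
  rownames(ref) <- NULL
  ord <- canonical_order(ref)
  shared <- shared[ord]
  ref <- ref[ord, , drop = FALSE]
  rownames(ref) <- NULL
  flips <- flips[keep, , drop = FALSE][ord, , drop = FALSE]

  aligned <- vector("list", length(sources))
  names(aligned) <- names(sources)
  for (s in seq_along(sources)) {
    idx <- match(shared, keys[[s]])
    aligned[[s]] <- .apply_orientation(sources[[s]], idx, flips[, s], ref)
  }
  report <- rbind(
    data.frame(key = shared, reason = "retained", source = NA),
    if (length(dropped)) do.call(rbind, dropped))
  structure(list(sources = aligned, variants = ref, sign_flips = flips,
                 report = report),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %d variants retained across %d sources; %d dropped\n",
              nrow(x$variants), length(x$sources),
              sum(x$report$reason != "retained")))
  invisible(x)
}

#' Mean-impute missing dosages in a genotype panel
#'
#' Each missing dosage is replaced by the per-variant mean of the observed
#' dosages, which preserves the variant mean and keeps variance estimates
#' well-defined. Variants with no observed calls are removed (with a
#' message).
#'
#' @param panel a [genotype_panel]
#' @return a [genotype_panel] without missing values
#' @export
fill_missing_dosages <- function(panel) {
  d <- panel$dosages
  na_count <- colSums(is.na(d))
  if (!any(na_count > 0)) return(panel)
  all_missing <- na_count == nrow(d)
  if (any(all_missing)) {
    message(sum(all_missing), " all-missing variant(s) removed")
    d <- d[, !all_missing, drop = FALSE]
    panel$variants <- panel$variants[!all_missing, , drop = FALSE]
    na_count <- na_count[!all_missing]
  }
  for (j in which(na_count > 0)) {
    miss <- is.na(d[, j])
    d[miss, j] <- mean(d[!miss, j])
  }
  genotype_panel(panel$variants, d)
}
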