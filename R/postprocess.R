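# Post-processing of association scans: fixed-effects meta-analysis across
# cohorts, multiple-testing control, clustering-based representative trait
# selection for conditional analysis, and replication enrichment.

#' Inverse-variance-weighted fixed-effects meta-analysis
#'
#' Combines per-study association results per trait with weights 1/se^2:
#' gamma_meta = sum(gamma_i/se_i^2) / sum(1/se_i^2),
#' se_meta = 1/sqrt(sum(1/se_i^2)). `direction_consistent` is TRUE iff all
#' study estimates share one sign. Traits with no usable study (finite
#' gamma, se > 0) are omitted with a message.
#'
#' @param results list of per-study data.frames with columns trait_id,
#'   gamma_hat, se (e.g. [assoc_scan()] outputs)
#' @return data.frame: trait_id, gamma_meta, se_meta, z_meta, p_meta,
#'   direction_consistent, k_studies
#' @export
meta_ivw <- function(results) {
  stopifnot(is.list(results), length(results) >= 1)
  all_traits <- unique(unlist(lapply(results, `[[`, "trait_id")))
  rows <- lapply(all_traits, function(tid) {
    g <- numeric(0); s <- numeric(0)
    for (st in results) {
      i <- which(st$trait_id == tid)
      if (length(i) == 1 && is.finite(st$gamma_hat[i]) &&
          is.finite(st$se[i]) && st$se[i] > 0) {
        g <- c(g, st$gamma_hat[i]); s <- c(s, st$se[i])
      }
    }
    if (!length(g)) return(NULL)
    wt <- 1 / s^2
    se_meta <- 1 / sqrt(sum(wt))
    gamma_meta <- sum(g * wt) * se_meta^2
    z <- gamma_meta / se_meta
    data.frame(trait_id = tid, gamma_meta = gamma_meta, se_meta = se_meta,
               z_meta = z, p_meta = p_from_z(z),
               direction_consistent = all(g > 0) || all(g < 0),
               k_studies = length(g), stringsAsFactors = FALSE)
  })
  omitted <- all_traits[vapply(rows, is.null, TRUE)]
  if (length(omitted))
    message("trait(s) omitted from meta-analysis (no usable study): ",
            paste(omitted, collapse = ", "))
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Bonferroni significance flags
#'
#' Flags p < alpha / m (strict), the family-wise threshold used for
#' scan-wide discovery (e.g. 0.05/1738 for a 1738-trait scan).
#'
#' @param p numeric vector of p-values
#' @param alpha family-wise error level (default 0.05)
#' @param m number of tests (default `length(p)`)
#' @return logical vector
#' @export
bonferroni <- function(p, alpha = 0.05, m = length(p)) {
  stopifnot(m >= 1)
  p < alpha / m
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up procedure at level `q`: flags every p-value not exceeding the
#' largest p_(i) with p_(i) <= i*q/m.
#'
#' @param p numeric vector of p-values in (0, 1]
#' @param q FDR level (default 0.05)
#' @return logical vector
#' @export
bh_fdr <- function(p, q = 0.05) {
  p.adjust(p, method = "BH") <= q
}

#' Cluster correlated traits and select one representative per cluster
#'
#' Agglomerative hierarchical clustering of traits on the distance
#' 1 - |correlation| (so strongly anti-correlated trait pairs, e.g. a
#' diagnosis and its medication-use counterpart, stay together), cut at `k`
#' clusters; within each cluster the trait with the smallest p-value is the
#' representative carried into conditional analysis.
#'
#' @param corr symmetric trait correlation matrix with unit diagonal,
#'   dimnames = trait ids (e.g. correlation of panel-imputed scores)
#' @param p per-trait p-values, same order as `corr` rows
#' @param k number of clusters (e.g. 15 in a 48-trait follow-up)
#' @param linkage hclust linkage (default "average")
#' @param distance "one_minus_abs_corr" (default) or "one_minus_corr"
#' @return a `cluster_selection` list: `labels` (named integer vector),
#'   `representatives` (cluster id -> trait id), `linkage`, `distance`
#' @export
cluster_select <- function(corr, p, k, linkage = "average",
                           distance = c("one_minus_abs_corr",
                                        "one_minus_corr")) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr), length(p) == nrow(corr))
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(corr)) stop("k exceeds the number of traits")
  ids <- rownames(corr)
  if (is.null(ids)) ids <- paste0("trait", seq_len(nrow(corr)))
  # order-invariance: cluster in canonical trait order
  ord <- order(ids, method = "radix")
  corr <- corr[ord, ord, drop = FALSE]
  p <- p[ord]; ids <- ids[ord]
  d <- if (distance == "one_minus_abs_corr") 1 - abs(corr) else 1 - corr
  labels <- cutree(hclust(stats::as.dist(d), method = linkage), k = k)
  reps <- vapply(sort(unique(labels)), function(cl) {
    members <- which(labels == cl)
    members[order(p[members], ids[members])][1]
  }, integer(1))
  structure(list(labels = structure(labels, names = ids),
                 representatives = structure(ids[reps],
                                             names = sort(unique(labels))),
                 linkage = linkage, distance = distance),
            class = "cluster_selection")
}

#' Hypergeometric replication enrichment
#'
#' Tests whether discovery hits replicate more often than expected by
#' chance: with `m` traits in the universe, `K` of which replicate
#' (p < threshold) universe-wide, and `k` of the `n` discovery hits
#' replicating, the enrichment is the observed over expected overlap
#' (k/n)/(K/m) and the p-value is the upper tail P(X >= k) of
#' Hypergeometric(m, K, n).
#'
#' @param m universe size
#' @param K replicated traits in the universe
#' @param n discovery hits
#' @param k replicated discovery hits
#' @return list: universe, replicated_in_universe, discovery_hits, overlap,
#'   enrichment, p
#' @export
replication_enrichment <- function(m, K, n, k) {
  stopifnot(n <= m, K <= m, k >= 0)
  if (K == 0 && k > 0) stop("K = 0 with k > 0 violates the overlap invariant")
  if (k > min(n, K))
    stop("overlap k exceeds min(n, K)")
  enrichment <- if (K > 0) (k / n) / (K / m) else 0
  if (k == 0) enrichment <- 0
  p <- phyper(k - 1, K, m - K, n, lower.tail = FALSE)
  list(universe = m, replicated_in_universe = K, discovery_hits = n,
       overlap = k, enrichment = enrichment, p = p)
}
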