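# The statistical core: association tests between a GWAS trait and
# panel-imputed complex traits, computed from summary statistics alone.
#
# Univariate: the z-score for the regression of Y on an imputed trait
# T = XW is Z = sum_j W_j * (sd(X_j)/sd(T)) * Ztilde_j, where Ztilde are the
# SNP-level GWAS z-scores for Y and the standard deviations come from an
# external reference panel. The standard-deviation (not variance) ratio is
# forced by the OLS algebra: cov(X_j, Y) = var(X_j) * beta_j and
# se(beta_j) ~ sqrt(var(Y) / (N var(X_j))).
#
# Multivariate (conditional): with U the inverse covariance of the K imputed
# traits estimated on the panel,
#   Z_k = U_kk^{-1/2} * e_k' U W' diag(sd(X_j)) Ztilde.
#
# se(gamma) is reconstructed as sqrt(var(Y) / (N var(T))) with var(Y) = 1
# (standardised-outcome convention; z and p are unaffected, gamma/se are on
# the standardised scale).

#' Estimate reference-panel moments for a set of imputation weights
#'
#' Computes per-variant dosage variances and the covariance matrix of the
#' panel-imputed traits (sample covariance, denominator n-1, centred).
#' The inverse of that covariance is the U matrix of the multivariate test.
#'
#' @param w a [weight_matrix]
#' @param panel a [genotype_panel] without missing dosages, >= 2 individuals
#' @return a `panel_moments` list: `var_x`/`sd_x` named by variant key,
#'   `var_t`, `cov_t`, `n_panel`, `unusable_traits`
#' @export
panel_moments <- function(w, panel) {
  if (panel$n_individuals < 2) stop("panel needs >= 2 individuals")
  if (anyNA(panel$dosages))
    stop("panel has missing dosages; run fill_missing_dosages() first")
  scores <- score_panel(w, panel)
  d <- panel$dosages
  mu <- colMeans(d)
  var_x <- (colSums(d^2) - panel$n_individuals * mu^2) /
    (panel$n_individuals - 1)
  var_x <- pmax(var_x, 0)
  names(var_x) <- variant_key(panel$variants)
  cov_t <- cov(scores)
  var_t <- diag(cov_t)
  unusable <- union(attr(scores, "unusable_traits"),
                    w$trait_ids[var_t <= 0])
  if (length(unusable))
    warning("zero-variance imputed trait(s): ", paste(unusable, collapse = ", "))
  structure(list(var_x = var_x, sd_x = sqrt(var_x), var_t = var_t,
                 cov_t = cov_t, n_panel = panel$n_individuals,
                 unusable_traits = unusable),
            class = "panel_moments")
}

# align a weight table with an outcome sumstats table on variant key,
# verifying allele orientation; returns weight rows, sd_x and Ztilde over
# the overlap
.align_for_test <- function(w, ss_y, moments) {
  key_w <- variant_key(w$variants)
  idx <- match(key_w, variant_key(ss_y))
  use <- which(!is.na(idx))
  if (!length(use)) stop("no variant overlap between weights and outcome GWAS")
  flip <- allele_orientation(w$variants$a1[use], w$variants$a2[use],
                             ss_y$a1[idx[use]], ss_y$a2[idx[use]])
  if (anyNA(flip))
    stop("allele mismatch between weights and outcome GWAS; run harmonize()")
  sd_x <- moments$sd_x[key_w[use]]
  if (anyNA(sd_x))
    stop("panel moments missing for ", sum(is.na(sd_x)), " variant(s)")
  list(W = w$weights[use, , drop = FALSE],
       z = ss_y$z[idx[use]] * flip,
       n = ss_y$n[idx[use]],
       sd_x = sd_x)
}

.assoc_row <- function(trait_id, z, n_gwas, var_t, n_snps, analysis) {
  se <- 1 / sqrt(n_gwas * var_t)
  data.frame(trait_id = trait_id, gamma_hat = z * se,
             gamma_std = z / sqrt(n_gwas), se = se, z = z,
             p = p_from_z(z), neglog10_p = neglog10p_from_z(z),
             n_gwas = n_gwas, n_snps = n_snps, analysis = analysis,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Univariate summary-statistics association test
#'
#' Tests the association between the GWAS outcome behind `ss_y` and one
#' panel-imputed trait, using only the outcome's SNP-level z-scores and
#' panel moments. `gamma_hat` is the effect per unit of the imputed trait
#' under the var(Y)=1 convention; `gamma_std` is per standard deviation of
#' the imputed trait.
#'
#' @param w a single-trait [weight_matrix]
#' @param ss_y outcome GWAS [sumstats]
#' @param moments [panel_moments] for `w` on the reference panel
#' @param n_gwas GWAS sample size override; default: median of the
#'   per-variant n over the variants used
#' @return one-row data.frame (AssociationResult)
#' @export
univariate_test <- function(w, ss_y, moments, n_gwas = NULL) {
  stopifnot(length(w$trait_ids) == 1)
  var_t <- moments$var_t[1]
  if (!is.finite(var_t) || var_t <= 0)
    stop("imputed trait has non-positive panel variance; trait unusable")
  al <- .align_for_test(w, ss_y, moments)
  if (is.null(n_gwas)) n_gwas <- median(al$n, na.rm = TRUE)
  if (!is.finite(n_gwas))
    stop("GWAS sample size unavailable; pass n_gwas explicitly")
  z <- sum(al$W[, 1] * al$sd_x * al$z) / sqrt(var_t)
  .assoc_row(w$trait_ids, z, n_gwas, var_t, sum(al$W[, 1] != 0),
             "univariate")
}

#' Multivariate (conditional) summary-statistics association test
#'
#' Jointly tests K imputed traits against the GWAS outcome, conditioning
#' each trait's effect on the others through the inverse panel covariance
#' U of the imputed traits. With K = 1 this reduces exactly to
#' [univariate_test()].
#'
#' @param w a K-trait [weight_matrix]
#' @param ss_y outcome GWAS [sumstats]
#' @param moments [panel_moments] for `w`
#' @param ridge ridge added to the covariance diagonal (fraction of the mean
#'   diagonal) when its condition number exceeds 1e10. `NULL` (default)
#'   applies 1e-6 automatically with a message; `0` disables the fallback
#'   and near-singular covariance is an error naming the most collinear
#'   trait pair
#' @param n_gwas GWAS sample size override (default: median per-variant n)
#' @return data.frame with one AssociationResult row per trait
#' @export
multivariate_test <- function(w, ss_y, moments, ridge = NULL, n_gwas = NULL) {
  K <- length(w$trait_ids)
  cov_t <- moments$cov_t
  kap <- kappa(cov_t, exact = TRUE)
  if (kap > 1e10) {
    if (!is.null(ridge) && ridge == 0) {
      cm <- cov2cor_safe(cov_t)
      diag(cm) <- 0
      worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "imputed-trait covariance is near-singular (condition %.3g); most collinear pair: %s / %s (|r| = %.4f); enable ridge",
        kap, w$trait_ids[worst[1]], w$trait_ids[worst[2]],
        abs(cm[worst[1], worst[2]])))
    }
    lambda <- if (is.null(ridge)) 1e-6 else ridge
    message(sprintf("covariance condition %.3g > 1e10; adding ridge %g * mean(diag)",
                    kap, lambda))
    cov_t <- cov_t + diag(lambda * mean(diag(cov_t)), K)
  }
  U <- solve(cov_t)
  al <- .align_for_test(w, ss_y, moments)
  if (is.null(n_gwas)) n_gwas <- median(al$n, na.rm = TRUE)
  if (!is.finite(n_gwas))
    stop("GWAS sample size unavailable; pass n_gwas explicitly")
  raw <- drop(U %*% crossprod(al$W, al$sd_x * al$z))
  zk <- raw / sqrt(diag(U))
  out <- do.call(rbind, lapply(seq_len(K), function(k)
    .assoc_row(w$trait_ids[k], zk[k], n_gwas, 1 / diag(U)[k],
               sum(al$W[, k] != 0), "multivariate")))
  out
}

cov2cor_safe <- function(m) {
  s <- sqrt(pmax(diag(m), .Machine$double.eps))
  m / tcrossprod(s)
}

#' Scan many imputed traits against one outcome GWAS
#'
#' End-to-end univariate scan: harmonises the weight table, outcome summary
#' statistics and reference panel, mean-imputes missing panel dosages,
#' estimates panel moments, and runs the univariate test for every trait
#' column. Traits that are unusable (zero panel variance or no variant
#' overlap) get an NA row with their name retained.
#'
#' @param weights a [weight_matrix] (any number of traits)
#' @param ss_y outcome GWAS [sumstats]
#' @param panel a [genotype_panel]
#' @param strict_ambiguous passed to [harmonize()]
#' @param n_gwas optional sample-size override
#' @return data.frame of AssociationResult rows, one per trait
#' @export
assoc_scan <- function(weights, ss_y, panel, strict_ambiguous = TRUE,
                       n_gwas = NULL) {
  h <- harmonize(list(weights = weights, outcome = ss_y, panel = panel),
                 strict_ambiguous = strict_ambiguous)
  w <- h$sources$weights
  ss <- h$sources$outcome
  pl <- fill_missing_dosages(h$sources$panel)
  mom <- suppressWarnings(panel_moments(w, pl))
  al <- .align_for_test(w, ss, mom)
  z_num <- drop(crossprod(al$W, al$sd_x * al$z))
  n_snps <- colSums(al$W != 0)
  rows <- lapply(seq_along(w$trait_ids), function(k) {
    tid <- w$trait_ids[k]
    vt <- mom$var_t[k]
    if (tid %in% mom$unusable_traits || !is.finite(vt) || vt <= 0 ||
        n_snps[k] == 0) {
      return(data.frame(trait_id = tid, gamma_hat = NA_real_,
                        gamma_std = NA_real_, se = NA_real_, z = NA_real_,
                        p = NA_real_, neglog10_p = NA_real_,
                        n_gwas = NA_real_, n_snps = n_snps[k],
                        analysis = "univariate", stringsAsFactors = FALSE))
    }
    ng <- if (is.null(n_gwas)) {
      median(al$n[al$W[, k] != 0], na.rm = TRUE)
    } else n_gwas
    .assoc_row(tid, z_num[k] / sqrt(vt), ng, vt, n_snps[k], "univariate")
  })
  do.call(rbind, rows)
}
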