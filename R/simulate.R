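# Seeded synthetic-data engine: block-LD genotypes, the four trait
# simulation settings used to validate the summary-statistics association
# machinery, a per-SNP GWAS scanner, and an individual-level OLS oracle.
#
# Genotypes are a stand-in for a real cohort (access-controlled in the
# motivating studies): a latent Gaussian with exchangeable within-block
# correlation is thresholded into allele counts, giving O(n*m) cost and a
# controllable LD structure. Cohort-specific published numbers therefore do
# not transfer; the engine is for property-level validation.

#' Simulation configuration
#'
#' @param n_individuals cohort size (default 5000; desk-scale stand-in for a
#'   biobank cohort)
#' @param n_variants number of SNPs (default 1000)
#' @param ld_block_size variants per LD block (default 20)
#' @param within_block_corr latent within-block correlation in [0, 1)
#'   (default 0.5)
#' @param maf_range minor-allele-frequency range, drawn uniformly per
#'   variant (default c(0.05, 0.5))
#' @param heritability h^2 of the additive polygenic background (default
#'   0.1, the value used throughout the validation settings)
#' @param prs_effect standardized PRS effect size rho (default 0.02, the
#'   largest value of the power grid)
#' @param gamma_sd sd of the per-pair effect gamma_i in Setting 4 (default
#'   sqrt(2), i.e. gamma_i ~ N(0, 2))
#' @param seed integer; fully determines every draw
#' @return a `sim_config` list
#' @export
sim_config <- function(n_individuals = 5000, n_variants = 1000,
                       ld_block_size = 20, within_block_corr = 0.5,
                       maf_range = c(0.05, 0.5), heritability = 0.1,
                       prs_effect = 0.02, gamma_sd = sqrt(2), seed = 1) {
  stopifnot(n_individuals >= 2, n_variants >= 1, ld_block_size >= 1,
            within_block_corr >= 0, within_block_corr < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            heritability >= 0, heritability < 1, gamma_sd > 0)
  structure(list(n_individuals = n_individuals, n_variants = n_variants,
                 ld_block_size = ld_block_size,
                 within_block_corr = within_block_corr,
                 maf_range = maf_range, heritability = heritability,
                 prs_effect = prs_effect, gamma_sd = gamma_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# non strand-ambiguous allele pairs only, so generated data never trips the
# ambiguity filter by accident
.ALLELE_PAIRS <- matrix(c("A","G", "A","C", "G","A", "C","A",
                          "T","G", "T","C", "G","T", "C","T"),
                        ncol = 2, byrow = TRUE)

# genotype draw using the current RNG state (callers manage the seed)
.gen_genotypes <- function(cfg) {
  n <- cfg$n_individuals; m <- cfg$n_variants; L <- cfg$ld_block_size
  rho <- cfg$within_block_corr
  n_blocks <- ceiling(m / L)
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  thr <- qnorm(1 - maf)
  dos <- matrix(0L, nrow = n, ncol = m)
  for (b in seq_len(n_blocks)) {
    cols <- ((b - 1) * L + 1):min(b * L, m)
    Lb <- length(cols)
    for (gamete in 1:2) {
      u <- rnorm(n)
      lat <- sqrt(rho) * u + sqrt(1 - rho) * matrix(rnorm(n * Lb), n, Lb)
      dos[, cols] <- dos[, cols] +
        (lat > matrix(thr[cols], n, Lb, byrow = TRUE))
    }
  }
  # blocks laid out across 22 chromosomes, 2 Mb apart on each, so a 1 Mb
  # clumping radius never spans two LD blocks
  block_of <- ceiling(seq_len(m) / L)
  chrom <- as.character(1 + (block_of - 1) %% 22)
  block_on_chrom <- (block_of - 1) %/% 22
  offset_in_block <- (seq_len(m) - 1) %% L
  pos <- block_on_chrom * 2e6 + offset_in_block * 5e3 + 1e4
  pair <- .ALLELE_PAIRS[sample.int(nrow(.ALLELE_PAIRS), m, replace = TRUE), ,
                        drop = FALSE]
  variants <- data.frame(id = sprintf("snp%05d", seq_len(m)), chrom = chrom,
                         pos = pos, a1 = pair[, 1], a2 = pair[, 2],
                         stringsAsFactors = FALSE)
  genotype_panel(variants, dos + 0)
}

#' Simulate a block-LD genotype panel
#'
#' Dosages are generated per LD block from a latent Gaussian with
#' exchangeable within-block correlation, thresholded to allele counts at
#' per-variant minor-allele frequencies drawn from `maf_range`. Two
#' independent gametes are summed, so marginals are Binomial(2, maf).
#'
#' @param cfg a [sim_config]
#' @return a [genotype_panel]
#' @export
sim_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  .gen_genotypes(cfg)
}

#' Vectorised per-SNP GWAS statistics for many traits at once
#'
#' Matrix form of [gwas_scan()]: simple linear regression (with intercept)
#' of every trait column on every dosage column. Used by the calibration
#' and power studies, where building one [sumstats] table per trait would
#' dominate the runtime.
#'
#' @param dosages individuals x variants matrix, no missing values
#' @param Y individuals x traits matrix
#' @return list of variants x traits matrices `beta`, `se`, `z`, plus a
#'   per-variant `flagged` logical (zero dosage variance or zero-residual
#'   fit)
#' @export
gwas_scan_stats <- function(dosages, Y) {
  Y <- as.matrix(Y)
  n <- nrow(dosages)
  stopifnot(nrow(Y) == n, n >= 3)
  mx <- colMeans(dosages)
  Sxx <- colSums(dosages^2) - n * mx^2
  Yc <- sweep(Y, 2, colMeans(Y))
  Sxy <- crossprod(dosages, Yc)            # m x k
  Syy <- colSums(Yc^2)
  zerovar <- Sxx <= 0 | !is.finite(Sxx)
  Sxx[zerovar] <- NA
  beta <- Sxy / Sxx
  rss <- pmax(sweep(-beta * Sxy, 2, Syy, `+`), 0)
  se <- sqrt(rss / (n - 2) / Sxx)
  beta[zerovar, ] <- 0
  se[zerovar, ] <- Inf
  z <- beta / se
  # perfect fits (zero residual): effectively infinite z, capped
  big <- se == 0 & beta != 0
  z[big] <- sign(beta[big]) * 1e8
  z[!is.finite(z)] <- 0
  list(beta = beta, se = se, z = z,
       flagged = zerovar | rowSums(big) > 0)
}

#' Per-SNP GWAS of one trait on a genotype panel
#'
#' Simple linear regression of the trait on each variant's dosage with an
#' intercept; classical standard errors. Zero-variance variants are emitted
#' with beta 0, infinite se, p 1 and flagged in the parse log.
#'
#' @param panel a [genotype_panel] without missing dosages
#' @param y numeric trait vector, length = individuals
#' @return a [sumstats] table with per-variant n = number of individuals
#' @export
gwas_scan <- function(panel, y) {
  if (anyNA(panel$dosages)) stop("missing dosages; fill first")
  st <- gwas_scan_stats(panel$dosages, y)
  ss <- sumstats(panel$variants, beta = st$beta[, 1], se = st$se[, 1],
                 z = st$z[, 1], p = p_from_z(st$z[, 1]),
                 n = nrow(panel$dosages),
                 parse_log = list(flagged_zero_variance = sum(st$flagged)))
  ss
}

.sim_output <- function(panel, traits, true_params, sumstats) {
  structure(list(panel = panel, traits = traits, true_params = true_params,
                 sumstats = sumstats),
            class = "sim_output")
}

.scan_all <- function(panel, Y, with_sumstats) {
  if (!with_sumstats) return(NULL)
  lapply(seq_len(ncol(Y)), function(k) gwas_scan(panel, Y[, k]))
}

#' Setting 1: null traits, independent of genotype
#'
#' Traits are i.i.d. standard normal, independent of the genotypes; any
#' association signal downstream is a type-I error.
#'
#' @param cfg a [sim_config]
#' @param n_traits number of traits (default 100)
#' @param with_sumstats also run the per-SNP GWAS for every trait (default
#'   TRUE; disable for large calibration runs that use [gwas_scan_stats()]
#'   directly)
#' @return a `sim_output`: panel, traits (matrix), true_params, sumstats
#'   (list of [sumstats] or NULL)
#' @export
sim_setting1 <- function(cfg, n_traits = 100, with_sumstats = TRUE) {
  set.seed(cfg$seed)
  panel <- .gen_genotypes(cfg)
  Y <- matrix(rnorm(cfg$n_individuals * n_traits), ncol = n_traits)
  colnames(Y) <- paste0("y", seq_len(n_traits))
  .sim_output(panel, Y, list(setting = 1), .scan_all(panel, Y, with_sumstats))
}

# additive polygenic background: X beta rescaled to variance h2, noise to
# 1 - h2, so realized heritability is h2 by construction. `mask` (variants x
# traits, optional) zeroes chosen effects before scaling.
.polygenic_traits <- function(dosages, n_traits, h2, mask = NULL) {
  n <- nrow(dosages); m <- ncol(dosages)
  B <- matrix(rnorm(m * n_traits), ncol = n_traits)
  if (!is.null(mask)) B[mask] <- 0
  G <- dosages %*% B
  gs <- apply(G, 2, sd)
  gs[gs == 0] <- 1
  scaleg <- sqrt(h2) / gs
  G <- sweep(sweep(G, 2, colMeans(G)), 2, scaleg, `*`)
  E <- matrix(rnorm(n * n_traits), ncol = n_traits) * sqrt(1 - h2)
  list(Y = G + E, beta = sweep(B, 2, scaleg, `*`), genetic = G)
}

#' Setting 2: heritable traits not tied to any score
#'
#' Additive random-effect model: Y = X beta + eps with i.i.d. normal beta
#' rescaled so the realized heritability var(X beta)/var(Y) equals
#' `cfg$heritability` (0.1 by default). Traits are associated with SNPs but
#' not constructed from any imputation weight, so score-level scans remain
#' null.
#'
#' @inheritParams sim_setting1
#' @return a `sim_output`; `true_params$beta` holds the rescaled SNP effects
#' @export
sim_setting2 <- function(cfg, n_traits = 100, with_sumstats = TRUE) {
  set.seed(cfg$seed)
  panel <- .gen_genotypes(cfg)
  pg <- .polygenic_traits(panel$dosages, n_traits, cfg$heritability)
  Y <- pg$Y
  colnames(Y) <- paste0("y", seq_len(n_traits))
  .sim_output(panel, Y, list(setting = 2, beta = pg$beta, h2 = cfg$heritability),
              .scan_all(panel, Y, with_sumstats))
}

#' Setting 3: traits with a direct standardized score effect
#'
#' For each weight column, Y = B + rho * P where P is the panel-scored,
#' standardized polygenic score and B is a separately standardized
#' polygenic background plus noise built as in Setting 2 ("normalized
#' separately"). `rho` is the standardized effect size; the grid used for
#' power evaluation is 0.005, 0.008, 0.01, 0.015, 0.02.
#'
#' Because the seed is consumed before `rho` enters, calls that differ only
#' in `rho` share panel, scores and background draws: power curves over a
#' `rho` grid use common random numbers by construction.
#'
#' @param cfg a [sim_config]
#' @param prs_weights a [weight_matrix]; one simulated trait per column
#' @param rho standardized effect size(s); scalar or one per trait column
#'   (default `cfg$prs_effect`)
#' @param with_sumstats run the per-SNP GWAS per trait (default TRUE)
#' @param exclude_score_blocks draw each trait's polygenic background only
#'   on LD blocks that carry none of that trait's score weights (default
#'   FALSE). At biobank scale the chance correlation between a score and an
#'   everywhere-polygenic background is O(sqrt(h2 / M_eff)) and negligible;
#'   a desk-scale cohort does not have enough variants for that dilution, so
#'   this option emulates the large-M regime explicitly.
#' @return a `sim_output`; `true_params` records rho per trait
#' @export
sim_setting3 <- function(cfg, prs_weights, rho = cfg$prs_effect,
                         with_sumstats = TRUE,
                         exclude_score_blocks = FALSE) {
  set.seed(cfg$seed)
  panel <- .gen_genotypes(cfg)
  K <- length(prs_weights$trait_ids)
  rho <- rep_len(rho, K)
  P <- scale(score_panel(prs_weights, panel))
  mask <- NULL
  if (exclude_score_blocks) {
    m <- cfg$n_variants
    block <- ceiling(seq_len(m) / cfg$ld_block_size)
    widx <- match(variant_key(prs_weights$variants),
                  variant_key(panel$variants))
    mask <- matrix(FALSE, m, K)
    for (k in seq_len(K)) {
      hit <- unique(block[widx[prs_weights$weights[, k] != 0]])
      mask[block %in% hit, k] <- TRUE
    }
  }
  pg <- .polygenic_traits(panel$dosages, K, cfg$heritability, mask = mask)
  B <- scale(pg$Y)
  Y <- B + sweep(P, 2, rho, `*`)
  colnames(Y) <- prs_weights$trait_ids
  .sim_output(panel, Y,
              list(setting = 3, rho = structure(rho,
                                                names = prs_weights$trait_ids),
                   beta = pg$beta),
              .scan_all(panel, Y, with_sumstats))
}

#' Setting 4: effect-size recovery across two half-cohorts
#'
#' For each pair i, a heritable exposure trait T_i (h^2 = 0.1 polygenic
#' model) and a response Y_i = gamma_i T_i + eps_i with
#' gamma_i ~ N(0, gamma_sd^2) and eps_i ~ N(0, Var(T_i)). The cohort is
#' split in half: summary statistics for T come from subset 1 and for Y
#' from subset 2, so the exposure GWAS (used to build weights) and the
#' outcome GWAS are independent.
#'
#' @param cfg a [sim_config]
#' @param n_pairs number of (T, Y) pairs (default 100)
#' @param with_sumstats run the per-SNP GWAS scans (default TRUE)
#' @return a `sim_output`; `traits` is `list(t = T, y = Y)`,
#'   `sumstats` is `list(t = ..., y = ...)` (subset-specific),
#'   `true_params$gamma` the generating effects, `$subset1`/`$subset2` the
#'   row indices
#' @export
sim_setting4 <- function(cfg, n_pairs = 100, with_sumstats = TRUE) {
  set.seed(cfg$seed)
  panel <- .gen_genotypes(cfg)
  n <- cfg$n_individuals
  i1 <- seq_len(floor(n / 2)); i2 <- setdiff(seq_len(n), i1)
  pg <- .polygenic_traits(panel$dosages, n_pairs, cfg$heritability)
  Tm <- pg$Y
  gamma <- rnorm(n_pairs, 0, cfg$gamma_sd)
  sds <- apply(Tm, 2, sd)
  E <- matrix(rnorm(n * n_pairs), ncol = n_pairs)
  E <- sweep(E, 2, sds, `*`)               # eps_i ~ N(0, Var(T_i))
  Y <- sweep(Tm, 2, gamma, `*`) + E
  colnames(Tm) <- paste0("t", seq_len(n_pairs))
  colnames(Y) <- paste0("y", seq_len(n_pairs))
  p1 <- genotype_panel(panel$variants, panel$dosages[i1, , drop = FALSE])
  p2 <- genotype_panel(panel$variants, panel$dosages[i2, , drop = FALSE])
  ss <- if (with_sumstats)
    list(t = lapply(seq_len(n_pairs), function(k) gwas_scan(p1, Tm[i1, k])),
         y = lapply(seq_len(n_pairs), function(k) gwas_scan(p2, Y[i2, k])))
  .sim_output(panel, list(t = Tm, y = Y),
              list(setting = 4, gamma = gamma, beta = pg$beta,
                   var_t = sds^2, subset1 = i1, subset2 = i2),
              ss)
}

#' Random sparse imputation weights for simulation studies
#'
#' Draws `n_traits` weight columns, each with `snps_per_trait` N(0, 1)
#' weights on variants sampled without replacement from the panel. Uses the
#' current RNG state; seed at the call site.
#'
#' @param panel a [genotype_panel]
#' @param n_traits number of weight columns (default 20)
#' @param snps_per_trait nonzero weights per trait (default 30)
#' @return a [weight_matrix]
#' @export
sim_weights <- function(panel, n_traits = 20, snps_per_trait = 30) {
  m <- nrow(panel$variants)
  stopifnot(snps_per_trait <= m)
  W <- matrix(0, nrow = m, ncol = n_traits)
  for (k in seq_len(n_traits))
    W[sample.int(m, snps_per_trait), k] <- rnorm(snps_per_trait)
  weight_matrix(panel$variants, W, paste0("prs", seq_len(n_traits)))
}

#' Individual-level OLS oracle
#'
#' Exact ordinary-least-squares fit of a trait on imputed scores with an
#' intercept and classical standard errors; the ground truth against which
#' the summary-statistics tests are validated. `multivariate = FALSE` fits
#' each score marginally; `TRUE` fits all scores jointly.
#'
#' @param scores individuals x traits matrix (e.g. [score_panel()] output)
#' @param y trait vector
#' @param multivariate joint fit instead of per-score marginal fits
#' @return data.frame: trait_id, gamma_hat, se, z, p, capped (TRUE where a
#'   zero-residual fit produced an effectively infinite z, capped at 1e8)
#' @export
ols_oracle <- function(scores, y, multivariate = FALSE) {
  scores <- as.matrix(scores)
  n <- length(y)
  K <- ncol(scores)
  ids <- colnames(scores)
  if (is.null(ids)) ids <- paste0("trait", seq_len(K))
  cap <- function(g, se) {
    z <- g / se
    capped <- !is.finite(z) | abs(z) > 1e8
    z[capped] <- sign(g[capped]) * 1e8
    data.frame(gamma_hat = g, se = se, z = z, p = p_from_z(z),
               capped = capped)
  }
  if (!multivariate) {
    stopifnot(n > 2)
    st <- gwas_scan_stats(scores, matrix(y, ncol = 1))
    out <- cap(st$beta[, 1], st$se[, 1])
  } else {
    stopifnot(n > K + 1)
    X <- cbind(`(intercept)` = 1, scores)
    qx <- qr(X)
    if (qx$rank < ncol(X)) stop("rank-deficient design in joint OLS fit")
    coefs <- qr.coef(qx, y)
    res <- y - X %*% coefs
    sigma2 <- sum(res^2) / (n - ncol(X))
    covb <- chol2inv(qr.R(qx)) * sigma2
    out <- cap(coefs[-1], sqrt(diag(covb))[-1])
  }
  cbind(data.frame(trait_id = ids, stringsAsFactors = FALSE), out)
}
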