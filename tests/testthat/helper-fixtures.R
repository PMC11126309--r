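# Small in-code fixtures shared across test files.

toy_variants <- function(n, chrom = "1", pos = NULL, a1 = "A", a2 = "G") {
  data.frame(id = paste0("rs", seq_len(n)), chrom = chrom,
             pos = if (is.null(pos)) seq_len(n) * 1e4 else pos,
             a1 = rep_len(a1, n), a2 = rep_len(a2, n),
             stringsAsFactors = FALSE)
}

toy_sumstats <- function(beta, se, pos = NULL, n = 1000, chrom = "1",
                         a1 = "A", a2 = "G") {
  v <- toy_variants(length(beta), chrom = chrom, pos = pos, a1 = a1, a2 = a2)
  sumstats(v, beta = beta, se = se, z = beta / se, n = n)
}

# panel with explicitly chosen dosage columns
toy_panel <- function(dosage_cols, pos = NULL, chrom = "1",
                      a1 = "A", a2 = "G") {
  d <- do.call(cbind, dosage_cols)
  v <- toy_variants(ncol(d), chrom = chrom, pos = pos, a1 = a1, a2 = a2)
  genotype_panel(v, d)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  path
}

# a small, fully worked simulation shared by several test files
small_sim <- function(seed = 42, n = 800, m = 120, n_traits = 5) {
  cfg <- sim_config(n_individuals = n, n_variants = m, ld_block_size = 10,
                    seed = seed)
  set.seed(seed + 1000)
  panel0 <- sim_genotypes(cfg)
  w <- sim_weights(panel0, n_traits = n_traits, snps_per_trait = 15)
  rho <- c(0.15, rep(0, n_traits - 1))
  sim <- sim_setting3(cfg, w, rho = rho, with_sumstats = FALSE)
  y <- sim$traits[, 1]
  list(cfg = cfg, panel = sim$panel, weights = w, y = y,
       ss = gwas_scan(sim$panel, y))
}
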