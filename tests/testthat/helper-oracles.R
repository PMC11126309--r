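# Independent reference implementations used as oracles. These stay
# deliberately naive (nested loops, explicit sums) and share no code with
# the package internals they check.

# greedy clumping, straight transliteration of the procedure: repeatedly
# pick the open variant with the smallest p (ties: chrom, then pos), close
# every open same-chromosome variant within the radius whose r^2 with it
# exceeds the cutoff
reference_clump <- function(ss, dosages, r2_cutoff, radius_bp) {
  m <- nrow(ss)
  status <- rep("open", m)
  repeat {
    open <- which(status == "open")
    if (!length(open)) break
    o <- open[order(ss$p[open], ss$chrom[open], ss$pos[open])]
    i <- o[1]
    status[i] <- "index"
    for (j in which(status == "open")) {
      if (ss$chrom[j] != ss$chrom[i]) next
      if (abs(ss$pos[j] - ss$pos[i]) > radius_bp) next
      si <- sd(dosages[, i]); sj <- sd(dosages[, j])
      r2 <- if (si == 0 || sj == 0) 0 else cor(dosages[, i], dosages[, j])^2
      if (r2 > r2_cutoff) status[j] <- "removed"
    }
  }
  ss$id[status == "index"]
}

# upper-tail hypergeometric by brute-force summation over the support
reference_hyper_p <- function(m, K, n, k) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(m - K, n - js)) / choose(m, n)
}

# hand-written allele-pair truth table: expected orientation of a source
# pair (b1,b2) against the non-ambiguous reference pair (A,G); NA means the
# pair cannot be reconciled in any orientation. Palindromic source pairs
# (A/T, C/G) can never match a non-palindromic reference.
AG_TRUTH <- c("A/G" = +1, "G/A" = -1,   # direct / effect-allele swap
              "T/C" = +1, "C/T" = -1,   # opposite strand (complement first)
              "A/C" = NA, "C/A" = NA, "G/T" = NA, "T/G" = NA,
              "A/T" = NA, "T/A" = NA, "C/G" = NA, "G/C" = NA)
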