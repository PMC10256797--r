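# Small in-code fixtures shared across the suite.

# Two-chromosome genome used in the worked coverage/enrichment examples:
# chrA 1000 bp diploid no gaps; chrY 500 bp haploid with a 100 bp gap.
toy_genome <- function() {
  genome_def(c(chrA = 1000, chrY = 500),
             gaps = data.frame(chrom = "chrY", start = 101, end = 200),
             ploidy = c(chrY = 1))
}

# Quick single-platform panel from positions/types/lengths, all precise,
# with a given genotype matrix (defaults to one alt carrier per record).
toy_panel <- function(pos, type, length, gt = NULL, gq = NULL,
                      samples = c("s1", "s2"), precise = TRUE,
                      chrom = "chrY", platform = NULL) {
  n <- length(pos)
  records <- tibble::tibble(id = sprintf("v%d", seq_len(n)), chrom = chrom,
                            pos = as.numeric(pos), type = type,
                            length = as.numeric(length),
                            precise = rep_len(precise, n))
  if (is.null(gt)) {
    gt <- matrix("hom_ref", n, length(samples))
    gt[, 1] <- "hom_alt"
  }
  sv_panel(records, gt, gq, samples = samples, platform = platform)
}

# Independent brute-force contiguity oracle: sort descending, scan.
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  acc <- 0
  for (i in seq_along(s)) {
    acc <- acc + s[i]
    if (acc >= sum(s) / 2) return(list(n50 = s[i], l50 = i))
  }
}

# Random binary vector with both classes present.
rand_binary <- function(n, p = 0.5) {
  repeat {
    x <- rbinom(n, 1, p)
    if (any(x == 1) && any(x == 0)) return(x)
  }
}
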