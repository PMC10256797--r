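#' Simulate a mapping summary under targeted enrichment
#'
#' Allocates `total_bases` across chromosomes multinomially with
#' probability proportional to each chromosome's ploidy-weighted non-N size,
#' multiplied by `fold` for the target chromosome. With target share `w`,
#' the expected enrichment factor of the target is
#' `fold / (w * fold + 1 - w)` (see [expected_enrichment()]); with
#' `fold = 1` every chromosome's expected factor is 1.
#'
#' @param genome A `genome_def` (or a `sim_genome`, whose genome is used).
#' @param fold Enrichment fold for the target (>= 1).
#' @param total_bases Total mapped bases to allocate (> 0).
#' @param target Target chromosome name.
#' @param seed Integer seed.
#' @param sample Sample label.
#' @return A mapping-summary tibble (`sample`, `chrom`, `mapped_bases`).
#' @export
simulate_mapping <- function(genome, fold = 50, total_bases = 1e7,
                             target = "chrY", seed = 1, sample = "sim") {
  if (is(genome, "sim_genome")) {
    target <- genome$target
    genome <- genome$genome
  }
  stopifnot(is(genome, "genome_def"))
  if (fold < 1) stop("fold must be >= 1", call. = FALSE)
  if (total_bases <= 0) stop("total_bases must be positive", call. = FALSE)
  if (!target %in% genome$chromosomes$name) {
    stop(sprintf("target chromosome %s not in genome", target), call. = FALSE)
  }
  p <- non_n_sizes(genome) * genome$ploidy
  p[target] <- p[target] * fold
  p <- p / sum(p)
  withr::with_seed(derive_seed(seed, "mapping"), {
    counts <- as.numeric(rmultinom(1, size = total_bases, prob = p))
  })
  tibble(sample = sample, chrom = names(p), mapped_bases = counts)
}
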