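#' Per-chromosome coverage excluding assembly gaps
#'
#' Coverage of a chromosome is its mapped bases divided by its non-N size
#' (length minus N-gap bases). Chromosomes present in the genome but absent
#' from the summary are reported with zero mapped bases.
#'
#' @param summary Mapping-summary tibble (`sample`, `chrom`, `mapped_bases`).
#' @param genome A `genome_def`.
#' @return Tibble with `sample`, `chrom`, `mapped_bases`, `coverage`.
#' @export
#' @examples
#' g <- genome_def(c(chrY = 500),
#'                 gaps = data.frame(chrom = "chrY", start = 101, end = 200))
#' s <- tibble::tibble(sample = "s1", chrom = "chrY", mapped_bases = 800)
#' chromosome_coverage(s, g)$coverage  # 800 / 400 = 2
chromosome_coverage <- function(summary, genome) {
  .assert_cols(summary, c("sample", "chrom", "mapped_bases"), "mapping summary")
  stopifnot(is(genome, "genome_def"))
  unknown <- setdiff(unique(summary$chrom), genome$chromosomes$name)
  if (length(unknown) > 0L) {
    stop(sprintf("mapped bases on chromosome(s) absent from genome: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  nn <- non_n_sizes(genome)
  grid <- tidyr::expand_grid(sample = unique(summary$sample),
                             chrom = genome$chromosomes$name)
  out <- grid |>
    left_join(summary, by = c("sample", "chrom")) |>
    mutate(mapped_bases = ifelse(is.na(.data$mapped_bases), 0,
                                 .data$mapped_bases))
  bad <- nn[out$chrom] == 0 & out$mapped_bases > 0
  if (any(bad)) {
    stop(sprintf("chromosome %s has zero non-N size but mapped bases",
                 paste(unique(out$chrom[bad]), collapse = ", ")), call. = FALSE)
  }
  out$coverage <- as.numeric(
    ifelse(nn[out$chrom] > 0, out$mapped_bases / nn[out$chrom], 0))
  out
}

#' Ploidy-aware enrichment factor per chromosome
#'
#' The enrichment factor of a chromosome is its share of all mapped bases
#' divided by its expected share, where the expected share is the
#' chromosome's non-N size times its ploidy over the ploidy-weighted non-N
#' genome size. A value of 1 means no enrichment. Chromosomes with zero
#' mapped bases are reported with factor 0, not dropped.
#'
#' By construction the factors satisfy the conservation identity
#' `sum(EF * w) = 1`, where `w` is the ploidy-weighted non-N share of each
#' chromosome, and are invariant under uniform rescaling of mapped bases.
#'
#' @inheritParams chromosome_coverage
#' @return Tibble with `sample`, `chrom`, `mapped_bases`, `coverage`,
#'   `weight` (the expected share `w`) and `enrichment_factor`.
#' @export
enrichment_factor <- function(summary, genome) {
  cov <- chromosome_coverage(summary, genome)
  nn <- non_n_sizes(genome)
  dip <- diploid_genome_size(genome)
  w <- nn * genome$ploidy / dip
  tot <- tapply(cov$mapped_bases, cov$sample, sum)
  if (any(tot == 0)) {
    stop(sprintf("total mapped bases is zero for sample(s): %s",
                 paste(names(tot)[tot == 0], collapse = ", ")), call. = FALSE)
  }
  cov$weight <- unname(w[cov$chrom])
  cov$enrichment_factor <- as.numeric(
    (cov$mapped_bases / unname(tot[cov$sample])) / cov$weight)
  cov
}

#' Expected enrichment factor of a target enriched by a given fold
#'
#' Closed form for the multinomial enrichment model: if reads are allocated
#' proportionally to ploidy-weighted non-N size except that the target's
#' allocation is multiplied by `fold`, the target's enrichment factor is
#' `fold / (w * fold + 1 - w)` where `w` is the target's expected share.
#'
#' @param fold Enrichment fold applied to the target's allocation.
#' @param w Target's ploidy-weighted non-N share of the genome.
#' @return Expected enrichment factor.
#' @export
#' @examples
#' expected_enrichment(50, 0.01)  # ~33.56
expected_enrichment <- function(fold, w) {
  stopifnot(fold >= 0, w >= 0, w <= 1)
  fold / (w * fold + 1 - w)
}

#' Per-sample enrichment report with autosome mean and SD
#'
#' Summarises an [enrichment_factor()] table into one row per sample: the
#' target chromosome's enrichment factor (optionally merging unplaced target
#' contigs into the target before computing it) and the mean and standard
#' deviation of the autosomal factors. Autosomes are all chromosomes except
#' the configured sex chromosomes and unplaced contigs (names containing
#' an underscore).
#'
#' @param ef Output of [enrichment_factor()].
#' @param target Target chromosome name (e.g. `"chrY"`).
#' @param merge_with Optional character vector of contigs (e.g. a
#'   `chrY_random`-like contig) merged with the target: their mapped bases
#'   and expected shares are pooled.
#' @param sex_chroms Chromosomes excluded from the autosome set.
#' @return Tibble with `sample`, `target_ef`, `autosome_mean`, `autosome_sd`,
#'   `n_autosomes`.
#' @export
enrichment_report <- function(ef, target, merge_with = NULL,
                              sex_chroms = c("chrX", "chrY")) {
  .assert_cols(ef, c("sample", "chrom", "mapped_bases", "weight",
                     "enrichment_factor"), "enrichment table")
  target_set <- c(target, merge_with)
  if (!all(target_set %in% ef$chrom)) {
    stop("target chromosome(s) not present in enrichment table", call. = FALSE)
  }
  auto <- setdiff(unique(ef$chrom),
                  c(sex_chroms, target_set,
                    grep("_", unique(ef$chrom), value = TRUE)))
  ef |>
    group_by(.data$sample) |>
    summarise(
      target_ef = (sum(.data$mapped_bases[.data$chrom %in% target_set]) /
                     sum(.data$mapped_bases)) /
        sum(.data$weight[.data$chrom %in% target_set]),
      autosome_mean = mean(.data$enrichment_factor[.data$chrom %in% auto]),
      autosome_sd = sd(.data$enrichment_factor[.data$chrom %in% auto]),
      n_autosomes = length(auto),
      .groups = "drop"
    )
}
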