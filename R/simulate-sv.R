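#' Simulate phylogeny-structured hemizygous SV panels on two platforms
#'
#' Each variant is assigned to a uniformly chosen branch of the haplogroup
#' tree (including a "root" pseudo-branch); all leaves below the branch
#' carry the alternative, hemizygous genotype (`hom_alt`), the rest are
#' `hom_ref`. The first panel reports the true genotypes (long-read-like);
#' the second perturbs them by flipping present/absent with probability
#' `platform_error` (short-read-like genotyping noise). Missing genotypes
#' are injected in both panels at `missing_rate`.
#'
#' @param tree Rooted `phylo`; tip labels are the sample names.
#' @param n_variants Number of variants.
#' @param platform_error Per-genotype flip probability in the second panel.
#' @param missing_rate Per-genotype missingness probability.
#' @param chrom,chrom_length Chromosome on which positions are drawn.
#' @param seed Integer seed.
#' @return List with `ont` and `illumina` (`sv_panel`s) and `truth` (list:
#'   `branch` node assignments, `carriers` per-variant tip sets, `expected`
#'   binary matrix, `records`).
#' @export
simulate_sv_panel <- function(tree, n_variants = 100, platform_error = 0.1,
                              missing_rate = 0.05, chrom = "chrY",
                              chrom_length = 5e6, seed = 1) {
  stopifnot(is(tree, "phylo"))
  stopifnot(platform_error >= 0, platform_error <= 1,
            missing_rate >= 0, missing_rate <= 1)
  samples <- tree$tip.label
  n_s <- length(samples)
  if (n_variants == 0L) {
    warning("n_variants is 0; returning empty panels", call. = FALSE)
    empty <- sv_panel(tibble(id = character(0), chrom = character(0),
                             pos = numeric(0), type = character(0),
                             length = numeric(0), precise = logical(0)),
                      matrix(character(0), 0, n_s,
                             dimnames = list(NULL, samples)))
    return(list(ont = empty, illumina = empty,
                truth = list(branch = integer(0), carriers = list(),
                             expected = matrix(0, 0, n_s))))
  }
  withr::with_seed(derive_seed(seed, "svpanel"), {
    # candidate branches: every edge's child node, plus the root (node 0
    # stands for a variant carried by every sample)
    nodes <- c(0L, tree$edge[, 2])
    branch <- sample(nodes, n_variants, replace = TRUE)
    carriers <- lapply(branch, function(nd) {
      if (nd == 0L) samples
      else samples[phangorn::Descendants(tree, nd, type = "tips")[[1]]]
    })
    expected <- t(vapply(carriers, function(cc) as.numeric(samples %in% cc),
                         numeric(n_s)))
    colnames(expected) <- samples

    pos <- as.numeric(sort(sample.int(chrom_length - 1e4, n_variants)))
    records <- tibble(
      id = sprintf("sv%04d", seq_len(n_variants)),
      chrom = chrom, pos = pos,
      type = sample(c("INS", "DEL"), n_variants, replace = TRUE),
      length = round(10 * 10^runif(n_variants, 0, 2.5)),
      precise = TRUE)
    rownames(expected) <- records$id

    gt_true <- ifelse(expected == 1, "hom_alt", "hom_ref")
    gq <- matrix(round(runif(n_variants * n_s, 30, 99)), n_variants, n_s)

    flip <- matrix(runif(n_variants * n_s) < platform_error, n_variants, n_s)
    gt_ill <- gt_true
    gt_ill[flip & gt_true == "hom_alt"] <- "hom_ref"
    gt_ill[flip & gt_true == "hom_ref"] <- "hom_alt"

    miss_ont <- matrix(runif(n_variants * n_s) < missing_rate, n_variants, n_s)
    miss_ill <- matrix(runif(n_variants * n_s) < missing_rate, n_variants, n_s)
    gt_ont <- gt_true
    gt_ont[miss_ont] <- "missing"
    gt_ill[miss_ill] <- "missing"

    list(
      ont = sv_panel(records, gt_ont, gq, samples = samples,
                     platform = "ONT"),
      illumina = sv_panel(records, gt_ill, gq, samples = samples,
                          platform = "Illumina"),
      truth = list(branch = branch, carriers = carriers,
                   expected = expected, records = records))
  })
}
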