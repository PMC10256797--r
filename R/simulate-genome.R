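#' Simulate a reference genome with a chrY-like target chromosome
#'
#' Builds a reduced-scale male reference genome: a handful of diploid
#' autosomes, a haploid chrX-like chromosome and a haploid target chromosome
#' carrying annotations with the structure of the male-specific region of
#' chrY: five mutually exclusive, exhaustive sequence classes (PAR,
#' X-degenerate, X-transposed, ampliconic, heterochromatic), CpG islands,
#' repeat intervals with class labels, and multi-exon gene models. Each
#' chromosome receives N-gap intervals totalling `gap_fraction` of its
#' length. All output is deterministic for a fixed seed.
#'
#' The default lengths are a desk-scale rendition of a human male karyotype:
#' the target is ~1% of the ploidy-weighted genome, as chrY is in GRCh38.
#'
#' @param seed Integer seed (fanned out internally, see [derive_seed()]).
#' @param autosome_lengths Named vector of autosome lengths (bp).
#' @param x_name,x_length Name/length of the haploid X-like chromosome.
#' @param target_name,target_length Name/length of the target chromosome.
#' @param gap_fraction Fraction of each chromosome covered by N gaps.
#' @param class_fractions Named fractions for the five sequence classes;
#'   must sum to 1.
#' @param n_cgi,cgi_width Number and width (bp) of CpG islands on the target.
#' @param n_repeats Number of repeat intervals on the target.
#' @param n_genes Number of gene models on the target.
#' @return A list of class `sim_genome` with elements `genome`
#'   (a [genome_def()]), `annotations` (list: `classes`, `cgi`, `repeats`,
#'   `genes`), `target` and `seed`.
#' @export
make_genome <- function(seed = 1,
                        autosome_lengths = c(chr1 = 8e6, chr2 = 6e6,
                                             chr3 = 5e6, chr4 = 4e6),
                        x_name = "chrX", x_length = 4e6,
                        target_name = "chrY", target_length = 5e5,
                        gap_fraction = 0.3,
                        class_fractions = c(PAR = 0.05,
                                            `X-degenerate` = 0.35,
                                            `X-transposed` = 0.10,
                                            ampliconic = 0.25,
                                            heterochromatic = 0.25),
                        n_cgi = 30, cgi_width = 1000,
                        n_repeats = 150, n_genes = 10) {
  if (abs(sum(class_fractions) - 1) > 1e-6) {
    stop("class fractions must sum to 1", call. = FALSE)
  }
  if (any(c(autosome_lengths, x_length, target_length) < 1e4)) {
    stop("chromosome lengths must be at least 10 kb", call. = FALSE)
  }
  withr::with_seed(derive_seed(seed, "genome"), {
    lens <- c(autosome_lengths,
              setNames(x_length, x_name), setNames(target_length, target_name))
    ploidy <- setNames(c(rep(2, length(autosome_lengths)), 1, 1),
                       c(names(autosome_lengths), x_name, target_name))

    # gaps: 3 non-overlapping intervals per chromosome (one per chromosome
    # third) totalling gap_fraction of the length
    gaps <- do.call(rbind, lapply(names(lens), function(ch) {
      L <- lens[[ch]]
      total <- round(gap_fraction * L)
      if (total == 0) return(NULL)
      w <- round(total * c(0.5, 0.3, 0.2))
      w[1] <- total - sum(w[-1])
      w <- w[w > 0]
      if (any(w >= floor(L / 3))) {
        stop("gap_fraction too large for the three-gap layout", call. = FALSE)
      }
      seg <- floor(L / 3) * (seq_along(w) - 1)
      offs <- vapply(w, function(wk) sample.int(floor(L / 3) - wk, 1),
                     integer(1))
      start <- seg + offs
      data.frame(chrom = ch, start = start, end = start + w - 1)
    }))
    genome <- genome_def(lens, gaps = gaps, ploidy = ploidy)

    # sequence classes tile the target chromosome
    edges <- round(cumsum(c(0, class_fractions)) * target_length)
    edges[length(edges)] <- target_length
    classes <- GenomicRanges::GRanges(
      target_name,
      IRanges::IRanges(head(edges, -1) + 1, tail(edges, -1)),
      name = names(class_fractions))

    # CpG islands: non-overlapping, away from the chromosome ends
    slots <- seq(5000, target_length - 5000 - cgi_width,
                 length.out = max(n_cgi * 3, 10))
    starts <- sort(sample(round(slots), n_cgi))
    cgi <- GenomicRanges::GRanges(
      target_name, IRanges::IRanges(starts, width = cgi_width),
      name = paste0("CGI_", seq_len(n_cgi)))
    cgi <- cgi[!duplicated(GenomicRanges::start(cgi))]

    repeat_classes <- c("Alu", "L1", "LTR12B", "Simple_repeat", "Satellite")
    rep_start <- sample.int(target_length - 5000, n_repeats)
    repeats <- GenomicRanges::GRanges(
      target_name,
      IRanges::IRanges(rep_start, width = sample(50:3000, n_repeats,
                                                 replace = TRUE)),
      name = sample(repeat_classes, n_repeats, replace = TRUE))

    genes <- .simulate_genes(target_name, target_length, classes, n_genes)

    structure(list(genome = genome,
                   annotations = list(classes = classes, cgi = cgi,
                                      repeats = repeats, genes = genes),
                   target = target_name, seed = seed),
              class = "sim_genome")
  })
}

# Multi-exon gene models placed inside the X-degenerate and ampliconic
# classes, where most Y genes live.
.simulate_genes <- function(chrom, chrom_length, classes, n_genes) {
  host <- classes[classes$name %in% c("X-degenerate", "ampliconic")]
  spans <- sample(seq_along(host), n_genes, replace = TRUE,
                  prob = GenomicRanges::width(host))
  tx_list <- lapply(seq_len(n_genes), function(i) {
    h <- host[spans[i]]
    lo <- GenomicRanges::start(h) + 3000
    hi <- GenomicRanges::end(h) - 3000
    width <- sample(8000:20000, 1)
    start <- sample(seq(lo, max(lo + 1, hi - width)), 1)
    end <- start + width - 1
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(2:4, 1)
    cuts <- sort(sample(seq(start + 500, end - 500, by = 100), 2 * (n_ex - 1)))
    ex_start <- c(start, cuts[seq(2, length(cuts), by = 2)])
    ex_end <- c(cuts[seq(1, length(cuts), by = 2)], end)
    thick <- IRanges::IRanges(start + round(width * 0.2),
                              end - round(width * 0.2))
    GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start, end), strand = strand,
      name = sprintf("gene%02d", i), thick = thick,
      blocks = IRanges::IRangesList(
        IRanges::IRanges(ex_start - start + 1, ex_end - start + 1)))
  })
  gene_models(do.call(c, tx_list))
}

#' Simulate contig lengths for contiguity-metric checks
#'
#' Draws heavy-tailed (log-normal) sequence lengths, reproducible for a
#' fixed seed, as input to [contiguity_stats()] and its brute-force oracle.
#'
#' @param n Number of contigs (>= 1).
#' @param meanlog,sdlog Log-normal parameters of the length distribution.
#' @param seed Integer seed.
#' @return Integer vector of `n` positive lengths.
#' @export
simulate_contigs <- function(n, meanlog = 11, sdlog = 1, seed = 1) {
  stopifnot(n >= 1)
  withr::with_seed(derive_seed(seed, "contigs"), {
    pmax(1L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
  })
}
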