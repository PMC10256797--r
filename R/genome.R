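#' Genome definition: chromosome sizes, assembly gaps and ploidies
#'
#' A `genome_def` holds the denominator universe for coverage and enrichment
#' calculations: ordered chromosome lengths, the N-gap intervals of the
#' assembly, and a per-chromosome ploidy (2 for autosomes in a diploid
#' genome, 1 for the sex chromosomes of a male). Gaps are normalized on
#' construction: merged, and clipped to the chromosome bounds.
#'
#' @param chromosomes A data frame with columns `name` and `length` (bp), or a
#'   named numeric vector of lengths. Order is preserved.
#' @param gaps `NULL`, or a [GenomicRanges::GRanges] / data frame
#'   (`chrom`, `start`, `end`, 1-based closed) of N stretches.
#' @param ploidy Named vector of per-chromosome ploidy overrides
#'   (e.g. `c(chrY = 1, chrX = 1)`).
#' @param default_ploidy Ploidy assumed for chromosomes not named in `ploidy`.
#' @return An object of class `genome_def`.
#' @export
#' @examples
#' g <- genome_def(c(chr1 = 1000, chrY = 500),
#'                 gaps = data.frame(chrom = "chrY", start = 101, end = 200),
#'                 ploidy = c(chrY = 1))
#' non_n_sizes(g)
genome_def <- function(chromosomes, gaps = NULL, ploidy = NULL,
                       default_ploidy = 2L) {
  if (is.numeric(chromosomes) && !is.null(names(chromosomes))) {
    chromosomes <- tibble(name = names(chromosomes),
                          length = unname(chromosomes))
  }
  chromosomes <- as_tibble(chromosomes)
  .assert_cols(chromosomes, c("name", "length"), "chromosome table")
  if (anyDuplicated(chromosomes$name)) {
    stop("duplicated chromosome names in sizes", call. = FALSE)
  }
  len <- chromosomes$length
  if (any(is.na(len)) || any(len != round(len)) || any(len <= 0)) {
    stop("chromosome lengths must be positive integers", call. = FALSE)
  }
  chromosomes$length <- as.numeric(len)

  if (is.null(gaps)) {
    gr <- GenomicRanges::GRanges()
  } else if (is(gaps, "GRanges")) {
    gr <- gaps
  } else {
    gaps <- as_tibble(gaps)
    .assert_cols(gaps, c("chrom", "start", "end"), "gap table")
    gr <- GenomicRanges::GRanges(gaps$chrom,
                                 IRanges::IRanges(gaps$start, gaps$end))
  }
  gap_chroms <- as.character(unique(GenomicRanges::seqnames(gr)))
  unknown <- setdiff(gap_chroms, chromosomes$name)
  if (length(unknown) > 0L) {
    stop(sprintf("gap interval on chromosome absent from sizes: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (length(gr) > 0L) {
    # clip to [1, length] then merge overlaps
    maxend <- chromosomes$length[match(as.character(GenomicRanges::seqnames(gr)),
                                       chromosomes$name)]
    GenomicRanges::start(gr) <- pmax(GenomicRanges::start(gr), 1L)
    GenomicRanges::end(gr) <- pmin(GenomicRanges::end(gr), maxend)
    gr <- gr[GenomicRanges::width(gr) > 0L]
    gr <- GenomicRanges::reduce(gr)
  }

  pl <- rep(as.numeric(default_ploidy), nrow(chromosomes))
  names(pl) <- chromosomes$name
  if (!is.null(ploidy) && length(ploidy) > 0L) {
    if (is.null(names(ploidy))) stop("ploidy overrides must be named", call. = FALSE)
    unknown <- setdiff(names(ploidy), chromosomes$name)
    if (length(unknown) > 0L) {
      stop(sprintf("ploidy given for chromosome absent from sizes: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    if (any(ploidy <= 0)) stop("ploidy must be positive", call. = FALSE)
    pl[names(ploidy)] <- as.numeric(ploidy)
  }

  out <- structure(list(chromosomes = chromosomes, gaps = gr, ploidy = pl),
                   class = "genome_def")
  stopifnot(all(non_n_sizes(out) >= 0))
  out
}

#' @export
print.genome_def <- function(x, ...) {
  cat(sprintf("<genome_def> %d chromosomes, %d gap intervals\n",
              nrow(x$chromosomes), length(x$gaps)))
  df <- x$chromosomes
  df$non_n <- non_n_sizes(x)
  df$ploidy <- x$ploidy[df$name]
  print(as_tibble(df), n = 10)
  invisible(x)
}

#' Read a genome definition from a sizes TSV and a gap BED
#'
#' @param sizes_path Two-column TSV (`name`, `length`), headerless or with a
#'   header row.
#' @param gaps_path Optional BED3 of assembly gaps (0-based half-open on disk;
#'   converted on read).
#' @param ploidy,default_ploidy See [genome_def()].
#' @return A `genome_def`.
#' @export
read_genome_def <- function(sizes_path, gaps_path = NULL,
                            ploidy = NULL, default_ploidy = 2L) {
  first <- strsplit(readLines(sizes_path, n = 1L), "\t")[[1]]
  has_header <- length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2])))
  sizes <- readr::read_tsv(sizes_path,
                           col_names = if (has_header) TRUE else c("name", "length"),
                           skip = 0, show_col_types = FALSE)
  names(sizes)[1:2] <- c("name", "length")
  gaps <- if (!is.null(gaps_path)) rtracklayer::import(gaps_path, format = "bed")
  genome_def(sizes[, c("name", "length")], gaps = gaps,
             ploidy = ploidy, default_ploidy = default_ploidy)
}

#' Non-N (gap-excluded) chromosome sizes
#'
#' @param genome A `genome_def`.
#' @return Named numeric vector: `length - total gap length` per chromosome.
#' @export
non_n_sizes <- function(genome) {
  stopifnot(is(genome, "genome_def"))
  sizes <- setNames(genome$chromosomes$length, genome$chromosomes$name)
  if (length(genome$gaps) > 0L) {
    gap_by <- tapply(GenomicRanges::width(genome$gaps),
                     as.character(GenomicRanges::seqnames(genome$gaps)), sum)
    sizes[names(gap_by)] <- sizes[names(gap_by)] - gap_by
  }
  sizes
}

#' Ploidy-weighted non-N genome size
#'
#' The "diploid genome size without N": the sum over chromosomes of non-N
#' size times ploidy. This is the denominator of the expected share of each
#' chromosome in the enrichment-factor calculation.
#'
#' @param genome A `genome_def`.
#' @return A single number (bp).
#' @export
diploid_genome_size <- function(genome) {
  sum(non_n_sizes(genome) * genome$ploidy)
}
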