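#' Load a per-CpG methylation frequency table
#'
#' Reads the nanopolish-dialect TSV (columns `chromosome`, `start`, `end`,
#' `num_motifs_in_group`, `called_sites`, `called_sites_methylated`,
#' `methylated_frequency`, `group_sequence`), converting its 0-based
#' positions to the package's 1-based convention on read. Rows where the
#' methylated count exceeds the coverage are rejected with a message naming
#' the line numbers. The group footprint is kept as one site (the default);
#' per-CpG splitting of grouped calls is not performed.
#'
#' @param path Path to the TSV.
#' @param sample Sample label; defaults to the file name.
#' @param zero_based Whether the file's coordinates are 0-based (the
#'   nanopolish convention).
#' @return Tibble with `chrom`, `start`, `end`, `sample`, `called_sites`,
#'   `called_sites_methylated`, `frequency`.
#' @export
load_frequency_table <- function(path, sample = NULL, zero_based = TRUE) {
  sample <- sample %||% sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  .assert_cols(tab, c("chromosome", "start", "end", "called_sites",
                      "called_sites_methylated"), "methylation table")
  bad <- tab$called_sites_methylated > tab$called_sites
  if (any(bad)) {
    message(sprintf("rejected %d row(s) with methylated > called (lines %s)",
                    sum(bad),
                    paste(head(which(bad) + 1L, 5), collapse = ", ")))
    tab <- tab[!bad, ]
  }
  off <- if (zero_based) 1L else 0L
  tibble(chrom = tab$chromosome,
         start = tab$start + off,
         end = tab$end + off,
         sample = sample,
         called_sites = tab$called_sites,
         called_sites_methylated = tab$called_sites_methylated,
         frequency = ifelse(tab$called_sites > 0,
                            tab$called_sites_methylated / tab$called_sites,
                            NA_real_))
}

#' Coverage and alternative-allele filtering of methylation calls
#'
#' Removes, per sample, sites with coverage below `min_coverage` (a site at
#' exactly the minimum is kept), and removes for all samples any site
#' overlapping the alternative-allele mask (positions where a non-reference
#' allele replaces the reference cytosine, making the 5mC call unreliable).
#'
#' @param table Long methylation tibble.
#' @param min_coverage Minimum `called_sites` per sample.
#' @param mask Optional `GRanges` of positions to drop everywhere.
#' @return The filtered tibble.
#' @export
filter_sites <- function(table, min_coverage = 4, mask = NULL) {
  .assert_cols(table, c("chrom", "start", "sample", "called_sites"),
               "methylation table")
  out <- table[table$called_sites >= min_coverage, ]
  if (!is.null(mask) && length(mask) > 0L) {
    gr <- .pos_granges(out$chrom, out$start)
    out <- out[!IRanges::overlapsAny(gr, mask, ignore.strand = TRUE), ]
  }
  out
}

#' Site-by-sample frequency matrix
#'
#' Pivots a long methylation table into a sites x samples matrix of
#' frequencies. With `complete = TRUE` (the default, and the precondition
#' for quantile normalization) only sites observed in every sample after
#' filtering are kept.
#'
#' @param table Long methylation tibble.
#' @param complete Keep complete cases only.
#' @return Numeric matrix with rownames `chrom:start` and attribute
#'   `positions` (tibble `chrom`, `start`).
#' @export
frequency_matrix <- function(table, complete = TRUE) {
  .assert_cols(table, c("chrom", "start", "sample", "frequency"),
               "methylation table")
  wide <- table |>
    mutate(site = paste(.data$chrom, .data$start, sep = ":")) |>
    select("site", "chrom", "start", "sample", "frequency") |>
    pivot_wider(names_from = "sample", values_from = "frequency") |>
    arrange(.data$chrom, .data$start)
  if (complete) wide <- wide[stats::complete.cases(wide), ]
  m <- as.matrix(wide[, -(1:3), drop = FALSE])
  rownames(m) <- wide$site
  attr(m, "positions") <- wide[, c("chrom", "start")]
  m
}

#' Quantile-normalize methylation frequencies across samples
#'
#' Replaces each sample's values by the across-sample mean of the order
#' statistics at each rank (ties receive the mean of their tied ranks'
#' values), so that afterwards every sample has the identical sorted value
#' multiset. Values are clamped back to `[0, 1]` (normalization can exit the
#' interval only by rounding). The transform is idempotent and preserves
#' each sample's rank order up to ties. Computation is delegated to
#' [limma::normalizeQuantiles()].
#'
#' @param mat Sites x samples matrix of frequencies (complete cases).
#' @return Matrix of the same shape (attributes preserved).
#' @export
#' @examples
#' m <- cbind(S1 = c(0, 0.5, 1), S2 = c(0.2, 0.4, 0.6))
#' quantile_normalize(m)  # both columns become {0.1, 0.45, 0.8}
quantile_normalize <- function(mat) {
  if (ncol(mat) < 2L) {
    warning("fewer than two samples; returning input unchanged", call. = FALSE)
    return(mat)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  out <- pmin(pmax(out, 0), 1)
  dimnames(out) <- dimnames(mat)
  attr(out, "positions") <- attr(mat, "positions")
  out
}

#' CpG category of each site: island, shore, shelf or open sea
#'
#' Islands are the (normalized) CGI intervals; shores the 2 kb flanking each
#' island end (minus islands); shelves the next 2 kb beyond the shores
#' (minus islands and shores); everything else is open sea. The four
#' categories are mutually exclusive and exhaustive, with island > shore >
#' shelf priority where flanks of neighbouring islands collide.
#'
#' @param sites `GRanges` of sites, or data frame with `chrom`, `start`
#'   (1-based).
#' @param cgi `GRanges` of CpG islands.
#' @param flank Flank width for shores and shelves (bp).
#' @return Factor with levels `island`, `shore`, `shelf`, `open_sea`.
#' @export
annotate_cpg_category <- function(sites, cgi, flank = 2000) {
  if (!is(sites, "GRanges")) {
    .assert_cols(sites, c("chrom", "start"), "sites")
    sites <- .pos_granges(sites$chrom, sites$start)
  }
  islands <- GenomicRanges::reduce(cgi, ignore.strand = TRUE)
  grow <- function(gr, by) {
    out <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(gr),
      IRanges::IRanges(pmax(GenomicRanges::start(gr) - by, 1L),
                       GenomicRanges::end(gr) + by))
    GenomicRanges::reduce(out)
  }
  ext2 <- grow(islands, flank)
  ext4 <- grow(islands, 2 * flank)
  out <- rep("open_sea", length(sites))
  out[IRanges::overlapsAny(sites, ext4)] <- "shelf"
  out[IRanges::overlapsAny(sites, ext2)] <- "shore"
  out[IRanges::overlapsAny(sites, islands)] <- "island"
  factor(out, levels = c("island", "shore", "shelf", "open_sea"))
}

#' Annotate sites on all three axes
#'
#' Assigns every site exactly one CpG category, one sequence class and one
#' gene feature.
#'
#' @param mat Frequency matrix (with `positions` attribute) or a tibble with
#'   `chrom` and `start`.
#' @param cgi `GRanges` of CpG islands.
#' @param classes Optional `GRanges` of sequence classes (with `name`).
#' @param genes Optional `gene_models` or [gene_features()] output.
#' @return Tibble with `chrom`, `start`, `cpg_category`, `seq_class`,
#'   `gene_feature`.
#' @export
annotate_sites <- function(mat, cgi, classes = NULL, genes = NULL) {
  pos <- if (is.matrix(mat)) attr(mat, "positions") else mat
  .assert_cols(pos, c("chrom", "start"), "positions")
  gr <- .pos_granges(pos$chrom, pos$start)
  out <- tibble(chrom = pos$chrom, start = pos$start,
                cpg_category = annotate_cpg_category(gr, cgi))
  out$seq_class <- if (!is.null(classes)) .annotate_class(gr, classes)
                   else NA_character_
  out$gene_feature <- if (!is.null(genes))
    annotate_gene_feature(gr, genes) else NA_character_
  out
}

#' Median methylation per sample, sequence class and CpG category
#'
#' @param mat Normalized frequency matrix (sites x samples).
#' @param annotations Output of [annotate_sites()] for the same sites.
#' @return Tibble with `sample`, `seq_class`, `cpg_category`, `median`,
#'   `n_sites`; empty cells are absent (missing).
#' @export
class_category_summary <- function(mat, annotations) {
  stopifnot(nrow(mat) == nrow(annotations))
  long <- as_tibble(mat) |>
    mutate(seq_class = annotations$seq_class,
           cpg_category = annotations$cpg_category) |>
    pivot_longer(cols = colnames(mat), names_to = "sample",
                 values_to = "frequency")
  long |>
    group_by(.data$sample, .data$seq_class, .data$cpg_category) |>
    summarise(median = median(.data$frequency, na.rm = TRUE),
              n_sites = sum(!is.na(.data$frequency)), .groups = "drop")
}
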