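#' Read a per-sample mapping summary
#'
#' Reads a TSV with columns `sample`, `chrom`, `mapped_bases` giving the
#' number of bases mapped to each chromosome per sample (the numerators of
#' the coverage and enrichment-factor calculations). Duplicate
#' (sample, chrom) rows are summed with a warning.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `sample`, `chrom`, `mapped_bases`.
#' @export
read_mapping_summary <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  .assert_cols(tab, c("sample", "chrom", "mapped_bases"), "mapping summary")
  if (nrow(tab) == 0L) stop("no records in mapping summary", call. = FALSE)
  if (any(is.na(tab$mapped_bases)) || any(tab$mapped_bases < 0)) {
    stop("mapped_bases must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(tab[, c("sample", "chrom")])) {
    warning("duplicate (sample, chrom) rows summed", call. = FALSE)
    tab <- tab |>
      group_by(.data$sample, .data$chrom) |>
      summarise(mapped_bases = sum(.data$mapped_bases), .groups = "drop")
  }
  as_tibble(tab[, c("sample", "chrom", "mapped_bases")])
}

#' Total mapped bases per sample
#'
#' @param summary A mapping-summary tibble (see [read_mapping_summary()]).
#' @return Named numeric vector of totals per sample.
#' @export
total_mapped <- function(summary) {
  .assert_cols(summary, c("sample", "mapped_bases"), "mapping summary")
  tapply(summary$mapped_bases, summary$sample, sum)
}

#' Summarise mapped bases per chromosome from an alignment file
#'
#' Adapter over a coordinate-sorted BAM: counts, per chromosome, the aligned
#' query bases (CIGAR M/I/=/X operations) of primary alignments only;
#' secondary and supplementary records are excluded. Alignments to
#' chromosomes absent from `genome` are kept under their own name with a
#' warning.
#'
#' @param path Path to a BAM file.
#' @param genome Optional `genome_def` used to flag unknown chromosomes.
#' @param sample Sample label for the output; defaults to the file name.
#' @return A mapping-summary tibble (`sample`, `chrom`, `mapped_bases`).
#' @export
ingest_alignments <- function(path, genome = NULL, sample = NULL) {
  sample <- sample %||% sub("\\.bam$", "", basename(path))
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "cigar"))
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  if (length(rec$rname) == 0L) {
    warning("no mapped primary alignments; returning all-zero summary",
            call. = FALSE)
    chroms <- if (!is.null(genome)) genome$chromosomes$name else character(0)
    return(tibble(sample = rep(sample, length(chroms)), chrom = chroms,
                  mapped_bases = rep(0, length(chroms))))
  }
  aligned <- vapply(regmatches(rec$cigar, gregexpr("\\d+[MIDNSHP=X]", rec$cigar)),
                    function(ops) {
                      keep <- grepl("[MI=X]$", ops)
                      sum(as.numeric(sub(".$", "", ops[keep])))
                    }, numeric(1))
  by_chrom <- tapply(aligned, as.character(rec$rname), sum)
  out <- tibble(sample = sample, chrom = names(by_chrom),
                mapped_bases = as.numeric(by_chrom))
  if (!is.null(genome)) {
    unknown <- setdiff(out$chrom, genome$chromosomes$name)
    if (length(unknown) > 0L) {
      warning(sprintf("alignments to chromosome(s) absent from genome: %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  out
}
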