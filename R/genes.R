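#' Read a BED3/BED6 annotation
#'
#' Thin wrapper over [rtracklayer::import()]; BED's 0-based half-open disk
#' coordinates become 1-based closed `GRanges` on read.
#'
#' @param path Path to a BED file.
#' @return A [GenomicRanges::GRanges].
#' @export
read_bed <- function(path) rtracklayer::import(path, format = "bed")

#' Write a GRanges as BED
#'
#' @param gr A `GRanges` (optionally with a `name` metadata column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read gene models from a BED12 file
#'
#' Each BED12 line is one transcript: blocks are the exons, the thick range
#' the coding sequence. Returns a `gene_models` object: a `GRanges` of
#' transcripts with metadata columns `name`, `thick` (CDS, `IRanges`) and
#' `exons` (a `GRangesList` in absolute coordinates).
#'
#' @param path Path to a BED12-like file.
#' @return A `gene_models` object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks)) {
    # BED6 genes: single-exon transcripts
    gr$blocks <- methods::as(IRanges::ranges(gr), "IRangesList")
    gr$thick <- IRanges::ranges(gr)
  }
  gene_models(gr)
}

#' Assemble a gene_models object from a transcript GRanges
#'
#' @param gr `GRanges` with mcols `name`, `thick` and `blocks` (as produced
#'   by [rtracklayer::import()] on BED12).
#' @return A `gene_models` object.
#' @export
gene_models <- function(gr) {
  stopifnot(is(gr, "GRanges"), !is.null(gr$name), !is.null(gr$blocks))
  if (anyDuplicated(gr$name)) stop("gene names must be unique", call. = FALSE)
  if (any(!as.character(GenomicRanges::strand(gr)) %in% c("+", "-"))) {
    stop("gene models must be stranded", call. = FALSE)
  }
  ex <- rtracklayer::blocks(gr)
  names(ex) <- gr$name
  # exons must be non-overlapping and within transcript bounds
  for (i in seq_along(ex)) {
    e <- ex[[i]]
    if (length(IRanges::reduce(e)) != length(e)) {
      stop(sprintf("overlapping exons in gene %s", gr$name[i]), call. = FALSE)
    }
  }
  out <- gr
  S4Vectors::mcols(out)$exons <- ex
  class(out) <- c(class(out))
  structure(list(transcripts = out), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d transcripts\n", length(x$transcripts)))
  invisible(x)
}

#' Derive strand-aware gene feature intervals
#'
#' For each transcript derives: the TSS region (exactly `tss_width` bp
#' immediately upstream of the strand-aware transcription start), the
#' upstream region (`upstream_width` bp beyond the TSS region), 5' and 3'
#' UTRs (exonic sequence outside the coding range, on the strand-appropriate
#' side), the first exon, the remaining exons and the introns.
#'
#' @param models A `gene_models` object.
#' @param tss_width Width of the TSS region (bp).
#' @param upstream_width Width of the upstream region beyond the TSS region.
#' @return `GRanges` with metadata columns `feature` (one of `tss`,
#'   `five_utr`, `three_utr`, `first_exon`, `other_exon`, `intron`,
#'   `upstream`) and `gene`.
#' @export
gene_features <- function(models, tss_width = 200, upstream_width = 2000) {
  stopifnot(is(models, "gene_models"))
  tx <- models$transcripts
  pieces <- list()
  for (i in seq_along(tx)) {
    g <- tx[i]
    strand_i <- as.character(GenomicRanges::strand(g))
    ex <- S4Vectors::mcols(tx)$exons[[i]]
    S4Vectors::mcols(ex) <- NULL
    chrom <- as.character(GenomicRanges::seqnames(g))
    add <- function(ranges, feature) {
      ranges <- ranges[GenomicRanges::width(ranges) > 0]
      if (length(ranges) == 0L) return(NULL)
      GenomicRanges::GRanges(chrom, IRanges::ranges(ranges),
                             strand = strand_i, feature = feature,
                             gene = tx$name[i])
    }
    prom <- GenomicRanges::promoters(g, upstream = tss_width, downstream = 0)
    up_all <- GenomicRanges::promoters(g, upstream = tss_width + upstream_width,
                                       downstream = 0)
    upstream <- GenomicRanges::setdiff(up_all, prom)
    # UTRs: exonic sequence outside the CDS (thick) range
    thick <- S4Vectors::mcols(g)$thick
    utr5 <- utr3 <- GenomicRanges::GRanges()
    if (!is.null(thick) && IRanges::width(thick) > 0 &&
        !(IRanges::start(thick) == GenomicRanges::start(g) &&
          IRanges::end(thick) == GenomicRanges::end(g))) {
      left <- IRanges::IRanges(GenomicRanges::start(g),
                               IRanges::start(thick) - 1)
      right <- IRanges::IRanges(IRanges::end(thick) + 1,
                                GenomicRanges::end(g))
      left_utr <- IRanges::intersect(IRanges::ranges(ex),
                                     left[IRanges::width(left) > 0])
      right_utr <- IRanges::intersect(IRanges::ranges(ex),
                                      right[IRanges::width(right) > 0])
      if (strand_i == "+") {
        utr5 <- GenomicRanges::GRanges(chrom, left_utr)
        utr3 <- GenomicRanges::GRanges(chrom, right_utr)
      } else {
        utr5 <- GenomicRanges::GRanges(chrom, right_utr)
        utr3 <- GenomicRanges::GRanges(chrom, left_utr)
      }
    }
    ord <- order(GenomicRanges::start(ex))
    first_idx <- if (strand_i == "+") ord[1] else ord[length(ord)]
    introns <- GenomicRanges::setdiff(
      GenomicRanges::GRanges(chrom, IRanges::ranges(g)),
      GenomicRanges::GRanges(chrom, IRanges::ranges(ex)))
    pieces[[length(pieces) + 1L]] <- do.call(c, Filter(Negate(is.null), list(
      add(prom, "tss"),
      add(utr5, "five_utr"),
      add(utr3, "three_utr"),
      add(ex[first_idx], "first_exon"),
      add(ex[-first_idx], "other_exon"),
      add(introns, "intron"),
      add(upstream, "upstream")
    )))
  }
  out <- do.call(c, pieces)
  out$feature <- factor(out$feature, levels = FEATURE_PRIORITY)
  out
}

# Priority order for overlapping gene annotations (highest first):
# promoter/TSS, UTRs, first exon, non-first exons, introns, upstream.
FEATURE_PRIORITY <- c("tss", "five_utr", "three_utr", "first_exon",
                      "other_exon", "intron", "upstream")

#' Assign each site its highest-priority gene feature
#'
#' Sites overlapping several feature intervals receive the highest-priority
#' one (promoter/TSS > 5'UTR > 3'UTR > first exon > non-first exons >
#' introns > upstream); sites overlapping no gene are `intergenic`. With
#' `collapse = TRUE`, non-first exons and introns are reported jointly as
#' `intragenic`.
#'
#' @param sites `GRanges` of sites, or a data frame with `chrom` and `start`
#'   (1-based positions).
#' @param features Output of [gene_features()] (or a `gene_models` object,
#'   in which case features are derived with defaults).
#' @param collapse Collapse non-first exons and introns into `intragenic`.
#' @return Character vector of feature labels, one per site.
#' @export
annotate_gene_feature <- function(sites, features, collapse = TRUE) {
  if (is(features, "gene_models")) features <- gene_features(features)
  if (!is(sites, "GRanges")) {
    .assert_cols(sites, c("chrom", "start"), "sites")
    sites <- .pos_granges(sites$chrom, sites$start)
  }
  hits <- GenomicRanges::findOverlaps(sites, features, ignore.strand = TRUE)
  prio <- as.integer(features$feature[S4Vectors::subjectHits(hits)])
  best <- tapply(prio, S4Vectors::queryHits(hits), min)
  out <- rep("intergenic", length(sites))
  out[as.integer(names(best))] <- FEATURE_PRIORITY[best]
  if (collapse) out[out %in% c("other_exon", "intron")] <- "intragenic"
  out
}

#' Write gene models as BED12
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(models, path) {
  tx <- models$transcripts
  lines <- vapply(seq_along(tx), function(i) {
    g <- tx[i]
    ex <- S4Vectors::mcols(tx)$exons[[i]]
    ex <- ex[order(GenomicRanges::start(ex))]
    start0 <- GenomicRanges::start(g) - 1L
    thick <- S4Vectors::mcols(g)$thick
    paste(c(as.character(GenomicRanges::seqnames(g)), start0,
            GenomicRanges::end(g), tx$name[i], 0,
            as.character(GenomicRanges::strand(g)),
            IRanges::start(thick) - 1L, IRanges::end(thick),
            "0", length(ex),
            paste0(paste(GenomicRanges::width(ex), collapse = ","), ","),
            paste0(paste(GenomicRanges::start(ex) - 1L - start0,
                         collapse = ","), ",")),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
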