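#' Windowed methylation track with cross-sample dispersion
#'
#' Tiles each chromosome with fixed-width windows anchored at position 1
#' (step defaults to the width, i.e. non-overlapping tiles; a smaller step
#' gives sliding windows) and records, per window, each sample's median
#' frequency, the cross-sample standard deviation of those medians, and the
#' number of sites. The SD is missing when fewer than two samples have a
#' median in the window.
#'
#' @param mat Frequency matrix (sites x samples, `positions` attribute).
#' @param width Window width (bp), 250 kb by default.
#' @param step Window step (bp), `<= width`.
#' @param chrom_length Optional chromosome length; defaults to the last site.
#' @return Tibble of class `window_track`: `chrom`, `start`, `end`,
#'   `n_sites`, `sd`, plus a `medians` attribute (windows x samples matrix).
#' @export
window_track <- function(mat, width = 250000, step = width,
                         chrom_length = NULL) {
  stopifnot(width > 0, step > 0, step <= width)
  pos <- attr(mat, "positions")
  if (is.null(pos)) stop("matrix lacks a positions attribute", call. = FALSE)
  out <- list()
  med_rows <- list()
  for (ch in unique(pos$chrom)) {
    idx <- which(pos$chrom == ch)
    len <- chrom_length %||% max(pos$start[idx])
    starts <- seq(1, len, by = step)
    win <- GenomicRanges::GRanges(ch, IRanges::IRanges(starts,
                                                       width = width))
    sites <- .pos_granges(ch, pos$start[idx])
    hits <- GenomicRanges::findOverlaps(win, sites)
    meds <- matrix(NA_real_, length(win), ncol(mat),
                   dimnames = list(NULL, colnames(mat)))
    n_sites <- integer(length(win))
    for (w in unique(S4Vectors::queryHits(hits))) {
      rows <- idx[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == w]]
      meds[w, ] <- apply(mat[rows, , drop = FALSE], 2, median, na.rm = TRUE)
      n_sites[w] <- length(rows)
    }
    sds <- apply(meds, 1, function(m) {
      if (sum(!is.na(m)) < 2) NA_real_ else sd(m, na.rm = TRUE)
    })
    out[[ch]] <- tibble(chrom = ch, start = starts,
                        end = starts + width - 1,
                        n_sites = n_sites, sd = sds)
    med_rows[[ch]] <- meds
  }
  track <- bind_rows(out)
  attr(track, "medians") <- do.call(rbind, med_rows)
  class(track) <- c("window_track", class(track))
  track
}

#' Per-sample window medians of a track
#'
#' @param track A [window_track()].
#' @return Windows x samples matrix of medians.
#' @export
window_medians <- function(track) attr(track, "medians")

#' Mean methylation per CpG island
#'
#' Mean frequency over the CpG sites inside each island, per sample, plus
#' the across-sample grand mean per island. Islands containing no sites are
#' reported as missing.
#'
#' @param mat Frequency matrix (sites x samples, `positions` attribute).
#' @param cgi Named `GRanges` of CpG islands (`name` column).
#' @return List: `per_sample` (tibble `cgi`, `sample`, `mean`, `n_sites`)
#'   and `summary` (tibble `cgi`, `grand_mean`, `n_sites`).
#' @export
cgi_means <- function(mat, cgi) {
  pos <- attr(mat, "positions")
  if (is.null(pos)) stop("matrix lacks a positions attribute", call. = FALSE)
  sites <- .pos_granges(pos$chrom, pos$start)
  hits <- GenomicRanges::findOverlaps(cgi, sites, ignore.strand = TRUE)
  names <- cgi$name %||% paste0("CGI_", seq_along(cgi))
  per_sample <- lapply(seq_along(cgi), function(i) {
    rows <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    if (length(rows) == 0L) {
      return(tibble(cgi = names[i], sample = colnames(mat), mean = NA_real_,
                    n_sites = 0L))
    }
    tibble(cgi = names[i], sample = colnames(mat),
           mean = unname(colMeans(mat[rows, , drop = FALSE], na.rm = TRUE)),
           n_sites = length(rows))
  }) |> bind_rows()
  summary <- per_sample |>
    group_by(.data$cgi) |>
    summarise(grand_mean = mean(.data$mean), n_sites = .data$n_sites[1],
              .groups = "drop")
  list(per_sample = per_sample, summary = summary)
}

#' Scan a window track for high-dispersion regions
#'
#' Ranks windows by cross-sample SD, keeps the top `top_k` windows whose SD
#' z-score (relative to all windows with a defined SD) is at least `z_min`,
#' merges adjacent kept windows into regions, and reports for each region
#' the overlapping genes, the per-sample medians, and the deviating sample
#' (the sample whose region median departs most from the cross-sample
#' median).
#'
#' @param track A [window_track()].
#' @param genes Optional `gene_models` whose transcripts are intersected
#'   with the regions.
#' @param top_k Maximum number of windows considered.
#' @param z_min Minimum SD z-score.
#' @return Tibble (possibly empty) with `chrom`, `start`, `end`, `max_sd`,
#'   `max_z`, `deviating_sample`, `deviation`, `genes` (list-column) and
#'   `sample_medians` (list-column), ordered by `max_sd` descending.
#' @export
dispersion_scan <- function(track, genes = NULL, top_k = 10, z_min = 3) {
  stopifnot(is(track, "window_track"))
  meds <- window_medians(track)
  sds <- track$sd
  ok <- !is.na(sds)
  z <- rep(NA_real_, length(sds))
  z[ok] <- (sds[ok] - mean(sds[ok])) / sd(sds[ok])
  keep <- which(ok & rank(-sds, ties.method = "first") <= top_k & z >= z_min)
  if (length(keep) == 0L) {
    return(tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  max_sd = numeric(0), max_z = numeric(0),
                  deviating_sample = character(0), deviation = numeric(0),
                  genes = list(), sample_medians = list()))
  }
  keep <- sort(keep)
  grp <- cumsum(c(TRUE, diff(keep) > 1 |
                    track$chrom[keep[-1]] != track$chrom[keep[-length(keep)]]))
  regions <- lapply(split(keep, grp), function(idx) {
    reg_meds <- colMeans(meds[idx, , drop = FALSE], na.rm = TRUE)
    dev <- abs(reg_meds - median(reg_meds, na.rm = TRUE))
    overlapping <- character(0)
    if (!is.null(genes)) {
      tx <- genes$transcripts
      reg <- GenomicRanges::GRanges(track$chrom[idx[1]],
                                    IRanges::IRanges(min(track$start[idx]),
                                                     max(track$end[idx])))
      overlapping <- tx$name[IRanges::overlapsAny(tx, reg,
                                                  ignore.strand = TRUE)]
    }
    tibble(chrom = track$chrom[idx[1]],
           start = min(track$start[idx]), end = max(track$end[idx]),
           max_sd = max(track$sd[idx]), max_z = max(z[idx]),
           deviating_sample = names(which.max(dev)),
           deviation = max(dev, na.rm = TRUE),
           genes = list(overlapping), sample_medians = list(reg_meds))
  })
  bind_rows(regions) |> arrange(desc(.data$max_sd))
}

#' Methylome-distance tree and comparison to a reference phylogeny
#'
#' Computes pairwise sample distances from the frequency matrix (one minus
#' the Pearson correlation over shared sites by default, or Euclidean
#' distance), builds an agglomerative tree (UPGMA, i.e. average linkage, by
#' default) and, when a reference phylogeny is given, reports the
#' Robinson-Foulds distance between the two topologies (0 means the
#' methylome recapitulates the reference).
#'
#' @param mat Frequency matrix (sites or windows x >= 3 samples).
#' @param reference Optional `phylo` with the same tip labels.
#' @param distance `"pearson"` or `"euclidean"`.
#' @param linkage Linkage method for [stats::hclust()].
#' @return List of class `methylome_tree`: `tree` (`phylo`), `dist`, and
#'   `rf` (`NA` without a reference).
#' @export
methylome_tree <- function(mat, reference = NULL,
                           distance = c("pearson", "euclidean"),
                           linkage = "average") {
  distance <- match.arg(distance)
  if (ncol(mat) < 3L) stop("need at least three samples", call. = FALSE)
  d <- if (distance == "pearson") {
    as.dist(1 - cor(mat, use = "pairwise.complete.obs"))
  } else {
    stats::dist(t(mat))
  }
  tree <- ape::as.phylo(hclust(d, method = linkage))
  rf <- NA_real_
  if (!is.null(reference)) {
    if (!setequal(tree$tip.label, reference$tip.label)) {
      stop("reference tree tips do not match the samples", call. = FALSE)
    }
    rf <- phangorn::RF.dist(ape::unroot(tree), ape::unroot(reference))
  }
  structure(list(tree = tree, dist = d, rf = rf), class = "methylome_tree")
}

#' @export
print.methylome_tree <- function(x, ...) {
  cat(sprintf("<methylome_tree> %d samples; RF distance to reference: %s\n",
              length(x$tree$tip.label),
              ifelse(is.na(x$rf), "not compared", format(x$rf))))
  invisible(x)
}
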