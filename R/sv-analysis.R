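#' Drop records with imprecise breakpoints
#'
#' Removes records whose caller flagged the breakpoints as imprecise; the
#' number removed is reported with a message.
#'
#' @param panel An `sv_panel`.
#' @return The filtered `sv_panel`.
#' @export
filter_imprecise <- function(panel) {
  stopifnot(is(panel, "sv_panel"))
  keep <- panel$records$precise
  if (any(!keep)) message(sprintf("removed %d imprecise record(s)", sum(!keep)))
  .subset_panel(panel, keep)
}

.subset_panel <- function(panel, keep) {
  sv_panel(panel$records[keep, , drop = FALSE],
           panel$gt[keep, , drop = FALSE],
           panel$gq[keep, , drop = FALSE],
           samples = panel$samples, platform = panel$platform)
}

#' Merge indel calls across panels by breakpoint proximity
#'
#' Single-linkage clustering of insertion and deletion records, separately
#' by type and chromosome, on start positions: records whose starts are
#' within `max_distance` of the previous record chain into one event. The
#' merged record takes the position and length of its first member (position
#' order); member ids are kept in a `members` list-column. Per-sample
#' genotypes are taken from each sample's member record; when two members of
#' one cluster carry conflicting non-missing genotypes for the same sample,
#' the higher-quality genotype wins and the conflict is reported. DUP and
#' TRA records pass through unmerged.
#'
#' Merging is idempotent (cluster representatives are farther apart than
#' `max_distance` by construction) and the number of merged events is
#' non-increasing in `max_distance`.
#'
#' @param panels An `sv_panel` or list of `sv_panel`s sharing a coordinate
#'   convention.
#' @param max_distance Maximum permitted distance between chained start
#'   positions (bp).
#' @return A merged `sv_panel` over the union of samples.
#' @export
merge_indels <- function(panels, max_distance = 100) {
  if (is(panels, "sv_panel")) panels <- list(panels)
  stopifnot(all(vapply(panels, is, logical(1), "sv_panel")))
  samples <- unique(unlist(lapply(panels, function(p) p$samples)))

  # flatten to one long record table with genotype rows aligned to samples
  rec_list <- lapply(seq_along(panels), function(k) {
    p <- panels[[k]]
    r <- p$records
    gt <- matrix("missing", nrow(r), length(samples),
                 dimnames = list(NULL, samples))
    gq <- matrix(NA_real_, nrow(r), length(samples),
                 dimnames = list(NULL, samples))
    gt[, p$samples] <- p$gt
    gq[, p$samples] <- p$gq
    if (!"members" %in% names(r)) r$members <- as.list(r$id)
    list(records = r, gt = gt, gq = gq)
  })
  records <- bind_rows(lapply(rec_list, `[[`, "records"))
  gt <- do.call(rbind, lapply(rec_list, `[[`, "gt"))
  gq <- do.call(rbind, lapply(rec_list, `[[`, "gq"))

  is_indel <- records$type %in% c("INS", "DEL")
  cluster <- rep(NA_integer_, nrow(records))
  next_id <- 0L
  for (grp in split(which(is_indel),
                    paste(records$type[is_indel], records$chrom[is_indel]))) {
    ord <- grp[order(records$pos[grp])]
    breaks <- c(TRUE, diff(records$pos[ord]) > max_distance)
    ids <- cumsum(breaks) + next_id
    cluster[ord] <- ids
    next_id <- max(ids)
  }
  # pass-through records become their own clusters
  solo <- which(!is_indel)
  cluster[solo] <- next_id + seq_along(solo)

  merged <- lapply(split(seq_len(nrow(records)), cluster), function(idx) {
    idx <- idx[order(records$pos[idx])]
    rep_idx <- idx[1]
    m_gt <- setNames(rep("missing", length(samples)), samples)
    m_gq <- setNames(rep(NA_real_, length(samples)), samples)
    for (s in samples) {
      have <- idx[gt[idx, s] != "missing"]
      if (length(have) == 0L) next
      if (length(unique(gt[have, s])) > 1L) {
        message(sprintf("genotype conflict for sample %s near %s:%d; keeping higher quality",
                        s, records$chrom[rep_idx], records$pos[rep_idx]))
        have <- have[order(-gq[have, s])]
      }
      m_gt[s] <- gt[have[1], s]
      m_gq[s] <- gq[have[1], s]
    }
    list(record = tibble(id = records$id[rep_idx],
                         chrom = records$chrom[rep_idx],
                         pos = records$pos[rep_idx],
                         type = records$type[rep_idx],
                         length = records$length[rep_idx],
                         precise = all(records$precise[idx]),
                         members = list(unlist(records$members[idx]))),
         gt = m_gt, gq = m_gq)
  })
  out_rec <- bind_rows(lapply(merged, `[[`, "record"))
  out_gt <- do.call(rbind, lapply(merged, `[[`, "gt"))
  out_gq <- do.call(rbind, lapply(merged, `[[`, "gq"))
  ord <- order(out_rec$chrom, out_rec$pos, out_rec$type)
  sv_panel(out_rec[ord, ], out_gt[ord, , drop = FALSE],
           out_gq[ord, , drop = FALSE], samples = samples,
           platform = panels[[1]]$platform)
}

#' Apply genotype-quality filtering and drop uninformative events
#'
#' Genotypes with quality strictly below `min_quality` are set to missing
#' ("quality under 25" means `< 25`; a quality of exactly 25 is kept).
#' Events left homozygous-reference or missing in every sample are dropped.
#' Genotypes without a recorded quality are kept.
#'
#' @param panel An `sv_panel`.
#' @param min_quality Quality threshold.
#' @return The filtered `sv_panel`.
#' @export
filter_genotypes <- function(panel, min_quality = 25) {
  stopifnot(is(panel, "sv_panel"))
  drop <- !is.na(panel$gq) & panel$gq < min_quality
  panel$gt[drop] <- "missing"
  panel$gq[drop] <- NA_real_
  has_alt <- apply(panel$gt, 1, function(g) any(g %in% c("het_alt", "hom_alt")))
  .subset_panel(panel, has_alt)
}

#' Classify indel lengths into size bins
#'
#' Half-open bins: `small` \[10, 50), `sv` \[50, 500) and `large`
#' \[500, Inf) — an indel of 50 bp or more counts as a structural variant,
#' and 500 bp or more as large. Lengths below the 10 bp panel floor are
#' rejected.
#'
#' @param lengths Numeric vector of indel lengths.
#' @return Factor with levels `small`, `sv`, `large`.
#' @export
#' @examples
#' classify_size(c(10, 49, 50, 499, 500))
classify_size <- function(lengths) {
  if (any(is.na(lengths)) || any(lengths < 10)) {
    stop("indel length below the 10 bp panel floor", call. = FALSE)
  }
  cut(lengths, breaks = c(10, 50, 500, Inf), right = FALSE,
      labels = c("small", "sv", "large"))
}

#' Repeat content of variant footprints
#'
#' For each record, the fraction of its footprint (`pos` to
#' `pos + length - 1`) covered by repeat intervals, and the repeat class
#' covering the most bases (ties broken lexicographically).
#'
#' @param panel An `sv_panel`.
#' @param repeats `GRanges` with a `name` column giving the repeat class.
#' @return Tibble with `id`, `repeat_fraction`, `dominant_class`
#'   (`NA` when no repeat overlaps).
#' @export
repeat_fraction <- function(panel, repeats) {
  stopifnot(is(panel, "sv_panel"), is(repeats, "GRanges"))
  r <- panel$records
  if (any(is.na(r$length) | r$length < 1)) {
    stop("all records need a positive footprint length", call. = FALSE)
  }
  fp <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$pos,
                                                         width = r$length))
  cov <- GenomicRanges::intersect(fp, GenomicRanges::reduce(repeats),
                                  ignore.strand = TRUE)
  frac <- rep(0, nrow(r))
  hit <- GenomicRanges::findOverlaps(fp, cov, ignore.strand = TRUE)
  if (length(hit) > 0L) {
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      fp[S4Vectors::queryHits(hit)], cov[S4Vectors::subjectHits(hit)]))
    agg <- tapply(w, S4Vectors::queryHits(hit), sum)
    frac[as.integer(names(agg))] <- agg / r$length[as.integer(names(agg))]
  }
  dominant <- rep(NA_character_, nrow(r))
  hits2 <- GenomicRanges::findOverlaps(fp, repeats, ignore.strand = TRUE)
  if (length(hits2) > 0L) {
    w2 <- GenomicRanges::width(GenomicRanges::pintersect(
      fp[S4Vectors::queryHits(hits2)], repeats[S4Vectors::subjectHits(hits2)]))
    df <- tibble(rec = S4Vectors::queryHits(hits2),
                 class = repeats$name[S4Vectors::subjectHits(hits2)],
                 w = w2) |>
      group_by(.data$rec, .data$class) |>
      summarise(w = sum(.data$w), .groups = "drop") |>
      group_by(.data$rec) |>
      arrange(desc(.data$w), .data$class, .by_group = TRUE) |>
      slice(1) |>
      ungroup()
    dominant[df$rec] <- df$class
  }
  tibble(id = r$id, repeat_fraction = frac, dominant_class = dominant)
}

#' Variant sharing profile across the haplogroup phylogeny
#'
#' Restricted to variants genotyped in every sample (no missing calls),
#' counts each presence pattern across the tree's samples: singletons per
#' sample, variants shared by all samples in the non-reference state, and
#' every intermediate pattern. The pattern matrix supports upset- or
#' heatmap-style display.
#'
#' @param bmat Binary genotype matrix (variants x samples; 1 present,
#'   0 absent, `NA` missing), e.g. from [binarize()].
#' @param tree Rooted `phylo` whose tip labels equal the matrix's samples.
#' @return List of class `sharing_profile`: `patterns` (tibble `pattern`,
#'   `n_carriers`, `count`), `pattern_matrix` (patterns x samples, 0/1),
#'   `singletons` (named vector), `n_complete`, `n_shared_all`,
#'   `frac_shared_all`.
#' @export
sharing_profile <- function(bmat, tree) {
  stopifnot(is(tree, "phylo"))
  samples <- colnames(bmat)
  if (!setequal(samples, tree$tip.label)) {
    stop("matrix samples do not match the tree's tip labels", call. = FALSE)
  }
  complete <- bmat[stats::complete.cases(bmat), , drop = FALSE]
  n_complete <- nrow(complete)
  pat <- apply(complete, 1, paste, collapse = "")
  counts <- table(pat)
  pattern_matrix <- do.call(rbind, lapply(names(counts), function(p) {
    as.integer(strsplit(p, "")[[1]])
  }))
  colnames(pattern_matrix) <- samples
  n_carriers <- rowSums(pattern_matrix)
  label <- vapply(seq_len(nrow(pattern_matrix)), function(i) {
    cc <- samples[pattern_matrix[i, ] == 1]
    if (length(cc) == 0L) "none" else paste(cc, collapse = "+")
  }, character(1))
  patterns <- tibble(pattern = label, n_carriers = n_carriers,
                     count = as.integer(counts)) |>
    arrange(desc(.data$count))
  singles <- pattern_matrix[n_carriers == 1, , drop = FALSE]
  singletons <- setNames(
    as.numeric(colSums(singles * as.integer(counts)[n_carriers == 1])),
    samples)
  shared_idx <- which(n_carriers == length(samples))
  n_shared_all <- if (length(shared_idx)) as.integer(counts)[shared_idx] else 0L
  structure(list(patterns = patterns, pattern_matrix = pattern_matrix,
                 singletons = singletons, n_complete = n_complete,
                 n_shared_all = n_shared_all,
                 frac_shared_all = if (n_complete > 0)
                   n_shared_all / n_complete else NA_real_),
            class = "sharing_profile")
}

#' @export
print.sharing_profile <- function(x, ...) {
  cat(sprintf("<sharing_profile> %d complete variants; %d (%.1f%%) shared by all\n",
              x$n_complete, x$n_shared_all, 100 * (x$frac_shared_all %||% 0)))
  print(head(x$patterns, 10))
  invisible(x)
}
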