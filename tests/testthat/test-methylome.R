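test_that("frequency tables load from the nanopolish dialect and round-trip", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("chromosome", "start", "end", "num_motifs_in_group", "called_sites",
          "called_sites_methylated", "methylated_frequency", "group_sequence",
          sep = "\t"),
    "chrY\t99\t99\t1\t10\t7\t0.7\tACGCGA",
    "chrY\t200\t200\t1\t5\t9\t1.8\tACGCGA",   # methylated > called: rejected
    "chrY\t300\t300\t1\t4\t0\t0\tACGCGA"), f)
  expect_message(tab <- load_frequency_table(f, sample = "s1"), "rejected 1")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$start, c(100, 301))  # 0-based file -> 1-based in memory
  expect_equal(tab$frequency, c(0.7, 0))

  # write/read round trip through the dialect writer
  out <- tempfile(fileext = ".tsv")
  write_frequency_table(tab, out)
  tab2 <- load_frequency_table(out, sample = "s1")
  expect_equal(tab2[, c("chrom", "start", "called_sites",
                        "called_sites_methylated")],
               tab[, c("chrom", "start", "called_sites",
                       "called_sites_methylated")])
})

test_that("site filtering enforces the coverage floor and the allele mask", {
  tab <- tibble::tibble(chrom = "chrY", start = c(100, 200, 300),
                        end = c(100, 200, 300), sample = "s1",
                        called_sites = c(3, 4, 10),
                        called_sites_methylated = c(1, 2, 5),
                        frequency = c(1 / 3, 0.5, 0.5))
  f <- filter_sites(tab, min_coverage = 4)
  expect_equal(f$start, c(200, 300))  # coverage 3 dropped, 4 kept
  mask <- GenomicRanges::GRanges("chrY", IRanges::IRanges(250, 350))
  f2 <- filter_sites(tab, min_coverage = 4, mask = mask)
  expect_equal(f2$start, 200)
  expect_equal(filter_sites(tab, min_coverage = 0)$start, c(100, 200, 300))
})

test_that("quantile normalization matches the hand-computed example and its laws", {
  m <- cbind(S1 = c(0, 0.5, 1), S2 = c(0.2, 0.4, 0.6))
  q <- quantile_normalize(m)
  expect_equal(unname(q[, "S1"]), c(0.1, 0.45, 0.8))
  expect_equal(unname(q[, "S2"]), c(0.1, 0.45, 0.8))  # 0.2->0.1, 0.4->0.45, 0.6->0.8
  # identical samples are a fixed point
  mm <- cbind(a = c(0.3, 0.6, 0.9), b = c(0.3, 0.6, 0.9))
  expect_equal(quantile_normalize(mm), mm, ignore_attr = TRUE)
  withr::with_seed(71, {
    for (i in 1:20) {
      r <- matrix(runif(40), 10, 4,
                  dimnames = list(NULL, paste0("s", 1:4)))
      q <- quantile_normalize(r)
      # sorted columns identical after normalization
      sorted <- apply(q, 2, sort)
      expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
      # idempotent
      expect_equal(quantile_normalize(q), q, tolerance = 1e-12)
      # rank order preserved within each sample
      for (j in 1:4) expect_equal(order(q[, j]), order(r[, j]))
      expect_true(all(q >= 0 & q <= 1))
    }
  })
  expect_warning(quantile_normalize(m[, 1, drop = FALSE]), "fewer than two")
})

test_that("CpG categories follow the 2-kb shore/shelf geometry", {
  cgi <- GenomicRanges::GRanges("chrY", IRanges::IRanges(10001, 11000))
  sites <- tibble::tibble(chrom = "chrY",
                          start = c(10500, 9500, 7000, 5000, 13000, 13001,
                                    15000, 15001))
  cat <- annotate_cpg_category(sites, cgi)
  expect_equal(as.character(cat),
               c("island", "shore", "shelf", "open_sea",
                 "shore", "shelf",      # shore/shelf boundary at +2 kb
                 "shelf", "open_sea"))  # shelf/open-sea boundary at +4 kb
  # two CGIs 1 kb apart: the gap is entirely shore (island priority kept)
  cgi2 <- GenomicRanges::GRanges("chrY",
                                 IRanges::IRanges(c(10001, 12001),
                                                  c(11000, 13000)))
  gap_sites <- tibble::tibble(chrom = "chrY", start = seq(11001, 12000, 100))
  expect_true(all(annotate_cpg_category(gap_sites, cgi2) == "shore"))
  # no CGIs: everything open sea
  expect_true(all(annotate_cpg_category(sites,
                                        GenomicRanges::GRanges()) == "open_sea"))
})

test_that("CpG category assignment partitions sampled positions", {
  withr::with_seed(72, {
    cgi <- GenomicRanges::GRanges(
      "chrY", IRanges::IRanges(sort(sample.int(9e5, 30)), width = 800))
    pos <- tibble::tibble(chrom = "chrY", start = sample.int(1e6, 2e4))
    cat <- annotate_cpg_category(pos, cgi)
    # exactly one category per site, none unassigned
    expect_false(any(is.na(cat)))
    expect_equal(length(cat), nrow(pos))
    # category regions are consistent with distance to the nearest island
    # (GenomicRanges::distance counts intervening bases: a site k bases
    # beyond an island end has distance k - 1)
    isl <- GenomicRanges::reduce(cgi)
    pgr <- GenomicRanges::GRanges(pos$chrom,
                                  IRanges::IRanges(pos$start, width = 1))
    d <- GenomicRanges::distance(pgr, isl[GenomicRanges::nearest(pgr, isl)])
    inside <- IRanges::overlapsAny(pgr, isl)
    expect_true(all(cat[inside] == "island"))
    expect_true(all(cat[!inside & d < 2000] == "shore"))
    expect_true(all(cat[!inside & d >= 2000 & d < 4000] == "shelf"))
    expect_true(all(cat[!inside & d >= 4000] == "open_sea"))
  })
})

test_that("gene feature priority resolves overlapping annotations", {
  # gene where the 5'UTR lies inside the first exon: UTR wins
  bed <- tempfile(fileext = ".bed")
  writeLines(
    "chrY\t10000\t14000\tg\t0\t+\t10500\t13500\t0\t2\t1000,1000\t0,3000",
    bed)
  gm <- read_gene_models(bed)
  feats <- annotate_gene_feature(
    tibble::tibble(chrom = "chrY",
                   start = c(10200, 10600, 13800, 9950, 12000, 9000, 50000)),
    gm, collapse = TRUE)
  expect_equal(feats, c("five_utr",     # exon base before CDS start
                        "first_exon",   # coding part of the first exon
                        "three_utr",    # exon base after CDS end
                        "tss",          # 100 bp upstream of the start
                        "intragenic",   # intron
                        "upstream",     # beyond the TSS window
                        "intergenic"))
})

test_that("window medians match a brute-force recomputation", {
  withr::with_seed(73, {
    n <- 500
    pos <- sort(sample.int(1e6, n))
    m <- matrix(runif(3 * n), n, 3, dimnames = list(NULL, paste0("s", 1:3)))
    attr(m, "positions") <- tibble::tibble(chrom = "chrY", start = pos)
    tk <- window_track(m, width = 250000, chrom_length = 1e6)
    meds <- window_medians(tk)
    for (w in seq_len(nrow(tk))) {
      rows <- pos >= tk$start[w] & pos <= tk$end[w]
      expect_equal(tk$n_sites[w], sum(rows))
      if (any(rows)) {
        expect_equal(unname(meds[w, ]),
                     unname(apply(m[rows, , drop = FALSE], 2, median)))
        expect_equal(tk$sd[w], sd(meds[w, ]))
      } else {
        expect_true(all(is.na(meds[w, ])) && is.na(tk$sd[w]))
      }
    }
    # identical samples: SD 0 everywhere there are sites
    m2 <- m
    m2[, 2] <- m2[, 3] <- m2[, 1]
    attr(m2, "positions") <- attr(m, "positions")
    tk2 <- window_track(m2, width = 250000, chrom_length = 1e6)
    expect_true(all(tk2$sd[tk2$n_sites > 0] == 0))
  })
})

test_that("per-island means aggregate sites per sample and across samples", {
  cgi <- GenomicRanges::GRanges("chrY",
                                IRanges::IRanges(c(100, 5000), width = 200),
                                name = c("CGI_1", "CGI_2"))
  m <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2,
              dimnames = list(NULL, c("a", "b")))
  attr(m, "positions") <- tibble::tibble(chrom = "chrY", start = c(150, 250))
  cm <- cgi_means(m, cgi)
  expect_equal(cm$per_sample$mean[cm$per_sample$sample == "a" &
                                    cm$per_sample$cgi == "CGI_1"], 0.15)
  expect_equal(cm$summary$grand_mean[cm$summary$cgi == "CGI_1"],
               mean(c(0.15, 0.35)))
  # island with no sites is missing
  expect_true(is.na(cm$summary$grand_mean[cm$summary$cgi == "CGI_2"]))
  # fully methylated island: grand mean 1
  m1 <- matrix(1, 2, 2, dimnames = list(NULL, c("a", "b")))
  attr(m1, "positions") <- attr(m, "positions")
  expect_equal(cgi_means(m1, cgi)$summary$grand_mean[1], 1)
})

test_that("a planted hypomethylated region tops the dispersion scan", {
  gsim <- make_genome(seed = 9, target_length = 5e6, n_cgi = 60)
  meth <- simulate_methylome(
    gsim, n_samples = 7, coverage_mean = 10,
    planted_region = list(start = 2250001, end = 2500000, sample = "S4",
                          delta = -0.3),
    seed = 81)
  q <- quantile_normalize(frequency_matrix(filter_sites(meth$table)))
  tk <- window_track(q, width = 250000, chrom_length = 5e6)
  ds <- dispersion_scan(tk, genes = gsim$annotations$genes)
  expect_gt(nrow(ds), 0)
  expect_lte(ds$start[1], 2500000)
  expect_gte(ds$end[1], 2250001)
  expect_equal(ds$deviating_sample[1], "S4")
  # null: no planted region, no window reaches the z threshold typically
  meth0 <- simulate_methylome(gsim, n_samples = 7, coverage_mean = 10,
                              seed = 82)
  q0 <- quantile_normalize(frequency_matrix(filter_sites(meth0$table)))
  ds0 <- dispersion_scan(window_track(q0, width = 250000,
                                      chrom_length = 5e6))
  expect_lte(nrow(ds0), 1)
})

test_that("per-class and per-category medians recover the simulated ordering", {
  gsim <- make_genome(seed = 10, target_length = 3e6, n_cgi = 60)
  meth <- simulate_methylome(gsim, n_samples = 4, coverage_mean = 15,
                             seed = 83)
  q <- quantile_normalize(frequency_matrix(filter_sites(meth$table)))
  ann <- annotate_sites(q, gsim$annotations$cgi, gsim$annotations$classes,
                        gsim$annotations$genes)
  summ <- class_category_summary(q, ann)
  med <- tapply(summ$median, summ$cpg_category, median, na.rm = TRUE)
  expect_true(med[["island"]] < med[["shore"]])
  expect_true(med[["shore"]] < med[["shelf"]])
  expect_true(med[["shelf"]] < med[["open_sea"]])
  # X-degenerate open sea sits near its configured 0.75 level
  xdeg <- summ$median[summ$seq_class == "X-degenerate" &
                        summ$cpg_category == "open_sea"]
  expect_equal(mean(xdeg), 0.75, tolerance = 0.05)
})

test_that("methylome trees recover a strong phylogenetic signal but not noise", {
  tr <- example_haplogroup_tree()
  gsim <- make_genome(seed = 11, target_length = 3e6)
  meth <- simulate_methylome(gsim, tree = tr, branch_scale = 0.02,
                             coverage_mean = 30, seed = 91)
  q <- quantile_normalize(frequency_matrix(filter_sites(meth$table)))
  mt <- methylome_tree(q, reference = tr)
  expect_equal(mt$rf, 0)
  # duplicate columns join first: their distance is zero
  m <- q[, c(1, 1, 2, 3)]
  colnames(m) <- c("d1", "d2", "x", "y")
  mt2 <- methylome_tree(m)
  expect_equal(as.matrix(mt2$dist)["d1", "d2"], 0)
  expect_error(methylome_tree(q[, 1:2]), "three samples")
  expect_error(methylome_tree(q, reference = ape::rtree(4)), "match")
})
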