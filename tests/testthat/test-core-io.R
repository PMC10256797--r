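test_that("genome definition applies gap arithmetic, clipping and validation", {
  # no gaps: non-N equals length
  g <- genome_def(c(chrA = 1000))
  expect_equal(unname(non_n_sizes(g)), 1000)

  # interior gap subtracts its width
  g <- genome_def(c(chrY = 500),
                  gaps = data.frame(chrom = "chrY", start = 101, end = 200))
  expect_equal(unname(non_n_sizes(g)["chrY"]), 400)

  # gap running past the chromosome end is clipped
  g <- genome_def(c(chrY = 500),
                  gaps = data.frame(chrom = "chrY", start = 451, end = 600))
  expect_equal(unname(non_n_sizes(g)["chrY"]), 450)

  # overlapping gaps are merged before subtraction (normalization idempotent)
  g <- genome_def(c(chrY = 500),
                  gaps = data.frame(chrom = "chrY",
                                    start = c(101, 151), end = c(200, 250)))
  expect_equal(unname(non_n_sizes(g)["chrY"]), 350)
  g2 <- genome_def(g$chromosomes, gaps = g$gaps, ploidy = c(chrY = g$ploidy[["chrY"]]))
  expect_identical(g2$gaps, g$gaps)

  expect_error(genome_def(c(chrA = 1000),
                          gaps = data.frame(chrom = "chrB", start = 1, end = 10)),
               "chrB")
  expect_error(genome_def(c(chrA = 1000), ploidy = c(chrZ = 1)), "chrZ")
  expect_error(genome_def(c(chrA = -5)), "positive")
  expect_error(genome_def(c(chrA = 10.5)), "positive")
})

test_that("genome definition reads sizes TSV and gap BED from disk", {
  sizes <- tempfile(fileext = ".tsv")
  writeLines(c("chrA\t1000", "chrY\t500"), sizes)
  gaps <- tempfile(fileext = ".bed")
  writeLines("chrY\t100\t200", gaps)  # BED 0-based half-open
  g <- read_genome_def(sizes, gaps, ploidy = c(chrY = 1))
  expect_equal(unname(non_n_sizes(g)), c(1000, 400))
  expect_equal(unname(g$ploidy), c(2, 1))
  expect_equal(diploid_genome_size(g), 2 * 1000 + 400)
})

test_that("mapping summaries aggregate and validate", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tmapped_bases",
               "s1\tchrA\t2000", "s1\tchrY\t800"), f)
  s <- read_mapping_summary(f)
  expect_equal(unname(total_mapped(s)["s1"]), 2800)

  writeLines("sample\tchrom\tmapped_bases", f)
  expect_error(read_mapping_summary(f), "no records")

  writeLines(c("sample\tchrom\tmapped_bases",
               "s1\tchrA\t100", "s1\tchrA\t50"), f)
  expect_warning(s <- read_mapping_summary(f), "summed")
  expect_equal(s$mapped_bases, 150)

  writeLines(c("sample\tchrom\tmapped_bases", "s1\tchrA\t-5"), f)
  expect_error(read_mapping_summary(f), "non-negative")
})

test_that("SV VCF reading converts coordinates and flags, and round-trips", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Float,Description=\"q\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chrY\t101\td1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-60\tGT:GQ\t1/1:60\t0/0:55",
    "chrY\t300\ti1\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=40;IMPRECISE\tGT:GQ\t0/1:20\t./.:.",
    "chrY\t500\tx1\tN\t<DEL>\t.\tPASS\tSVLEN=-10\tGT:GQ\t1/1:60\t0/0:55"),
    vcf)
  expect_message(p <- read_sv_vcf(vcf), "rejected 1")
  expect_equal(nrow(p$records), 2)
  expect_equal(p$records$pos, c(101, 300))
  expect_equal(p$records$length, c(60, 40))
  expect_equal(p$records$precise, c(TRUE, FALSE))
  expect_equal(unname(p$gt[1, ]), c("hom_alt", "hom_ref"))
  expect_equal(unname(p$gt[2, ]), c("het_alt", "missing"))
  expect_equal(unname(p$gq[1, ]), c(60, 55))

  out <- tempfile(fileext = ".vcf")
  write_sv_vcf(p, out)
  p2 <- read_sv_vcf(out)
  expect_equal(p2$records, p$records)
  expect_equal(p2$gt, p$gt)
  expect_equal(p2$gq[!is.na(p$gq)], p$gq[!is.na(p$gq)])
})

test_that("record QUAL backs genotype quality when GQ is absent", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chrY\t101\td1\tN\t<DEL>\t17.5\tPASS\tSVTYPE=DEL;SVLEN=-60\tGT\t1/1"),
    vcf)
  p <- read_sv_vcf(vcf)
  expect_equal(unname(p$gq[1, 1]), 17.5)
})

test_that("newick trees parse and basal structure is preserved", {
  f <- tempfile(fileext = ".nwk")
  writeLines("((A0,A1a),(H,J));", f)
  tr <- read_newick(f)
  expect_equal(ape::Ntip(tr), 4)
  # A0 and A1a are sisters, separated from H and J
  mrca <- ape::getMRCA(tr, c("A0", "A1a"))
  expect_false(any(c("H", "J") %in%
    tr$tip.label[phangorn::Descendants(tr, mrca, "tips")[[1]]]))
  writeLines("((A0,A1a),(H,J;", f)
  expect_error(read_newick(f))
})

test_that("gene models derive strand-aware features from BED12", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c(
    # + strand, 2 exons, CDS inside
    "chrY\t10000\t14000\tgplus\t0\t+\t10500\t13500\t0\t2\t1000,1000\t0,3000",
    # - strand, 2 exons
    "chrY\t20000\t24000\tgminus\t0\t-\t20500\t23500\t0\t2\t1000,1000\t0,3000"),
    bed)
  gm <- read_gene_models(bed)
  ft <- gene_features(gm)

  plus <- ft[ft$gene == "gplus"]
  tss <- plus[plus$feature == "tss"]
  # + strand: TSS region is exactly the 200 bp before txStart (1-based 10001)
  expect_equal(GenomicRanges::start(tss), 9801)
  expect_equal(GenomicRanges::end(tss), 10000)
  expect_equal(GenomicRanges::width(tss), 200)
  # first exon is the leftmost exon on + strand
  expect_equal(GenomicRanges::start(plus[plus$feature == "first_exon"]), 10001)

  minus <- ft[ft$gene == "gminus"]
  tss_m <- minus[minus$feature == "tss"]
  # - strand: TSS region is the 200 bp after txEnd
  expect_equal(GenomicRanges::start(tss_m), 24001)
  expect_equal(GenomicRanges::end(tss_m), 24200)
  # first exon is the rightmost exon on - strand
  expect_equal(GenomicRanges::end(minus[minus$feature == "first_exon"]), 24000)

  # BED12 round trip through the writer
  out <- tempfile(fileext = ".bed")
  write_bed12(gm, out)
  gm2 <- read_gene_models(out)
  expect_equal(as.character(GenomicRanges::strand(gm2$transcripts)),
               as.character(GenomicRanges::strand(gm$transcripts)))
  expect_equal(S4Vectors::mcols(gm2$transcripts)$exons,
               S4Vectors::mcols(gm$transcripts)$exons)
})

test_that("feature assignment partitions the gene span without overlap", {
  bed <- tempfile(fileext = ".bed")
  writeLines(
    "chrY\t10000\t14000\tg\t0\t+\t10500\t13500\t0\t2\t1000,1000\t0,3000",
    bed)
  gm <- read_gene_models(bed)
  # every base from upstream edge to txEnd gets exactly one feature label
  span <- tibble::tibble(chrom = "chrY", start = (10001 - 2200):14000)
  feats <- annotate_gene_feature(span, gm, collapse = FALSE)
  expect_false(any(feats == "intergenic"))
  # feature widths add up to the full span
  expect_equal(sum(table(feats)), nrow(span))
  # the priority collapse maps exactly the non-first exon and intron bases
  coll <- annotate_gene_feature(span, gm, collapse = TRUE)
  expect_equal(sum(coll == "intragenic"),
               sum(feats %in% c("other_exon", "intron")))
  expect_equal(annotate_gene_feature(
    tibble::tibble(chrom = "chrY", start = 50000), gm), "intergenic")
})

test_that("alignment adapter counts primary alignments only", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrY\tLN:10000",
    "@SQ\tSN:chrA\tLN:10000",
    # primary, 100 aligned bases on chrY
    paste("r1\t0\tchrY\t100\t60\t100M\t*\t0\t0",
          paste(rep("A", 100), collapse = ""), "*", sep = "\t"),
    # secondary alignment: excluded
    "r1\t256\tchrA\t200\t0\t100M\t*\t0\t0\t*\t*",
    # supplementary alignment: excluded
    "r2\t2048\tchrY\t500\t60\t50M50S\t*\t0\t0\t*\t*",
    # primary with clips and insertion: 60M + 5I aligned
    paste("r3\t0\tchrA\t100\t60\t10S60M5I10M\t*\t0\t0",
          paste(rep("A", 85), collapse = ""), "*", sep = "\t")),
    sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  s <- ingest_alignments(bam, sample = "t")
  expect_equal(s$mapped_bases[s$chrom == "chrY"], 100)
  expect_equal(s$mapped_bases[s$chrom == "chrA"], 75)

  g <- genome_def(c(chrY = 10000))
  expect_warning(ingest_alignments(bam, genome = g, sample = "t"),
                 "absent from genome")
})
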