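GT_LEVELS <- c("hom_ref", "het_alt", "hom_alt", "missing")

#' Construct a structural-variant panel
#'
#' An `sv_panel` couples a table of variant records with per-sample genotype
#' and genotype-quality matrices. Genotypes take values `hom_ref`, `het_alt`,
#' `hom_alt` or `missing`; on a hemizygous chromosome any alternative call
#' implies carrier status.
#'
#' @param records Tibble with columns `id`, `chrom`, `pos` (1-based start),
#'   `type` (`INS`, `DEL`, `DUP`, `TRA`), `length` (bp, `NA` allowed for
#'   `TRA`), `precise` (logical). An optional list-column `members` records
#'   post-merge provenance.
#' @param gt Character matrix (variants x samples) of genotypes.
#' @param gq Numeric matrix of per-genotype qualities (same shape), or `NULL`.
#' @param samples Sample names; defaults to `colnames(gt)`.
#' @param platform Optional platform label (e.g. `"ONT"`, `"Illumina"`).
#' @return An object of class `sv_panel`.
#' @export
sv_panel <- function(records, gt, gq = NULL, samples = colnames(gt),
                     platform = NULL) {
  records <- as_tibble(records)
  .assert_cols(records, c("id", "chrom", "pos", "type", "length", "precise"),
               "SV records")
  gt <- as.matrix(gt)
  if (nrow(gt) != nrow(records)) stop("gt rows must match records", call. = FALSE)
  if (!all(gt %in% GT_LEVELS)) stop("invalid genotype value", call. = FALSE)
  if (is.null(gq)) gq <- matrix(NA_real_, nrow(gt), ncol(gt))
  gq <- as.matrix(gq)
  stopifnot(all(dim(gq) == dim(gt)))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gt)))
  colnames(gt) <- colnames(gq) <- samples
  rownames(gt) <- rownames(gq) <- records$id
  indel <- records$type %in% c("INS", "DEL")
  if (any(indel & (is.na(records$length) | records$length < 1))) {
    stop("indel records must have length >= 1", call. = FALSE)
  }
  structure(list(records = records, gt = gt, gq = gq,
                 samples = samples, platform = platform),
            class = "sv_panel")
}

#' @export
print.sv_panel <- function(x, ...) {
  cat(sprintf("<sv_panel> %d records x %d samples%s\n", nrow(x$records),
              length(x$samples),
              if (!is.null(x$platform)) paste0(" [", x$platform, "]") else ""))
  print(table(x$records$type))
  invisible(x)
}

#' @export
dim.sv_panel <- function(x) c(nrow(x$records), length(x$samples))

.gt_from_vcf <- function(g) {
  g <- sub(":.*", "", g)
  out <- rep("missing", length(g))
  out[g %in% c("0/0", "0|0", "0")] <- "hom_ref"
  out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- "het_alt"
  out[g %in% c("1/1", "1|1", "1")] <- "hom_alt"
  out
}

.gt_to_vcf <- c(hom_ref = "0/0", het_alt = "0/1", hom_alt = "1/1",
                missing = "./.")

#' Read a structural-variant VCF
#'
#' Reads a VCF dialect carrying `SVTYPE` (INS/DEL/DUP/TRA/BND), `SVLEN`
#' and/or `END`, an optional `IMPRECISE` flag, and per-sample `GT` (with `GQ`
#' if present; otherwise the record `QUAL` is used as every genotype's
#' quality, since quality filtering applies to whichever was read). Records
#' without `SVTYPE` are rejected with a message. `BND` records are read as
#' type `TRA`.
#'
#' @param path Path to a (plain or gzipped) VCF.
#' @param platform Optional platform label stored on the panel.
#' @return An `sv_panel`.
#' @export
read_sv_vcf <- function(path, platform = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info <- fix$INFO %||% rep("", nrow(fix))
  get_info <- function(key) {
    m <- regexpr(paste0("(^|;)", key, "=[^;]+"), info)
    out <- rep(NA_character_, length(info))
    out[m > 0] <- sub(paste0("^.*", key, "="), "", regmatches(info, m))
    out
  }
  svtype <- get_info("SVTYPE")
  keep <- !is.na(svtype)
  if (any(!keep)) {
    message(sprintf("rejected %d record(s) without SVTYPE", sum(!keep)))
  }
  svtype[svtype == "BND"] <- "TRA"
  svlen <- suppressWarnings(as.numeric(get_info("SVLEN")))
  endpos <- suppressWarnings(as.numeric(get_info("END")))
  pos <- as.numeric(fix$POS)
  len <- abs(svlen)
  # DEL length from END when SVLEN absent
  need <- is.na(len) & svtype == "DEL" & !is.na(endpos)
  len[need] <- endpos[need] - pos[need]
  precise <- !grepl("(^|;)IMPRECISE(;|$)", info)
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0("sv", seq_len(nrow(fix)))[is.na(id) | id == "."]

  gt_raw <- v@gt
  samples <- colnames(gt_raw)[-1]
  fmt <- strsplit(gt_raw[, 1], ":")
  gq_idx <- vapply(fmt, function(f) match("GQ", f), integer(1))
  gt <- apply(gt_raw[, -1, drop = FALSE], 2, .gt_from_vcf)
  if (nrow(fix) == 1L) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, samples))
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  gq <- matrix(NA_real_, nrow(fix), length(samples))
  for (i in seq_len(nrow(fix))) {
    if (!is.na(gq_idx[i])) {
      parts <- strsplit(gt_raw[i, -1, drop = TRUE], ":")
      gq[i, ] <- suppressWarnings(vapply(parts, function(p) {
        as.numeric(p[gq_idx[i]])
      }, numeric(1)))
    } else if (!is.na(qual[i])) {
      gq[i, ] <- qual[i]
    }
  }
  records <- tibble(id = id, chrom = fix$CHROM, pos = pos, type = svtype,
                    length = len, precise = precise)
  sv_panel(records[keep, ], gt[keep, , drop = FALSE],
           gq[keep, , drop = FALSE], samples = samples, platform = platform)
}

#' Write a structural-variant panel as VCF
#'
#' Emits the same dialect [read_sv_vcf()] reads: `SVTYPE`, signed `SVLEN`
#' (negative for deletions), `END` for deletions, `IMPRECISE` where the
#' precise flag is unset, and per-sample `GT:GQ`. A write/read round trip
#' preserves the records.
#'
#' @param panel An `sv_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(panel, path) {
  stopifnot(is(panel, "sv_panel"))
  r <- panel$records
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ychrtools",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise breakpoints\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Float,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "FORMAT",
            panel$samples), collapse = "\t")
  )
  info <- vapply(seq_len(nrow(r)), function(i) {
    parts <- paste0("SVTYPE=", r$type[i])
    if (!is.na(r$length[i])) {
      sl <- if (r$type[i] == "DEL") -r$length[i] else r$length[i]
      parts <- c(parts, paste0("SVLEN=", format(sl, scientific = FALSE)))
      if (r$type[i] == "DEL") {
        parts <- c(parts,
                   paste0("END=", format(r$pos[i] + r$length[i],
                                         scientific = FALSE)))
      }
    }
    if (!r$precise[i]) parts <- c(parts, "IMPRECISE")
    paste(parts, collapse = ";")
  }, character(1))
  gt_field <- matrix(.gt_to_vcf[panel$gt], nrow = nrow(r))
  gq_field <- ifelse(is.na(panel$gq), ".",
                     format(panel$gq, trim = TRUE, scientific = FALSE))
  sample_cols <- matrix(paste(gt_field, gq_field, sep = ":"), nrow = nrow(r))
  body <- vapply(seq_len(nrow(r)), function(i) {
    paste(c(r$chrom[i], format(r$pos[i], scientific = FALSE), r$id[i], "N",
            paste0("<", r$type[i], ">"), ".", "PASS", info[i], "GT:GQ",
            sample_cols[i, ]), collapse = "\t")
  }, character(1))
  # header-reordered to place FORMAT after INFO column header
  header[length(header)] <- paste(c("#CHROM", "POS", "ID", "REF", "ALT",
                                    "QUAL", "FILTER", "INFO", "FORMAT",
                                    panel$samples), collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
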