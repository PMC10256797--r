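#' Default per-category methylation parameters
#'
#' Mean and concentration of the beta distribution from which per-site true
#' 5mC frequencies are drawn, by CpG category, with a class-specific
#' override raising the X-degenerate open sea to the 0.75 level typical of
#' single-copy, autosome-like sequence. Rows with `seq_class = "*"` apply to
#' every sequence class; a row naming a class takes precedence for sites in
#' that class.
#'
#' @return Tibble with columns `cpg_category`, `seq_class`, `mean`,
#'   `concentration`.
#' @export
default_methylation_params <- function() {
  tribble(
    ~cpg_category, ~seq_class,       ~mean, ~concentration,
    "island",      "*",              0.10,  10,
    "shore",       "*",              0.40,  10,
    "shelf",       "*",              0.55,  10,
    "open_sea",    "*",              0.70,  10,
    "open_sea",    "X-degenerate",   0.75,  15
  )
}

.lookup_params <- function(params, category, class) {
  key_specific <- paste(category, class)
  key_star <- paste(category, "*")
  tab <- setNames(seq_len(nrow(params)),
                  paste(params$cpg_category, params$seq_class))
  idx <- tab[key_specific]
  idx[is.na(idx)] <- tab[key_star][is.na(idx)]
  if (any(is.na(idx))) {
    stop(sprintf("no methylation parameters for category %s",
                 paste(unique(category[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  params[idx, c("mean", "concentration")]
}

#' Simulate per-CpG methylation frequency tables
#'
#' Places CpG sites along the target chromosome (geometric spacing, gaps
#' excluded), draws a per-site true frequency from the beta distribution of
#' the site's CpG category and sequence class, then observes each sample
#' through Poisson coverage and binomial methylated counts. A planted region
#' shifts one sample's true frequencies by `delta` (clamped to [0.01,
#' 0.99]), creating a sample-specific differentially methylated region.
#' When a `tree` is supplied, Gaussian per-branch site effects with variance
#' proportional to branch length are added along each sample's root-to-tip
#' path, giving the samples a phylogeny-structured methylome.
#'
#' @param sim A `sim_genome` from [make_genome()].
#' @param n_samples Number of samples (ignored when `tree` is given: its
#'   tips define the samples).
#' @param params Parameter table, see [default_methylation_params()].
#' @param site_spacing Mean spacing between CpG sites (bp).
#' @param coverage_mean Mean per-site read coverage.
#' @param planted_region `NULL`, or
#'   `list(start =, end =, sample =, delta =)` on the target chromosome.
#' @param tree Optional ultrametric `phylo` for tree-structured signal.
#' @param branch_scale Standard deviation of branch effects per unit branch
#'   length (0 disables the tree signal).
#' @param seed Integer seed.
#' @return List of class `sim_methylome`: `table` (long tibble with
#'   `chrom`, `start`, `end`, `sample`, `called_sites`,
#'   `called_sites_methylated`, `frequency`), `truth` (list: `positions`,
#'   `base_freq`, `true_freq` site x sample matrix, `planted_region`) and
#'   `samples`.
#' @export
simulate_methylome <- function(sim, n_samples = 7,
                               params = default_methylation_params(),
                               site_spacing = 150, coverage_mean = 10,
                               planted_region = NULL, tree = NULL,
                               branch_scale = 0, seed = 1) {
  stopifnot(is(sim, "sim_genome"))
  genome <- sim$genome
  target <- sim$target
  len <- genome$chromosomes$length[genome$chromosomes$name == target]
  if (!is.null(planted_region)) {
    if (planted_region$start < 1 || planted_region$end > len) {
      stop("planted region outside the target chromosome", call. = FALSE)
    }
  }
  samples <- if (!is.null(tree)) tree$tip.label else
    sprintf("S%d", seq_len(n_samples))
  n_s <- length(samples)

  withr::with_seed(derive_seed(seed, "methylome"), {
    n_draw <- ceiling(1.3 * len / site_spacing)
    pos <- cumsum(2L + stats::rgeom(n_draw, prob = 1 / (site_spacing - 1)))
    pos <- pos[pos <= len - 1]
    site_gr <- .pos_granges(target, pos)
    in_gap <- IRanges::overlapsAny(site_gr, genome$gaps)
    pos <- pos[!in_gap]
    site_gr <- site_gr[!in_gap]
    n_sites <- length(pos)

    category <- annotate_cpg_category(site_gr, sim$annotations$cgi)
    class <- .annotate_class(site_gr, sim$annotations$classes)
    par <- .lookup_params(params, as.character(category), as.character(class))
    a <- par$mean * par$concentration
    b <- (1 - par$mean) * par$concentration
    base <- rbeta(n_sites, a, b)

    true_freq <- matrix(base, n_sites, n_s, dimnames = list(NULL, samples))
    if (!is.null(tree) && branch_scale > 0) {
      paths <- .root_paths(tree)
      for (e in seq_len(nrow(tree$edge))) {
        eff <- rnorm(n_sites, 0, branch_scale * sqrt(tree$edge.length[e]))
        below <- samples[paths[[e]]]
        true_freq[, below] <- true_freq[, below] + eff
      }
    }
    if (!is.null(planted_region)) {
      in_reg <- pos >= planted_region$start & pos <= planted_region$end
      true_freq[in_reg, planted_region$sample] <-
        true_freq[in_reg, planted_region$sample] + planted_region$delta
    }
    true_freq <- pmin(pmax(true_freq, 0.01), 0.99)

    coverage <- matrix(rpois(n_sites * n_s, coverage_mean), n_sites, n_s)
    meth <- matrix(rbinom(n_sites * n_s, coverage, true_freq), n_sites, n_s)

    table <- tibble(
      chrom = target,
      start = rep(pos, n_s),
      end = rep(pos, n_s),
      sample = rep(samples, each = n_sites),
      called_sites = as.vector(coverage),
      called_sites_methylated = as.vector(meth),
      frequency = ifelse(as.vector(coverage) > 0,
                         as.vector(meth) / as.vector(coverage), NA_real_))
    structure(list(table = table,
                   truth = list(positions = pos, base_freq = base,
                                true_freq = true_freq,
                                category = category, seq_class = class,
                                planted_region = planted_region),
                   samples = samples),
              class = "sim_methylome")
  })
}

# tips below each edge (per-edge index into tip labels)
.root_paths <- function(tree) {
  lapply(tree$edge[, 2], function(nd) {
    if (nd <= length(tree$tip.label)) nd
    else phangorn::Descendants(tree, nd, type = "tips")[[1]]
  })
}

.annotate_class <- function(sites, classes) {
  hits <- GenomicRanges::findOverlaps(sites, classes, select = "first",
                                      ignore.strand = TRUE)
  out <- rep("other", length(sites))
  out[!is.na(hits)] <- classes$name[hits[!is.na(hits)]]
  out
}

#' Write a methylation table in the nanopolish frequency dialect
#'
#' Columns `chromosome`, `start`, `end` (0-based), `num_motifs_in_group`,
#' `called_sites`, `called_sites_methylated`, `methylated_frequency`,
#' `group_sequence`; one file per sample is conventional, so the table is
#' filtered to `sample` if given.
#'
#' @param table Long methylation tibble (see [simulate_methylome()]).
#' @param path Output path.
#' @param sample Optional sample to subset.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(table, path, sample = NULL) {
  if (!is.null(sample)) table <- table[table$sample == sample, ]
  out <- tibble(
    chromosome = table$chrom,
    start = table$start - 1L,
    end = table$end - 1L,
    num_motifs_in_group = 1L,
    called_sites = table$called_sites,
    called_sites_methylated = table$called_sites_methylated,
    methylated_frequency = round(table$frequency, 3),
    group_sequence = "split")
  readr::write_tsv(out, path)
  invisible(path)
}
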