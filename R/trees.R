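#' Read a rooted phylogeny in newick format
#'
#' @param path Path to a newick file.
#' @return An [ape::read.tree] `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tr)) stop(sprintf("failed to parse newick file '%s'", path),
                        call. = FALSE)
  tr
}

#' A synthetic ultrametric haplogroup tree
#'
#' Seven leaves named after major Y-chromosome haplogroup labels, with two
#' basal lineages (A0, A1a) and plausible split times in thousands of years;
#' a stand-in reference topology for simulations and tree-recovery checks,
#' not an inferred phylogeny.
#'
#' @return A rooted, ultrametric `phylo` with 7 tips.
#' @export
#' @examples
#' tr <- example_haplogroup_tree()
#' ape::is.ultrametric(tr)
example_haplogroup_tree <- function() {
  ape::read.tree(text = paste0(
    "(A0:235,(A1a:161,(E1b:70,(G2a:55,(H1a:45,(J1a:30,R1b:30):15):10):15)",
    ":91):74);"))
}
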