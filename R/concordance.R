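#' Binarize a genotype panel into presence/absence
#'
#' On a hemizygous chromosome any alternative call implies carrier status:
#' homozygous- and heterozygous-alternative genotypes become present (1),
#' homozygous-reference genotypes absent (0), missing stays missing (`NA`).
#'
#' @param panel An `sv_panel`.
#' @param label_platform Append the panel's platform label to the column
#'   names (useful before joining two platforms into one matrix).
#' @return Numeric matrix (variants x samples) with values 1, 0, `NA`.
#' @export
binarize <- function(panel, label_platform = FALSE) {
  stopifnot(is(panel, "sv_panel"))
  m <- matrix(NA_real_, nrow(panel$gt), ncol(panel$gt),
              dimnames = dimnames(panel$gt))
  m[panel$gt %in% c("het_alt", "hom_alt")] <- 1
  m[panel$gt == "hom_ref"] <- 0
  if (label_platform && !is.null(panel$platform)) {
    colnames(m) <- paste(colnames(m), panel$platform, sep = ".")
  }
  m
}

#' Phi (Matthews) coefficient of two binary vectors
#'
#' Pairwise-complete positions (missing in neither vector) are cross-
#' tabulated and phi computed as
#' `(n11*n00 - n10*n01) / sqrt(n1. * n0. * n.1 * n.0)`. The coefficient is
#' undefined when any table margin is zero; this is reported as `NA` (never
#' coerced to 0), with the reason attached as an attribute. Phi equals the
#' Pearson correlation of the two 0/1 vectors, and `n * phi^2` is the 2x2
#' chi-square statistic.
#'
#' @param x,y Vectors of 0/1 with `NA` for missing.
#' @return A number in `[-1, 1]`, or `NA` with attribute `reason`.
#' @export
#' @examples
#' phi_coef(c(1, 1, 0, 0), c(1, 1, 0, 0))  #  1
#' phi_coef(c(1, 1, 0, 0), c(0, 0, 1, 1))  # -1
#' phi_coef(c(1, 1, 0, 0), c(1, 0, 1, 0))  #  0
phi_coef <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  if (!any(keep)) {
    return(structure(NA_real_, reason = "no informative positions"))
  }
  x <- x[keep]; y <- y[keep]
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  margins <- c(n11 + n10, n01 + n00, n11 + n01, n10 + n00)
  if (any(margins == 0)) {
    return(structure(NA_real_, reason = "degenerate margin"))
  }
  (n11 * n00 - n10 * n01) / sqrt(prod(margins))
}

#' Pairwise phi matrix with Bonferroni-corrected significance
#'
#' Computes phi for every pair of columns of a binary genotype matrix with
#' pairwise-complete deletion of missing entries, a p-value per pair, and a
#' Bonferroni significance mask at level `alpha` with the family size `m`
#' equal to the number of pairs actually tested (pairs with a defined phi).
#' P-values come from Fisher's exact test on the 2x2 table by default
#' (appropriate for small, sparse tables); `method = "chisq"` uses the
#' identity `chi^2 = n * phi^2` with 1 degree of freedom.
#'
#' @param mat Binary matrix (variants x samples/platform columns).
#' @param alpha Significance level before correction.
#' @param method P-value procedure: `"fisher"` or `"chisq"`.
#' @return List of class `concordance`: `phi`, `p`, `significant` (logical
#'   mask, `p <= alpha / m`), `n` (informative positions per pair), `m`,
#'   `alpha`, `method`.
#' @export
phi_matrix <- function(mat, alpha = 0.05, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  k <- ncol(mat)
  if (k < 2L) stop("need at least two columns", call. = FALSE)
  phi <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(mat),
                                                     colnames(mat)))
  n <- matrix(0L, k, k, dimnames = dimnames(phi))
  diag(phi) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- mat[, i]; y <- mat[, j]
      keep <- !is.na(x) & !is.na(y)
      n[i, j] <- n[j, i] <- sum(keep)
      ph <- phi_coef(x, y)
      phi[i, j] <- phi[j, i] <- as.numeric(ph)
      if (!is.na(ph)) {
        tab <- table(factor(x[keep], c(0, 1)), factor(y[keep], c(0, 1)))
        p[i, j] <- p[j, i] <- if (method == "fisher") {
          fisher.test(tab)$p.value
        } else {
          pchisq(sum(keep) * ph^2, df = 1, lower.tail = FALSE)
        }
      }
    }
  }
  tested <- sum(!is.na(p[upper.tri(p)]))
  significant <- !is.na(p) & p <= alpha / max(tested, 1L)
  structure(list(phi = phi, p = p, significant = significant, n = n,
                 m = tested, alpha = alpha, method = method),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("<concordance> %d columns, %d tested pairs (%s, Bonferroni at alpha = %g)\n",
              ncol(x$phi), x$m, x$method, x$alpha))
  print(round(x$phi, 3))
  invisible(x)
}

#' Population presence calls from group genotype frequencies
#'
#' For each variant and group, the carrier frequency is the number of
#' carriers over the number genotyped within the group; a variant is called
#' present in the group when that frequency is strictly greater than the
#' threshold. Groups with no genotyped individuals give a missing call.
#'
#' @param carriers Binary matrix (variants x individuals; 1 carrier,
#'   0 non-carrier, `NA` not genotyped).
#' @param groups Character/factor of group (population or haplogroup)
#'   membership, one per individual (column).
#' @param threshold Presence threshold on the within-group frequency
#'   (strict `>`).
#' @return Numeric matrix (variants x groups) with values 1, 0, `NA`.
#' @export
population_presence <- function(carriers, groups, threshold = 0.2) {
  stopifnot(ncol(carriers) == length(groups))
  groups <- as.character(groups)
  out <- sapply(unique(groups), function(g) {
    sub <- carriers[, groups == g, drop = FALSE]
    n_gen <- rowSums(!is.na(sub))
    freq <- ifelse(n_gen > 0, rowSums(sub == 1, na.rm = TRUE) / n_gen,
                   NA_real_)
    ifelse(is.na(freq), NA_real_, as.numeric(freq > threshold))
  })
  out <- matrix(out, nrow = nrow(carriers),
                dimnames = list(rownames(carriers), unique(groups)))
  out
}
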