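#' Strand-resolved correlations between a focal gene and mutation classes
#'
#' A mutator acting on single-stranded DNA of the untranscribed (coding)
#' strand produces coding-strand C>A mutations; the same lesion on the
#' transcribed template strand reads as G>T at the gene level. Comparing the
#' correlation of a focal gene's expression with coding C>A versus coding
#' G>T burden therefore probes transcriptional strand asymmetry.
#'
#' @param norm_expr Housekeeping-normalized expression matrix.
#' @param focal_gene Gene id (must be a row of `norm_expr`).
#' @param profiles `mutation_profiles` carrying stranded counts.
#' @param classes Mutation class selectors (see [mutation_burden()]).
#'   Defaults to every stranded class plus the collapsed C>A/G>T class and
#'   the total burden.
#' @return Data frame `class`, `r`, `p` (Spearman, t-approximation). Classes
#'   with all-zero or constant counts give `NA`.
#' @export
stranded_correlations <- function(norm_expr, focal_gene, profiles,
                                  classes = c(sub_types(), "C>A/G>T", "total")) {
  if (!focal_gene %in% rownames(norm_expr))
    stop("focal gene not found in expression matrix: ", focal_gene)
  out <- data.frame(class = classes, r = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(classes)) {
    burden <- mutation_burden(profiles, classes[i])
    shared <- shared_samples(norm_expr, burden)
    x <- norm_expr[focal_gene, shared]
    y <- burden[shared]
    if (stats::var(y) == 0 || stats::var(x) == 0) next
    sp <- row_spearman(matrix(x, nrow = 1L), y)
    out$r[i] <- sp$r
    out$p[i] <- sp$p
  }
  out
}

#' Group-number sweep of the focal-gene t-test
#'
#' For each mutation class and each group count g, patients are split into g
#' burden groups and the focal gene's expression difference between the
#' extreme groups is tested (FC and two-tailed Student p), showing how the
#' association depends on the grouping resolution.
#'
#' @inheritParams stranded_correlations
#' @param classes Mutation class selectors.
#' @param group_numbers Integer vector of group counts, each in 2-5.
#' @return Data frame `class`, `g`, `fc`, `p`. A class whose burden is
#'   identical across all samples cannot rank patients; its cells carry
#'   `fc = NA`, `p = 1`.
#' @export
group_sweep <- function(norm_expr, focal_gene, profiles,
                        classes = c("C>A", "G>T", "C>A/G>T", "total"),
                        group_numbers = 2:5) {
  if (!focal_gene %in% rownames(norm_expr))
    stop("focal gene not found in expression matrix: ", focal_gene)
  grid <- expand.grid(class = classes, g = group_numbers,
                      stringsAsFactors = FALSE)
  grid$fc <- NA_real_
  grid$p <- NA_real_
  for (i in seq_len(nrow(grid))) {
    burden <- mutation_burden(profiles, grid$class[i])
    if (stats::var(burden) == 0) {
      grid$p[i] <- 1
      next
    }
    assignment <- group_by_burden(profiles, grid$class[i], g = grid$g[i])
    res <- ttest_screen(norm_expr[focal_gene, , drop = FALSE], assignment)
    grid$fc[i] <- res$statistic[1L]
    grid$p[i] <- res$p[1L]
  }
  grid
}
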