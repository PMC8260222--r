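#' Normalize an expression matrix by a housekeeping gene
#'
#' Each sample's column is divided by that sample's value for the
#' housekeeping gene (TATA-binding protein by default), so expression is
#' expressed relative to a gene assumed stable across samples. Samples whose
#' housekeeping value is zero or missing cannot be normalized and are
#' dropped.
#'
#' @param expr Numeric matrix, genes x samples, with gene ids as rownames
#'   and sample ids as colnames.
#' @param housekeeping Housekeeping gene id; must be a rowname of `expr`.
#' @return The normalized matrix (housekeeping row identically 1), with
#'   attributes `housekeeping` and `dropped` (ids of removed samples).
#' @export
tbp_normalize <- function(expr, housekeeping = "TBP") {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (!housekeeping %in% rownames(expr))
    stop("housekeeping gene not found in expression matrix: ", housekeeping)
  hk <- expr[housekeeping, ]
  drop <- is.na(hk) | hk == 0
  if (any(drop))
    message("tbp_normalize: dropping ", sum(drop),
            " sample(s) with zero/missing housekeeping value: ",
            paste(colnames(expr)[drop], collapse = ", "))
  out <- sweep(expr[, !drop, drop = FALSE], 2L, hk[!drop], "/")
  attr(out, "housekeeping") <- housekeeping
  attr(out, "dropped") <- colnames(expr)[drop]
  out
}

# Samples shared between an expression matrix and a burden vector.
shared_samples <- function(norm_expr, burden, min_n = 4L) {
  shared <- intersect(colnames(norm_expr), names(burden))
  if (length(shared) < length(colnames(norm_expr)) ||
      length(shared) < length(burden))
    warning("expression and mutation data share ", length(shared),
            " samples; restricting to the intersection")
  if (length(shared) < min_n)
    stop("need at least ", min_n, " shared samples, found ", length(shared))
  sort(shared)
}

# Spearman r and two-sided p (t approximation, average-rank ties) of each
# row of X against y. Rows with zero rank variance give NA.
row_spearman <- function(X, y) {
  n <- length(y)
  rx <- t(apply(X, 1L, rank))
  ry <- rank(y)
  rx_c <- rx - rowMeans(rx)
  ry_c <- ry - mean(ry)
  denom <- sqrt(rowSums(rx_c^2) * sum(ry_c^2))
  r <- as.vector(rx_c %*% ry_c) / denom
  r[!is.finite(r)] <- NA_real_
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[is.nan(p)] <- 0  # |r| = 1 exactly
  list(r = r, p = p)
}

new_screen_result <- function(gene, statistic, p, screen, extra = NULL,
                              rank_desc = TRUE) {
  q <- stats::p.adjust(p, method = "BH")
  key <- if (rank_desc) -statistic else statistic
  rk <- rank(key, ties.method = "first", na.last = "keep")
  rk[is.na(rk)] <- seq(sum(!is.na(rk)) + 1L, length.out = sum(is.na(rk)))
  out <- data.frame(gene = gene, statistic = statistic, p = p, q = q,
                    rank = as.integer(rk), stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "screen") <- screen
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Genome-wide Spearman screen of expression against mutation burden
#'
#' For every gene, the Spearman rank correlation between its normalized
#' expression and the per-sample burden of a chosen mutation class, with
#' average-rank tie handling and a two-sided p-value from the t-distribution
#' approximation. A positive r flags the gene as a candidate endogenous
#' mutation source for that class.
#'
#' @param norm_expr Housekeeping-normalized matrix from [tbp_normalize()].
#' @param profiles `mutation_profiles` for the same cohort.
#' @param type Mutation class selector passed to [mutation_burden()].
#' @return A `screen_result` data frame: `gene`, `statistic` (r), `p`, `q`
#'   (Benjamini-Hochberg, reported only), `rank` (1 = largest r). Genes with
#'   zero expression variance are skipped; their count is attribute
#'   `n_skipped`.
#' @export
spearman_screen <- function(norm_expr, profiles, type = "C>A/G>T") {
  burden <- mutation_burden(profiles, type)
  shared <- shared_samples(norm_expr, burden)
  X <- norm_expr[, shared, drop = FALSE]
  y <- burden[shared]

  sp <- row_spearman(X, y)
  keep <- !is.na(sp$r)
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message("spearman_screen: skipped ", n_skipped,
            " gene(s) with zero expression variance")
  res <- new_screen_result(rownames(X)[keep], sp$r[keep], sp$p[keep],
                           screen = paste0("spearman:", type))
  attr(res, "n_skipped") <- n_skipped
  attr(res, "n_samples") <- length(shared)
  res
}

#' Split a cohort into burden groups
#'
#' Samples are sorted by ascending burden (ties broken by sample id) and cut
#' into `g` contiguous blocks of near-equal size, so group 1 is the
#' lowest-burden group and group `g` the highest. When sizes cannot be equal
#' the lower groups receive the extra samples.
#'
#' @param profiles `mutation_profiles`.
#' @param type Mutation class selector (see [mutation_burden()]).
#' @param g Number of groups, 2-5.
#' @return Factor with levels `"1"` ... `"g"`, named by sample id.
#' @export
group_by_burden <- function(profiles, type = "C>A/G>T", g = 3L) {
  stopifnot(g >= 2L, g <= 5L)
  burden <- mutation_burden(profiles, type)
  n <- length(burden)
  if (n < 2L * g)
    stop("need at least ", 2L * g, " samples for g = ", g, ", found ", n)
  ord <- order(burden, names(burden))
  k <- n %/% g
  extra <- n %% g
  sizes <- rep(k, g) + c(rep(1L, extra), rep(0L, g - extra))
  assignment <- factor(rep(seq_len(g), times = sizes), levels = seq_len(g))
  out <- assignment
  names(out) <- names(burden)[ord]
  out[names(burden)]  # restore input order
}

# Vectorized two-sample t-test of each row of X between columns `high` and
# `low`. Equal-variance Student by default; Welch via var_equal = FALSE.
row_ttest <- function(X, high, low, var_equal = TRUE) {
  xh <- X[, high, drop = FALSE]
  xl <- X[, low, drop = FALSE]
  nh <- length(high); nl <- length(low)
  mh <- rowMeans(xh); ml <- rowMeans(xl)
  vh <- apply(xh, 1L, stats::var); vl <- apply(xl, 1L, stats::var)
  if (var_equal) {
    sp2 <- ((nh - 1) * vh + (nl - 1) * vl) / (nh + nl - 2)
    se <- sqrt(sp2 * (1 / nh + 1 / nl))
    df <- rep(nh + nl - 2, length(mh))
  } else {
    se <- sqrt(vh / nh + vl / nl)
    df <- (vh / nh + vl / nl)^2 /
      ((vh / nh)^2 / (nh - 1) + (vl / nl)^2 / (nl - 1))
  }
  tstat <- (mh - ml) / se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  degenerate <- se == 0
  p[degenerate & mh == ml] <- 1
  p[degenerate & mh != ml] <- 0
  fc <- ifelse(ml == 0, NA_real_, mh / ml)
  list(fc = fc, t = tstat, p = p, mean_high = mh, mean_low = ml,
       degenerate = degenerate)
}

#' Burden-group t-test screen
#'
#' Two-tailed Student's t-test of each gene's normalized expression between
#' the highest- and lowest-burden groups (middle groups are ignored), with
#' fold change FC = mean(high) / mean(low).
#'
#' @param norm_expr Housekeeping-normalized matrix from [tbp_normalize()].
#' @param assignment Burden-group factor from [group_by_burden()], named by
#'   sample id.
#' @param var_equal Use the pooled-variance Student statistic (default);
#'   `FALSE` switches to Welch.
#' @return A `screen_result` data frame: `gene`, `statistic` (FC, `NA` when
#'   mean(low) = 0), `t`, `p`, `q`, `rank` (1 = largest FC). Genes constant
#'   in both extreme groups get p = 1 and are flagged in column `flag`.
#' @export
ttest_screen <- function(norm_expr, assignment, var_equal = TRUE) {
  lv <- levels(assignment)
  high <- names(assignment)[assignment == lv[length(lv)]]
  low <- names(assignment)[assignment == lv[1L]]
  high <- intersect(colnames(norm_expr), high)
  low <- intersect(colnames(norm_expr), low)
  if (length(high) < 2L || length(low) < 2L)
    stop("need at least 2 samples in each extreme group")
  tt <- row_ttest(norm_expr, high, low, var_equal = var_equal)
  res <- new_screen_result(
    rownames(norm_expr), tt$fc, tt$p, screen = "ttest",
    extra = data.frame(t = tt$t,
                       flag = ifelse(tt$degenerate, "constant", ""),
                       stringsAsFactors = FALSE))
  attr(res, "n_high") <- length(high)
  attr(res, "n_low") <- length(low)
  res
}

#' Mutation-status t-test screen
#'
#' Same statistic contract as [ttest_screen()], but groups are defined by a
#' per-sample mutation status (e.g. carriers versus non-carriers of a
#' C>A/G>T mutation in a gene of interest): FC = mean(positive) /
#' mean(negative).
#'
#' @param norm_expr Housekeeping-normalized matrix.
#' @param status Named vector (sample id -> `"positive"`/`"negative"`, or
#'   logical where `TRUE` means positive).
#' @inheritParams ttest_screen
#' @return A `screen_result` data frame (see [ttest_screen()]).
#' @export
mutation_status_screen <- function(norm_expr, status, var_equal = TRUE) {
  if (is.logical(status))
    status <- stats::setNames(ifelse(status, "positive", "negative"),
                              names(status))
  status <- status[intersect(colnames(norm_expr), names(status))]
  pos <- names(status)[status == "positive"]
  neg <- names(status)[status == "negative"]
  if (length(pos) < 2L || length(neg) < 2L)
    stop("need at least 2 samples in each status class (positive: ",
         length(pos), ", negative: ", length(neg), ")")
  tt <- row_ttest(norm_expr, pos, neg, var_equal = var_equal)
  res <- new_screen_result(
    rownames(norm_expr), tt$fc, tt$p, screen = "status",
    extra = data.frame(t = tt$t,
                       flag = ifelse(tt$degenerate, "constant", ""),
                       stringsAsFactors = FALSE))
  attr(res, "n_positive") <- length(pos)
  attr(res, "n_negative") <- length(neg)
  res
}

#' Select top-ranked screen candidates
#'
#' Keeps genes with p below `alpha`, ranks them by the screen statistic
#' (descending) or by p (ascending), and truncates to the top `k` —
#' mirroring a "top-ranked 200 genes at p < 0.05" selection rule. BH
#' q-values are carried along but never drive selection.
#'
#' @param result A `screen_result`.
#' @param k Maximum number of candidates.
#' @param alpha Raw p-value threshold.
#' @param rank_by `"statistic"` (default) or `"p"`.
#' @return An object of class `candidate_set`: list with `screen`, ordered
#'   `genes`, the selection `table`, and parameters `k`, `alpha`, `rank_by`.
#' @export
select_candidates <- function(result, k = 200L, alpha = 0.05,
                              rank_by = c("statistic", "p")) {
  rank_by <- match.arg(rank_by)
  stopifnot(nrow(result) > 0L)
  keep <- !is.na(result$p) & result$p < alpha & !is.na(result$statistic)
  tab <- result[keep, , drop = FALSE]
  ord <- if (rank_by == "statistic") order(-tab$statistic, tab$p)
         else order(tab$p, -tab$statistic)
  tab <- tab[ord, , drop = FALSE]
  if (nrow(tab) < k)
    warning("only ", nrow(tab), " candidate(s) survive p < ", alpha,
            " (requested k = ", k, ")")
  tab <- utils::head(tab, k)
  rownames(tab) <- NULL
  structure(
    list(screen = attr(result, "screen"), genes = tab$gene, table = tab,
         k = k, alpha = alpha, rank_by = rank_by),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set [", x$screen, "]: ", length(x$genes),
      " gene(s), p < ", x$alpha, ", ranked by ", x$rank_by, "\n", sep = "")
  cat(paste(utils::head(x$genes, 10L), collapse = ", "))
  if (length(x$genes) > 10L) cat(", ...")
  cat("\n")
  invisible(x)
}

#' Intersection of candidate sets across screens
#'
#' The strict intersection of two or more candidate sets, ordered by mean
#' within-set rank, together with the sizes of every Venn region.
#'
#' @param ... Two or more `candidate_set` objects (or a single list of
#'   them).
#' @return List with `genes` (intersection, best mean rank first) and
#'   `regions`, a data frame of all Venn region memberships and sizes.
#' @export
candidate_overlap <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "candidate_set"))
    sets <- sets[[1]]
  if (length(sets) < 2L) stop("need at least 2 candidate sets")
  gene_lists <- lapply(sets, function(s)
    if (inherits(s, "candidate_set")) s$genes else as.character(s))
  labels <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "candidate_set") && !is.null(s$screen)) s$screen
    else paste0("set", i)
  }, character(1))
  labels <- make.unique(labels)

  common <- Reduce(intersect, gene_lists)
  if (length(common)) {
    mean_rank <- vapply(common, function(g)
      mean(vapply(gene_lists, function(gl) match(g, gl), numeric(1))),
      numeric(1))
    common <- common[order(mean_rank, common)]
  }

  all_genes <- unique(unlist(gene_lists))
  membership <- vapply(gene_lists, function(gl) all_genes %in% gl,
                       logical(length(all_genes)))
  membership <- matrix(membership, nrow = length(all_genes),
                       dimnames = list(all_genes, labels))
  key <- apply(membership, 1L, function(m) paste(labels[m], collapse = "&"))
  combos <- unlist(lapply(seq_along(labels), function(k)
    utils::combn(labels, k, paste, collapse = "&", simplify = FALSE)))
  sizes <- vapply(combos, function(cm) sum(key == cm), integer(1))
  regions <- data.frame(region = combos, size = unname(sizes),
                        stringsAsFactors = FALSE)

  list(genes = common, regions = regions)
}
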