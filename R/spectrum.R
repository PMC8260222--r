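#' Base composition of a reference sequence
#'
#' Counts A/C/G/T on the given (plus/coding) strand. Used to normalize
#' spectra by the number of mutable reference sites.
#'
#' @param seq A single character string over A/C/G/T (case-insensitive).
#' @return Named integer vector `c(A=, C=, G=, T=)`.
#' @export
base_composition <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (any(!chars %in% BASES))
    stop("non-ACGT character(s) in sequence: ",
         paste(unique(chars[!chars %in% BASES]), collapse = ", "))
  out <- table(factor(chars, levels = BASES))
  stats::setNames(as.integer(out), BASES)
}

#' Build a substitution spectrum table for one or more groups
#'
#' @param type Character vector of 12-channel substitution labels, one per
#'   call/mutation.
#' @param group Parallel vector of group labels (a single label is recycled).
#' @param levels Optional explicit group ordering; groups listed here but
#'   absent from `group` get all-zero rows.
#' @return An object of class `spectrum_table`: list with `groups`,
#'   count matrices `counts12` and `counts6` (group x class), and integer
#'   percentage matrices `percent12`/`percent6` (rows with zero calls are
#'   `NA`). Percentages are rounded to the nearest integer percent for
#'   reporting.
#' @export
spectrum_table <- function(type, group = "all", levels = NULL) {
  group <- rep_len(as.character(group), length(type))
  if (is.null(levels)) levels <- unique(group)
  t12 <- sub_types()
  counts12 <- table(factor(group, levels = levels),
                    factor(type, levels = t12))
  counts12 <- matrix(as.integer(counts12), nrow = length(levels),
                     dimnames = list(levels, t12))
  counts6 <- t(rowsum(t(counts12), group = collapse_to_csub(t12)))
  counts6 <- counts6[, csub_types(), drop = FALSE]
  storage.mode(counts6) <- "integer"

  pct <- function(m) {
    tot <- rowSums(m)
    out <- round(100 * m / tot)
    out[tot == 0, ] <- NA_real_
    out
  }
  structure(
    list(groups = levels, counts12 = counts12, counts6 = counts6,
         percent12 = pct(counts12), percent6 = pct(counts6)),
    class = "spectrum_table"
  )
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat("spectrum_table over", length(x$groups), "group(s)\n")
  cat("c-substitution counts:\n")
  print(x$counts6)
  if (!is.null(x$normalized6)) {
    cat("normalized per-site rates (c-substitution):\n")
    print(signif(x$normalized6, 4))
  }
  invisible(x)
}

#' Normalize a spectrum by the base composition of its reference
#'
#' Divides each class count by the number of reference sites at which that
#' class can occur: C- or G-rooted c-substitution classes by `nC + nG`,
#' A/T-rooted classes by `nA + nT`, and each stranded 12-channel class by the
#' count of its own reference base on the coding strand. Rates are per site
#' (per clone set), so multiplying back by the site counts recovers the raw
#' counts exactly.
#'
#' @param tab A `spectrum_table`.
#' @param comp Base composition from [base_composition()].
#' @return `tab` with added matrices `normalized6` and `normalized12`.
#' @export
normalize_by_base_composition <- function(tab, comp) {
  stopifnot(inherits(tab, "spectrum_table"))
  stopifnot(all(BASES %in% names(comp)))
  cg <- comp[["C"]] + comp[["G"]]
  at <- comp[["A"]] + comp[["T"]]
  sites6 <- ifelse(substr(csub_types(), 1L, 1L) == "C", cg, at)
  sites12 <- comp[substr(sub_types(), 1L, 1L)]

  check_zero <- function(counts, sites, what) {
    bad <- sites == 0 & colSums(counts) > 0
    if (any(bad))
      stop("zero available sites for ", what, " class(es) with nonzero ",
           "counts: ", paste(colnames(counts)[bad], collapse = ", "))
  }
  check_zero(tab$counts6, sites6, "c-substitution")
  check_zero(tab$counts12, sites12, "stranded")

  tab$normalized6 <- sweep(tab$counts6, 2L, sites6, "/")
  tab$normalized12 <- sweep(tab$counts12, 2L, sites12, "/")
  tab$sites6 <- stats::setNames(sites6, csub_types())
  tab$sites12 <- stats::setNames(unname(sites12), sub_types())
  tab
}

#' Compare two mutation spectra
#'
#' Tests whether two groups' class counts come from the same distribution,
#' either over the full class vector or, with `focal`, on the 2x2 collapse
#' focal class versus all others. 2x2 chi-squared tests use the Yates
#' continuity correction; larger tables use the uncorrected statistic.
#' Fisher's exact test (2x2 only) is two-sided in the usual sense of summing
#' the probabilities of tables at most as probable as the observed one.
#'
#' @param a,b Named numeric count vectors over the same classes, or rows of
#'   `spectrum_table$counts6`/`counts12`.
#' @param method `"chi2"` or `"fisher"`.
#' @param focal Optional class name to collapse against the rest (required
#'   for `"fisher"` when more than two classes are given).
#' @return List with `statistic`, `df` (chi2 only), `p.value`, `method`, and
#'   the 2xK `table` tested.
#' @export
#' @examples
#' # spectrum shift between two clone sets, focal class vs rest:
#' compare_spectra(c(focal = 2, rest = 30), c(focal = 25, rest = 11))
compare_spectra <- function(a, b, method = c("chi2", "fisher"), focal = NULL) {
  method <- match.arg(method)
  if (any(a < 0) || any(b < 0)) stop("negative counts are not allowed")
  if (sum(a) + sum(b) == 0) stop("all-zero table")
  if (length(a) != length(b)) stop("count vectors differ in length")
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    stop("count vectors are over different classes")

  if (!is.null(focal)) {
    if (!focal %in% names(a)) stop("focal class not found: ", focal)
    a <- c(a[focal], rest = sum(a[names(a) != focal]))
    b <- c(b[focal], rest = sum(b[names(b) != focal]))
  }
  keep <- a + b > 0
  m <- rbind(A = a[keep], B = b[keep])

  if (method == "chi2") {
    correct <- all(dim(m) == 2L)
    ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value,
         method = if (correct) "chi2 (Yates-corrected)" else "chi2",
         table = m)
  } else {
    if (!all(dim(m) == 2L))
      stop("fisher comparison needs a 2x2 table; supply `focal` to collapse")
    ht <- stats::fisher.test(m)
    list(statistic = unname(ht$estimate), df = NA_integer_,
         p.value = ht$p.value, method = "fisher", table = m)
  }
}

#' Recurrently mutated positions, most frequent first
#'
#' @param position Integer vector of 1-based positions (one element per
#'   call).
#' @return Data frame `position`, `count`, sorted by descending count with
#'   ties broken by ascending position.
#' @export
#' @examples
#' hotspot_counts(c(1576, 1576, 1576, 1699))
hotspot_counts <- function(position) {
  if (length(position) == 0L)
    return(data.frame(position = integer(0), count = integer(0)))
  tab <- table(position)
  out <- data.frame(position = as.integer(names(tab)),
                    count = as.integer(tab))
  out <- out[order(-out$count, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
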