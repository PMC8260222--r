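#' Call substitutions between a reference CDS and a clone sequence
#'
#' Positions are 1-based from the reference 5' end. The comparison is
#' strictly positional (the desk-scale contract assumes indel-free Sanger
#' consensus sequences); length mismatch is fatal. Positions carrying an
#' ambiguity code in either sequence are skipped and tallied.
#'
#' @param reference,clone Character strings of equal length.
#' @param clone_id Label recorded in the output.
#' @return Data frame `clone`, `position`, `ref`, `alt` with one row per
#'   mismatch; the number of ambiguity-skipped positions is attribute
#'   `n_skipped`.
#' @export
#' @examples
#' call_substitutions("ACGT", "AAGT")  # position 2, C>A
call_substitutions <- function(reference, clone, clone_id = "clone") {
  stopifnot(is.character(reference), is.character(clone),
            length(reference) == 1L, length(clone) == 1L)
  r <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  c_ <- strsplit(toupper(clone), "", fixed = TRUE)[[1]]
  if (length(r) != length(c_))
    stop("clone length (", length(c_), ") differs from reference length (",
         length(r), "); indels are not handled")
  usable <- r %in% BASES & c_ %in% BASES
  n_skipped <- sum(!usable)
  if (n_skipped > 0)
    message("call_substitutions: skipped ", n_skipped,
            " position(s) with ambiguity codes")
  idx <- which(usable & r != c_)
  out <- data.frame(clone = rep(clone_id, length(idx)), position = idx,
                    ref = r[idx], alt = c_[idx], stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Mutation frequency from fluctuation cultures
#'
#' Each culture's frequency is resistant colonies per 1e9 viable plated
#' cells; the assay summary is the median across cultures (midpoint-averaged
#' for even counts), which is robust to Luria-Delbruck jackpot cultures.
#'
#' @param resistant Non-negative integer vector of resistant colony counts.
#' @param viable Positive vector of viable plated cells per culture.
#' @return Object of class `fluctuation_summary`: list with `per_culture`
#'   frequencies, `median_frequency`, `n_cultures`.
#' @export
#' @examples
#' mutation_frequency(c(0, 3, 10), rep(1e9, 3))$median_frequency  # 3
mutation_frequency <- function(resistant, viable) {
  stopifnot(length(resistant) == length(viable), length(resistant) >= 1L)
  if (any(viable <= 0)) stop("viable_plated must be positive")
  if (any(resistant < 0)) stop("resistant counts must be non-negative")
  if (any(resistant > viable))
    stop("resistant colonies exceed viable plated cells")
  freq <- resistant * 1e9 / viable
  structure(
    list(per_culture = freq, median_frequency = stats::median(freq),
         n_cultures = length(freq)),
    class = "fluctuation_summary"
  )
}

#' @export
print.fluctuation_summary <- function(x, ...) {
  cat("fluctuation assay:", x$n_cultures, "cultures, median",
      signif(x$median_frequency, 4), "resistant per 1e9 viable cells\n")
  invisible(x)
}

#' Simulate Luria-Delbruck fluctuation cultures
#'
#' Discrete-generation growth: in each generation every cell divides once;
#' each wild-type daughter independently becomes a resistant mutant with
#' probability `mu`, and existing mutants double deterministically.
#' Mutations arising early found large resistant clones, producing the
#' characteristic heavy-tailed ("jackpot") distribution of resistant counts
#' across parallel cultures. Back-mutation and mutant fitness costs are
#' ignored. Plating defaults to the whole final population; `plating_fraction`
#' subsamples binomially.
#'
#' @param n0 Initial wild-type cells per culture.
#' @param generations Number of doublings.
#' @param mu Per-division mutation probability, in `[0, 1]`.
#' @param n_cultures Number of parallel cultures.
#' @param seed Optional RNG seed for reproducibility.
#' @param plating_fraction Fraction of the final population plated.
#' @return Data frame `culture`, `resistant`, `viable`.
#' @export
ld_simulate <- function(n0 = 1000, generations = 20, mu, n_cultures = 30,
                        seed = NULL, plating_fraction = 1) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0 || mu > 1)
    stop("mu must be a single probability in [0, 1]")
  stopifnot(n0 >= 1, generations >= 1, n_cultures >= 1,
            plating_fraction > 0, plating_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  res <- via <- numeric(n_cultures)
  for (i in seq_len(n_cultures)) {
    wt <- n0
    mut <- 0
    for (g in seq_len(generations)) {
      daughters <- 2 * wt
      new_mut <- stats::rbinom(1L, daughters, mu)
      wt <- daughters - new_mut
      mut <- 2 * mut + new_mut
    }
    total <- wt + mut
    if (plating_fraction < 1) {
      mut <- stats::rbinom(1L, mut, plating_fraction)
      total <- round(total * plating_fraction)
    }
    res[i] <- mut
    via[i] <- total
  }
  data.frame(culture = seq_len(n_cultures), resistant = res, viable = via)
}

#' Substitution spectrum of sequenced resistant clones
#'
#' Tallies mutation calls into per-group 12-channel and 6-channel spectra
#' with integer-percent class shares, ready for [compare_spectra()].
#'
#' @param calls Data frame with columns `ref`, `alt` (from
#'   [call_substitutions()], possibly row-bound over clones).
#' @param group Per-call group labels (e.g. `"vector"` / `"treated"`); a
#'   single label is recycled.
#' @param levels Optional explicit group ordering (groups absent from
#'   `group` get all-zero rows).
#' @return A `spectrum_table` (see [spectrum_table()]).
#' @export
clone_spectrum <- function(calls, group = "all", levels = NULL) {
  type <- classify_substitution(calls$ref, calls$alt)$type
  spectrum_table(type, group = group, levels = levels)
}
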