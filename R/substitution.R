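#' @importFrom stats complete.cases
NULL

BASES <- c("A", "C", "G", "T")
BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
PURINES <- c("A", "G")

#' The twelve substitution types
#'
#' All ordered pairs of distinct bases, written `"ref>alt"`. This is the
#' 12-channel alphabet in which single-nucleotide substitutions are classified
#' before any complementary-strand collapse.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' sub_types()
sub_types <- function() {
  unlist(lapply(BASES, function(r) paste0(r, ">", setdiff(BASES, r))),
         use.names = FALSE)
}

#' The six complementary substitution (c-substitution) classes
#'
#' Each substitution is pooled with its reverse-complement partner (a C>A on
#' one strand is a G>T on the other), giving six classes. Labels put the
#' C- or A-rooted member first, e.g. `"C>A/G>T"`.
#'
#' @return Character vector of length 6.
#' @export
csub_types <- function() {
  c("C>A/G>T", "C>G/G>C", "C>T/G>A", "A>C/T>G", "A>G/T>C", "A>T/T>A")
}

#' Complement of a substitution type
#'
#' @param type Character vector of `"ref>alt"` substitution labels.
#' @return The reverse-complement substitution of each element.
#' @export
#' @examples
#' complement_substitution("C>A")  # "G>T"
complement_substitution <- function(type) {
  parts <- split_type(type)
  paste0(BASE_COMPLEMENT[parts$ref], ">", BASE_COMPLEMENT[parts$alt])
}

split_type <- function(type) {
  if (!all(grepl("^[ACGT]>[ACGT]$", type)))
    stop("invalid substitution label(s): ",
         paste(unique(type[!grepl("^[ACGT]>[ACGT]$", type)]), collapse = ", "))
  list(ref = substr(type, 1L, 1L), alt = substr(type, 3L, 3L))
}

#' Classify a base change as one of the 12 substitution types
#'
#' @param ref,alt Character vectors of single bases (A/C/G/T). Recycled to a
#'   common length.
#' @return A data frame with columns `ref`, `alt`, `type` (one of
#'   [sub_types()]) and `class` (`"transition"` if ref and alt are of the same
#'   purine/pyrimidine class, `"transversion"` otherwise).
#' @export
#' @examples
#' classify_substitution("C", "T")  # transition
#' classify_substitution("C", "A")  # transversion
classify_substitution <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  bad <- !(ref %in% BASES) | !(alt %in% BASES)
  if (any(bad))
    stop("invalid base(s): ",
         paste(unique(c(ref[bad], alt[bad])), collapse = ", "))
  if (any(ref == alt))
    stop("degenerate record(s): ref equals alt (",
         paste(unique(ref[ref == alt]), collapse = ", "), ")")
  data.frame(
    ref = ref, alt = alt,
    type = paste0(ref, ">", alt),
    class = ifelse((ref %in% PURINES) == (alt %in% PURINES),
                   "transition", "transversion"),
    stringsAsFactors = FALSE
  )
}

#' Collapse a substitution type to its c-substitution class
#'
#' A substitution and its reverse complement are indistinguishable without
#' strand information, so the 12 types map 2-to-1 onto 6 complementary
#' classes.
#'
#' @param type Character vector of `"ref>alt"` labels.
#' @return Character vector of c-substitution labels (see [csub_types()]).
#' @export
#' @examples
#' collapse_to_csub(c("C>A", "G>T"))  # both "C>A/G>T"
collapse_to_csub <- function(type) {
  parts <- split_type(type)
  canon <- ifelse(parts$ref %in% c("C", "A"), type, complement_substitution(type))
  paste0(canon, "/", complement_substitution(canon))
}

#' Resolve substitutions onto the coding strand of their gene
#'
#' Mutation catalogs report ref/alt on the genomic plus strand. For genes
#' transcribed from the minus strand, a plus-strand C>A is a G>T on the
#' gene's coding (untranscribed) strand; a C>A occurring on the transcribed
#' template strand likewise reads as G>T at the gene level. Strand-asymmetry
#' analyses therefore need every record re-expressed in the coding frame.
#'
#' @param records Data frame with at least columns `ref`, `alt` and
#'   `gene_strand` (`"+"`, `"-"`, or `NA` for unknown).
#' @return `records` with an added `coding_type` column (`NA` where the
#'   strand is unknown). The number of strand-unknown records is attached as
#'   attribute `"n_excluded"`.
#' @export
strand_resolve <- function(records) {
  stopifnot(all(c("ref", "alt", "gene_strand") %in% names(records)))
  strand <- as.character(records$gene_strand)
  strand[!strand %in% c("+", "-")] <- NA_character_
  type <- paste0(toupper(records$ref), ">", toupper(records$alt))
  coding <- ifelse(strand == "+", type, complement_substitution(type))
  coding[is.na(strand)] <- NA_character_
  records$coding_type <- coding
  attr(records, "n_excluded") <- sum(is.na(strand))
  records
}

is_valid_record <- function(records) {
  ref <- toupper(as.character(records$ref))
  alt <- toupper(as.character(records$alt))
  pos <- suppressWarnings(as.numeric(records$position))
  ref %in% BASES & alt %in% BASES & ref != alt &
    !is.na(pos) & pos >= 1 & pos == floor(pos) &
    !is.na(records$sample) & !is.na(records$gene)
}

#' Per-sample mutation profiles
#'
#' Tallies each sample's substitutions into the 12-channel genomic-strand
#' spectrum, the 6-channel c-substitution spectrum, and a 12-channel
#' coding-strand ("stranded") spectrum restricted to records whose gene
#' strand is known.
#'
#' @param records Data frame of mutation records with columns `sample`,
#'   `gene`, `position`, `ref`, `alt`, `gene_strand`.
#' @param roster Optional character vector of sample ids. Samples in the
#'   roster but absent from `records` get all-zero profiles; without a
#'   roster only observed samples appear.
#' @return An object of class `mutation_profiles`: a list with matrices
#'   `counts12` (samples x 12 genomic-strand types), `counts6` (samples x 6
#'   c-substitution classes), `stranded` (samples x 12 coding-strand types),
#'   vector `total`, and tallies `n_malformed` (records dropped for failing
#'   validation) and `n_excluded` (valid records without strand, absent from
#'   `stranded` only).
#' @export
count_profiles <- function(records, roster = NULL) {
  need <- c("sample", "gene", "position", "ref", "alt", "gene_strand")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))

  ok <- is_valid_record(records)
  n_malformed <- sum(!ok)
  if (n_malformed > 0)
    message("count_profiles: skipped ", n_malformed, " malformed record(s)")
  records <- records[ok, , drop = FALSE]

  samples <- sort(unique(c(as.character(records$sample), roster)))
  t12 <- sub_types()
  c6 <- csub_types()

  counts12 <- matrix(0L, length(samples), 12L,
                     dimnames = list(samples, t12))
  stranded <- matrix(0L, length(samples), 12L,
                     dimnames = list(samples, t12))

  if (nrow(records)) {
    type <- paste0(toupper(records$ref), ">", toupper(records$alt))
    tab <- table(factor(as.character(records$sample), levels = samples),
                 factor(type, levels = t12))
    counts12[] <- as.integer(tab)

    rec_s <- strand_resolve(records)
    known <- !is.na(rec_s$coding_type)
    tab_s <- table(factor(as.character(rec_s$sample[known]), levels = samples),
                   factor(rec_s$coding_type[known], levels = t12))
    stranded[] <- as.integer(tab_s)
    n_excluded <- sum(!known)
  } else {
    n_excluded <- 0L
  }

  map6 <- collapse_to_csub(t12)
  counts6 <- t(rowsum(t(counts12), group = map6))[, c6, drop = FALSE]
  storage.mode(counts6) <- "integer"

  structure(
    list(counts12 = counts12, counts6 = counts6, stranded = stranded,
         total = rowSums(counts12),
         n_malformed = n_malformed, n_excluded = n_excluded),
    class = "mutation_profiles"
  )
}

#' @export
print.mutation_profiles <- function(x, ...) {
  cat("mutation_profiles:", nrow(x$counts12), "samples,",
      sum(x$total), "substitutions\n")
  cat("c-substitution totals:\n")
  print(colSums(x$counts6))
  if (x$n_malformed) cat("malformed records skipped:", x$n_malformed, "\n")
  if (x$n_excluded) cat("strand-unknown records (excluded from stranded counts):",
                        x$n_excluded, "\n")
  invisible(x)
}

#' Cohort-level c-substitution frequencies
#'
#' @param profiles A `mutation_profiles` object.
#' @return Named numeric vector over the six c-substitution classes, summing
#'   to 1.
#' @export
cohort_csub_frequencies <- function(profiles) {
  stopifnot(inherits(profiles, "mutation_profiles"))
  tot <- colSums(profiles$counts6)
  if (sum(tot) == 0)
    stop("cohort contains no mutations; frequencies undefined")
  tot / sum(tot)
}

#' Selector used by screens: per-sample burden of a mutation class
#'
#' @param profiles A `mutation_profiles` object.
#' @param type `"total"` for all substitutions, a c-substitution label
#'   (e.g. `"C>A/G>T"`) for collapsed counts, or a single substitution label
#'   (e.g. `"C>A"`) for coding-strand-resolved counts.
#' @return Named integer vector of per-sample counts.
#' @export
mutation_burden <- function(profiles, type = "C>A/G>T") {
  stopifnot(inherits(profiles, "mutation_profiles"))
  if (identical(type, "total")) return(profiles$total)
  if (type %in% csub_types()) return(profiles$counts6[, type])
  if (type %in% sub_types()) return(profiles$stranded[, type])
  stop("unknown mutation class selector: ", type)
}
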