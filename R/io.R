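# All files are UTF-8 TSV with "NA" as the missing sentinel; genomic-style
# positions are 1-based inclusive throughout.

#' Read a somatic mutation catalog (MAF-like TSV)
#'
#' Expected header: `sample gene position ref alt gene_strand`, ref/alt on
#' the genomic plus strand, `NA` for unknown strand. Rows failing validation
#' (ref = alt, non-ACGT bases, bad positions) are skipped with a counted
#' warning, never silently.
#'
#' @param path Path to a TSV file.
#' @return Data frame of mutation records; skipped-row count as attribute
#'   `n_skipped`.
#' @export
read_mutation_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("ref", "alt")),
                          na.strings = "NA", data.table = FALSE,
                          showProgress = FALSE)
  need <- c("sample", "gene", "position", "ref", "alt", "gene_strand")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("mutation TSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  dt <- dt[need]
  dt$gene_strand <- as.character(dt$gene_strand)
  dt$gene_strand[!dt$gene_strand %in% c("+", "-")] <- NA_character_
  ok <- is_valid_record(dt)
  if (any(!ok))
    warning("read_mutation_tsv: skipped ", sum(!ok), " malformed row(s)")
  out <- dt[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' @rdname read_mutation_tsv
#' @param records Mutation record data frame.
#' @param path Output path.
#' @export
write_mutation_tsv <- function(records, path) {
  data.table::fwrite(records, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a gene x sample expression matrix TSV
#'
#' First column gene ids, header row of sample ids. Duplicate gene or
#' sample ids are fatal.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          data.table = FALSE, showProgress = FALSE)
  if (nrow(dt) == 0L || ncol(dt) < 2L) stop("empty expression file: ", path)
  genes <- as.character(dt[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  samples <- names(dt)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample column(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- genes
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param mat Expression matrix.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a clinical endpoints TSV
#'
#' Header `sample os_months os_event dfs_months dfs_event`; `NA` is allowed
#' per endpoint. Duplicate sample ids are fatal.
#'
#' @param path Path to a TSV file.
#' @return Data frame of clinical records.
#' @export
read_clinical_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          data.table = FALSE, showProgress = FALSE)
  need <- c("sample", "os_months", "os_event", "dfs_months", "dfs_event")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("clinical TSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(dt) == 0L) stop("empty clinical file: ", path)
  if (anyDuplicated(dt$sample))
    stop("duplicate sample id(s): ",
         paste(unique(dt$sample[duplicated(dt$sample)]), collapse = ", "))
  dt[need]
}

#' @rdname read_clinical_tsv
#' @param clinical Clinical data frame.
#' @export
write_clinical_tsv <- function(clinical, path) {
  data.table::fwrite(clinical, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read / write FASTA
#'
#' Standard FASTA with wrapped sequence lines. When a combined file holds a
#' reference plus clones, the first record is taken as the reference by
#' downstream callers.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id(s) in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write a screen result table
#'
#' @param result A `screen_result`.
#' @param path Output path; `.json` extension (or `format = "json"`) writes
#'   JSON, otherwise TSV.
#' @param format `"tsv"` or `"json"`.
#' @export
write_screen_result <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (grepl("\\.json$", path)) format <- "json"
  if (format == "json") {
    jsonlite::write_json(list(screen = attr(result, "screen"),
                              table = as.data.frame(result)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    data.table::fwrite(as.data.frame(result), path, sep = "\t", na = "NA",
                       quote = FALSE)
  }
  invisible(path)
}

#' Volcano-plot data from a screen result
#'
#' @param result A `screen_result`.
#' @param log2_statistic Log2-transform the statistic (sensible for FC
#'   screens; leave `FALSE` for correlation screens).
#' @return Data frame `gene`, `x` (statistic, optionally log2),
#'   `neg_log10_p`.
#' @export
volcano_data <- function(result, log2_statistic = FALSE) {
  x <- result$statistic
  if (log2_statistic) x <- log2(x)
  data.frame(gene = result$gene, x = x,
             neg_log10_p = -log10(pmax(result$p, .Machine$double.xmin)),
             stringsAsFactors = FALSE)
}

#' Write a candidate gene list, one gene per line
#'
#' @param set A `candidate_set` (or character vector of genes).
#' @param path Output path.
#' @export
write_candidates <- function(set, path) {
  genes <- if (inherits(set, "candidate_set")) set$genes else as.character(set)
  writeLines(genes, path)
  invisible(path)
}

#' Write a KM curve table
#'
#' Columns `time at_risk events S lowerCI upperCI`.
#'
#' @param curve A `km_curve`.
#' @param path Output path.
#' @export
write_km_tsv <- function(curve, path) {
  out <- data.frame(time = curve$time, at_risk = curve$n.risk,
                    events = curve$n.event, S = curve$surv,
                    lowerCI = curve$lower, upperCI = curve$upper)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write a spectrum table TSV
#'
#' One row per c-substitution class, one count column per group, plus
#' integer percentages and (if present) normalized per-site rates.
#'
#' @param tab A `spectrum_table`.
#' @param path Output path.
#' @export
write_spectrum_tsv <- function(tab, path) {
  out <- data.frame(class = csub_types(), t(tab$counts6),
                    check.names = FALSE)
  names(out)[-1] <- paste0("count_", tab$groups)
  pct <- t(tab$percent6)
  colnames(pct) <- paste0("percent_", tab$groups)
  out <- cbind(out, pct)
  if (!is.null(tab$normalized6)) {
    nrm <- t(tab$normalized6)
    colnames(nrm) <- paste0("rate_", tab$groups)
    out <- cbind(out, nrm)
  }
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records package version, parameters, and md5 checksums of the input
#' files alongside the outputs, so a run can be reproduced exactly.
#'
#' @param path Output JSON path.
#' @param params Named list of run parameters.
#' @param inputs Character vector of input file paths to checksum.
#' @export
write_manifest <- function(path, params = list(), inputs = character(0)) {
  existing <- inputs[file.exists(inputs)]
  manifest <- list(
    package = "esmscreen",
    version = as.character(utils::packageVersion("esmscreen")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    input_md5 = as.list(tools::md5sum(existing))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
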