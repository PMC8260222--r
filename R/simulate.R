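#' Default 12-channel substitution type mix for synthetic cohorts
#'
#' A C>T/G>A-dominant background with elevated C>A/G>T, A>T/T>A and A>C/T>G
#' shares, the pattern characteristic of clear-cell kidney tumors relative
#' to other major cancers. Class mass is split evenly between the two
#' members of each complementary pair.
#'
#' @return Named probability vector over [sub_types()], summing to 1.
#' @export
default_type_mix <- function() {
  mix6 <- c("C>T/G>A" = 0.40, "C>A/G>T" = 0.25, "A>G/T>C" = 0.15,
            "A>T/T>A" = 0.08, "A>C/T>G" = 0.07, "C>G/G>C" = 0.05)
  t12 <- sub_types()
  out <- mix6[collapse_to_csub(t12)] / 2
  stats::setNames(as.numeric(out), t12)
}

#' Specification of a synthetic tumor cohort
#'
#' Describes the cohort the generator emulates: a clear-cell kidney cancer
#' study of ~532 patients carrying ~30,000 somatic substitutions in total
#' (about 57 per patient), a C>T/G>A-dominant substitution mix, one planted
#' gene whose expression tracks a chosen mutation class, and a VHL-like
#' frequently hit "status" gene used by the mutation-status screen.
#'
#' Per-patient burdens are negative binomial; the planted gene's expression
#' is `baseline_expr * exp(beta * z + N(0, noise_sd))` where `z` is the
#' patient's standardized burden of `link_class`. With `noise_sd = 1`,
#' `beta = 0.6` targets a true Spearman correlation of about 0.5
#' (Gaussian-copula back-calculation: rho = beta / sqrt(beta^2 + noise_sd^2)).
#' Set `link_class` to a stranded class such as `"C>A"` to emulate a
#' coding-strand-only mutator.
#'
#' @param n_patients,n_genes Cohort dimensions.
#' @param mean_burden,size Negative-binomial mean and dispersion of
#'   per-patient substitution counts.
#' @param type_mix Probability vector over the 12 coding-strand substitution
#'   types.
#' @param planted_gene,status_gene Gene ids of the planted expression-linked
#'   gene and the frequently mutated status gene.
#' @param status_weight Share of each mutation's gene assignment given to
#'   the status gene (remaining mass is uniform over all genes); 0.05 gives
#'   a carrier fraction near 50%, like VHL in this tumor type.
#' @param beta,noise_sd Planted effect size and log-scale noise.
#' @param link_class Mutation class whose burden drives the planted gene.
#' @param baseline_expr Baseline expression level (FPKM-like units).
#' @param cds_length Positions are drawn uniformly on `1..cds_length`.
#' @param housekeeping Housekeeping gene id added to the expression matrix.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 532L, n_genes = 200L, mean_burden = 57,
                        size = 2, type_mix = default_type_mix(),
                        planted_gene = "G001", status_gene = "G002",
                        status_weight = 0.05, beta = 0.6, noise_sd = 1,
                        link_class = "C>A/G>T", baseline_expr = 100,
                        cds_length = 1500L, housekeeping = "TBP") {
  fail <- function(field) stop("invalid cohort_spec field: ", field)
  if (!is.numeric(n_patients) || n_patients < 8) fail("n_patients")
  if (!is.numeric(n_genes) || n_genes < 3) fail("n_genes")
  if (!is.numeric(mean_burden) || mean_burden <= 0) fail("mean_burden")
  if (!is.numeric(size) || size <= 0) fail("size")
  if (length(type_mix) != 12L || any(type_mix < 0) ||
      abs(sum(type_mix) - 1) > 1e-8) fail("type_mix")
  if (!is.numeric(beta) || beta < 0) fail("beta")
  if (!is.numeric(noise_sd) || noise_sd < 0) fail("noise_sd")
  if (!is.numeric(status_weight) || status_weight < 0 || status_weight >= 1)
    fail("status_weight")
  if (!(link_class %in% c("total", csub_types(), sub_types())))
    fail("link_class")
  structure(
    list(n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
         mean_burden = mean_burden, size = size,
         type_mix = stats::setNames(as.numeric(type_mix), sub_types()),
         planted_gene = planted_gene, status_gene = status_gene,
         status_weight = status_weight, beta = beta, noise_sd = noise_sd,
         link_class = link_class, baseline_expr = baseline_expr,
         cds_length = as.integer(cds_length), housekeeping = housekeeping),
    class = "cohort_spec"
  )
}

#' Simulate a tumor cohort: mutations, expression, clinical tables
#'
#' Draws per-patient substitution burdens from a negative binomial,
#' assigns each mutation a coding-strand type from the spec's mix, a gene
#' (the status gene with elevated weight, otherwise uniform), and a uniform
#' position; records ref/alt on the genomic plus strand given each gene's
#' fixed orientation. Expression is independent log-normal for all genes
#' except the planted gene, which is conditioned on the patient's
#' standardized `link_class` burden; clinical endpoints come from
#' [simulate_survival()] driven by the planted gene.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional RNG seed; fixed seeds give identical cohorts.
#' @return List with `mutations` (plus-strand record table), `expression`
#'   (genes+housekeeping x patients matrix), `clinical` (per-patient
#'   survival table), `gene_strand` (named vector), and `truth`
#'   (planted/status gene ids and the per-patient link burden).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)

  patients <- sprintf("S%03d", seq_len(spec$n_patients))
  genes <- sprintf("G%03d", seq_len(spec$n_genes))
  if (!all(c(spec$planted_gene, spec$status_gene) %in% genes))
    stop("invalid cohort_spec field: planted_gene/status_gene")
  gene_strand <- stats::setNames(
    sample(c("+", "-"), spec$n_genes, replace = TRUE), genes)

  burden <- stats::rnbinom(spec$n_patients, mu = spec$mean_burden,
                           size = spec$size)
  n_mut <- sum(burden)

  coding_type <- sample(sub_types(), n_mut, replace = TRUE,
                        prob = spec$type_mix)
  gene_prob <- rep((1 - spec$status_weight) / spec$n_genes, spec$n_genes)
  names(gene_prob) <- genes
  gene_prob[spec$status_gene] <- gene_prob[spec$status_gene] + spec$status_weight
  mut_gene <- sample(genes, n_mut, replace = TRUE, prob = gene_prob)
  mut_sample <- rep(patients, times = burden)
  strand <- gene_strand[mut_gene]
  plus_type <- ifelse(strand == "+", coding_type,
                      complement_substitution(coding_type))
  mutations <- data.frame(
    sample = mut_sample, gene = mut_gene,
    position = sample.int(spec$cds_length, n_mut, replace = TRUE),
    ref = substr(plus_type, 1L, 1L), alt = substr(plus_type, 3L, 3L),
    gene_strand = unname(strand), stringsAsFactors = FALSE
  )

  # link burden computed in the coding frame, per patient
  link_count <- link_burden(mut_sample, coding_type, patients, spec$link_class)
  z <- if (stats::sd(link_count) > 0) as.numeric(scale(link_count))
       else rep(0, spec$n_patients)

  expr <- matrix(
    stats::rlnorm(spec$n_genes * spec$n_patients,
                  meanlog = log(spec$baseline_expr), sdlog = 1),
    nrow = spec$n_genes, dimnames = list(genes, patients))
  expr[spec$planted_gene, ] <- spec$baseline_expr *
    exp(spec$beta * z + stats::rnorm(spec$n_patients, 0, spec$noise_sd))
  hk <- stats::rlnorm(spec$n_patients, meanlog = log(30), sdlog = 0.3)
  expr <- rbind(expr, matrix(hk, nrow = 1L,
                             dimnames = list(spec$housekeeping, patients)))

  planted_norm <- expr[spec$planted_gene, ] / hk
  clinical <- simulate_survival(planted_norm, hazard_ratio = 2.5,
                                baseline_rate = 0.01, censor_rate = 0.008)

  list(mutations = mutations, expression = expr, clinical = clinical,
       gene_strand = gene_strand,
       truth = list(planted_gene = spec$planted_gene,
                    status_gene = spec$status_gene,
                    link_class = spec$link_class,
                    link_burden = stats::setNames(link_count, patients)))
}

link_burden <- function(mut_sample, coding_type, patients, link_class) {
  if (identical(link_class, "total")) {
    keep <- rep(TRUE, length(coding_type))
  } else if (link_class %in% csub_types()) {
    keep <- collapse_to_csub(coding_type) == link_class
  } else {
    keep <- coding_type == link_class
  }
  as.integer(table(factor(mut_sample[keep], levels = patients)))
}

#' Simulate survival endpoints driven by an expression split
#'
#' Exponential event times with rate `baseline_rate *
#' hazard_ratio^(high indicator)` where the indicator is the median split of
#' `values`; censoring is independent exponential with rate `censor_rate`
#' (0 = no censoring). Both an overall-survival and a faster disease-free
#' endpoint are generated.
#'
#' @param values Named expression vector (sample id -> value).
#' @param hazard_ratio Hazard ratio of the high- versus low-expression arm.
#' @param baseline_rate Events per month in the low arm.
#' @param censor_rate Censoring rate per month.
#' @param seed Optional RNG seed.
#' @return Data frame `sample`, `os_months`, `os_event`, `dfs_months`,
#'   `dfs_event`.
#' @export
simulate_survival <- function(values, hazard_ratio = 2.5,
                              baseline_rate = 0.01, censor_rate = 0.008,
                              seed = NULL) {
  stopifnot(hazard_ratio > 0, baseline_rate > 0, censor_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  high <- split_median(values) == "high"
  draw <- function(rate_scale) {
    rate <- baseline_rate * rate_scale * hazard_ratio^high
    t_event <- stats::rexp(n, rate)
    t_cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
    list(time = pmin(t_event, t_cens),
         event = as.integer(t_event <= t_cens))
  }
  os <- draw(1)
  dfs <- draw(1.5)
  data.frame(sample = if (!is.null(names(values))) names(values)
                      else sprintf("S%03d", seq_len(n)),
             os_months = os$time, os_event = os$event,
             dfs_months = dfs$time, dfs_event = dfs$event,
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic resistant-clone sequencing experiment
#'
#' Emulates Sanger sequencing of a 627-bp rpoB amplicon from
#' rifampicin-resistant colonies in two arms (control vs treated), each with
#' its own substitution-type mix and optional positional hotspots.
#'
#' @param ref_length Reference CDS length.
#' @param n_control,n_treated Clones per arm.
#' @param control_mix,treated_mix Probability vectors over [sub_types()]
#'   giving each arm's substitution mix (in reference coordinates).
#' @param hotspots Named list per arm (`control`, `treated`) of data frames
#'   `position`, `enrichment` (>= 1); mutated positions are drawn with these
#'   multiplicative weights among positions matching the drawn type's
#'   reference base.
#' @param muts_per_clone Poisson mean of substitutions per clone.
#' @param reference Optional fixed reference sequence (ACGT string); when
#'   given it overrides `ref_length`, otherwise a random reference is drawn
#'   per simulation.
#' @return Object of class `clone_spec`.
#' @export
clone_spec <- function(ref_length = 627L, n_control = 25L, n_treated = 25L,
                       control_mix = NULL, treated_mix = NULL,
                       hotspots = list(), muts_per_clone = 1.4,
                       reference = NULL) {
  if (!is.null(reference)) {
    stopifnot(is.character(reference), length(reference) == 1L)
    if (!grepl("^[ACGTacgt]+$", reference))
      stop("reference must be an ACGT string")
    ref_length <- nchar(reference)
  }
  mix_for <- function(csub_mass, mix) {
    if (!is.null(mix)) {
      stopifnot(length(mix) == 12L, abs(sum(mix) - 1) < 1e-8)
      return(stats::setNames(as.numeric(mix), sub_types()))
    }
    out <- csub_mass[collapse_to_csub(sub_types())] / 2
    stats::setNames(as.numeric(out), sub_types())
  }
  # control: transition-dominated; treated: C>A-shifted
  control_mix <- mix_for(c("C>T/G>A" = 0.80, "C>A/G>T" = 0.06,
                           "A>G/T>C" = 0.08, "A>T/T>A" = 0.03,
                           "A>C/T>G" = 0.02, "C>G/G>C" = 0.01), control_mix)
  treated_mix <- mix_for(c("C>T/G>A" = 0.20, "C>A/G>T" = 0.70,
                           "A>G/T>C" = 0.05, "A>T/T>A" = 0.02,
                           "A>C/T>G" = 0.02, "C>G/G>C" = 0.01), treated_mix)
  for (arm in names(hotspots)) {
    h <- hotspots[[arm]]
    stopifnot(all(c("position", "enrichment") %in% names(h)))
    if (any(h$position < 1 | h$position > ref_length))
      stop("hotspot position outside the reference")
    if (any(h$enrichment < 1)) stop("hotspot enrichment must be >= 1")
  }
  structure(
    list(ref_length = as.integer(ref_length),
         n_control = as.integer(n_control), n_treated = as.integer(n_treated),
         control_mix = control_mix, treated_mix = treated_mix,
         hotspots = hotspots, muts_per_clone = muts_per_clone,
         reference = if (is.null(reference)) NULL else toupper(reference)),
    class = "clone_spec"
  )
}

#' Simulate a reference CDS and mutated resistant clones
#'
#' Generates a random ACGT reference and, per clone, a Poisson number of
#' substitutions: a position is drawn (hotspot positions with elevated
#' weight), then an alt base according to the arm's type mix conditional on
#' the reference base at that position.
#'
#' @param spec A [clone_spec()].
#' @param seed Optional RNG seed.
#' @return List with `reference` (character), `clones` (named character
#'   vector, names like `ctrl01`/`trt01`), `arm` (named vector of arm
#'   labels), and `truth` (data frame of planted calls: `clone`, `position`,
#'   `ref`, `alt`, `arm`).
#' @export
simulate_clones <- function(spec = clone_spec(), seed = NULL) {
  stopifnot(inherits(spec, "clone_spec"))
  if (!is.null(seed)) set.seed(seed)
  reference <- if (is.null(spec$reference))
    paste(sample(BASES, spec$ref_length, replace = TRUE), collapse = "")
  else spec$reference
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1]]

  one_arm <- function(n, prefix, mix, hotspot) {
    weights <- rep(1, spec$ref_length)
    if (!is.null(hotspot))
      weights[hotspot$position] <- hotspot$enrichment
    ids <- sprintf("%s%02d", prefix, seq_len(n))
    truth <- vector("list", n)
    clones <- character(n)
    for (i in seq_len(n)) {
      k <- stats::rpois(1L, spec$muts_per_clone)
      if (k > spec$ref_length)
        stop("more planted mutations than reference positions")
      chars <- ref_chars
      if (k > 0) {
        # draw the substitution type from the arm mix, then a matching-ref
        # position (hotspot weights apply among matching sites), so the
        # realized spectrum follows the mix
        type <- sample(sub_types(), k, replace = TRUE, prob = mix)
        pos <- integer(k)
        used <- logical(spec$ref_length)
        for (j in seq_len(k)) {
          ref_b <- substr(type[j], 1L, 1L)
          avail <- which(ref_chars == ref_b & !used)
          if (!length(avail))
            stop("more planted mutations than reference positions for base ",
                 ref_b)
          pos[j] <- if (length(avail) == 1L) avail else
            sample(avail, 1L, prob = weights[avail])
          used[pos[j]] <- TRUE
        }
        alt <- substr(type, 3L, 3L)
        chars[pos] <- alt
        ord <- order(pos)
        truth[[i]] <- data.frame(clone = ids[i], position = pos[ord],
                                 ref = ref_chars[pos][ord], alt = alt[ord],
                                 stringsAsFactors = FALSE)
      }
      clones[i] <- paste(chars, collapse = "")
    }
    list(ids = ids, clones = stats::setNames(clones, ids),
         truth = do.call(rbind, truth))
  }

  ctrl <- one_arm(spec$n_control, "ctrl", spec$control_mix,
                  spec$hotspots$control)
  trt <- one_arm(spec$n_treated, "trt", spec$treated_mix,
                 spec$hotspots$treated)
  truth <- rbind(
    if (!is.null(ctrl$truth)) cbind(ctrl$truth, arm = "control"),
    if (!is.null(trt$truth)) cbind(trt$truth, arm = "treated"))
  if (is.null(truth))
    truth <- data.frame(clone = character(0), position = integer(0),
                        ref = character(0), alt = character(0),
                        arm = character(0), stringsAsFactors = FALSE)
  truth <- truth[order(truth$clone, truth$position), , drop = FALSE]
  rownames(truth) <- NULL
  arm <- stats::setNames(c(rep("control", spec$n_control),
                           rep("treated", spec$n_treated)),
                         c(ctrl$ids, trt$ids))
  list(reference = reference, clones = c(ctrl$clones, trt$clones),
       arm = arm, truth = truth)
}
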