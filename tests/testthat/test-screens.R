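# shared small fixture: 20-sample cohort with named samples
make_norm <- function(n_genes = 10, n_samples = 20, seed = 5) {
  set.seed(seed)
  m <- matrix(rlnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m <- rbind(m, TBP = rlnorm(n_samples, log(30), 0.3))
  suppressMessages(tbp_normalize(m))
}

make_profiles <- function(counts, samples = names(counts)) {
  recs <- data.frame(sample = rep(samples, counts), gene = "g",
                     position = 1, ref = "C", alt = "A", gene_strand = "+")
  count_profiles(recs, roster = samples)
}

test_that("housekeeping normalization divides columns and drops zeros", {
  m <- matrix(c(2, 1, 4, 2), 2, 2,
              dimnames = list(c("g1", "TBP"), c("s1", "s2")))
  out <- tbp_normalize(m)
  expect_equal(unname(out["g1", ]), c(2, 2))
  expect_equal(unname(out["TBP", ]), c(1, 1))
  expect_error(tbp_normalize(m, housekeeping = "ACTB"), "not found")

  m2 <- cbind(m, s3 = c(5, 0))
  expect_message(out2 <- tbp_normalize(m2), "dropping 1")
  expect_equal(colnames(out2), c("s1", "s2"))
  expect_equal(attr(out2, "dropped"), "s3")
  expect_equal(unname(out2["g1", ]), c(2, 2))
})

test_that("spearman screen recovers perfect monotone relations", {
  samples <- paste0("s", 1:4)
  m <- matrix(c(1, 2, 3, 4,
                4, 3, 2, 1,
                rep(1, 4)), 3, 4, byrow = TRUE,
              dimnames = list(c("up", "down", "TBP"), samples))
  norm <- tbp_normalize(m)
  prof <- make_profiles(setNames(c(10, 20, 30, 40), samples))
  res <- spearman_screen(norm, prof)
  expect_equal(res$statistic[res$gene == "up"], 1)
  expect_equal(res$statistic[res$gene == "down"], -1)
  expect_equal(res$rank[res$gene == "up"], 1L)
})

test_that("spearman screen equals the brute-force oracle, ties included", {
  norm <- make_norm(50, 20)
  set.seed(6)
  prof <- make_profiles(setNames(rpois(20, 3), colnames(norm)))
  res <- spearman_screen(norm, prof)
  y <- mutation_burden(prof)[colnames(norm)]
  for (g in sample(res$gene, 10)) {
    o <- oracle_spearman(norm[g, ], y)
    expect_equal(res$statistic[res$gene == g], o$r, tolerance = 1e-12)
    expect_equal(res$p[res$gene == g], o$p, tolerance = 1e-12)
  }
  expect_error(suppressWarnings(spearman_screen(norm[, 1:3], prof)),
               "at least 4")
})

test_that("burden grouping is deterministic with stated tie-breaks", {
  prof <- make_profiles(c(s1 = 5, s2 = 1, s3 = 9, s4 = 3, s5 = 7, s6 = 2))
  g <- group_by_burden(prof, g = 3)
  expect_equal(names(g)[g == 1], c("s2", "s6"))
  expect_equal(names(g)[g == 2], c("s1", "s4"))
  expect_equal(names(g)[g == 3], c("s3", "s5"))

  # all-equal counts: split purely by sample id, low group gets the extra
  prof_eq <- make_profiles(setNames(rep(2, 5), paste0("s", 1:5)))
  g2 <- group_by_burden(prof_eq, g = 2)
  expect_equal(names(g2)[g2 == 1], c("s1", "s2", "s3"))
  expect_equal(names(g2)[g2 == 2], c("s4", "s5"))

  # sizes differ by at most one for a large odd cohort
  prof_big <- make_profiles(setNames(rpois(533, 5), sprintf("t%03d", 1:533)))
  for (gg in 2:5) {
    sizes <- table(group_by_burden(prof_big, g = gg))
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_error(group_by_burden(prof, g = 4), "at least 8")
})

test_that("t-test screen: FC and p match the textbook pooled-variance oracle", {
  samples <- paste0("s", 1:4)
  m <- rbind(gene = c(4, 6, 1, 3), TBP = rep(1, 4))
  colnames(m) <- samples
  norm <- tbp_normalize(m)
  assignment <- factor(c(2, 2, 1, 1), levels = 1:2)
  names(assignment) <- samples
  res <- ttest_screen(norm, assignment)
  row <- res[res$gene == "gene", ]
  expect_equal(row$statistic, 2.5)  # FC = mean(4,6)/mean(1,3)
  o <- oracle_ttest(c(4, 6), c(1, 3))
  expect_equal(row$t, o$t, tolerance = 1e-12)
  expect_equal(round(row$t, 3), 2.121)
  expect_equal(row$p, o$p, tolerance = 1e-12)
  expect_equal(round(row$p, 3), 0.168)

  # identical groups: FC = 1, p = 1 (flagged when constant)
  m2 <- rbind(gene = c(2, 2, 2, 2), TBP = rep(1, 4))
  colnames(m2) <- samples
  res2 <- ttest_screen(tbp_normalize(m2), assignment)
  expect_equal(res2$statistic[res2$gene == "gene"], 1)
  expect_equal(res2$p[res2$gene == "gene"], 1)
  expect_equal(res2$flag[res2$gene == "gene"], "constant")
})

test_that("t-test screen agrees with stats::t.test on random matrices", {
  norm <- make_norm(50, 20, seed = 7)
  set.seed(8)
  prof <- make_profiles(setNames(rpois(20, 4), colnames(norm)))
  assignment <- group_by_burden(prof, g = 3)
  res <- ttest_screen(norm, assignment)
  high <- names(assignment)[assignment == 3]
  low <- names(assignment)[assignment == 1]
  for (g in sample(res$gene, 10)) {
    ht <- t.test(norm[g, high], norm[g, low], var.equal = TRUE)
    expect_equal(res$p[res$gene == g], ht$p.value, tolerance = 1e-12)
    expect_equal(res$statistic[res$gene == g],
                 mean(norm[g, high]) / mean(norm[g, low]), tolerance = 1e-12)
  }
  # Welch variant matches t.test default
  resw <- ttest_screen(norm, assignment, var_equal = FALSE)
  g1 <- resw$gene[1]
  expect_equal(resw$p[resw$gene == g1],
               t.test(norm[g1, high], norm[g1, low])$p.value,
               tolerance = 1e-12)
})

test_that("mutation-status screen mirrors the t-test contract", {
  samples <- paste0("s", 1:4)
  m <- rbind(gene = c(2, 2, 1, 1), TBP = rep(1, 4))
  colnames(m) <- samples
  norm <- tbp_normalize(m)
  status <- setNames(c("positive", "positive", "negative", "negative"),
                     samples)
  res <- mutation_status_screen(norm, status)
  expect_equal(res$statistic[res$gene == "gene"], 2)

  # label swap inverts FC, keeps p
  swapped <- setNames(rev(status), samples)
  res2 <- mutation_status_screen(norm, swapped)
  expect_equal(res2$statistic[res2$gene == "gene"], 0.5)
  expect_equal(res2$p[res2$gene == "gene"], res$p[res$gene == "gene"])

  expect_error(mutation_status_screen(norm, setNames(rep("positive", 4),
                                                     samples)),
               "at least 2")

  # planted difference matches the oracle
  norm_big <- make_norm(20, 30, seed = 9)
  status_big <- setNames(rep(c("positive", "negative"), c(12, 18)),
                         colnames(norm_big))
  res3 <- mutation_status_screen(norm_big, status_big)
  pos <- names(status_big)[status_big == "positive"]
  neg <- names(status_big)[status_big == "negative"]
  for (g in sample(setdiff(res3$gene, "TBP"), 8)) {
    o <- oracle_ttest(norm_big[g, pos], norm_big[g, neg])
    expect_equal(res3$p[res3$gene == g], o$p, tolerance = 1e-10)
    expect_equal(res3$statistic[res3$gene == g], o$fc, tolerance = 1e-10)
  }
})

test_that("candidate selection filters on p then truncates by rank key", {
  res <- structure(
    data.frame(gene = paste0("g", 1:10),
               statistic = c(5, 4.5, 4, 3, 2.5, 2, 1.5, 1.2, 1.1, 1),
               p = c(0.01, 0.2, 0.02, 0.03, 0.04, 0.001, 0.3, 0.4, 0.5, 0.6),
               q = NA_real_, rank = 1:10),
    class = c("screen_result", "data.frame"), screen = "toy")
  cand <- select_candidates(res, k = 3, alpha = 0.05)
  expect_equal(cand$genes, c("g1", "g3", "g4"))
  expect_true(all(cand$table$p < 0.05))

  expect_warning(c2 <- select_candidates(res, k = 200, alpha = 0.015),
                 "2 candidate")
  expect_equal(sort(c2$genes), c("g1", "g6"))

  # ranking by p reorders where statistic and p disagree
  by_p <- select_candidates(res, k = 3, alpha = 0.05, rank_by = "p")
  expect_equal(by_p$genes[1], "g6")
  by_stat <- select_candidates(res, k = 3, alpha = 0.05,
                               rank_by = "statistic")
  expect_equal(by_stat$genes[1], "g1")
})

test_that("candidate overlap: strict intersection plus Venn regions", {
  mk <- function(genes, screen) structure(list(genes = genes, screen = screen),
                                          class = "candidate_set")
  ov <- candidate_overlap(mk(c("A", "B", "C"), "s1"),
                          mk(c("B", "C", "D"), "s2"),
                          mk(c("C", "E"), "s3"))
  expect_equal(ov$genes, "C")
  expect_equal(sum(ov$regions$size), 5)  # A B C D E

  disj <- candidate_overlap(mk(c("A", "B"), "x"), mk(c("C", "D"), "y"))
  expect_equal(disj$genes, character(0))
  expect_equal(disj$regions$size[disj$regions$region == "x&y"], 0L)
  expect_error(candidate_overlap(mk("A", "x")), "at least 2")
})

test_that("screens are invariant to row and column permutations", {
  norm <- make_norm(20, 16, seed = 12)
  set.seed(13)
  prof <- make_profiles(setNames(rpois(16, 4), colnames(norm)))
  res <- spearman_screen(norm, prof)
  perm <- norm[sample(nrow(norm)), sample(ncol(norm))]
  attr(perm, "housekeeping") <- "TBP"
  res_p <- spearman_screen(perm, prof)
  m <- match(res$gene, res_p$gene)
  expect_equal(res$statistic, res_p$statistic[m], tolerance = 1e-12)
  expect_equal(res$p, res_p$p[m], tolerance = 1e-12)

  assignment <- group_by_burden(prof, g = 2)
  tt <- ttest_screen(norm, assignment)
  tt_p <- ttest_screen(perm, assignment)
  m2 <- match(tt$gene, tt_p$gene)
  expect_equal(tt$statistic, tt_p$statistic[m2], tolerance = 1e-12)
})

test_that("FC of swapped groups is the reciprocal", {
  norm <- make_norm(15, 12, seed = 14)
  a <- factor(rep(1:2, 6), levels = 1:2)
  names(a) <- colnames(norm)
  b <- factor(3 - as.integer(a), levels = 1:2)
  names(b) <- colnames(norm)
  r1 <- ttest_screen(norm, a)
  r2 <- ttest_screen(norm, b)
  m <- match(r1$gene, r2$gene)
  both <- !is.na(r1$statistic) & !is.na(r2$statistic[m])
  expect_equal(r1$statistic[both] * r2$statistic[m][both],
               rep(1, sum(both)), tolerance = 1e-12)
})
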