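test_that("normalized coverage follows its scaling laws", {
  expect_equal(avg_norm_coverage(0, 1000, 1e9), 0)
  expect_equal(avg_norm_coverage(1000, 1000, 1e9), 1e-9)
  expect_equal(avg_norm_coverage(500, 1000, 2e9),
               avg_norm_coverage(500, 1000, 1e9) / 2)
})

test_that("toy mapper counts error-free reads and rejects divergent ones", {
  set.seed(61)
  ctg <- c(cA = random_dna(4000), cB = random_dna(4000))
  starts <- seq(1, 3800, by = 200)
  reads <- setNames(substring(ctg[["cA"]], starts, starts + 149),
                    sprintf("r%02d", seq_along(starts)))
  cov <- toy_map_reads(reads, ctg)
  expect_equal(cov$aligned_bases[cov$contig_id == "cA"],
               150 * length(reads))
  expect_equal(cov$aligned_bases[cov$contig_id == "cB"], 0)
  # reads from an absent genome map nowhere
  set.seed(62)
  alien <- setNames(replicate(5, random_dna(150)), paste0("x", 1:5))
  cov2 <- toy_map_reads(alien, ctg)
  expect_true(all(cov2$aligned_bases == 0))
  # 15% divergence fails the 0.9 similarity floor even when a seed is clean
  bad <- vapply(reads[1:5], function(r) {
    paste0(substr(r, 1, 20), mutate_sequence(substr(r, 21, 150), 22))
  }, character(1))
  cov3 <- toy_map_reads(setNames(bad, paste0("b", 1:5)), ctg)
  expect_true(all(cov3$aligned_bases == 0))
  # reverse-complemented reads still map
  covrc <- toy_map_reads(setNames(revcomp(reads[1:3]), paste0("rc", 1:3)), ctg)
  expect_equal(covrc$aligned_bases[covrc$contig_id == "cA"], 450)
})

test_that("relative abundance sums member shares and normalizes columns", {
  covtab <- data.frame(
    contig_id = c("c1", "c2", "c3"), sample_id = "s1",
    aligned_bases = c(2000, 1000, 3000), dataset_size = 1e8)
  lens <- c(c1 = 1000, c2 = 1000, c3 = 2000)
  gm <- c(c1 = "gX", c2 = "gX", c3 = "gY")
  # normalized coverages 2e-8, 1e-8, 1.5e-8 -> shares 4/9, 2/9, 3/9
  ab <- relative_abundance(covtab, lens, gm)$abundance
  expect_equal(ab["gX", "s1"], 6 / 9)
  expect_equal(ab["gY", "s1"], 3 / 9)
  expect_equal(sum(ab[, "s1"]), 1, tolerance = 1e-9)
  # a single contig has abundance 1
  ab1 <- relative_abundance(covtab[1, ], lens, gm)$abundance
  expect_equal(unname(ab1[1, 1]), 1)
})

test_that("diversity indices match closed forms", {
  p10 <- rep(0.1, 10)
  expect_equal(shannon(p10), log(10), tolerance = 1e-12)
  expect_equal(pielou(p10), 1, tolerance = 1e-12)
  expect_equal(shannon(1), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.5 * log(2), tolerance = 1e-12)
  expect_equal(round(shannon(c(0.5, 0.25, 0.25)), 4), 1.0397)
  # bounds: 0 <= J <= 1, H <= ln S
  set.seed(63)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1)); p <- p / sum(p)
    expect_lte(shannon(p), log(length(p)) + 1e-12)
    expect_gte(pielou(p), 0)
    expect_lte(pielou(p), 1 + 1e-12)
  }
})

test_that("Bray-Curtis matches its definition and vegan", {
  expect_equal(bray_curtis(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(0.5, 0.5), c(1, 0)), 0.5)
  set.seed(64)
  m <- matrix(runif(40), nrow = 8)
  D <- bray_curtis_matrix(m)
  expect_true(isSymmetric(D))
  expect_true(all(D >= 0 & D <= 1))
  ref <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  expect_equal(unname(D), unname(ref), tolerance = 1e-12)
})

test_that("PCoA round-trips an exact Euclidean distance matrix", {
  set.seed(65)
  pts <- matrix(rnorm(5 * 3), nrow = 5)
  D <- as.matrix(dist(pts))
  ord <- pcoa_ord(D, k = 4)
  recovered <- as.matrix(dist(ord$points))
  expect_equal(unname(recovered), unname(D), tolerance = 1e-6)
  # negative eigenvalues are reported for non-Euclidean input
  m <- matrix(c(0, 1, 9, 1, 0, 1, 9, 1, 0), 3)
  expect_true(any(suppressWarnings(pcoa_ord(m, k = 2))$eig < 0))
})

test_that("rarefaction endpoints and saturation behave", {
  comm <- local_community(seed = 17, n_reads_per_sample = 400)
  reads <- comm$reads[["s1"]]
  rc <- rarefaction_curve(reads, comm$viruses, c(0, 0.25, 0.5, 0.75, 1),
                          seed = 5)
  expect_equal(rc$n_detected[1], 0)
  full <- toy_map_reads(reads, comm$viruses, detail = TRUE)
  det_full <- sum(vapply(names(comm$viruses), function(ctg) {
    full$coverage$n_reads[full$coverage$contig_id == ctg] >= 1 &&
      asvirome:::horizontal_coverage(full$intervals, ctg,
                                     nchar(comm$viruses[[ctg]])) >= 0.10
  }, logical(1)))
  expect_equal(rc$n_detected[5], det_full)
  expect_true(all(diff(rc$n_detected) >= -1))  # near-monotone in practice
  # saturating community: last-step increment small relative to total
  expect_lte(rc$n_detected[5] - rc$n_detected[4],
             max(1, 0.25 * rc$n_detected[5]))
})

test_that("UpSet counts enumerate exclusive intersections", {
  pres <- matrix(c(TRUE, TRUE, FALSE,     # g1: s1 & s2
                   FALSE, TRUE, TRUE,     # g2: s2 & s3
                   TRUE, TRUE, TRUE),     # g3: all samples
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
  out <- core_shared_genera(pres)
  expect_identical(out$core, "g3")
  cnt <- setNames(out$counts$count, out$counts$subset)
  expect_equal(unname(cnt[["s1&s2"]]), 1)
  expect_equal(unname(cnt[["s2&s3"]]), 1)
  expect_equal(unname(cnt[["s1&s2&s3"]]), 1)
  expect_equal(sum(out$counts$count), 3)
  expect_equal(nrow(out$counts), 7)
  # empty matrix: all counts zero
  empty <- core_shared_genera(pres[0, , drop = FALSE])
  expect_true(all(empty$counts$count == 0))
})

test_that("rank-abundance reports the threshold-crossing rank", {
  p <- c(a = 0.5, b = 0.3, c = 0.15, d = 0.05)
  ra <- rank_abundance(p, threshold = 0.1)
  expect_identical(ra$table$genus, c("a", "b", "c", "d"))
  expect_equal(ra$crossing_rank, 4)
  u <- setNames(rep(0.2, 5), letters[1:5])
  expect_equal(rank_abundance(u, threshold = 0.1)$crossing_rank, 6)
  expect_equal(rank_abundance(c(x = 1))$table$rank, 1)
})

test_that("estimated genus abundances track the planted truth", {
  comm <- local_community(seed = 19, n_reads_per_sample = 1500)
  truth <- comm$truth$true_abundance
  gm <- comm$truth$true_genus_of
  est <- relative_abundance(comm$coverage, nchar(comm$viruses), gm)$abundance
  for (s in colnames(truth)) {
    rho <- cor(truth[rownames(est), s], est[, s], method = "spearman")
    expect_gte(rho, 0.95)
  }
  # and from mapped reads
  mp <- toy_map_reads(comm$reads[["s1"]], comm$viruses)
  covtab <- data.frame(contig_id = mp$contig_id, sample_id = "s1",
                       aligned_bases = mp$aligned_bases, dataset_size = 1e8)
  est2 <- relative_abundance(covtab, nchar(comm$viruses), gm)$abundance
  rho2 <- cor(truth[rownames(est2), "s1"], est2[, "s1"], method = "spearman")
  expect_gte(rho2, 0.85)
})
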