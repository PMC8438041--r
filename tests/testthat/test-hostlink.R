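test_that("match_spacer applies the identity/coverage/mismatch thresholds", {
  set.seed(51)
  ctg <- random_dna(3000)
  sp32 <- substr(ctg, 1001, 1032)
  hit <- match_spacer(sp32, ctg)
  expect_equal(hit$identity, 1)
  expect_equal(hit$spacer_coverage, 1)
  expect_equal(hit$mismatches, 0)
  expect_equal(hit$contig_start, 1000)
  expect_equal(hit$contig_end, 1032)
  # one central substitution in a 32-mer: 31/32 < 0.97, no trimmed rescue
  sp32m <- mutate_with_central_sub(sp32)
  expect_null(match_spacer(sp32m, ctg))
  # one central substitution in a 40-mer: 39/40 = 0.975 passes
  sp40 <- substr(ctg, 2001, 2040)
  sp40m <- mutate_with_central_sub(sp40)
  hit40 <- match_spacer(sp40m, ctg)
  expect_equal(hit40$identity, 39 / 40)
  expect_equal(hit40$spacer_coverage, 1)
  expect_equal(hit40$mismatches, 1)
  # reverse-complement occurrences are found on the minus strand
  hitrc <- match_spacer(revcomp(sp32), ctg)
  expect_identical(hitrc$strand, "-")
  expect_equal(hitrc$contig_start, 1000)
  expect_error(match_spacer("ACGTACGT", ctg), "seed")
})

test_that("matcher agrees with the brute-force sliding-window oracle", {
  set.seed(52)
  for (i in 1:60) {
    ctg <- random_dna(1200)
    n <- sample(19:48, 1)
    pos <- sample(1:(1200 - n), 1)
    sp <- mutate_sequence(substr(ctg, pos, pos + n - 1), sample(0:2, 1))
    if (sample(c(TRUE, FALSE), 1)) sp <- revcomp(sp)
    a <- match_spacer(sp, ctg)
    b <- match_spacer_oracle(sp, ctg)
    expect_identical(is.null(a), is.null(b))
    if (!is.null(a)) {
      expect_equal(a$identity, b$identity)
      expect_equal(a$spacer_coverage, b$spacer_coverage)
      expect_equal(a$mismatches, b$mismatches)
      expect_equal(a$contig_start, b$contig_start)
      expect_identical(a$strand, b$strand)
    }
  }
})

test_that("full-length matches of spacers under 34 bp must be exact", {
  set.seed(53)
  for (n in 19:33) {
    ctg <- random_dna(1000)
    sp <- substr(ctg, 501, 500 + n)
    expect_false(is.null(match_spacer(sp, ctg)))
    expect_null(match_spacer(mutate_with_central_sub(sp), ctg))
  }
})

test_that("predict_hosts recovers planted links exactly at subs = 0", {
  comm <- local_community()
  db <- build_spacer_db(comm$hosts, comm$host_lineage)
  links <- predict_hosts(comm$viruses, db)
  pred <- unique(paste(links$contig_id, links$genome_id))
  tru <- unique(paste(comm$truth$true_links$virus_id,
                      comm$truth$true_links$host_id))
  expect_setequal(pred, tru)
  # exactly one primary hit per linked contig
  expect_equal(sum(links$primary), length(unique(links$contig_id)))
  # a contig without a protospacer gets no link
  set.seed(54)
  naive <- c(virX = random_dna(8000))
  expect_equal(nrow(predict_hosts(naive, db)), 0)
})

test_that("one spacer in two hosts links the virus to both genomes", {
  set.seed(55)
  vir <- c(v1 = random_dna(6000))
  proto <- substr(vir[["v1"]], 3001, 3036)
  mk <- function(seed) {
    set.seed(seed)
    plant_crispr_array(random_dna(8000), random_dna(28),
                       c(proto, random_dna(33)), 4000)
  }
  hosts <- c(hA = mk(561), hB = mk(562))
  lin <- data.frame(genome_id = c("hA", "hB"), domain = "Bacteria",
                    phylum = "x", class = "x", order = "x", family = "x",
                    genus = c("genA", "genB"))
  db <- build_spacer_db(hosts, lin)
  links <- predict_hosts(vir, db)
  expect_setequal(links$genome_id, c("hA", "hB"))
  hr <- classify_host_range(links)
  expect_identical(hr$label, "multi-genus")
  expect_equal(hr$n_genera, 2)
})

test_that("benchmark_thresholds reports precision and recall per grid point", {
  comm <- local_community()
  db <- build_spacer_db(comm$hosts, comm$host_lineage)
  tl <- comm$truth$true_links
  known <- lapply(setNames(nm = names(comm$viruses)), function(v)
    unique(tl$host_genus[tl$virus_id == v]))
  grid <- data.frame(identity = c(0.97, 1.0), coverage = 0.90,
                     max_mismatch = c(1L, 0L))
  res <- benchmark_thresholds(comm$viruses, known, db, grid)
  # defaults on unmutated spacers: every prediction correct
  expect_equal(res$precision[1], 100)
  expect_equal(res$recall_any[1],
               100 * length(unique(tl$virus_id)) / length(comm$viruses))
  # empty database: recall 0, precision missing
  res0 <- benchmark_thresholds(comm$viruses, known, db[0, ], grid)
  expect_true(all(res0$recall == 0))
  expect_true(all(is.na(res0$precision)))
})

test_that("identity 1.0 with one planted substitution gives zero recall", {
  comm <- local_community(seed = 13, subs_per_spacer = 1)
  db <- build_spacer_db(comm$hosts, comm$host_lineage)
  # spacers of 40+ bp would pass at defaults but nothing passes identity 1
  th <- match_thresholds(identity = 1.0)
  links <- predict_hosts(comm$viruses, db, th)
  # any surviving full-length match must be mismatch-free; planted spacers
  # all carry one substitution, so only trimmed exact windows could pass
  expect_true(all(links$mismatches == 0))
})

test_that("random null recall is near zero for genuine spacer databases", {
  comm <- local_community()
  db <- build_spacer_db(comm$hosts, comm$host_lineage)
  null_rate <- random_null_recall(db, n_seqs = 15, lengths = 10000,
                                  n_replicates = 3, seed = 7)
  expect_lt(null_rate, 0.01)
  # adversarial fixture: spacers copied verbatim into the "random" pool
  expect_equal(random_null_recall(db[0, ], 10, 1000), 0)
})

test_that("the cross-domain error model reproduces its arithmetic", {
  ef <- erroneous_fraction(0.70, 11.7)
  expect_equal(ef$percent, 100 * 0.70 / 11.7, tolerance = 1e-12)
  expect_equal(ef$reported, 6)
  expect_equal(erroneous_fraction(0, 5)$percent, 0)
  expect_equal(erroneous_fraction(3.3, 3.3)$percent, 100)
  expect_error(erroneous_fraction(0.7, 0), "zero")

  expect_equal(false_multidomain_prob(0.06, 2), 0.1164, tolerance = 1e-12)
  expect_equal(false_multidomain_prob(0, 5), 0)
  expect_equal(false_multidomain_prob(0.3, 1), 0.3)

  efc <- expected_false_count(135, 0.1164)
  expect_equal(efc$expected, 15.714, tolerance = 1e-9)
  expect_equal(efc$reported, 16)
  expect_equal(expected_false_count(0, 0.5)$reported, 0)
  expect_equal(expected_false_count(100, 0.5)$reported, 50)
  # monotone in both arguments
  p2 <- false_multidomain_prob(0.06, 2)
  expect_gt(false_multidomain_prob(0.12, 2), p2)
  expect_gt(false_multidomain_prob(0.06, 3), p2)
  expect_gt(expected_false_count(200, p2)$expected,
            expected_false_count(135, p2)$expected)
})

test_that("host-range classification distinguishes the three labels", {
  links <- data.frame(
    contig_id = c("v1", "v2", "v2", "v3", "v3"),
    genus = c("gA", "gA", "gB", "gA", "gC"),
    domain = c("Bacteria", "Bacteria", "Bacteria", "Bacteria", "Archaea"))
  hr <- classify_host_range(links)
  expect_identical(hr$label, c("specialist", "multi-genus", "cross-domain"))
  # cross-domain implies multi-genus
  expect_true(all(hr$n_genera[hr$label == "cross-domain"] > 1))
})

test_that("function mapping double-counts multi-function hosts", {
  ft <- data.frame(genus = c("gA", "gB", "gB"),
                   func = c("P-removal", "S-reduction", "Nitrification"))
  links <- data.frame(contig_id = c("v1", "v1"), genus = c("gA", "gB"))
  out <- map_functions(links, ft)
  expect_setequal(out$func, c("P-removal", "S-reduction", "Nitrification"))
  expect_true(all(out$count == 1))
  # unknown genus falls back to unclassified
  out2 <- map_functions(data.frame(contig_id = "v9", genus = "gZ"), ft)
  expect_identical(out2$func, "unclassified")
})
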