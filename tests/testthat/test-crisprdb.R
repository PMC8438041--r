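test_that("planted arrays round-trip through the detector", {
  set.seed(21)
  g <- random_dna(10000)
  R <- random_dna(28)
  sp <- c("TTTACTTTGGATCCTAAGCAGGACGTACGCAAA",
          "ACGGCTTGATACCTTGACCATTGGACTAACGGC",
          "CCATTAGGAGCGCGTTAACCTTGAGACTACTAA")
  g2 <- plant_crispr_array(g, R, sp, 5000)
  arrs <- find_crispr_arrays(g2)
  expect_length(arrs, 1)
  expect_identical(arrs[[1]]$repeat_seq, R)
  expect_identical(arrs[[1]]$spacers$sequence, sp)
  expect_equal(arrs[[1]]$n_repeats, 4)
  # spacer coordinates slice back to the spacer sequence (0-based half-open)
  for (i in 1:3) {
    expect_identical(substr(g2, arrs[[1]]$spacers$start[i] + 1,
                            arrs[[1]]$spacers$end[i]), sp[i])
  }
})

test_that("two repeat copies do not make an array", {
  set.seed(22)
  g <- random_dna(5000)
  R <- random_dna(28)
  # single spacer -> two repeat copies, below the 3-copy floor
  g2 <- paste0(substr(g, 1, 2000), R, random_dna(33), R,
               substr(g, 2001, 5000))
  expect_length(find_crispr_arrays(g2), 0)
})

test_that("an oversized spacer splits the array at that junction", {
  set.seed(23)
  g <- random_dna(12000)
  R <- random_dna(28)
  left <- c("GATTCAGGACCTAGGCATTACCGGATACGCA",
            "TCCGGATTACCAGGATCGGATTTACGGCAAT",
            "AAGGTTCCAGGATTCGGAACCTTGGCAGACT")
  right <- c("TTGGCCAATTGGACTACGGATCAGGATTACA",
             "CCGGTTAACCGGATTACGGACCTAGGATACT",
             "GGAATTCCGGATTAGGACCATTGGACTTACG")
  # two valid 4-repeat arrays joined by a 60-bp gap: the junction is
  # rejected and each side stands alone
  arr1 <- paste0(R, paste0(left, R, collapse = ""))
  arr2 <- paste0(R, paste0(right, R, collapse = ""))
  g2 <- paste0(substr(g, 1, 6000), arr1, random_dna(60), arr2,
               substr(g, 6001, 12000))
  arrs <- find_crispr_arrays(g2)
  expect_length(arrs, 2)
  expect_identical(arrs[[1]]$spacers$sequence, left)
  expect_identical(arrs[[2]]$spacers$sequence, right)
})

test_that("planted-array recovery is complete across generator seeds", {
  for (s in c(31, 32, 33)) {
    comm <- gen_community(synth_config(n_viruses = 8, n_hosts = 5,
                                       host_len = 12000, seed = s))
    ps <- comm$truth$planted_spacers
    for (h in names(comm$hosts)) {
      arrs <- find_crispr_arrays(comm$hosts[[h]])
      got <- unlist(lapply(arrs, function(a) a$spacers$sequence))
      expect_true(setequal(got, ps$spacer_seq[ps$host_id == h]))
    }
  }
})

test_that("random sequence yields no arrays (false-positive control)", {
  n_found <- 0L
  for (s in 1:20) {
    set.seed(s)
    n_found <- n_found + length(find_crispr_arrays(random_dna(100000)))
  }
  expect_identical(n_found, 0L)
})

test_that("build_spacer_db carries lineage and deduplicates per genome", {
  comm <- local_community()
  db <- build_spacer_db(comm$hosts, comm$host_lineage)
  ps <- comm$truth$planted_spacers
  expect_setequal(db$sequence, unique(ps$spacer_seq))
  expect_true(all(c("domain", "genus") %in% names(db)))
  expect_identical(db$genus,
                   comm$host_lineage$genus[match(db$genome_id,
                                                 comm$host_lineage$genome_id)])
  # genomes with no arrays -> empty DB
  set.seed(44)
  plain <- c(p1 = random_dna(5000))
  lin <- data.frame(genome_id = "p1", domain = "Bacteria", phylum = "x",
                    class = "x", order = "x", family = "x", genus = "x")
  expect_equal(nrow(build_spacer_db(plain, lin)), 0)
  # missing lineage errors with the genome named
  expect_error(build_spacer_db(comm$hosts, lin), "host001")
  # an identical spacer in two genomes keeps both records
  set.seed(45)
  R <- random_dna(28); R2 <- random_dna(28)
  sp <- c("ACCGGATTACGGATCCTAGGCAATTCCGGAT",
          "TTGGCCAATTACGGATCAGGACCTTAGGACA")
  gA <- plant_crispr_array(random_dna(6000), R, sp, 3000)
  gB <- plant_crispr_array(random_dna(6000), R2, sp, 2000)
  lin2 <- data.frame(genome_id = c("gA", "gB"),
                     domain = c("Bacteria", "Archaea"), phylum = "x",
                     class = "x", order = "x", family = "x",
                     genus = c("g1", "g2"))
  db2 <- build_spacer_db(c(gA = gA, gB = gB), lin2)
  expect_equal(sum(db2$sequence == sp[1]), 2)
})
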