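test_that("shared_pc_significance matches the enumeration oracle", {
  expect_equal(shared_pc_significance(3, 3, 0, 10), 0)
  expect_equal(shared_pc_significance(5, 5, 5, 5), 0)
  expect_equal(shared_pc_significance(3, 3, 3, 10), log10(120),
               tolerance = 1e-9)
  set.seed(4)
  for (i in 1:25) {
    n_total <- sample(4:12, 1)
    nA <- sample(1:n_total, 1)
    nB <- sample(1:n_total, 1)
    shared <- sample(0:min(nA, nB), 1)
    expect_equal(shared_pc_significance(nA, nB, shared, n_total),
                 hyper_score_oracle(nA, nB, shared, n_total),
                 tolerance = 1e-9)
  }
  expect_error(shared_pc_significance(3, 3, 4, 10), "shared")
})

test_that("cluster_proteins follows the greedy centroid rule", {
  p <- random_protein(60)
  two <- c(x = p, y = p)
  cl <- cluster_proteins(two)
  expect_equal(length(unique(cl$pc_id)), 1)
  set.seed(8)
  unrelated <- c(a = random_protein(60), b = random_protein(60))
  expect_equal(length(unique(cluster_proteins(unrelated)$pc_id)), 2)
  # A founds the cluster; B and C join via A (~92% id each) even though
  # B vs C (~84%) is below the threshold -- the greedy centroid rule
  core <- random_protein(100)
  A <- core
  B <- paste0(substr(core, 1, 92), random_protein(8))
  C <- paste0(random_protein(8), substr(core, 9, 100))
  cl3 <- cluster_proteins(c(A = A, B = B, C = C), id_threshold = 0.9)
  expect_equal(length(unique(cl3$pc_id)), 1)
  expect_equal(nrow(cluster_proteins(character(0))), 0)
})

test_that("assign_genera takes connected components with deterministic labels", {
  pc <- data.frame(contig_id = c("a", "b", "c"),
                   pc_id = c("p1", "p2", "p3"))
  out <- assign_genera(pc, score_threshold = 1)
  expect_true(all(out$assignment$genus == "singleton"))
  # chain a-b, b-c: one genus by transitive closure
  pc2 <- data.frame(
    contig_id = c("a", "a", "b", "b", "c", "c"),
    pc_id = c("p1", "p2", "p2", "p3", "p3", "p4"))
  # with a tiny universe the single shared PC is significant
  out2 <- assign_genera(pc2, score_threshold = 0.5, n_total = 40)
  expect_true(all(out2$assignment$genus == "VC_a"))
})

test_that("assign_genera is invariant to input row order", {
  comm <- local_community()
  pcs <- cluster_proteins(comm$proteins)
  pc_map <- merge(pcs, comm$gene_map, by.x = "protein_id", by.y = "gene_id")
  a1 <- assign_genera(pc_map)$assignment
  set.seed(2)
  a2 <- assign_genera(pc_map[sample.int(nrow(pc_map)), ])$assignment
  expect_identical(a1, a2)
})

test_that("assign_genera recovers the planted genus partition", {
  comm <- local_community()
  pcs <- cluster_proteins(comm$proteins)
  pc_map <- merge(pcs, comm$gene_map, by.x = "protein_id", by.y = "gene_id")
  got <- assign_genera(pc_map, contigs = names(comm$viruses))$assignment
  truth <- comm$truth$true_genus_of[got$contig_id]
  # same partition: contigs share a predicted genus iff they share a
  # planted genus (size-1 planted genera are singletons)
  for (i in seq_len(nrow(got))) for (j in seq_len(nrow(got))) {
    if (i >= j) next
    same_pred <- got$genus[i] == got$genus[j] && got$genus[i] != "singleton"
    expect_identical(same_pred, unname(truth[i] == truth[j]))
  }
  planted_singletons <- names(table(truth))[table(truth) == 1]
  expect_true(all(got$genus[truth %in% planted_singletons] == "singleton"))
})

test_that("dereplicate absorbs duplicates and substrings", {
  set.seed(6)
  a <- random_dna(1000)
  out <- dereplicate(c(c1 = a, c2 = a))
  expect_equal(length(unique(out$representative_id)), 1)
  sub <- substr(a, 1, 850)
  out2 <- dereplicate(c(full = a, part = sub))
  expect_identical(out2$representative_id[out2$contig_id == "part"], "full")
  out3 <- dereplicate(c(u = random_dna(800), v = random_dna(800)))
  expect_equal(length(unique(out3$representative_id)), 2)
  # a 90%-identity mutated copy is absorbed at the default thresholds
  b <- mutate_sequence(a, 80)
  out4 <- dereplicate(c(orig = a, mut = b), id_threshold = 0.90)
  expect_equal(length(unique(out4$representative_id)), 1)
})
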