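test_that("pair similarity matches the threshold rule on constructed pairs", {
  a <- random_dna(100, seed = 1)
  # identical sequences: identity 1 over the full length
  e <- pair_similarity(a, a)
  expect_equal(e$identity, 1.0)
  expect_equal(e$overlap, 100)

  # reverse complement: same edge on the minus strand
  rc <- as.character(ltrtracer:::cpp_revcomp(a))
  erc <- pair_similarity(a, rc)
  expect_equal(erc$identity, 1.0)
  expect_equal(erc$strand, "-")

  # 54-base exact terminal overlap, random remainders: below the 55% floor
  core <- random_dna(54, seed = 2)
  x <- paste0(random_dna(46, seed = 3), core)
  y <- paste0(core, random_dna(46, seed = 4))
  expect_null(pair_similarity(x, y))
  # widening the shared core to 56 restores the edge
  core2 <- random_dna(56, seed = 5)
  x2 <- paste0(random_dna(44, seed = 6), core2)
  y2 <- paste0(core2, random_dna(44, seed = 7))
  e2 <- pair_similarity(x2, y2)
  expect_equal(e2$overlap, 56)
  expect_equal(e2$identity, 1.0)
})

test_that("a 60-column overlap with 6 mismatches sits exactly at 0.90", {
  # overlap of 60 with mismatches at spread positions; identity = 54/60
  core <- random_dna(60, seed = 8)
  mut <- core
  for (p in c(5, 15, 25, 35, 45, 55)) {
    old <- substr(mut, p, p)
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  x <- paste0(random_dna(40, seed = 9), core)
  y <- paste0(mut, random_dna(40, seed = 10))
  e <- pair_similarity(x, y)
  expect_false(is.null(e))
  expect_equal(e$overlap, 60)
  expect_equal(e$identity, 0.90)
  # independent dynamic-programming oracle confirms the optimal score
  expect_equal(e$score, Biostrings::score(oracle_align(x, y)))
  # one more mismatch drops identity below 0.90: no edge
  mut2 <- mut
  substr(mut2, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                  substr(mut2, 30, 30))[1]
  expect_null(pair_similarity(x, paste0(mut2, random_dna(40, seed = 11))))
})

test_that("the aligner agrees with an independent implementation", {
  set.seed(12)
  for (i in 1:25) {
    core <- random_dna(sample(55:90, 1))
    a <- paste0(random_dna(sample(5:40, 1)), core)
    b <- paste0(core, random_dna(sample(5:40, 1)))
    ours <- ltrtracer:::cpp_overlap_align(a, b)
    expect_equal(ours$score, Biostrings::score(oracle_align(a, b)))
  }
})

test_that("similarity graphs equal the brute-force all-pairs graph", {
  # reads from one family at 3% copy divergence plus background reads
  spec <- family_spec("f", "gypsy", "A", 3000, 30, copy_divergence = 0.03,
                      panel_divergence = 0)
  panel <- simulate_reference_panel(spec, seed = 13)
  g <- simulate_species_genome(panel, spec, background_length = 1e5,
                               seed = 14)
  reads <- simulate_reads(g, 300, seed = 15)
  seqs <- setNames(reads$bases, reads$read_id)

  gb <- build_similarity_graph(seqs, prefilter = "none")
  gp <- build_similarity_graph(seqs, prefilter = "shared-kmer")
  expect_identical(gb$edges, gp$edges)
  expect_gt(nrow(gb$edges), 50)

  # the at-scale component path gives the same clusters as the graph path
  cb <- extract_clusters(gb)
  cs <- cluster_sequences(reads)
  expect_identical(cb$membership, cs$membership)
  expect_identical(cb$clusters, cs$clusters)
})

test_that("simple graph topologies come out as expected", {
  a <- random_dna(100, seed = 16)
  tri <- setNames(c(a, a, a), c("r1", "r2", "r3"))
  g <- build_similarity_graph(tri)
  expect_equal(nrow(g$edges), 3) # a triangle

  # reads from two unrelated sequences: no cross edges
  s1 <- random_dna(2000, seed = 17)
  s2 <- random_dna(2000, seed = 18)
  r1 <- simulate_reads(s1, 20, error_rate = 0, seed = 19, prefix = "a")
  r2 <- simulate_reads(s2, 20, error_rate = 0, seed = 20, prefix = "b")
  g2 <- build_similarity_graph(setNames(c(r1$bases, r2$bases),
                                        c(r1$read_id, r2$read_id)))
  cross <- (g2$edges$id_a %in% r1$read_id) !=
    (g2$edges$id_b %in% r1$read_id)
  expect_equal(sum(cross), 0)
})

test_that("clusters partition sequences with deterministic ordering", {
  seqs <- setNames(replicate(5, random_dna(100)), paste0("s", 1:5))
  g <- build_similarity_graph(seqs)
  cl <- extract_clusters(g)
  expect_equal(nrow(cl$clusters), 5) # all singletons
  expect_equal(sum(cl$clusters$size), 5)
  expect_setequal(cl$membership$seq_id, names(seqs))

  # two unrelated families clustered with their tracers: exactly two
  # tracer-containing clusters, one per family, never mixed
  specs <- rbind(family_spec("fa", "gypsy", "A", 2000, 15, 0.02, 0),
                 family_spec("fb", "copia", "1", 2000, 15, 0.02, 0))
  panel <- simulate_reference_panel(specs, seed = 21)
  tracers <- kmerize_panel(panel)$tracers
  g2 <- simulate_species_genome(panel, specs, background_length = 4e4,
                                seed = 22)
  reads <- simulate_reads(g2, 400, seed = 23)
  cl2 <- cluster_sequences(reads, tracers)
  with_tracers <- cl2$clusters[cl2$clusters$tracer_total > 0, ]
  expect_equal(nrow(with_tracers), 2)
  expect_gt(min(with_tracers$read_count), 50)
  # neither cluster mixes sublineages
  expect_equal(nrow(cl2$tracer_counts), 2)
  # ordering: decreasing size, ties by smallest member id
  expect_true(all(diff(cl2$clusters$size) <= 0))
})

test_that("the graph is invariant to reverse-complementing reads", {
  spec <- family_spec("f", "gypsy", "A", 2000, 10, 0.02, 0)
  panel <- simulate_reference_panel(spec, seed = 24)
  g <- simulate_species_genome(panel, spec, background_length = 2e4,
                               seed = 25)
  reads <- simulate_reads(g, 150, seed = 26)
  cl1 <- cluster_sequences(reads)
  flipped <- reads
  idx <- seq(1, nrow(reads), by = 2)
  flipped$bases[idx] <-
    as.character(ltrtracer:::cpp_revcomp(reads$bases[idx]))
  cl2 <- cluster_sequences(flipped)
  expect_identical(cl1$membership, cl2$membership)
})

test_that("repetitive fraction applies the 0.01% cluster-size rule", {
  mk_clusters <- function(read_counts) {
    ids <- unlist(lapply(seq_along(read_counts), function(i)
      sprintf("c%02d_%05d", i, seq_len(read_counts[i]))))
    labels <- rep(seq_along(read_counts), read_counts)
    ltrtracer:::make_clusters(ids, labels)
  }
  # 3 M sampled reads -> minimum cluster size 300
  cl <- mk_clusters(c(400, 299))
  fr <- repetitive_fraction(cl, 3e6)
  expect_equal(fr$min_cluster_size, 300)
  expect_equal(fr$repetitive_fraction, 400 / 3e6)
  # a 299-read cluster alone contributes nothing
  fr2 <- repetitive_fraction(mk_clusters(299), 3e6)
  expect_equal(fr2$repetitive_fraction, 0)
  # all reads in one cluster -> fraction 1
  fr3 <- repetitive_fraction(mk_clusters(5000), 5000)
  expect_equal(fr3$repetitive_fraction, 1.0)
  # 0.01% of 2.4 M reads -> 240 (ceiling rule)
  expect_equal(repetitive_fraction(cl, 2.4e6)$min_cluster_size, 240)
  expect_error(repetitive_fraction(cl, 0), "positive")
})

test_that("replicate runs report mean and standard error", {
  spec <- family_spec("f", "gypsy", "A", 2000, 25, 0.02, 0.02)
  panel <- simulate_reference_panel(spec, seed = 27)
  g <- simulate_species_genome(panel, spec, background_length = 1e5,
                               seed = 28)
  reads <- simulate_reads(g, 3000, seed = 29)
  # sampling the full read set every run: identical estimates, SE 0
  rep1 <- suppressMessages(
    replicate_fraction(reads, n_runs = 3, n_per_run = 1e6, seed = 1))
  expect_equal(rep1$se, 0)
  expect_equal(length(rep1$runs), 3)
  expect_equal(rep1$mean, mean(rep1$runs))
  # distinct subsamples: per-run values recorded, mean is their average
  rep2 <- replicate_fraction(reads, n_runs = 3, n_per_run = 1500, seed = 5)
  expect_equal(length(unique(rep2$seeds)), 3)
  expect_equal(rep2$mean, mean(rep2$runs))
  expect_error(replicate_fraction(reads, n_runs = 1), "n_runs")
})

test_that("repetitive fraction grows with simulated copy number", {
  fracs <- vapply(c(5, 15, 30), function(cp) {
    spec <- family_spec("f", "gypsy", "A", 2000, cp, 0.02, 0.02)
    panel <- simulate_reference_panel(spec, seed = 30)
    g <- simulate_species_genome(panel, spec, background_length = 2e5,
                                 seed = 31)
    reads <- simulate_reads(g, 4000, seed = 32)
    cl <- cluster_sequences(reads)
    repetitive_fraction(cl, nrow(reads), min_cluster_size = 5)$
      repetitive_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})
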