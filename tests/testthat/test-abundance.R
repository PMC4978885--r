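# builds a repeat_clusters object with prescribed tracer composition
mock_clusters <- function(read_counts, tracer_members) {
  all_sub <- data.frame(
    superfamily = c("gypsy", "gypsy", "copia"),
    sublineage = c("A", "B", "1"),
    stringsAsFactors = FALSE
  )
  tracers <- do.call(rbind, lapply(seq_len(nrow(all_sub)), function(i)
    data.frame(tracer_id = sprintf("%s|%d", all_sub$sublineage[i], 1:400),
               superfamily = all_sub$superfamily[i],
               sublineage = all_sub$sublineage[i],
               stringsAsFactors = FALSE)))
  ids <- character(0); labels <- integer(0)
  used <- setNames(rep(0L, nrow(all_sub)), all_sub$sublineage)
  for (i in seq_along(read_counts)) {
    rid <- sprintf("cl%02d_r%05d", i, seq_len(read_counts[i]))
    tm <- tracer_members[[i]]
    tid <- character(0)
    for (sl in names(tm)) {
      tid <- c(tid, sprintf("%s|%d", sl, used[sl] + seq_len(tm[[sl]])))
      used[sl] <- used[sl] + tm[[sl]]
    }
    ids <- c(ids, rid, tid)
    labels <- c(labels, rep(i, read_counts[i] + length(tid)))
  }
  ltrtracer:::make_clusters(ids, labels, tracers)
}

test_that("cluster annotation follows majority tracers with a purity flag", {
  cl <- mock_clusters(
    read_counts = c(500, 120, 60, 40),
    tracer_members = list(
      list(A = 281),          # pure sublineage A
      list(A = 10, B = 2),    # top share 10/12 = 0.833: unflagged
      list(A = 7, B = 3),     # top share 0.7 < 0.8: flagged
      list()                  # no tracers: unassigned
    ))
  ann <- annotate_clusters(cl)
  ann <- ann[match(cl$clusters$cluster_id, ann$cluster_id), ]
  by_reads <- order(-cl$clusters$read_count)
  a <- ann[by_reads, ]
  expect_equal(a$sublineage, c("A", "A", "A", "unassigned"))
  expect_equal(a$superfamily, c("gypsy", "gypsy", "gypsy", "unassigned"))
  expect_equal(a$ambiguity_flag, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(a$top_share[2], 10 / 12)
})

test_that("mixed-superfamily clusters are always flagged", {
  cl <- mock_clusters(read_counts = c(100),
                      tracer_members = list(list(A = 30, `1` = 2)))
  ann <- annotate_clusters(cl)
  expect_equal(ann$sublineage[1], "A")
  expect_true(ann$ambiguity_flag[1])
})

test_that("profiles convert qualifying-cluster reads into proportions", {
  cl <- mock_clusters(
    read_counts = c(600, 300, 90, 2),
    tracer_members = list(list(A = 50), list(`1` = 40), list(),
                          list(B = 5)))
  prof <- sublineage_profile(cl, n_sampled = 10000, min_cluster_size = 10)
  get <- function(sl) prof$proportion[prof$sublineage == sl]
  expect_equal(get("A"), 0.06)
  expect_equal(get("1"), 0.03)
  expect_equal(get("unassigned"), 0.009)
  expect_equal(get("B"), 0) # its only cluster is below the size threshold
  # exact identity: profile total equals the repetitive fraction
  fr <- repetitive_fraction(cl, 10000, min_cluster_size = 10)
  expect_equal(sum(prof$proportion), fr$repetitive_fraction)
  expect_equal(attr(prof, "repetitive_fraction"), fr$repetitive_fraction)
})

test_that("no annotated clusters means an all-zero profile", {
  cl <- mock_clusters(read_counts = c(3, 2),
                      tracer_members = list(list(), list()))
  prof <- sublineage_profile(cl, 1000, min_cluster_size = 5)
  expect_true(all(prof$proportion == 0))
})

test_that("superfamily ratio is a simple fold with a guarded zero", {
  prof <- data.frame(superfamily = c("gypsy", "gypsy", "copia"),
                     sublineage = c("A", "B", "1"),
                     proportion = c(0.25, 0.15, 0.10))
  expect_equal(superfamily_ratio(prof), 4.0)
  prof$proportion <- c(0.1, 0, 0.1)
  expect_equal(superfamily_ratio(prof), 1.0)
  prof$proportion <- c(0.1, 0.1, 0)
  expect_warning(r <- superfamily_ratio(prof), "copia")
  expect_true(is.na(r))
})

test_that("replicate aggregation reproduces hand-computed mean and SE", {
  vals <- c(0.10, 0.12, 0.14, 0.10, 0.14)
  profs <- lapply(vals, function(v) {
    data.frame(species = "sp", superfamily = c("gypsy", "copia"),
               sublineage = c("A", "1"), proportion = c(v, 0.05),
               stringsAsFactors = FALSE)
  })
  agg <- aggregate_replicates(profs)
  i <- which(agg$sublineage == "A")
  expect_equal(agg$mean[i], 0.12)
  expect_equal(agg$se[i], sd(vals) / sqrt(5))
  expect_equal(agg$n_runs[i], 5)
  # identical replicates: SE 0
  agg0 <- aggregate_replicates(profs[c(1, 1)])
  expect_equal(agg0$se, c(0, 0))
  # mismatched sublineage sets rejected; single replicate rejected
  bad <- profs
  bad[[2]]$sublineage <- c("A", "2")
  expect_error(aggregate_replicates(bad), "mismatched")
  expect_error(aggregate_replicates(profs[1]), "at least 2")
})

test_that("simulated family fractions are recovered by the profile", {
  specs <- tiny_specs(copies = 60, copy_divergence = 0.02,
                      panel_divergence = 0.02)
  panel <- simulate_reference_panel(specs, seed = 40)
  tracers <- kmerize_panel(panel)$tracers
  genome <- simulate_species_genome(panel, specs, background_length = 4e6,
                                    seed = 41)
  n <- 20000
  reads <- simulate_reads(genome, n, seed = 42)
  cl <- cluster_sequences(reads, tracers)
  prof <- sublineage_profile(cl, n)
  truth <- genome$truth_table
  for (i in seq_len(nrow(truth))) {
    est <- prof$proportion[prof$sublineage == truth$sublineage[i] &
                             prof$superfamily == truth$superfamily[i]]
    p <- truth$fraction[i]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(est - p), 3 * se + 0.003)
  }
  # two species with identical composition agree within sampling error
  genome2 <- simulate_species_genome(panel, specs, background_length = 4e6,
                                     seed = 43)
  reads2 <- simulate_reads(genome2, n, seed = 44)
  prof2 <- sublineage_profile(cluster_sequences(reads2, tracers), n)
  expect_lt(max(abs(prof$proportion - prof2$proportion)), 0.012)
})

test_that("quantify_abundance aggregates replicate profiles", {
  specs <- tiny_specs(copies = 30)
  panel <- simulate_reference_panel(specs, seed = 50)
  tracers <- kmerize_panel(panel)$tracers
  genome <- simulate_species_genome(panel, specs, background_length = 1e6,
                                    seed = 51)
  reads <- simulate_reads(genome, 12000, seed = 52)
  qa <- quantify_abundance(reads, tracers, n_runs = 3, n_per_run = 6000,
                           seed = 53, species = "simA")
  expect_equal(length(qa$fraction$runs), 3)
  expect_equal(nrow(qa$summary), 4) # 3 sublineages + unassigned
  expect_true(all(qa$summary$se >= 0 | is.na(qa$summary$se)))
  expect_equal(unique(qa$summary$species), "simA")
})
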