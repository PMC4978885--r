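test_that("family specs validate their invariants", {
  expect_error(family_spec("f", "gypsy", "A", 100, 1), "element_length")
  expect_error(family_spec("f", "weird", "A", 5000, 1), "superfamily")
  expect_error(family_spec("f", "gypsy", "A", 5000, 1,
                           copy_divergence = 0.6), "divergences")
  specs <- rbind(family_spec("f", "gypsy", "A", 5000, 1),
                 family_spec("f", "gypsy", "B", 5000, 1))
  expect_error(validate_family_specs(specs), "duplicate family_id: f")
})

test_that("reference panel elements carry identical terminal LTRs", {
  spec <- family_spec("fam1", "gypsy", "A", 4300, 5)
  panel <- simulate_reference_panel(spec, seed = 11)
  s <- panel$sequence
  expect_equal(nchar(s), 4300)
  expect_identical(substr(s, 1, 400), substr(s, 4300 - 399, 4300))
  # internal region is not a repeat of the LTR
  expect_false(substr(s, 401, 800) == substr(s, 1, 400))
})

test_that("a 40 gypsy + 12 copia spec set yields a 52-element panel", {
  specs <- example_family_specs()
  panel <- simulate_reference_panel(specs, seed = 1)
  expect_equal(nrow(panel), 52)
  expect_equal(sum(panel$superfamily == "gypsy"), 40)
  expect_equal(sum(panel$superfamily == "copia"), 12)
})

test_that("panel simulation is byte-reproducible per seed", {
  specs <- tiny_specs()
  p1 <- simulate_reference_panel(specs, seed = 7)
  p2 <- simulate_reference_panel(specs, seed = 7)
  p3 <- simulate_reference_panel(specs, seed = 8)
  expect_identical(p1, p2)
  expect_false(identical(p1$sequence, p3$sequence))
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(setNames(p1$sequence, p1$element_id), f1)
  write_fasta(setNames(p2$sequence, p2$element_id), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("genome truth table records exact inserted fractions", {
  panel <- simulate_reference_panel(tiny_specs(), seed = 2)

  zero <- tiny_specs(copies = 0)
  g0 <- simulate_species_genome(panel, zero, background_length = 5e4,
                                seed = 3)
  expect_equal(g0$truth_table$fraction, rep(0, 3))
  expect_equal(g0$background_fraction, 1.0)

  # one family, 20 copies x 5 kb into 400 kb background -> 0.2 exactly
  spec1 <- family_spec("f5k", "gypsy", "A", 5000, 20,
                       copy_divergence = 0, panel_divergence = 0)
  p1 <- simulate_reference_panel(spec1, seed = 4)
  g1 <- simulate_species_genome(p1, spec1, background_length = 4e5,
                                seed = 5)
  expect_equal(g1$length, 5e5)
  expect_equal(g1$truth_table$fraction, 0.2)
  expect_equal(sum(g1$truth_table$fraction) + g1$background_fraction, 1,
               tolerance = 1e-12)
  # conservation: recorded fractions match the copy coordinate table
  expect_equal(sum(g1$copy_table$end - g1$copy_table$start + 1) /
                 g1$length, 0.2)
})

test_that("inserted-copy divergence matches the substitution model", {
  # copies at divergence d from a consensus at rate d/2 each; exemplar
  # identity expected from two mutation rounds p1 (shared) and p2 (private):
  # P(differ) = p1 + p2 - (4/3) p1 p2
  spec <- family_spec("fd", "gypsy", "A", 2000, 100,
                      copy_divergence = 0.05, panel_divergence = 0.04)
  panel <- simulate_reference_panel(spec, seed = 6)
  g <- simulate_species_genome(panel, spec, background_length = 1e4,
                               seed = 7, max_repeat_fraction = 1)
  p1 <- 0.04 - 0.05 / 2
  p2 <- 0.05 / 2
  exp_diff <- p1 + p2 - (4 / 3) * p1 * p2
  # oracle: per-site comparison of each copy against the exemplar
  ex <- strsplit(panel$sequence, "")[[1]]
  diffs <- vapply(seq_len(nrow(g$copy_table)), function(i) {
    cp <- strsplit(substr(g$sequence, g$copy_table$start[i],
                          g$copy_table$end[i]), "")[[1]]
    mean(cp != ex)
  }, numeric(1))
  # the shared consensus stage is drawn once, so its sampling error does
  # not shrink with the number of copies
  se <- sqrt(p1 * (1 - p1) / 2000 + p2 * (1 - p2) / (2000 * 100))
  expect_lt(abs(mean(diffs) - exp_diff), 4 * se)
  # pairwise copy-copy divergence ~ copy_divergence
  pair_diff <- mean(strsplit(substr(g$sequence, g$copy_table$start[1],
                                    g$copy_table$end[1]), "")[[1]] !=
                      strsplit(substr(g$sequence, g$copy_table$start[2],
                                      g$copy_table$end[2]), "")[[1]])
  expect_lt(abs(pair_diff - 0.05), 0.015)
})

test_that("error-free reads are exact genome substrings", {
  panel <- simulate_reference_panel(tiny_specs(), seed = 8)
  g <- simulate_species_genome(panel, tiny_specs(copies = 2),
                               background_length = 3e4, seed = 9)
  reads <- simulate_reads(g, 200, error_rate = 0, seed = 10)
  for (i in seq_len(50)) {
    sub <- substr(g$sequence, reads$start[i], reads$start[i] + 99)
    if (reads$strand[i] == "-")
      sub <- as.character(ltrtracer:::cpp_revcomp(sub))
    expect_identical(reads$bases[i], sub)
  }
  # resampling with replacement allows n_reads >> genome size
  tiny <- simulate_reads(random_dna(150, seed = 1), 5000, seed = 11)
  expect_equal(nrow(tiny), 5000)
})

test_that("read origins follow the genomic family fractions", {
  spec <- family_spec("fr", "gypsy", "A", 5000, 20, 0, 0)
  panel <- simulate_reference_panel(spec, seed = 12)
  g <- simulate_species_genome(panel, spec, background_length = 4e5,
                               seed = 13)
  n <- 20000
  reads <- simulate_reads(g, n, error_rate = 0, seed = 14)
  in_fam <- mapply(function(s) {
    any(g$copy_table$start <= s & g$copy_table$end >= s)
  }, reads$start)
  p <- g$truth_table$fraction
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(in_fam) - p), 3 * se + 100 / g$length)
})

test_that("read simulation is deterministic and respects qualities", {
  g <- random_dna(5000, seed = 20)
  r1 <- simulate_reads(g, 100, seed = 21)
  r2 <- simulate_reads(g, 100, seed = 21)
  expect_identical(r1, r2)
  expect_true(all(nchar(r1$qualities) == 100))
  r3 <- simulate_reads(g, 10, quality_profile = c(rep(35, 50), rep(20, 50)),
                       seed = 22)
  q <- utf8ToInt(r3$qualities[1]) - 33L
  expect_equal(q, c(rep(35L, 50), rep(20L, 50)))
})

test_that("brownian traits honour the increment correlation", {
  tree <- ape::rtree(8, rooted = TRUE)
  # degenerate: perfectly correlated increments -> identical traits
  tr1 <- simulate_brownian_traits(tree, sigma = 1, true_correlation = 1,
                                  seed = 30)
  expect_equal(tr1[, "x"], tr1[, "y"], tolerance = 1e-12)
  expect_equal(pic_correlation(tree, tr1[, "x"], tr1[, "y"])$r, 1,
               tolerance = 1e-9)
  # sigma 0 -> all tips at the ancestral value, all contrasts zero
  tr0 <- simulate_brownian_traits(tree, sigma = 0, true_correlation = 0.5,
                                  seed = 31)
  expect_true(all(tr0 == 0))
  # missing branch lengths rejected
  bad <- tree; bad$edge.length <- NULL
  expect_error(simulate_brownian_traits(bad, seed = 1), "branch lengths")
})

test_that("uncorrelated brownian traits give mean PIC r near zero", {
  rs <- vapply(1:300, function(i) {
    tree <- ltrtracer:::with_seed(1000 + i, ape::rtree(6, rooted = TRUE))
    tr <- simulate_brownian_traits(tree, 1, 0, seed = 2000 + i)
    pic_correlation(tree, tr[, "x"], tr[, "y"])$r
  }, numeric(1))
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs)), 3 * se + 0.02)
})
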