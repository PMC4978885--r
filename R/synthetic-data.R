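#' Define simulated LTR retrotransposon family specifications
#'
#' A family specification describes one reference element (the family
#' exemplar) together with the number and divergence of its genomic copies.
#' `copy_divergence` is the expected pairwise substitution distance among
#' genomic copies of the family; `panel_divergence` is the expected
#' substitution distance between genomic copies and the panel exemplar.
#' Internally each copy is drawn from a family consensus mutated away from
#' the exemplar, so the requested `panel_divergence` is achieved whenever it
#' is at least `copy_divergence / 2`.
#'
#' @param family_id unique family label.
#' @param superfamily `"gypsy"` or `"copia"`.
#' @param sublineage sublineage label (e.g. `"A"`, `"X1"`, `"1"`).
#' @param element_length element length in bases (>= 200).
#' @param copies number of genomic copies (>= 0).
#' @param copy_divergence,panel_divergence substitutions per site, in
#'   `[0, 0.5)`.
#' @return a `data.frame` with one row per family.
#' @export
family_spec <- function(family_id, superfamily, sublineage, element_length,
                        copies, copy_divergence = 0.03,
                        panel_divergence = 0.02) {
  spec <- data.frame(
    family_id = as.character(family_id),
    superfamily = as.character(superfamily),
    sublineage = as.character(sublineage),
    element_length = as.integer(element_length),
    copies = as.integer(copies),
    copy_divergence = as.numeric(copy_divergence),
    panel_divergence = as.numeric(panel_divergence),
    stringsAsFactors = FALSE
  )
  validate_family_specs(spec)
}

#' Validate a family specification table
#'
#' @param specs data.frame as produced by [family_spec()] (rows may be
#'   concatenated with `rbind`).
#' @return `specs`, invisibly validated.
#' @export
validate_family_specs <- function(specs) {
  req <- c("family_id", "superfamily", "sublineage", "element_length",
           "copies", "copy_divergence", "panel_divergence")
  miss <- setdiff(req, names(specs))
  if (length(miss))
    stop("family specs missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(specs) == 0) stop("family specs are empty", call. = FALSE)
  dup <- specs$family_id[duplicated(specs$family_id)]
  if (length(dup))
    stop("duplicate family_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (!all(specs$superfamily %in% c("gypsy", "copia")))
    stop("superfamily must be 'gypsy' or 'copia'", call. = FALSE)
  if (any(specs$element_length < 200))
    stop("element_length must be >= 200", call. = FALSE)
  if (any(specs$copies < 0)) stop("copies must be >= 0", call. = FALSE)
  dv <- c(specs$copy_divergence, specs$panel_divergence)
  if (any(dv < 0 | dv >= 0.5))
    stop("divergences must lie in [0, 0.5)", call. = FALSE)
  specs
}

#' Study-like default family specifications
#'
#' A compact panel patterned on the composition of the sunflower reference
#' panel: gypsy sublineages A, B, C, X1, X2, E', Y1, Y2, Z1, Z2 (four
#' exemplars each, 40 elements) and copia sublineages 1-7 (12 elements).
#' Element lengths span 4.3-16.2 kb, the range implied by 281-1073 tracer
#' kmers per element at k = 100, step = 15.  With `small = TRUE` a reduced
#' panel (3 gypsy + 2 copia sublineages, one exemplar each) suitable for
#' fast desk-scale simulation is returned.
#'
#' @param small logical; return the reduced panel.
#' @param copies copies per family in simulated genomes (recycled).
#' @param copy_divergence,panel_divergence divergence defaults applied to
#'   every family.
#' @return a family specification `data.frame`.
#' @export
example_family_specs <- function(small = FALSE, copies = 20,
                                 copy_divergence = 0.03,
                                 panel_divergence = 0.02) {
  if (small) {
    sub <- data.frame(
      superfamily = c("gypsy", "gypsy", "gypsy", "copia", "copia"),
      sublineage = c("A", "C", "X1", "1", "3"),
      element_length = c(5200L, 4300L, 6100L, 4800L, 5500L),
      stringsAsFactors = FALSE
    )
    n_per <- 1L
  } else {
    gy <- c("A", "B", "C", "X1", "X2", "E'", "Y1", "Y2", "Z1", "Z2")
    co <- as.character(1:7)
    sub <- rbind(
      data.frame(superfamily = "gypsy", sublineage = rep(gy, each = 4),
                 stringsAsFactors = FALSE),
      data.frame(superfamily = "copia",
                 sublineage = co[c(1, 1, 2, 3, 3, 4, 5, 6, 7, 7, 2, 5)],
                 stringsAsFactors = FALSE)
    )
    # deterministic spread of element lengths across the observed range
    sub$element_length <-
      as.integer(round(seq(4300, 16180, length.out = nrow(sub))))
    n_per <- 1L
  }
  specs <- data.frame(
    family_id = paste0(substr(sub$superfamily, 1, 1), "_", sub$sublineage,
                       "_", stats::ave(seq_len(nrow(sub)),
                                       sub$superfamily, sub$sublineage,
                                       FUN = seq_along)),
    superfamily = sub$superfamily,
    sublineage = sub$sublineage,
    element_length = sub$element_length,
    copies = rep_len(as.integer(copies), nrow(sub)),
    copy_divergence = copy_divergence,
    panel_divergence = panel_divergence,
    stringsAsFactors = FALSE
  )
  validate_family_specs(specs)
}

#' Simulate a reference panel of full-length LTR retrotransposons
#'
#' One element per specification, of the requested length, with two
#' identical terminal direct repeats (the LTRs) flanking a random internal
#' region.  The LTR length is `min(400, floor(element_length / 4))` unless
#' overridden.
#'
#' @param specs family specification table ([family_spec()]).
#' @param seed integer seed; the same seed yields byte-identical panels.
#' @param ltr_length optional fixed LTR length in bases.
#' @return data.frame with columns `element_id`, `superfamily`,
#'   `sublineage`, `sequence`.
#' @export
simulate_reference_panel <- function(specs, seed = 1, ltr_length = NULL) {
  specs <- validate_family_specs(specs)
  with_seed(seed, {
    seqs <- character(nrow(specs))
    for (i in seq_len(nrow(specs))) {
      L <- specs$element_length[i]
      ltr <- if (is.null(ltr_length)) min(400L, L %/% 4L)
             else as.integer(ltr_length)
      if (2L * ltr > L) stop("LTRs longer than the element", call. = FALSE)
      ltr_seq <- cpp_random_dna(ltr)
      internal <- cpp_random_dna(L - 2L * ltr)
      seqs[i] <- paste0(ltr_seq, internal, ltr_seq)
    }
    data.frame(
      element_id = specs$family_id,
      superfamily = specs$superfamily,
      sublineage = specs$sublineage,
      sequence = seqs,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a species genome with known TE family composition
#'
#' A uniform-random background sequence receives `copies` mutated copies of
#' each family's exemplar at uniform random positions.  Each family has a
#' species consensus mutated away from the exemplar by
#' `max(0, panel_divergence - copy_divergence / 2)` substitutions per site;
#' copies are then mutated independently from the consensus at
#' `copy_divergence / 2`, giving the requested expected pairwise divergence
#' among copies.  The truth table records the exact fraction of genome
#' bases contributed by each family.
#'
#' @param panel reference panel ([simulate_reference_panel()] or
#'   [load_panel()]).
#' @param specs family specification table; every `family_id` must be a
#'   panel `element_id`.
#' @param background_length background (non-repetitive) bases.
#' @param seed integer seed.
#' @param max_repeat_fraction reject scenarios whose inserted bases exceed
#'   this fraction of the final genome.
#' @return an object of class `sim_genome`: a list with `sequence`,
#'   `truth_table` (family_id, superfamily, sublineage, bases, fraction),
#'   `background_fraction`, `copy_table` (coordinates of each inserted
#'   copy), and `length`.
#' @export
simulate_species_genome <- function(panel, specs, background_length = 5e5,
                                    seed = 1, max_repeat_fraction = 0.95) {
  specs <- validate_family_specs(specs)
  missing <- setdiff(specs$family_id, panel$element_id)
  if (length(missing))
    stop("specs reference families absent from the panel: ",
         paste(missing, collapse = ", "), call. = FALSE)
  assert_scalar_number(background_length, "background_length", min = 1)

  total_insert <- sum(as.numeric(specs$copies) *
                        nchar(panel$sequence[match(specs$family_id,
                                                   panel$element_id)]))
  genome_len <- background_length + total_insert
  if (total_insert / genome_len > max_repeat_fraction)
    stop(sprintf(
      "inserted bases (%.0f) exceed %.0f%% of the genome; raise background_length or max_repeat_fraction",
      total_insert, 100 * max_repeat_fraction), call. = FALSE)

  with_seed(seed, {
    background <- cpp_random_dna(as.integer(background_length))
    ins_seq <- character(0)
    ins_fam <- character(0)
    for (i in seq_len(nrow(specs))) {
      n <- specs$copies[i]
      if (n == 0) next
      exemplar <- panel$sequence[match(specs$family_id[i], panel$element_id)]
      shared <- max(0, specs$panel_divergence[i] -
                       specs$copy_divergence[i] / 2)
      consensus <- cpp_mutate_seq(exemplar, shared)
      copies <- vapply(seq_len(n), function(j)
        cpp_mutate_seq(consensus, specs$copy_divergence[i] / 2),
        character(1))
      ins_seq <- c(ins_seq, copies)
      ins_fam <- c(ins_fam, rep(specs$family_id[i], n))
    }

    n_ins <- length(ins_seq)
    if (n_ins > 0) {
      # insertion points in the background, assembled left to right
      pts <- sort(sample.int(as.integer(background_length) + 1L, n_ins,
                             replace = TRUE) - 1L)
      ord <- sample.int(n_ins) # which copy goes at which point
      pieces <- character(2L * n_ins + 1L)
      fam_at <- ins_fam[ord]
      seq_at <- ins_seq[ord]
      starts <- integer(n_ins)
      pos <- 0L; prev <- 0L
      for (j in seq_len(n_ins)) {
        bg_piece <- substr(background, prev + 1L, pts[j])
        pieces[2L * j - 1L] <- bg_piece
        pos <- pos + nchar(bg_piece)
        starts[j] <- pos + 1L
        pieces[2L * j] <- seq_at[j]
        pos <- pos + nchar(seq_at[j])
        prev <- pts[j]
      }
      pieces[2L * n_ins + 1L] <-
        substr(background, prev + 1L, nchar(background))
      genome <- paste(pieces, collapse = "")
      copy_table <- data.frame(
        family_id = fam_at, start = starts,
        end = starts + nchar(seq_at) - 1L, stringsAsFactors = FALSE)
    } else {
      genome <- background
      copy_table <- data.frame(family_id = character(0), start = integer(0),
                               end = integer(0), stringsAsFactors = FALSE)
    }

    fam_bases <- vapply(specs$family_id, function(f)
      sum(as.numeric(copy_table$end[copy_table$family_id == f] -
                       copy_table$start[copy_table$family_id == f] + 1L)),
      numeric(1))
    G <- nchar(genome)
    truth <- data.frame(
      family_id = specs$family_id,
      superfamily = specs$superfamily,
      sublineage = specs$sublineage,
      bases = fam_bases,
      fraction = fam_bases / G,
      stringsAsFactors = FALSE
    )
    structure(list(
      sequence = genome,
      truth_table = truth,
      background_fraction = 1 - sum(truth$fraction),
      copy_table = copy_table,
      length = G
    ), class = "sim_genome")
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %s bases, %d families, repeat fraction %.3f\n",
              format(x$length, big.mark = ","), nrow(x$truth_table),
              1 - x$background_fraction))
  invisible(x)
}

#' Simulate uniform single-end reads from a genome
#'
#' Start positions are uniform over the genome (sampling with replacement),
#' strand is chosen uniformly, and each base is substituted with
#' probability `error_rate`.  Quality strings are generated from
#' `quality_profile` (per-position Phred scores, recycled to the read
#' length).
#'
#' @param genome a `sim_genome` or a single sequence string.
#' @param n_reads number of reads.
#' @param read_length read length in bases (default 100).
#' @param error_rate per-base substitution error probability.
#' @param quality_profile per-position mean Phred quality (default a flat
#'   Q38).
#' @param seed integer seed.
#' @param prefix read identifier prefix.
#' @return data.frame with `read_id`, `bases`, `qualities`, `start`
#'   (1-based origin), `strand`.
#' @export
simulate_reads <- function(genome, n_reads, read_length = 100,
                           error_rate = 0.001, quality_profile = NULL,
                           seed = 1, prefix = "r") {
  seqstr <- if (inherits(genome, "sim_genome")) genome$sequence else genome
  stopifnot(is.character(seqstr), length(seqstr) == 1)
  assert_scalar_number(read_length, "read_length", min = 1)
  assert_scalar_number(error_rate, "error_rate", min = 0, max = 1 - 1e-12)
  if (nchar(seqstr) < read_length)
    stop("genome shorter than read_length", call. = FALSE)
  qp <- rep_len(as.integer(quality_profile %||% 38L), read_length)
  qual <- rawToChar(as.raw(pmin(93L, pmax(0L, qp)) + 33L))
  with_seed(seed, {
    sim <- cpp_simulate_reads(seqstr, as.integer(n_reads),
                              as.integer(read_length), error_rate)
    data.frame(
      read_id = sprintf("%s%07d", prefix, seq_len(n_reads)),
      bases = as.character(sim$bases),
      qualities = qual,
      start = sim$start,
      strand = as.character(sim$strand),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate correlated Brownian-motion traits on a tree
#'
#' Two traits evolve along the tree under Brownian motion with variance
#' rate `sigma` per unit branch length; the per-branch increments of the
#' two traits have correlation `true_correlation`.  Used to validate the
#' phylogenetically independent contrasts machinery by parameter recovery.
#'
#' @param tree an `ape::phylo` tree with positive branch lengths.
#' @param sigma Brownian variance rate (>= 0).
#' @param true_correlation correlation of trait increments, in `[-1, 1]`.
#' @param seed integer seed.
#' @param root_value length-2 ancestral value.
#' @return numeric matrix (tips x 2) with tip labels as row names.
#' @export
simulate_brownian_traits <- function(tree, sigma = 1, true_correlation = 0,
                                     seed = 1, root_value = c(0, 0)) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object",
                                     call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths", call. = FALSE)
  if (any(tree$edge.length <= 0))
    stop("all branch lengths must be > 0", call. = FALSE)
  assert_scalar_number(sigma, "sigma", min = 0)
  assert_scalar_number(true_correlation, "true_correlation", -1, 1)
  rho <- true_correlation
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "cladewise")
  nnode <- tree$Nnode
  vals <- matrix(NA_real_, ntip + nnode, 2)
  root <- ntip + 1L
  vals[root, ] <- root_value
  with_seed(seed, {
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      s <- sqrt(sigma * tree$edge.length[e])
      z1 <- rnorm(1); z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * rnorm(1)
      vals[child, ] <- vals[par, ] + s * c(z1, z2)
    }
  })
  out <- vals[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  colnames(out) <- c("x", "y")
  out
}
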