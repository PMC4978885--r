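#' Read-mapping policy
#'
#' @param max_mismatches allowed mismatches per 100 aligned bases;
#'   3 is the stringent default, 6 a relaxed setting.
#' @param min_aligned_frac fraction of the read that must align within a
#'   panel element (default 1: full-length, ungapped).
#' @return a `mapping_policy` list.
#' @export
mapping_policy <- function(max_mismatches = 3, min_aligned_frac = 1) {
  assert_scalar_number(max_mismatches, "max_mismatches", min = 0)
  assert_scalar_number(min_aligned_frac, "min_aligned_frac", min = 0.05,
                       max = 1)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 min_aligned_frac = min_aligned_frac),
            class = "mapping_policy")
}

#' Map reads to the reference panel by mismatch counting
#'
#' The read-mapping alternative to tracer clustering: each read is placed
#' ungapped, at every exact seed-kmer match against the panel (both
#' strands), and assigned to the element with the fewest mismatches,
#' provided the aligned region covers `min_aligned_frac` of the read and
#' mismatches stay within `max_mismatches` per 100 aligned bases.  The
#' seed size is derived from the policy so that any placement within the
#' mismatch budget is guaranteed to contain an exact seed.
#'
#' @param reads reads data.frame.
#' @param panel reference panel data.frame (with `element_id`,
#'   `superfamily`, `sublineage`, `sequence`).
#' @param policy a [mapping_policy()].
#' @param seed_k optional explicit seed size (4-32).
#' @return an object of class `mapping_result`: list with `density`
#'   (assigned reads / total reads), `per_sublineage` densities,
#'   `assignments`, `n_reads` and the policy.
#' @export
map_reads_to_panel <- function(reads, panel, policy = mapping_policy(),
                               seed_k = NULL) {
  check_reads_df(reads)
  stopifnot(is.data.frame(panel), nrow(panel) > 0)
  L <- min(nchar(reads$bases))
  alen_min <- ceiling(policy$min_aligned_frac * L)
  allowed <- floor(policy$max_mismatches * alen_min / 100)
  k_guar <- if (allowed == 0) min(alen_min, 31L)
            else floor((alen_min - allowed) / (allowed + 1))
  k <- as.integer(seed_k %||% max(8L, min(31L, k_guar)))
  if (k > k_guar)
    warning("seed_k exceeds the guaranteed exact-seed length; ",
            "some valid placements may be missed")
  hit <- cpp_map_reads(toupper(reads$bases), toupper(panel$sequence),
                       policy$max_mismatches, policy$min_aligned_frac, k)
  assigned <- hit > 0
  assignments <- data.frame(
    read_id = reads$read_id,
    element_id = ifelse(assigned, panel$element_id[hit], NA_character_),
    superfamily = ifelse(assigned, panel$superfamily[hit], NA_character_),
    sublineage = ifelse(assigned, panel$sublineage[hit], NA_character_),
    stringsAsFactors = FALSE
  )
  lev <- unique(panel[, c("superfamily", "sublineage")])
  lev <- lev[order(lev$superfamily, lev$sublineage), , drop = FALSE]
  per <- data.frame(
    lev,
    density = vapply(seq_len(nrow(lev)), function(i)
      sum(assigned & assignments$superfamily == lev$superfamily[i] &
            assignments$sublineage == lev$sublineage[i]) / nrow(reads),
      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(density = mean(assigned), per_sublineage = per,
                 assignments = assignments, n_reads = nrow(reads),
                 policy = policy, seed_k = k),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf(
    "mapping_result: %.4f of %d reads assigned (<= %d mismatches/100)\n",
    x$density, x$n_reads, x$policy$max_mismatches))
  invisible(x)
}

#' Divergence-bias assay: clustering vs read mapping
#'
#' For each divergence level d, a genome is simulated whose TE copies
#' diverge from the reference panel by d at a fixed true abundance, reads
#' are drawn, and the TE-assigned read density is estimated twice: by
#' tracer clustering (reads in qualifying tracer-annotated clusters) and by
#' mismatch-counting read mapping.  The Spearman rank correlation of
#' density against divergence is reported per method and per seed: mapping
#' density falls with divergence while clustering density stays flat, the
#' qualitative contrast between the two approaches.
#'
#' @param specs family specification table; `panel_divergence` is
#'   overwritten by the grid, all else (copies, lengths) stays fixed.
#' @param divergence_grid ascending substitutions-per-site levels; rank
#'   correlations need >= 4 levels.  The default spans 0-0.08: beyond ~0.10
#'   the 90% identity rule itself stops read-tracer edges forming, so the
#'   flat-density behaviour of clustering is only defined below that.
#' @param n_seeds independent replicate seeds (default 5).
#' @param n_reads reads simulated per genome.
#' @param background_length background bases per genome.
#' @param seed base seed.
#' @param policy mapping policy (stringent 3/100 by default; pass
#'   `mapping_policy(6)` for the relaxed contrast).
#' @param copy_divergence within-species copy divergence (kept small: the
#'   assay varies distance to the panel, not copy age).
#' @param min_identity,min_overlap_frac,min_cluster_frac clustering
#'   parameters.
#' @return an object of class `bias_curve`: `curve` (seed, divergence,
#'   method, density), `rho` (per seed and method), `summary` (mean rho per
#'   method).
#' @export
divergence_bias_assay <- function(specs,
                                  divergence_grid = c(0, 0.02, 0.04, 0.06,
                                                      0.08),
                                  n_seeds = 5, n_reads = 4000,
                                  background_length = 3e5, seed = 1,
                                  policy = mapping_policy(),
                                  copy_divergence = 0.01,
                                  min_identity = 0.90,
                                  min_overlap_frac = 0.55,
                                  min_cluster_frac = 1e-4) {
  specs <- validate_family_specs(specs)
  if (is.unsorted(divergence_grid))
    stop("divergence_grid must be ascending", call. = FALSE)
  panel <- simulate_reference_panel(specs, seed = seed)
  tracers <- kmerize_panel(panel)$tracers

  rows <- list()
  for (s in seq_len(n_seeds)) {
    for (d in divergence_grid) {
      sp <- specs
      sp$panel_divergence <- d
      sp$copy_divergence <- copy_divergence
      gseed <- seed + 1000L * s + round(10000 * d)
      genome <- simulate_species_genome(panel, sp, background_length,
                                        seed = gseed)
      reads <- simulate_reads(genome, n_reads, seed = gseed + 1L)

      cl <- cluster_sequences(reads, tracers, min_identity,
                              min_overlap_frac)
      prof <- sublineage_profile(cl, nrow(reads),
                                 min_cluster_frac = min_cluster_frac)
      clust_density <- sum(prof$proportion[prof$superfamily %in%
                                             c("gypsy", "copia")])
      map <- map_reads_to_panel(reads, panel, policy)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, divergence = d,
        method = c("clustering", "mapping"),
        density = c(clust_density, map$density),
        stringsAsFactors = FALSE)
    }
  }
  curve <- do.call(rbind, rows)

  rho <- NULL
  if (length(divergence_grid) >= 4) {
    combos <- expand.grid(seed = seq_len(n_seeds),
                          method = c("clustering", "mapping"),
                          stringsAsFactors = FALSE)
    rho <- data.frame(combos, rho = vapply(seq_len(nrow(combos)),
      function(i) {
        sub <- curve[curve$seed == combos$seed[i] &
                       curve$method == combos$method[i], ]
        suppressWarnings(stats::cor(sub$divergence, sub$density,
                                    method = "spearman"))
      }, numeric(1)))
  }
  summary <- if (!is.null(rho))
    stats::aggregate(rho ~ method, rho, mean) else NULL
  structure(list(curve = curve, rho = rho, summary = summary,
                 divergence_grid = divergence_grid, policy = policy),
            class = "bias_curve")
}

#' @export
print.bias_curve <- function(x, ...) {
  cat("divergence-bias assay\n")
  if (!is.null(x$summary)) {
    for (i in seq_len(nrow(x$summary)))
      cat(sprintf("  mean Spearman rho (%s): %.3f\n",
                  x$summary$method[i], x$summary$rho[i]))
  }
  invisible(x)
}
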