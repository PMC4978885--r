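#' Annotate clusters by their tracer content
#'
#' Each cluster is assigned the sublineage holding the majority of its
#' tracer kmers (ties broken by the lexicographically smallest label); its
#' superfamily is that sublineage's superfamily.  Clusters whose top
#' sublineage holds less than `purity_threshold` of the tracers, or whose
#' tracers mix superfamilies, are flagged ambiguous (mixed-superfamily
#' clusters are always flagged, so chaining artefacts stay visible).
#' Clusters without tracers are unassigned repeats.
#'
#' @param clusters a `repeat_clusters` object produced with a tracer table.
#' @param purity_threshold flag clusters whose top sublineage holds less
#'   than this fraction of tracers (default 0.8).
#' @return data.frame with `cluster_id`, `superfamily`, `sublineage`,
#'   `tracer_total`, `top_share`, `ambiguity_flag`.
#' @export
annotate_clusters <- function(clusters, purity_threshold = 0.8) {
  stopifnot(inherits(clusters, "repeat_clusters"))
  cl <- clusters$clusters
  out <- data.frame(
    cluster_id = cl$cluster_id,
    superfamily = "unassigned",
    sublineage = "unassigned",
    tracer_total = cl$tracer_total,
    top_share = NA_real_,
    ambiguity_flag = FALSE,
    stringsAsFactors = FALSE
  )
  tc <- clusters$tracer_counts
  if (is.null(tc) || nrow(tc) == 0) return(out)
  for (cid in unique(tc$cluster_id)) {
    rows <- tc[tc$cluster_id == cid, , drop = FALSE]
    rows <- rows[order(-rows$n_tracers, rows$sublineage), , drop = FALSE]
    total <- sum(rows$n_tracers)
    i <- match(cid, out$cluster_id)
    out$superfamily[i] <- rows$superfamily[1]
    out$sublineage[i] <- rows$sublineage[1]
    out$top_share[i] <- rows$n_tracers[1] / total
    mixed_sf <- length(unique(rows$superfamily)) > 1
    out$ambiguity_flag[i] <- mixed_sf ||
      (rows$n_tracers[1] / total < purity_threshold)
  }
  out
}

#' Per-sublineage genome-proportion profile
#'
#' For every sublineage, the proportion of sampled reads lying in
#' qualifying clusters (read count >= the minimum cluster size) annotated
#' to that sublineage; qualifying clusters without tracers contribute to an
#' `unassigned` row.  The sum of all rows equals the repetitive fraction of
#' the same run exactly.  Sublineages present in the tracer set but absent
#' from every cluster appear with proportion 0, so replicate profiles
#' always share one sublineage set.
#'
#' @param clusters a `repeat_clusters` object.
#' @param n_sampled reads that entered clustering (tracers excluded).
#' @param annotations optional precomputed [annotate_clusters()] output.
#' @param min_cluster_frac,min_cluster_size threshold rule, as in
#'   [repetitive_fraction()].
#' @param species optional species label stored with the profile.
#' @return an object of class `sublineage_profile`: data.frame with
#'   `species`, `superfamily`, `sublineage`, `read_count`, `n_clusters`,
#'   `proportion`; attributes `n_sampled`, `min_cluster_size`,
#'   `repetitive_fraction`.
#' @export
sublineage_profile <- function(clusters, n_sampled, annotations = NULL,
                               min_cluster_frac = 1e-4,
                               min_cluster_size = NULL,
                               species = NA_character_) {
  stopifnot(inherits(clusters, "repeat_clusters"))
  if (!is.numeric(n_sampled) || length(n_sampled) != 1 || n_sampled <= 0)
    stop("n_sampled must be a positive count", call. = FALSE)
  ann <- annotations %||% annotate_clusters(clusters)
  mcs <- as.integer(min_cluster_size %||% ceiling(min_cluster_frac *
                                                    n_sampled))
  cl <- clusters$clusters
  qual <- cl$read_count >= mcs

  levels <- clusters$sublineage_levels
  if (is.null(levels))
    levels <- unique(ann[ann$sublineage != "unassigned",
                         c("superfamily", "sublineage")])
  levels <- rbind(levels,
                  data.frame(superfamily = "unassigned",
                             sublineage = "unassigned",
                             stringsAsFactors = FALSE))

  key <- paste(ann$superfamily, ann$sublineage, sep = "\r")
  lev_key <- paste(levels$superfamily, levels$sublineage, sep = "\r")
  reads_by <- vapply(lev_key, function(kk)
    sum(cl$read_count[qual & key == kk]), numeric(1))
  nclust_by <- vapply(lev_key, function(kk)
    sum(qual & key == kk), numeric(1))

  out <- data.frame(
    species = species,
    superfamily = levels$superfamily,
    sublineage = levels$sublineage,
    read_count = as.integer(reads_by),
    n_clusters = as.integer(nclust_by),
    proportion = reads_by / n_sampled,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("sublineage_profile", "data.frame"),
            n_sampled = as.integer(n_sampled), min_cluster_size = mcs,
            repetitive_fraction = sum(out$proportion))
}

#' Gypsy-to-copia abundance ratio
#'
#' @param profile a `sublineage_profile`.
#' @return the fold ratio of summed gypsy to summed copia proportions;
#'   `NA` with a warning when the copia total is zero.
#' @export
superfamily_ratio <- function(profile) {
  g <- sum(profile$proportion[profile$superfamily == "gypsy"])
  c_ <- sum(profile$proportion[profile$superfamily == "copia"])
  if (c_ == 0) {
    warning("copia total is zero; ratio undefined")
    return(NA_real_)
  }
  g / c_
}

#' Aggregate replicate sublineage profiles
#'
#' @param profiles list of `sublineage_profile` objects (>= 2) sharing one
#'   sublineage set.
#' @return data.frame with per-sublineage `mean`, `se` (sd / sqrt(n)) and
#'   `n_runs`.
#' @export
aggregate_replicates <- function(profiles) {
  if (length(profiles) < 2)
    stop("need at least 2 replicate profiles", call. = FALSE)
  keys <- lapply(profiles, function(p)
    paste(p$superfamily, p$sublineage, sep = "\r"))
  for (i in seq_along(keys)[-1])
    if (!identical(sort(keys[[1]]), sort(keys[[i]])))
      stop("replicate profiles have mismatched sublineage sets",
           call. = FALSE)
  base <- profiles[[1]][, c("species", "superfamily", "sublineage")]
  mat <- vapply(profiles, function(p)
    p$proportion[match(keys[[1]], paste(p$superfamily, p$sublineage,
                                        sep = "\r"))],
    numeric(nrow(base)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  data.frame(
    base,
    mean = rowMeans(mat),
    se = apply(mat, 1, se_mean),
    n_runs = length(profiles),
    stringsAsFactors = FALSE
  )
}

#' Replicated abundance quantification
#'
#' The full per-species estimation procedure: `n_runs` times, sample
#' `n_per_run` reads, cluster them jointly with the tracer kmers, estimate
#' the repetitive fraction and the per-sublineage profile, then aggregate
#' replicates into mean +/- SE.
#'
#' @param reads full read set for one species.
#' @param tracers tracer table ([kmerize_panel()]`$tracers`).
#' @param n_runs replicate clustering runs (default 5).
#' @param n_per_run reads sampled per run (default 3e6).
#' @param seed base seed (run i uses `seed + i - 1`).
#' @param species species label.
#' @param min_identity,min_overlap_frac,min_cluster_frac parameters as in
#'   [cluster_sequences()] and [repetitive_fraction()].
#' @return list with `summary` (aggregated mean +/- SE per sublineage),
#'   `profiles` (per-run), `fraction` (mean, se, runs), `species`.
#' @export
quantify_abundance <- function(reads, tracers, n_runs = 5, n_per_run = 3e6,
                               seed = 1, species = NA_character_,
                               min_identity = 0.90, min_overlap_frac = 0.55,
                               min_cluster_frac = 1e-4) {
  check_reads_df(reads)
  seeds <- seed + seq_len(n_runs) - 1
  profiles <- vector("list", n_runs)
  fractions <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    smp <- sample_reads(reads, n_per_run, seed = seeds[i])
    cl <- cluster_sequences(smp, tracers, min_identity, min_overlap_frac)
    profiles[[i]] <- sublineage_profile(cl, nrow(smp),
                                        min_cluster_frac = min_cluster_frac,
                                        species = species)
    fractions[i] <- attr(profiles[[i]], "repetitive_fraction")
  }
  summary <- if (n_runs >= 2) aggregate_replicates(profiles)
             else cbind(profiles[[1]][, c("species", "superfamily",
                                          "sublineage")],
                        mean = profiles[[1]]$proportion, se = NA_real_,
                        n_runs = 1L)
  list(summary = summary, profiles = profiles,
       fraction = list(mean = mean(fractions), se = se_mean(fractions),
                       runs = fractions),
       species = species, seeds = seeds)
}
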