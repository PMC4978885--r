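#' Similarity of one sequence pair under the clustering rule
#'
#' Computes the best overlap (free end-gap) alignment of `a` against `b`
#' and against the reverse complement of `b` (match +1, mismatch -2, gap
#' -3) and reports an edge when the optimal alignment reaches
#' `min_identity` over at least `min_overlap_frac` of the shorter
#' sequence.  Identity is matches divided by alignment columns, internal
#' gap columns included.
#'
#' @param a,b nucleotide strings (>= 20 bases).
#' @param min_identity minimum identity (default 0.90).
#' @param min_overlap_frac minimum overlap as a fraction of the shorter
#'   sequence (default 0.55).
#' @return `NULL` when the pair forms no edge, otherwise a list with
#'   `identity`, `overlap` (aligned columns), `score` and `strand`.
#' @export
pair_similarity <- function(a, b, min_identity = 0.90,
                            min_overlap_frac = 0.55) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1, length(b) == 1)
  if (nchar(a) < 20 || nchar(b) < 20)
    stop("sequences must be at least 20 bases", call. = FALSE)
  r <- cpp_pair_similarity(toupper(a), toupper(b), min_identity,
                           min_overlap_frac)
  if (!isTRUE(r$edge)) return(NULL)
  r[c("identity", "overlap", "score", "strand")]
}

#' Build the all-by-all similarity graph
#'
#' Every unordered pair is tested with [pair_similarity()].  A shared-kmer
#' prescreen (canonical 8-mers) can skip pairs that cannot meet the
#' thresholds: pigeonhole over the matched runs of the optimal alignment
#' guarantees that any pair with identity >= 0.90 over >= 55% of the
#' shorter sequence shares at least 5 exact 8-mers when all sequences are
#' >= 100 bases (4 at >= 92, 3 at >= 80), so the prescreened graph equals
#' the brute-force graph.  The prescreen is only applied automatically when
#' all sequences are >= 80 bases.
#'
#' @param sequences named character vector (unique names are the sequence
#'   ids).
#' @param min_identity,min_overlap_frac edge thresholds (defaults 0.90 and
#'   0.55).
#' @param prefilter `"auto"` (default), `"shared-kmer"`, or `"none"`.
#' @return an object of class `similarity_graph`: list with `ids` and
#'   `edges` (`id_a`, `id_b`, `identity`, `overlap`, `strand`).
#' @export
build_similarity_graph <- function(sequences, min_identity = 0.90,
                                   min_overlap_frac = 0.55,
                                   prefilter = c("auto", "shared-kmer",
                                                 "none")) {
  prefilter <- match.arg(prefilter)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names", call. = FALSE)
  seqs <- toupper(sequences)
  use_pf <- switch(prefilter,
                   "auto" = min(nchar(seqs)) >= 80,
                   "shared-kmer" = TRUE,
                   "none" = FALSE)
  ed <- cpp_all_pair_edges(unname(seqs), min_identity, min_overlap_frac,
                           use_pf, 8L,
                           if (use_pf) prescreen_min_shared(seqs) else 3L)
  edges <- data.frame(
    id_a = names(seqs)[ed$i],
    id_b = names(seqs)[ed$j],
    identity = ed$identity,
    overlap = ed$overlap,
    strand = ed$strand,
    stringsAsFactors = FALSE
  )
  structure(list(ids = names(seqs), edges = edges,
                 min_identity = min_identity,
                 min_overlap_frac = min_overlap_frac),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph: %d sequences, %d edges\n",
              length(x$ids), nrow(x$edges)))
  invisible(x)
}

# Guaranteed minimum number of shared canonical 8-mers (counted as
# sum over kmer values of min multiplicity) for any pair meeting
# identity >= 0.90 over >= 0.55 * min length: pigeonhole over the matched
# runs of the optimal alignment gives >= 5 when all sequences are >= 100
# bases, >= 4 at >= 92, >= 3 at >= 80.  Below 80 bases no useful bound
# exists and the prescreen may drop edges (warned).
prescreen_min_shared <- function(seqs) {
  if (!length(seqs)) return(3L)
  minlen <- min(nchar(seqs))
  if (minlen < 80)
    warning("sequences shorter than 80 bases weaken the shared-kmer ",
            "prescreen guarantee")
  if (minlen >= 100) 5L else if (minlen >= 92) 4L else 3L
}

# Shared builder: component labels -> ordered repeat_clusters object.
# Clusters are ordered by decreasing size, ties by the lexicographically
# smallest member id, and labelled CL0001, CL0002, ...
make_clusters <- function(ids, labels, tracers = NULL) {
  is_tracer <- if (is.null(tracers)) rep(FALSE, length(ids))
               else ids %in% tracers$tracer_id
  comp <- split(seq_along(ids), labels)
  sizes <- lengths(comp)
  firsts <- vapply(comp, function(ix) min(ids[ix]), character(1))
  ord <- order(-sizes, firsts)
  comp <- comp[ord]

  cluster_id <- sprintf("CL%05d", seq_along(comp))
  membership <- data.frame(
    seq_id = unlist(lapply(comp, function(ix) sort(ids[ix])),
                    use.names = FALSE),
    cluster_id = rep(cluster_id, lengths(comp)),
    stringsAsFactors = FALSE
  )
  membership$is_tracer <- membership$seq_id %in%
    if (is.null(tracers)) character(0) else tracers$tracer_id

  n_tracer <- vapply(split(membership$is_tracer, membership$cluster_id)
                     [cluster_id], sum, numeric(1))
  size <- lengths(comp)
  clusters <- data.frame(
    cluster_id = cluster_id,
    size = as.integer(size),
    read_count = as.integer(size - n_tracer),
    tracer_total = as.integer(n_tracer),
    stringsAsFactors = FALSE
  )

  tracer_counts <- NULL
  sublineage_levels <- NULL
  if (!is.null(tracers)) {
    tm <- membership[membership$is_tracer, , drop = FALSE]
    if (nrow(tm) > 0) {
      ti <- match(tm$seq_id, tracers$tracer_id)
      tc <- as.data.frame(table(
        cluster_id = tm$cluster_id,
        superfamily = tracers$superfamily[ti],
        sublineage = tracers$sublineage[ti]), stringsAsFactors = FALSE)
      tc <- tc[tc$Freq > 0, , drop = FALSE]
      names(tc)[names(tc) == "Freq"] <- "n_tracers"
      # keep only superfamily x sublineage pairs that exist in the tracer set
      key <- paste(tc$superfamily, tc$sublineage)
      valid <- unique(paste(tracers$superfamily, tracers$sublineage))
      tc <- tc[key %in% valid, , drop = FALSE]
      tc <- tc[order(tc$cluster_id, tc$superfamily, tc$sublineage), ,
               drop = FALSE]
      rownames(tc) <- NULL
    } else {
      tc <- data.frame(cluster_id = character(0),
                       superfamily = character(0),
                       sublineage = character(0),
                       n_tracers = integer(0), stringsAsFactors = FALSE)
    }
    tracer_counts <- tc
    sublineage_levels <- unique(tracers[, c("superfamily", "sublineage")])
    sublineage_levels <- sublineage_levels[
      order(sublineage_levels$superfamily, sublineage_levels$sublineage), ,
      drop = FALSE]
    rownames(sublineage_levels) <- NULL
  }

  structure(list(membership = membership, clusters = clusters,
                 tracer_counts = tracer_counts,
                 sublineage_levels = sublineage_levels),
            class = "repeat_clusters")
}

#' @export
print.repeat_clusters <- function(x, ...) {
  cat(sprintf(
    "repeat_clusters: %d clusters over %d sequences (%d reads, %d tracers)\n",
    nrow(x$clusters), nrow(x$membership),
    sum(x$clusters$read_count), sum(x$clusters$tracer_total)))
  invisible(x)
}

#' Extract clusters from a similarity graph
#'
#' Clusters are the connected components of the graph; sequences without
#' edges are singleton clusters.  Components are ordered deterministically
#' by decreasing size, then by the lexicographically smallest member id.
#'
#' @param graph a `similarity_graph`.
#' @param tracers optional tracer table (from [kmerize_panel()]`$tracers`)
#'   identifying which sequence ids are tracers and their labels.
#' @return an object of class `repeat_clusters`: `membership` (seq_id,
#'   cluster_id, is_tracer), `clusters` (cluster_id, size, read_count,
#'   tracer_total), and per-cluster `tracer_counts`.
#' @export
extract_clusters <- function(graph, tracers = NULL) {
  stopifnot(inherits(graph, "similarity_graph"))
  ids <- graph$ids
  parent <- seq_along(ids)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  ia <- match(graph$edges$id_a, ids)
  ib <- match(graph$edges$id_b, ids)
  for (e in seq_along(ia)) {
    ra <- find(ia[e]); rb <- find(ib[e])
    if (ra != rb) parent[rb] <- ra
  }
  labels <- vapply(seq_along(ids), find, integer(1))
  make_clusters(ids, labels, tracers)
}

#' Cluster reads (and tracers) at scale
#'
#' Computes the connected components of the similarity graph directly,
#' without materialising every edge: candidate pairs come from a canonical
#' 8-mer index (every pair meeting the thresholds is guaranteed to reach
#' the shared-kmer floor of [build_similarity_graph()]'s prescreen),
#' candidates are vetted with a banded necessary-score alignment around
#' their seed diagonals, and pairs whose members are already connected are
#' skipped.  The resulting components are identical to
#' [extract_clusters()] on [build_similarity_graph()] output.
#'
#' @param reads reads data.frame.
#' @param tracers optional tracer table ([kmerize_panel()]`$tracers`);
#'   tracer kmers join the clustering but never count as reads.
#' @param min_identity,min_overlap_frac edge thresholds.
#' @return a `repeat_clusters` object.
#' @export
cluster_sequences <- function(reads, tracers = NULL, min_identity = 0.90,
                              min_overlap_frac = 0.55) {
  check_reads_df(reads)
  ids <- reads$read_id
  seqs <- toupper(reads$bases)
  if (!is.null(tracers)) {
    both <- intersect(ids, tracers$tracer_id)
    if (length(both))
      stop("read ids collide with tracer ids: ",
           paste(utils::head(both, 3), collapse = ", "), call. = FALSE)
    ids <- c(ids, tracers$tracer_id)
    seqs <- c(seqs, toupper(tracers$sequence))
  }
  labels <- cpp_cluster_components(unname(seqs), min_identity,
                                   min_overlap_frac, 8L,
                                   prescreen_min_shared(seqs))
  make_clusters(ids, labels, tracers)
}

#' Genomic repetitive fraction from clusters
#'
#' The repetitive fraction is the proportion of sampled reads lying in
#' clusters whose read count reaches the minimum cluster size,
#' `ceiling(min_cluster_frac * n_sampled)` (0.01% of sampled reads by
#' default, i.e. 300 reads at 3 M sampled).  Tracer kmers never count
#' toward `n_sampled`, the size threshold, or the numerator.
#'
#' @param clusters a `repeat_clusters` object.
#' @param n_sampled number of reads that entered clustering (tracers
#'   excluded).
#' @param min_cluster_frac minimum cluster size as a fraction of
#'   `n_sampled` (default 1e-4).
#' @param min_cluster_size explicit override of the derived threshold.
#' @return an object of class `fraction_estimate`: list with
#'   `repetitive_fraction`, `n_sampled`, `min_cluster_size` and
#'   `qualifying` (the qualifying cluster table).
#' @export
repetitive_fraction <- function(clusters, n_sampled,
                                min_cluster_frac = 1e-4,
                                min_cluster_size = NULL) {
  stopifnot(inherits(clusters, "repeat_clusters"))
  if (!is.numeric(n_sampled) || length(n_sampled) != 1 || n_sampled <= 0)
    stop("n_sampled must be a positive count", call. = FALSE)
  mcs <- as.integer(min_cluster_size %||% ceiling(min_cluster_frac *
                                                    n_sampled))
  qual <- clusters$clusters[clusters$clusters$read_count >= mcs, ,
                            drop = FALSE]
  structure(list(
    repetitive_fraction = sum(qual$read_count) / n_sampled,
    n_sampled = as.integer(n_sampled),
    min_cluster_size = mcs,
    qualifying = qual
  ), class = "fraction_estimate")
}

#' @export
print.fraction_estimate <- function(x, ...) {
  cat(sprintf(
    "repetitive fraction %.4f (%d reads sampled, min cluster size %d, %d qualifying clusters)\n",
    x$repetitive_fraction, x$n_sampled, x$min_cluster_size,
    nrow(x$qualifying)))
  invisible(x)
}

#' Replicated repetitive-fraction estimation
#'
#' Runs `n_runs` independent clustering analyses, each on a fresh random
#' subsample of `n_per_run` reads, and reports the per-run estimates with
#' their mean and standard error (sd / sqrt(n_runs)).
#'
#' @param reads full read set (post filtering).
#' @param tracers optional tracer table; joined to every run.
#' @param n_runs number of replicate runs (>= 2; default 5).
#' @param n_per_run reads sampled per run (default 3e6).
#' @param seed base seed; run i uses `seed + i - 1` unless `seeds` is given.
#' @param seeds optional explicit per-run seeds.
#' @param min_identity,min_overlap_frac,min_cluster_frac clustering and
#'   threshold parameters.
#' @return list with `mean`, `se`, `runs` (per-run fractions), `estimates`
#'   (per-run `fraction_estimate` objects) and `seeds`.
#' @export
replicate_fraction <- function(reads, tracers = NULL, n_runs = 5,
                               n_per_run = 3e6, seed = 1, seeds = NULL,
                               min_identity = 0.90, min_overlap_frac = 0.55,
                               min_cluster_frac = 1e-4) {
  check_reads_df(reads)
  if (n_runs < 2) stop("n_runs must be >= 2 for a standard error",
                       call. = FALSE)
  seeds <- seeds %||% (seed + seq_len(n_runs) - 1)
  if (length(seeds) != n_runs) stop("need one seed per run", call. = FALSE)
  ests <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    smp <- sample_reads(reads, n_per_run, seed = seeds[i])
    cl <- cluster_sequences(smp, tracers, min_identity, min_overlap_frac)
    ests[[i]] <- repetitive_fraction(cl, nrow(smp), min_cluster_frac)
  }
  runs <- vapply(ests, `[[`, numeric(1), "repetitive_fraction")
  list(mean = mean(runs), se = se_mean(runs), runs = runs,
       estimates = ests, seeds = seeds)
}
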