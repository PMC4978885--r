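#' Read-trimming policy
#'
#' Thresholds for quality trimming: reads shorter than `min_length` after
#' trimming are discarded; leading/trailing bases with quality below
#' `end_quality` are removed; then ends are trimmed while the mean quality
#' of the terminal `window` bases is below `window_mean_quality`.
#'
#' @param min_length minimum retained read length (default 80).
#' @param end_quality Phred threshold for end-base removal (default 30).
#' @param window sliding window width in bases (default 4).
#' @param window_mean_quality mean-quality threshold within the terminal
#'   window (default 25).
#' @return a `trim_policy` list.
#' @export
trim_policy <- function(min_length = 80, end_quality = 30, window = 4,
                        window_mean_quality = 25) {
  for (v in c(min_length, end_quality, window, window_mean_quality))
    if (!is.numeric(v) || length(v) != 1 || v < 0)
      stop("all trim policy thresholds must be single numbers >= 0",
           call. = FALSE)
  structure(list(min_length = as.integer(min_length),
                 end_quality = as.numeric(end_quality),
                 window = as.integer(window),
                 window_mean_quality = as.numeric(window_mean_quality)),
            class = "trim_policy")
}

trim_one <- function(bases, qual, policy) {
  q <- utf8ToInt(qual) - 33L
  lo <- 1L; hi <- length(q)
  w <- policy$window
  # rules 1 (end-quality strip) and 2 (sliding-window trim) are iterated to
  # a fixpoint: the window rule can expose a fresh terminal base below the
  # end-quality threshold, and idempotence requires removing it too
  repeat {
    changed <- FALSE
    while (lo <= hi && q[lo] < policy$end_quality) { lo <- lo + 1L
      changed <- TRUE }
    while (hi >= lo && q[hi] < policy$end_quality) { hi <- hi - 1L
      changed <- TRUE }
    if (lo > hi) return(NULL)
    if (w >= 1) {
      repeat {
        if (hi - lo + 1L < w) break
        if (mean(q[lo:(lo + w - 1L)]) < policy$window_mean_quality) {
          lo <- lo + 1L; changed <- TRUE
        } else if (mean(q[(hi - w + 1L):hi]) <
                     policy$window_mean_quality) {
          hi <- hi - 1L; changed <- TRUE
        } else break
      }
    }
    if (!changed) break
  }
  # rule 3: length filter
  if (hi - lo + 1L < policy$min_length) return(NULL)
  c(lo, hi)
}

#' Quality-trim reads
#'
#' Applies the trimming rules of [trim_policy()] in fixed order (end-quality
#' strip, sliding-window trim, length filter).  Trimming is idempotent.
#' Reads without quality strings pass through unchanged with a warning
#' (FASTA mode).
#'
#' @param reads reads data.frame (`read_id`, `bases`, `qualities`).
#' @param policy a [trim_policy()].
#' @return the retained, trimmed reads; attribute `report` holds input,
#'   retained and discarded counts.
#' @export
quality_trim <- function(reads, policy = trim_policy()) {
  check_reads_df(reads)
  if (!inherits(policy, "trim_policy")) stop("policy must be a trim_policy",
                                             call. = FALSE)
  qual <- reads$qualities %||% rep(NA_character_, nrow(reads))
  no_q <- is.na(qual)
  if (any(no_q))
    warning(sum(no_q), " read(s) without qualities passed through untrimmed")
  keep <- rep(TRUE, nrow(reads))
  bases <- reads$bases
  quals <- qual
  for (i in which(!no_q)) {
    lim <- trim_one(bases[i], qual[i], policy)
    if (is.null(lim)) {
      keep[i] <- FALSE
    } else {
      bases[i] <- substr(bases[i], lim[1], lim[2])
      quals[i] <- substr(qual[i], lim[1], lim[2])
    }
  }
  out <- reads[keep, , drop = FALSE]
  out$bases <- bases[keep]
  out$qualities <- quals[keep]
  rownames(out) <- NULL
  attr(out, "report") <- list(n_input = nrow(reads), n_retained = nrow(out),
                              n_discarded = sum(!keep))
  out
}

#' Remove organelle-derived reads by k-mer containment
#'
#' A read is removed when at least `min_hit_frac` of its k-mers (either
#' strand) occur in the organelle reference k-mer set.  This reproduces the
#' effect of mapping against the chloroplast genome without an external
#' aligner; k-mer containment at k = 31 is a stringent proxy for a
#' high-identity alignment.  Reads shorter than `k` are retained.
#'
#' @param reads reads data.frame.
#' @param organelle_ref organelle reference: FASTA path, named character
#'   vector of sequences, or `DNAStringSet`.
#' @param k k-mer size (4-32; default 31).
#' @param min_hit_frac minimum fraction of read k-mers found in the
#'   reference (default 0.5).
#' @return retained reads; attribute `report` holds input/removed counts.
#' @export
filter_organelle <- function(reads, organelle_ref, k = 31,
                             min_hit_frac = 0.5) {
  check_reads_df(reads)
  ref <- organelle_ref
  if (is.character(ref) && length(ref) == 1 && file.exists(ref))
    ref <- read_fasta(ref)
  if (inherits(ref, "DNAStringSet")) ref <- as.character(ref)
  if (!is.character(ref) || length(ref) == 0 || all(nchar(ref) == 0))
    stop("organelle reference is empty", call. = FALSE)
  frac <- cpp_kmer_hit_fraction(toupper(reads$bases), toupper(ref),
                                as.integer(k))
  removed <- frac >= min_hit_frac
  out <- reads[!removed, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- list(n_input = nrow(reads),
                              n_removed = sum(removed),
                              n_retained = nrow(out))
  out
}

#' Randomly subsample reads
#'
#' Uniform sampling without replacement of `min(n, available)` reads,
#' deterministic per seed.  When fewer than `n` reads are available all
#' reads are returned with a notice.
#'
#' @param reads reads data.frame.
#' @param n target sample size (default 3e6, the study-scale sample).
#' @param seed integer seed.
#' @return sampled reads (input order preserved); attribute `n_sampled`
#'   records the realised count.
#' @export
sample_reads <- function(reads, n = 3e6, seed = 1) {
  check_reads_df(reads)
  assert_scalar_number(n, "n", min = 1)
  avail <- nrow(reads)
  if (n >= avail) {
    message(sprintf("requested %s reads but only %s available; using all",
                    format(n, big.mark = ","), format(avail, big.mark = ",")))
    out <- reads
  } else {
    idx <- with_seed(seed, sort(sample.int(avail, n)))
    out <- reads[idx, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_sampled") <- nrow(out)
  out
}
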