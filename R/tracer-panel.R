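#' Load a reference panel of full-length LTR retrotransposons
#'
#' Pairs a FASTA file of full-length elements with a metadata table carrying
#' superfamily and sublineage labels.  Every FASTA record must have a
#' metadata row; ids must be unique; sequences must be predominantly ACGT.
#'
#' @param fasta FASTA path or named character vector of element sequences.
#' @param metadata TSV path or data.frame with columns `element_id`,
#'   `superfamily`, `sublineage` and optionally `family_alias`.
#' @param min_acgt_frac reject sequences whose ACGT fraction falls below
#'   this value.
#' @return data.frame with columns `element_id`, `superfamily`,
#'   `sublineage`, `family_alias`, `sequence`.
#' @export
load_panel <- function(fasta, metadata, min_acgt_frac = 0.9) {
  seqs <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta))
    read_fasta(fasta) else fasta
  if (!is.character(seqs) || is.null(names(seqs)))
    stop("panel FASTA must yield a named character vector", call. = FALSE)
  meta <- if (is.character(metadata) && length(metadata) == 1)
    read_tsv(metadata) else metadata
  if (!is.data.frame(meta) || nrow(meta) == 0)
    stop("panel metadata is empty", call. = FALSE)
  req <- c("element_id", "superfamily", "sublineage")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("panel metadata missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(meta$element_id))
    stop("duplicate metadata ids: ",
         paste(unique(meta$element_id[duplicated(meta$element_id)]),
               collapse = ", "), call. = FALSE)
  no_meta <- setdiff(names(seqs), meta$element_id)
  if (length(no_meta))
    stop("FASTA records without metadata: ",
         paste(no_meta, collapse = ", "), call. = FALSE)
  if (!all(meta$superfamily %in% c("gypsy", "copia")))
    stop("superfamily labels must be 'gypsy' or 'copia'", call. = FALSE)
  if (any(!nzchar(meta$sublineage)) || anyNA(meta$sublineage))
    stop("sublineage labels must be non-empty", call. = FALSE)

  meta <- meta[meta$element_id %in% names(seqs), , drop = FALSE]
  sq <- toupper(seqs[meta$element_id])
  acgt <- vapply(sq, function(s) {
    n <- nchar(s)
    if (n == 0) return(0)
    sum(strsplit(s, "", fixed = TRUE)[[1]] %in% c("A", "C", "G", "T")) / n
  }, numeric(1))
  bad <- meta$element_id[acgt < min_acgt_frac]
  if (length(bad))
    stop("sequences are not predominantly ACGT: ",
         paste(bad, collapse = ", "), call. = FALSE)

  panel <- data.frame(
    element_id = meta$element_id,
    superfamily = meta$superfamily,
    sublineage = as.character(meta$sublineage),
    family_alias = if ("family_alias" %in% names(meta))
      as.character(meta$family_alias) else NA_character_,
    sequence = unname(sq),
    stringsAsFactors = FALSE
  )
  tab <- table(panel$superfamily)
  message(sprintf("panel loaded: %d elements (%s)", nrow(panel),
                  paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  panel
}

#' Number of tracer kmers for an element length
#'
#' `floor((L - k) / step) + 1` kmers at offsets `0, step, 2*step, ...` while
#' the full window fits; no 3'-anchored tail kmer is added, so up to
#' `step - 1` terminal bases may be untraced.
#'
#' @param length element length(s) in bases.
#' @param k kmer size (default 100).
#' @param step offset step; `k - step` is the overlap between consecutive
#'   kmers (default 15, i.e. 85 bp overlap).
#' @return integer vector of kmer counts.
#' @export
tracer_kmer_count <- function(length, k = 100, step = 15) {
  if (any(length < k)) stop("element shorter than kmer size", call. = FALSE)
  as.integer((length - k) %/% step + 1L)
}

#' Decompose one element into tracer kmers
#'
#' @param element one-row data.frame from a panel (columns `element_id`,
#'   `superfamily`, `sublineage`, `sequence`).
#' @param k,step kmer size and offset step (defaults 100 and 15; consecutive
#'   kmers share `k - step` = 85 bases).
#' @return data.frame of tracer kmers with columns `tracer_id`
#'   (`parentId|offset`), `parent_id`, `offset` (0-based), `superfamily`,
#'   `sublineage`, `sequence`.
#' @export
kmerize_element <- function(element, k = 100, step = 15) {
  stopifnot(is.data.frame(element), nrow(element) == 1)
  L <- nchar(element$sequence)
  if (L < k)
    stop(sprintf("element %s (%d bp) shorter than kmer size %d",
                 element$element_id, L, k), call. = FALSE)
  offsets <- seq.int(0L, L - k, by = step)
  data.frame(
    tracer_id = paste0(element$element_id, "|", offsets),
    parent_id = element$element_id,
    offset = as.integer(offsets),
    superfamily = element$superfamily,
    sublineage = element$sublineage,
    sequence = substring(element$sequence, offsets + 1L, offsets + k),
    stringsAsFactors = FALSE
  )
}

#' Decompose a panel into its full tracer kmer set
#'
#' Consecutive kmers of one element overlap by `k - step` identical bases
#' (85 by default), far above the clustering thresholds (90% identity over
#' 55% overlap), so the tracer set of any single element always forms one
#' connected component in the similarity graph.
#'
#' @param panel panel data.frame ([load_panel()] or
#'   [simulate_reference_panel()]).
#' @param k,step kmer size and offset step.
#' @return list with `tracers` (the concatenated kmer table) and `counts`
#'   (per-element kmer counts); `k` and `step` are recorded.
#' @export
kmerize_panel <- function(panel, k = 100, step = 15) {
  stopifnot(is.data.frame(panel), nrow(panel) > 0)
  parts <- lapply(seq_len(nrow(panel)), function(i)
    kmerize_element(panel[i, , drop = FALSE], k = k, step = step))
  tracers <- do.call(rbind, parts)
  counts <- data.frame(
    element_id = panel$element_id,
    n_kmers = vapply(parts, nrow, integer(1)),
    stringsAsFactors = FALSE
  )
  list(tracers = tracers, counts = counts, total = nrow(tracers),
       k = k, step = step)
}

#' Write tracer kmers to FASTA
#'
#' @param tracers tracer table from [kmerize_panel()] (`$tracers`).
#' @param path output path.
#' @export
write_tracer_fasta <- function(tracers, path) {
  write_fasta(setNames(tracers$sequence, tracers$tracer_id), path)
}
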