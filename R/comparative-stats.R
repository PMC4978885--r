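#' Convert picograms of DNA to megabases
#'
#' Uses the standard conversion 1 pg = 978 Mb.
#'
#' @param pg DNA mass in picograms (>= 0).
#' @return length in megabases.
#' @export
pg_to_mb <- function(pg) {
  if (any(pg < 0)) stop("pg must be >= 0", call. = FALSE)
  pg * 978
}

#' Expected genome coverage from paired-end read counts
#'
#' Coverage C = L * N / G, where L is the read length, N the number of
#' reads (both mates of every pair) and G the haploid genome length derived
#' from the 2C value (1C = 2C / 2, 1 pg = 978 Mb).
#'
#' @param read_pairs number of read pairs (> 0).
#' @param c2_pg 2C nuclear DNA amount in picograms (> 0).
#' @param read_length read length in bases (default 100).
#' @param digits optional rounding (round-half-even, as in [round()]);
#'   `NULL` returns full precision.
#' @return coverage fold.
#' @export
genome_coverage <- function(read_pairs, c2_pg, read_length = 100,
                            digits = NULL) {
  if (any(read_pairs <= 0) || any(c2_pg <= 0) || any(read_length <= 0))
    stop("read_pairs, c2_pg and read_length must be > 0", call. = FALSE)
  cv <- read_length * (2 * read_pairs) / ((c2_pg / 2) * 978e6)
  if (!is.null(digits)) round(cv, digits) else cv
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric trait vectors of equal length >= 3 with nonzero
#'   variance.
#' @return list with `r`, `p` (two-sided, t transform with n - 2 df), `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in a trait", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = "pearson")
}

#' Prune named tips from a phylogeny
#'
#' Removes the named tips and suppresses the resulting degree-2 internal
#' nodes, summing their branch lengths, so root-to-tip path lengths of the
#' surviving tips are unchanged.
#'
#' @param tree an `ape::phylo` tree.
#' @param remove tip labels to remove (may be empty).
#' @return the pruned tree.
#' @export
drop_tips <- function(tree, remove) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object",
                                     call. = FALSE)
  if (length(remove) == 0) return(tree)
  unknown <- setdiff(remove, tree$tip.label)
  if (length(unknown))
    stop("tip label(s) not in tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ape::drop.tip(tree, remove)
}

check_pic_inputs <- function(tree, trait, resolve_polytomies) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object",
                                     call. = FALSE)
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    if (!resolve_polytomies)
      stop("tree contains polytomies; set resolve_polytomies = TRUE to ",
           "resolve them with zero-length branches", call. = FALSE)
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths", call. = FALSE)
  if (!is.null(names(trait))) {
    miss <- setdiff(tree$tip.label, names(trait))
    if (length(miss))
      stop("trait values missing for tips: ", paste(miss, collapse = ", "),
           call. = FALSE)
    trait <- trait[tree$tip.label]
  } else if (length(trait) != length(tree$tip.label)) {
    stop("trait length differs from the number of tips", call. = FALSE)
  }
  list(tree = tree, trait = trait)
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's contrasts: in post-order, the contrast at each internal
#' node is the difference of its daughters' values standardised by the
#' square root of the summed (adjusted) branch lengths; the node value is
#' the branch-length-weighted average of the daughters and its parent
#' branch is extended by the product-over-sum correction.  Computed via
#' `ape::pic`.
#'
#' @param tree a rooted, fully bifurcating `ape::phylo` tree with branch
#'   lengths.
#' @param trait numeric tip values, named by tip label (or ordered as
#'   `tree$tip.label`).
#' @param resolve_polytomies resolve polytomies with zero-length branches
#'   instead of failing (default FALSE; contrasts across zero-length
#'   branches are not standardisable when both daughters sit at zero
#'   distance).
#' @return numeric vector of n - 1 standardised contrasts.
#' @export
pic_contrasts <- function(tree, trait, resolve_polytomies = FALSE) {
  inp <- check_pic_inputs(tree, trait, resolve_polytomies)
  ape::pic(inp$trait, inp$tree)
}

#' Correlation of two traits through phylogenetically independent contrasts
#'
#' The two contrast sets are correlated through the origin (no intercept),
#' the standard treatment for contrasts, whose expectation is zero;
#' r = sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2)).  The two-sided p-value
#' uses the t transform with (n - 1) - 1 degrees of freedom for n tips.
#'
#' @param tree a rooted, fully bifurcating `ape::phylo` tree.
#' @param x,y numeric tip traits (named by tip label, or in tip order).
#' @param resolve_polytomies as in [pic_contrasts()].
#' @return list with `r`, `p`, `n_contrasts`, `method`.
#' @export
pic_correlation <- function(tree, x, y, resolve_polytomies = FALSE) {
  cx <- pic_contrasts(tree, x, resolve_polytomies)
  cy <- pic_contrasts(tree, y, resolve_polytomies)
  r <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  df <- length(cx) - 1
  p <- if (df < 1) NA_real_ else {
    if (abs(r) >= 1) 0 else {
      tval <- r * sqrt(df / (1 - r^2))
      2 * stats::pt(-abs(tval), df)
    }
  }
  list(r = r, p = p, n_contrasts = length(cx), method = "pic")
}

#' Load the bundled species table
#'
#' Species names, 2C genome sizes (flow-cytometry estimates, with SE),
#' post-processing read-pair counts and clustering-derived repetitive
#' fractions for the eight Helianthus species and the outgroup
#' P. tenuifolius.
#'
#' @param path optional path to a species table TSV with the same columns;
#'   defaults to the bundled table.
#' @return data.frame with columns `species`, `abbreviation`, `life_cycle`,
#'   `read_pairs`, `c2_pg`, `c2_se`, `coverage`,
#'   `repetitive_fraction_pct`, `repetitive_fraction_se`.
#' @export
load_species_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "species_table.tsv",
                                package = "ltrtracer", mustWork = TRUE)
  tab <- read_tsv(path)
  req <- c("species", "abbreviation", "read_pairs", "c2_pg",
           "repetitive_fraction_pct")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("species table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(tab$c2_pg <= 0)) stop("2C values must be > 0", call. = FALSE)
  if (any(tab$repetitive_fraction_pct < 0 |
            tab$repetitive_fraction_pct > 100))
    stop("repetitive fractions must be percentages", call. = FALSE)
  tab
}

#' Load the bundled study-tree topology
#'
#' A representative topology for the study species (without the
#' hybrid-origin H. anomalus), constructed from published relationships and
#' shipped with unit branch lengths as placeholders: the file is a
#' synthetic stand-in, not an estimated phylogeny, so correlations computed
#' on it illustrate the machinery rather than reproduce published values.
#'
#' @param path optional path to a newick file; defaults to the bundled
#'   topology.
#' @return an `ape::phylo` tree.
#' @export
load_study_tree <- function(path = NULL) {
  path <- path %||% system.file("extdata", "helianthus_topology_synthetic.nwk",
                                package = "ltrtracer", mustWork = TRUE)
  ape::read.tree(path)
}
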