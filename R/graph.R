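new_ccdbg <- function(ptr, k) {
  g <- new.env(parent = emptyenv())
  g$ptr <- ptr
  g$k <- as.integer(k)
  g$color_ids <- integer(0)
  g$annotated <- FALSE
  class(g) <- "ccdbg"
  g
}

#' Build a compacted de Bruijn graph from reads
#'
#' Counts canonical k-mers of the input sequences (reads are split at non-ACGT
#' symbols first), discards k-mers seen fewer than `min_count` times, and
#' compacts the surviving k-mer set into maximal non-branching unitigs. The
#' per-k-mer multiplicities are kept as coverage. `k` must be odd so that no
#' k-mer equals its own reverse complement.
#'
#' The returned object has reference semantics: [color_graph()] and
#' [annotate_candidate_snps()] modify it in place.
#'
#' @param reads character vector of DNA sequences
#' @param k odd integer k-mer length, >= 3
#' @param min_count minimum k-mer multiplicity to retain (default 2: k-mers
#'   seen once are assumed to carry a sequencing error)
#' @return a `ccdbg` object
#' @export
build_graph <- function(reads, k, min_count = 2) {
  stopifnot(k >= 3, k %% 2 == 1, min_count >= 1)
  g <- new_ccdbg(cpp_build_graph(as.character(reads), as.integer(k),
                                 as.integer(min_count)), k)
  if (n_kmers(g) == 0) {
    warning("no k-mer survives the multiplicity filter; graph is empty")
  }
  g
}

#' Build a graph directly from unitig sequences
#'
#' Indexes the k-mers of the given sequences without re-compacting them. Used
#' for graph import ([import_gfa()]) and for constructing small graphs with a
#' prescribed unitig set. Errors if a k-mer occurs at more than one position.
#'
#' @param seqs character vector of unitig sequences
#' @param k odd integer k-mer length
#' @return a `ccdbg` object
#' @export
graph_from_unitigs <- function(seqs, k) {
  stopifnot(k >= 3, k %% 2 == 1, all(nchar(seqs) >= k))
  new_ccdbg(cpp_graph_from_unitigs(as.character(seqs), as.integer(k)), k)
}

#' Build the short-k-mer graph from the unitigs of a long-k-mer graph
#'
#' Returns the graph of all `k_small`-mers occurring in the parent graph's
#' unitig sequences. The parent's multiplicity filter has already been applied,
#' so all occurring `k_small`-mers are kept (min_count = 1).
#'
#' @param parent a `ccdbg`
#' @param k_small odd integer, strictly smaller than `parent`'s k
#' @return a `ccdbg` with k = `k_small`
#' @export
build_subgraph_from_unitigs <- function(parent, k_small) {
  stopifnot(inherits(parent, "ccdbg"))
  if (k_small >= parent$k) stop("k_small must be smaller than the parent graph's k")
  stopifnot(k_small %% 2 == 1)
  seqs <- unitig_seqs(parent)
  if (length(seqs) == 0) {
    return(new_ccdbg(cpp_build_graph(character(0), as.integer(k_small), 1L), k_small))
  }
  new_ccdbg(cpp_build_graph(seqs, as.integer(k_small), 1L), k_small)
}

#' Color graph k-mers with read (pair) identifiers
#'
#' Each unit is one color: a short-read pair in the first correction pass, a
#' single corrected long read in the second. For every unit sharing at least
#' one k-mer with the graph, the unit's color id is added to the color set of
#' every shared k-mer position. Colors are stored per k-mer position, not per
#' unitig, so color lookups at specific matches are position-accurate.
#'
#' The graph is modified in place (and returned invisibly).
#'
#' @param graph a `ccdbg`
#' @param units list of character vectors (one or two sequences per unit)
#' @param ids integer color identifiers, unique per unit and not previously used
#' @return the graph, invisibly
#' @export
color_graph <- function(graph, units, ids = seq_along(units)) {
  stopifnot(inherits(graph, "ccdbg"))
  ids <- as.integer(ids)
  if (anyDuplicated(ids) || any(ids %in% graph$color_ids)) {
    stop("color id collision: identifiers must be unique across all coloring calls")
  }
  if (!is.list(units)) units <- as.list(units)
  cpp_color_graph(graph$ptr, units, ids)
  graph$color_ids <- c(graph$color_ids, ids)
  invisible(graph)
}

#' Split and trim unitigs whose k-mers carry too few colors
#'
#' Drops every k-mer whose color set has fewer than `min_colors` members and
#' re-compacts the remainder into maximal unitigs. Coverage and color sets are
#' carried over; candidate-SNP annotations are not and must be recomputed with
#' [annotate_candidate_snps()] on the returned graph.
#'
#' @param graph a colored `ccdbg`
#' @param min_colors minimum color-set size per retained k-mer
#' @return a new `ccdbg`
#' @export
prune_low_color_kmers <- function(graph, min_colors) {
  stopifnot(inherits(graph, "ccdbg"), min_colors >= 0)
  if (min_colors == 0) return(graph)
  g2 <- new_ccdbg(cpp_prune_low_colors(graph$ptr, as.integer(min_colors)), graph$k)
  g2$color_ids <- graph$color_ids
  if (n_kmers(g2) == 0) warning("all k-mers fall below the color threshold; graph is empty")
  g2
}

#' Annotate candidate SNP sites with IUPAC symbols
#'
#' For every pair of graph k-mers at Hamming distance 1, both unitigs are
#' annotated at the substituted base with the IUPAC symbol covering the two
#' observed bases (e.g. `R` for an A/G substitution). Annotations accumulate:
#' several alternate bases at one site merge into the covering symbol. The
#' graph is modified in place (and returned invisibly).
#'
#' @param graph a `ccdbg`
#' @return the graph, invisibly
#' @export
annotate_candidate_snps <- function(graph) {
  stopifnot(inherits(graph, "ccdbg"))
  cpp_annotate_snps(graph$ptr)
  graph$annotated <- TRUE
  invisible(graph)
}

#' Look up k-mers in the graph
#'
#' Exact canonical lookup; each k-mer has at most one hit. `strand` is +1 when
#' the queried k-mer matches the stored unitig slice as written, -1 when its
#' reverse complement does.
#'
#' @param graph a `ccdbg`
#' @param kmers character vector of length-k DNA strings
#' @return a tibble with columns `kmer`, `present`, `unitig`, `offset` (1-based
#'   k-mer start in the unitig), `strand`
#' @export
graph_lookup <- function(graph, kmers) {
  stopifnot(inherits(graph, "ccdbg"))
  if (any(nchar(kmers) != graph$k)) stop("all queries must have length k = ", graph$k)
  df <- cpp_lookup(graph$ptr, as.character(kmers))
  tibble::tibble(kmer = as.character(kmers), tibble::as_tibble(df))
}

#' Unitig table of a graph
#' @param graph a `ccdbg`
#' @return a tibble with columns `unitig` (integer id), `seq`, `length`,
#'   `n_kmers`, `mean_cov`
#' @export
unitigs <- function(graph) {
  stopifnot(inherits(graph, "ccdbg"))
  seqs <- unitig_seqs(graph)
  n <- length(seqs)
  mean_cov <- vapply(seq_len(n), function(i) mean(unitig_info(graph, i)$cov), numeric(1))
  tibble::tibble(
    unitig = seq_len(n), seq = seqs, length = nchar(seqs),
    n_kmers = nchar(seqs) - graph$k + 1L, mean_cov = mean_cov
  )
}

#' Unitig sequences of a graph
#' @param graph a `ccdbg`
#' @return character vector, one sequence per unitig in id order
#' @export
unitig_seqs <- function(graph) cpp_unitig_seqs(graph$ptr)

#' Color sets at specific k-mer positions
#' @param graph a colored `ccdbg`
#' @param unitig,offset parallel integer vectors (1-based)
#' @return list of sorted integer color vectors
#' @export
kmer_colors_at <- function(graph, unitig, offset) {
  stopifnot(inherits(graph, "ccdbg"))
  kmer_colors(graph, unitig, offset)
}

#' Per-k-mer detail of one unitig
#' @param graph a `ccdbg`
#' @param id unitig id
#' @return list with `seq`, `cov` (per k-mer), `colors` (list of integer sets,
#'   per k-mer), `snp_pos` (1-based annotated base positions), `snp_mask`
#'   (IUPAC base bitmasks), `snp_symbol`
#' @export
unitig_info <- function(graph, id) {
  info <- cpp_unitig_info(graph$ptr, as.integer(id))
  info$snp_symbol <- if (length(info$snp_pos)) iupac_symbol(info$snp_mask) else character(0)
  info
}

#' Number of unitigs in a graph
#' @param graph a `ccdbg`
#' @export
n_unitigs <- function(graph) cpp_graph_stats(graph$ptr)$n_unitigs

#' Number of k-mers in a graph
#' @param graph a `ccdbg`
#' @export
n_kmers <- function(graph) cpp_graph_stats(graph$ptr)$n_kmers

# color sets at specific k-mer positions; uid/off 1-based vectors
kmer_colors <- function(graph, unitig, offset) {
  cpp_kmer_colors(graph$ptr, as.integer(unitig), as.integer(offset))
}

#' @export
print.ccdbg <- function(x, ...) {
  st <- cpp_graph_stats(x$ptr)
  cat(sprintf("ccdbg: k = %d, %d unitigs, %s k-mers, %d colors%s\n",
              st$k, st$n_unitigs, format(st$n_kmers, big.mark = ","),
              length(x$color_ids),
              if (x$annotated) ", SNP-annotated" else ""))
  invisible(x)
}
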