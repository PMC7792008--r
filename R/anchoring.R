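#' Classify long-read k-mers against the graph
#'
#' Every k-mer window of the read is classified as solid (exact match to a
#' unitig slice), near-solid (match with exactly one substitution or indel) or
#' weak (neither). A window that is solid contributes no near-solid matches,
#' and only unique near-solid matches (UNSM: exactly one matched graph locus
#' at that read position) are reported, so that the read is never anchored on
#' the wrong allele of a SNP or indel.
#'
#' All positions are 1-based. `edit` is one of `"substitution"` (one base
#' differs), `"insertion"` (the read carries one extra base relative to the
#' graph k-mer) or `"deletion"` (the read lacks one base). Indel candidates
#' are only generated when the neighboring read base needed to refill the
#' window exists.
#'
#' @param read a DNA string
#' @param graph a `ccdbg`
#' @return list with tibbles `solid` (`pos`, `unitig`, `offset`, `strand`) and
#'   `near_solid` (same plus `edit`), both sorted by `pos`
#' @export
classify_kmers <- function(read, graph) {
  stopifnot(inherits(graph, "ccdbg"), length(read) == 1)
  if (nchar(read) < graph$k) {
    empty <- tibble::tibble(pos = integer(0), unitig = integer(0),
                            offset = integer(0), strand = integer(0))
    return(list(solid = empty, near_solid = tibble::tibble(empty, edit = character(0))))
  }
  res <- cpp_classify_read(graph$ptr, read)
  near <- tibble::as_tibble(res$near_solid)
  near$edit <- c("substitution", "insertion", "deletion")[near$edit + 1L]
  list(solid = tibble::as_tibble(res$solid), near_solid = near)
}

#' Delimit the non-solid regions of a read
#'
#' One region is produced for every pair of successive solid matches that are
#' not adjacent on the read (`pos_target != pos_source + 1`), plus a head
#' region when the read starts non-solid, a tail region when it ends
#' non-solid, and a single full-read region when the read has no solid match
#' at all. Each region records the read interval it covers (including the
#' flanking solid k-mers), its raw length `l`, the candidate path length
#' bounds `l_min = ceiling(l / (1 + F))` and `l_max = floor(l * (1 + F))`
#' where `F` is the assumed upper bound on the read error rate, and the unique
#' near-solid matches usable as traversal waypoints
#' (`pos_source + k <= pos <= pos_target - k`).
#'
#' @param solid tibble of solid matches sorted by `pos`
#' @param near_solid tibble of unique near-solid matches
#' @param read_len read length in bases
#' @param k graph k-mer length
#' @param F assumed upper bound on the read error rate
#' @return tibble with one row per region: `start`, `end` (1-based inclusive
#'   read interval), `l`, `l_min`, `l_max`, and list columns `source`,
#'   `target` (match records: lists with `pos`, `unitig`, `offset`, `strand`,
#'   or NULL for a missing anchor) and `unsms` (data frames of waypoints)
#' @export
delimit_regions <- function(solid, near_solid, read_len, k, F = 0.4) {
  stopifnot(read_len >= 1, k >= 3, F > 0)
  if (nrow(solid) > 0 && is.unsorted(solid$pos)) solid <- solid[order(solid$pos), ]
  near_solid <- as.data.frame(near_solid)
  match_at <- function(df, i) {
    if (is.null(i)) NULL else list(pos = df$pos[i], unitig = df$unitig[i],
                                   offset = df$offset[i], strand = df$strand[i])
  }
  regions <- list()
  add_region <- function(si, ti) {
    src <- match_at(solid, si); tgt <- match_at(solid, ti)
    p_s <- if (is.null(src)) NA_integer_ else as.integer(src$pos)
    p_t <- if (is.null(tgt)) NA_integer_ else as.integer(tgt$pos)
    start <- if (is.null(src)) 1L else p_s
    end <- if (is.null(tgt)) as.integer(read_len) else p_t + as.integer(k) - 1L
    l <- end - start + 1L
    un_lo <- if (is.null(src)) 1L else p_s + k
    un_hi <- if (is.null(tgt)) read_len else p_t - k
    keep <- near_solid$pos >= un_lo & near_solid$pos <= un_hi
    unsms <- near_solid[keep & !duplicated(near_solid$pos), , drop = FALSE]
    regions[[length(regions) + 1L]] <<- list(
      source = src, target = tgt, start = start, end = end, l = l,
      l_min = as.integer(ceiling(l / (1 + F))), l_max = as.integer(floor(l * (1 + F))),
      unsms = unsms
    )
  }
  if (nrow(solid) == 0) {
    add_region(NULL, NULL)
  } else {
    if (solid$pos[1] > 1) add_region(NULL, 1L)
    if (nrow(solid) > 1) {
      gaps <- which(diff(solid$pos) != 1L)
      for (i in gaps) add_region(i, i + 1L)
    }
    if (solid$pos[nrow(solid)] + k - 1L < read_len) add_region(nrow(solid), NULL)
  }
  tibble::tibble(
    start = vapply(regions, function(r) r$start, integer(1)),
    end = vapply(regions, function(r) r$end, integer(1)),
    l = vapply(regions, function(r) r$l, integer(1)),
    l_min = vapply(regions, function(r) r$l_min, integer(1)),
    l_max = vapply(regions, function(r) r$l_max, integer(1)),
    source = lapply(regions, function(r) r$source),
    target = lapply(regions, function(r) r$target),
    unsms = lapply(regions, function(r) r$unsms)
  )
}
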