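#' Traversal parameter set
#'
#' Tunables of the guided graph traversal. `F` is the assumed upper bound on
#' the long-read error rate (path length bounds are `l / (1+F)` to
#' `l * (1+F)`). `B` is the color-collection buffer in bases around a
#' non-solid region (pass 1) or the base-length frontier of one search stage
#' (pass 2). `P_max` is the number of unitigs explored per search stage when
#' `frontier_mode = "unitig_count"`. `D` in \[0,1\] scales the local color
#' floor: paths must keep at least `floor(D * min |C_u|)` of the surrounding
#' colors at every k-mer.
#'
#' @param F error-rate upper bound, > 0
#' @param B color buffer / base-length frontier, bases
#' @param P_max unitigs per search stage, >= 1
#' @param D color-floor factor in \[0, 1\]
#' @param frontier_mode `"unitig_count"` (pass 1) or `"base_length"` (pass 2)
#' @return a `traversal_params` list
#' @export
traversal_params <- function(F = 0.4, B = 1000, P_max = 4, D = 0.2,
                             frontier_mode = c("unitig_count", "base_length")) {
  frontier_mode <- match.arg(frontier_mode)
  stopifnot(F > 0, P_max >= 1, D >= 0, D <= 1, B >= 1)
  structure(list(F = F, B = as.integer(B), P_max = as.integer(P_max), D = D,
                 frontier_mode = frontier_mode),
            class = "traversal_params")
}

# matches (solid and unique near-solid) whose read position falls in the
# color-collection window [pos_source - B, pos_target + B] of a region
window_matches <- function(solid, near_solid, region, B) {
  lo <- if (is.null(region$source)) -Inf else region$source$pos - B
  hi <- if (is.null(region$target)) Inf else region$target$pos + B
  rbind(
    solid[solid$pos >= lo & solid$pos <= hi, c("pos", "unitig", "offset"), drop = FALSE],
    near_solid[near_solid$pos >= lo & near_solid$pos <= hi,
               c("pos", "unitig", "offset"), drop = FALSE]
  )
}

#' Union of surrounding colors for a region (pass-1 color guidance)
#'
#' Returns the union of the k-mer color sets of all solid matches and unique
#' near-solid matches whose read position lies within `B` bases of the region
#' (head/tail regions: the missing bound is the read end).
#'
#' @param solid,near_solid match tibbles from [classify_kmers()]
#' @param region one region (a row of [delimit_regions()] output, as a list)
#' @param B color buffer in bases
#' @param graph a colored `ccdbg`
#' @return sorted integer vector of color identifiers
#' @export
collect_color_union <- function(solid, near_solid, region, B, graph) {
  m <- window_matches(solid, near_solid, region, B)
  if (nrow(m) == 0) return(integer(0))
  sort(unique(unlist(kmer_colors(graph, m$unitig, m$offset))))
}

#' Local minimum color count for traversal pruning
#'
#' `T_C = floor(D * min |C_u|)` over the color-set sizes at the matched k-mer
#' positions within the window; 0 when the window holds no matches. Every
#' k-mer on a candidate path must keep at least `T_C` of the surrounding
#' colors, which prunes chimeric paths early.
#'
#' @inheritParams collect_color_union
#' @param D color-floor factor in \[0, 1\]
#' @return non-negative integer threshold
#' @export
color_floor <- function(solid, near_solid, region, B, D, graph) {
  m <- window_matches(solid, near_solid, region, B)
  if (nrow(m) == 0) return(0L)
  sizes <- lengths(kmer_colors(graph, m$unitig, m$offset))
  as.integer(floor(D * min(sizes)))
}

#' Conflate color- and sequence-matching probabilities
#'
#' `s_P = s_c s_q / (s_c s_q + (1 - s_c)(1 - s_q))`, the product conflation of
#' the two evidence sources; returns 0 on the degenerate 0/0 case. Monotone
#' non-decreasing in each argument.
#'
#' @param s_c,s_q probabilities in \[0, 1\]
#' @return conflated probability in \[0, 1\]
#' @export
path_probability <- function(s_c, s_q) {
  stopifnot(all(s_c >= 0 & s_c <= 1), all(s_q >= 0 & s_q <= 1))
  num <- s_c * s_q
  den <- num + (1 - s_c) * (1 - s_q)
  ifelse(den == 0, 0, num / den)
}

new_graph_path <- function(sequence, ann, ann_unitig, from_graph, walk, complete,
                           colors = integer(0)) {
  structure(list(sequence = sequence, ann = ann, ann_unitig = ann_unitig,
                 from_graph = from_graph, walk = walk, complete = complete,
                 colors = colors, s_c = NA_real_, s_q = NA_real_, s_P = NA_real_),
            class = "graph_path")
}

#' @export
print.graph_path <- function(x, ...) {
  cat(sprintf("graph_path: %d bases, %s, %d gap bases, s_P = %s\n",
              nchar(x$sequence), if (x$complete) "complete" else "incomplete",
              sum(!x$from_graph), format(x$s_P, digits = 4)))
  invisible(x)
}

#' Score a candidate path against a region
#'
#' Fills the color-matching probability `s_c = |C_p intersect C| / |C|` (1
#' when `C` is empty: absent evidence is not negative evidence), the
#' sequence-matching probability `s_q = 1 - d / |path|` where `d` is the
#' infix edit distance of the path sequence against the region (gaps at the
#' region ends unpenalized), and their conflation `s_P`.
#'
#' @param path a `graph_path`
#' @param C integer vector of guiding colors (possibly empty)
#' @param region_subseq the uncorrected region sequence
#' @return the path with `s_c`, `s_q`, `s_P` filled in
#' @export
score_path <- function(path, C, region_subseq) {
  stopifnot(inherits(path, "graph_path"))
  if (nchar(path$sequence) == 0) stop("cannot score an empty path sequence")
  path$s_c <- if (length(C) == 0) 1 else length(intersect(path$colors, C)) / length(C)
  d <- cpp_edit_dist(path$sequence, region_subseq, FALSE)
  path$s_q <- max(0, 1 - d / nchar(path$sequence))
  path$s_P <- path_probability(path$s_c, path$s_q)
  path
}

# one leg of guided traversal between two anchor loci (or open-ended)
# from/to: list(unitig, offset, strand); to = NULL for open-ended
traverse_leg <- function(graph, from, to, region_subseq, max_bases, min_bases,
                         C, T_C, params, want_len = 0L) {
  cpp_traverse(graph$ptr, from$unitig, from$offset, from$strand,
               if (is.null(to)) 0L else to$unitig,
               if (is.null(to)) 0L else to$offset,
               if (is.null(to)) 0L else to$strand,
               region_subseq, as.integer(max_bases), as.integer(min_bases),
               as.integer(C), as.integer(T_C), params$P_max, params$B,
               params$frontier_mode == "base_length", params$F,
               as.integer(want_len))
}

#' Greedy staged graph walk between two anchors
#'
#' Extends a path from the source k-mer locus towards the target by repeated
#' bounded stages: all simple extensions up to `P_max` unitigs (or at least
#' `B` appended bases in `"base_length"` mode) are enumerated, extensions
#' containing a k-mer with fewer than `T_C` of the guiding colors are
#' discarded, survivors are scored against the region and only the best is
#' extended (ties break to the lexicographically smallest sequence). The walk
#' stops on reaching the target, exceeding `max_bases`, or a dead end.
#'
#' @param graph a `ccdbg`
#' @param from,to anchor loci: lists with `unitig`, `offset`, `strand`
#'   (1-based); `to = NULL` for an open-ended walk
#' @param max_bases hard bound on the path sequence length
#' @param C guiding color set (integer vector)
#' @param T_C color floor (see [color_floor()])
#' @param region_subseq uncorrected region sequence, starting at the source
#'   k-mer
#' @param params a [traversal_params()] set
#' @param min_bases minimum path length for accepting a target hit
#' @param want_len target sequence length for open-ended walks
#' @return a scored `graph_path`; `complete` is TRUE when the target (or the
#'   open-ended length goal) was reached
#' @export
greedy_bfs_extend <- function(graph, from, to, max_bases, C, T_C, region_subseq,
                              params, min_bases = 0L, want_len = 0L) {
  stopifnot(inherits(graph, "ccdbg"))
  res <- traverse_leg(graph, from, to, region_subseq, max_bases, min_bases,
                      C, T_C, params, want_len)
  walk <- tibble::tibble(unitig = res$walk_unitig, strand = res$walk_strand)
  p <- new_graph_path(res$seq, res$ann, res$ann_unitig,
                      rep(TRUE, nchar(res$seq)), walk,
                      complete = res$found, colors = res$colors_all)
  score_path(p, C, region_subseq)
}

# anchor locus of a match row
match_locus <- function(m) list(unitig = m$unitig, offset = m$offset, strand = m$strand)

flip_locus <- function(m) list(unitig = m$unitig, offset = m$offset, strand = -m$strand)

#' Extract one candidate corrective path for a non-solid region
#'
#' Chains greedy walks across the region's waypoints (source anchor, unique
#' near-solid matches in read order, target anchor); each leg's length bound
#' is `(waypoint distance + k) * (1 + F)`. A failed leg contributes a gap
#' element holding the corresponding uncorrected read subsequence, and the
#' search resumes from the next waypoint. Regions without waypoints are
#' searched source-to-target with path length bounds `[l_min, l_max]`;
#' head/tail regions run an open-ended walk from their single anchor.
#' `direction = "backward"` runs the search from the target towards the
#' source on the reverse complement and returns the result in read
#' orientation.
#'
#' @param graph a `ccdbg`
#' @param region one region (a row of [delimit_regions()] output, as a list)
#' @param read the full uncorrected read
#' @param solid,near_solid match tibbles from [classify_kmers()]
#' @param params a [traversal_params()] set
#' @param direction `"forward"` or `"backward"`
#' @param C guiding color set; computed by the caller (pass-1 union or pass-2
#'   side intersection)
#' @param T_C color floor
#' @return a scored `graph_path` covering the read interval
#'   `[region$start, region$end]`, or NULL when the region has no anchor
#' @export
find_region_path <- function(graph, region, read, solid, near_solid, params,
                             direction = c("forward", "backward"),
                             C = integer(0), T_C = 0L) {
  direction <- match.arg(direction)
  k <- graph$k
  if (is.null(region$source) && is.null(region$target)) return(NULL)
  region_seq <- substr(read, region$start, region$end)
  l <- region$l

  # express the problem in walk orientation: list of waypoints with positions
  # local to the (possibly reverse-complemented) region sequence
  localize <- function(m, flip) {
    q <- m$pos - region$start + 1L  # 1-based k-mer start in region coords
    if (flip) q <- (l - k + 1L) - q + 1L
    list(pos = q, locus = if (flip) flip_locus(m) else match_locus(m))
  }
  flip <- direction == "backward"
  src <- if (flip) region$target else region$source
  tgt <- if (flip) region$source else region$target
  if (is.null(src)) {
    # single-anchor region whose anchor sits at the far end: walk from the
    # anchor over the reverse complement regardless of requested direction
    flip <- !flip
    tmp <- src; src <- tgt; tgt <- tmp
  }
  oriented_region <- if (flip) revcomp(region_seq) else region_seq
  unsms <- region$unsms
  way <- lapply(seq_len(nrow(unsms)), function(i) {
    localize(list(pos = unsms$pos[i], unitig = unsms$unitig[i],
                  offset = unsms$offset[i], strand = unsms$strand[i]), flip)
  })
  way <- way[order(vapply(way, function(w) w$pos, numeric(1)))]
  src_l <- localize(src, flip)

  seq_parts <- character(0)
  ann <- integer(0); annuid <- integer(0); fromg <- logical(0)
  had_gap <- FALSE
  reached_target <- TRUE

  # initial k bases: the source k-mer as written along the walk
  init <- traverse_leg(graph, src_l$locus, NULL, substr(oriented_region, 1, k),
                       k, 0L, C, 0L, params, want_len = k)
  seq_parts <- init$seq
  ann <- init$ann; annuid <- init$ann_unitig; fromg <- rep(TRUE, k)
  walk_u <- init$walk_unitig; walk_s <- init$walk_strand
  colors_all <- init$colors_all
  cur <- src_l

  append_result <- function(res) {
    add <- substr(res$seq, k + 1L, nchar(res$seq))
    seq_parts <<- c(seq_parts, add)
    n_add <- nchar(add)
    ann <<- c(ann, res$ann[(k + 1):length(res$ann)][seq_len(n_add)])
    annuid <<- c(annuid, res$ann_unitig[(k + 1):length(res$ann_unitig)][seq_len(n_add)])
    fromg <<- c(fromg, rep(TRUE, n_add))
    walk_u <<- c(walk_u, res$walk_unitig[-1])
    walk_s <<- c(walk_s, res$walk_strand[-1])
    colors_all <<- union(colors_all, res$colors_all)
  }
  append_gap <- function(from_pos, to_pos) {
    # raw (oriented) region bases (from_pos + k, to_pos + k - 1]
    gap <- substr(oriented_region, from_pos + k, to_pos + k - 1L)
    seq_parts <<- c(seq_parts, gap)
    n <- nchar(gap)
    ann <<- c(ann, rep(0L, n)); annuid <<- c(annuid, rep(NA_integer_, n))
    fromg <<- c(fromg, rep(FALSE, n))
    had_gap <<- TRUE
  }

  if (!is.null(tgt)) {
    tgt_l <- localize(tgt, flip)
    stops <- c(way, list(tgt_l))
    no_unsm <- length(way) == 0
    for (i in seq_along(stops)) {
      nxt <- stops[[i]]
      leg_region <- substr(oriented_region, cur$pos, nxt$pos + k - 1L)
      span <- nxt$pos - cur$pos + k
      max_b <- if (no_unsm) region$l_max else as.integer(floor(span * (1 + params$F)))
      min_b <- if (no_unsm) region$l_min else 0L
      res <- traverse_leg(graph, cur$locus, nxt$locus, leg_region, max_b, min_b,
                          C, T_C, params)
      if (res$found) append_result(res) else {
        append_gap(cur$pos, nxt$pos)
        reached_target <- reached_target && FALSE
      }
      cur <- nxt
    }
    if (!reached_target) reached_target <- FALSE
    complete <- !had_gap && reached_target
  } else {
    # open-ended tail (in walk orientation): aim for the region length
    res <- traverse_leg(graph, cur$locus, NULL, oriented_region,
                        region$l_max, region$l_min, C, T_C, params,
                        want_len = l)
    if (nchar(res$seq) > k) append_result(res)
    if (!res$found) {
      # stalled early: carry the remaining raw bases as a gap
      done <- nchar(paste(seq_parts, collapse = ""))
      if (done < l) {
        gap <- substr(oriented_region, done + 1L, l)
        seq_parts <- c(seq_parts, gap)
        ann <- c(ann, rep(0L, nchar(gap))); annuid <- c(annuid, rep(NA_integer_, nchar(gap)))
        fromg <- c(fromg, rep(FALSE, nchar(gap)))
        had_gap <- TRUE
      }
    }
    complete <- res$found && !had_gap
  }

  sequence <- paste(seq_parts, collapse = "")
  if (flip) {
    sequence <- revcomp(sequence)
    ann <- rev(iupac_complement_mask(ann))
    ann[is.na(ann)] <- 0L
    annuid <- rev(annuid)
    fromg <- rev(fromg)
    walk_u <- rev(walk_u)
    walk_s <- -rev(walk_s)
  }
  walk <- tibble::tibble(unitig = walk_u, strand = walk_s)
  # a complete path must respect the region length bounds
  if (complete && (nchar(sequence) < region$l_min || nchar(sequence) > region$l_max)) {
    complete <- FALSE
  }
  p <- new_graph_path(sequence, as.integer(ann), annuid, fromg, walk, complete,
                      colors = colors_all)
  score_path(p, C, region_seq)
}
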