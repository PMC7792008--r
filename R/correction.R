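new_region_correction <- function(sequence, ann, ann_unitig, from_graph,
                                  source_direction, complete) {
  structure(list(sequence = sequence, ann = ann, ann_unitig = ann_unitig,
                 from_graph = from_graph, source_direction = source_direction,
                 complete = complete, snp_sites = NULL, flagged = FALSE),
            class = "region_correction")
}

path_to_correction <- function(path, direction) {
  new_region_correction(path$sequence, path$ann, path$ann_unitig, path$from_graph,
                        direction, path$complete)
}

# per-region-position decomposition of a correction aligned to the region:
# m_base[r] = correction index aligned (M) at region position r (NA if none);
# pieces[[r + 1]] = correction indices consumed at region position r plus the
# insertion run that follows it (pieces[[1]] is the leading-insertion prefix)
alignment_pieces <- function(corr_seq, region_seq) {
  ops <- strsplit(cpp_align_global(corr_seq, region_seq)$ops, "")[[1]]
  l <- nchar(region_seq)
  pieces <- vector("list", l + 1L)
  m_base <- rep(NA_integer_, l)
  ci <- 0L; ri <- 0L
  for (op in ops) {
    if (op == "M") {
      ci <- ci + 1L; ri <- ri + 1L
      m_base[ri] <- ci
      pieces[[ri + 1L]] <- c(pieces[[ri + 1L]], ci)
    } else if (op == "I") {
      ci <- ci + 1L
      pieces[[ri + 1L]] <- c(pieces[[ri + 1L]], ci)
    } else {
      ri <- ri + 1L
    }
  }
  list(pieces = pieces, m_base = m_base)
}

#' Reconcile forward and backward corrections of a region
#'
#' If exactly one direction produced a complete path it wins. When both are
#' incomplete, each is globally aligned to the uncorrected region and the two
#' alignments are walked in parallel: at every region position the correction
#' whose aligned base is graph-derived (not part of a gap element) supplies
#' the output, ties going to the forward correction. If neither direction
#' produced a path the region is left uncorrected.
#'
#' @param fwd,bwd `graph_path` objects (either may be NULL)
#' @param region_subseq the uncorrected region sequence
#' @return a `region_correction`
#' @export
reconcile_directions <- function(fwd, bwd, region_subseq) {
  if (is.null(fwd) && is.null(bwd)) {
    n <- nchar(region_subseq)
    out <- new_region_correction(region_subseq, rep(0L, n), rep(NA_integer_, n),
                                 rep(FALSE, n), "uncorrected", FALSE)
    return(out)
  }
  if (is.null(bwd) || (isTRUE(fwd$complete) && !isTRUE(bwd$complete))) {
    return(path_to_correction(fwd, "forward"))
  }
  if (is.null(fwd) || (isTRUE(bwd$complete) && !isTRUE(fwd$complete))) {
    return(path_to_correction(bwd, "backward"))
  }
  if (isTRUE(fwd$complete) && isTRUE(bwd$complete)) {
    return(path_to_correction(fwd, "forward"))  # tie: forward
  }
  # both incomplete: merge along the region
  pf <- alignment_pieces(fwd$sequence, region_subseq)
  pb <- alignment_pieces(bwd$sequence, region_subseq)
  l <- nchar(region_subseq)
  fc <- strsplit(fwd$sequence, "")[[1]]
  bc <- strsplit(bwd$sequence, "")[[1]]
  seq_out <- character(0); ann <- integer(0); annuid <- integer(0); fromg <- logical(0)
  take <- function(corr, chars, idx) {
    seq_out <<- c(seq_out, chars[idx])
    ann <<- c(ann, corr$ann[idx])
    annuid <<- c(annuid, corr$ann_unitig[idx])
    fromg <<- c(fromg, corr$from_graph[idx])
  }
  # leading-insertion prefix: forward wins when it has one
  if (length(pf$pieces[[1]])) take(fwd, fc, pf$pieces[[1]])
  else if (length(pb$pieces[[1]])) take(bwd, bc, pb$pieces[[1]])
  for (r in seq_len(l)) {
    fM <- pf$m_base[r]; bM <- pb$m_base[r]
    f_graph <- !is.na(fM) && fwd$from_graph[fM]
    b_graph <- !is.na(bM) && bwd$from_graph[bM]
    if (f_graph) take(fwd, fc, pf$pieces[[r + 1L]])
    else if (b_graph) take(bwd, bc, pb$pieces[[r + 1L]])
    else if (!is.na(fM)) take(fwd, fc, pf$pieces[[r + 1L]])
    else if (!is.na(bM)) take(bwd, bc, pb$pieces[[r + 1L]])
  }
  new_region_correction(paste(seq_out, collapse = ""), ann, annuid, fromg,
                        "merged", FALSE)
}

#' Restore candidate-SNP alleles from the raw read
#'
#' The corrected region is globally aligned to the uncorrected one. At every
#' match/mismatch column whose corrected base carries an IUPAC candidate-SNP
#' annotation, the raw base overwrites the corrected one if it belongs to the
#' symbol's base set -- only bases actually observed in the read are written,
#' so the correction never invents an allele. A site whose bases already
#' agreed is *strongly compatible*: the path choice around it is trusted, and
#' annotated bases of the same unitig inside the insertion run adjacent to
#' the site are additionally restored from the correspondingly offset raw
#' bases.
#'
#' @param region_subseq the uncorrected region sequence
#' @param correction a `region_correction`
#' @param graph the annotated `ccdbg` (for documentation of provenance;
#'   annotations travel with the correction)
#' @param F error-rate bound; corrections whose length ratio to the region
#'   falls outside `[1/(1+F), 1+F]` are returned unchanged, flagged
#' @return the updated `region_correction` with a `snp_sites` tibble
#' @export
restore_snps <- function(region_subseq, correction, graph, F = 0.4) {
  stopifnot(inherits(correction, "region_correction"))
  if (nchar(correction$sequence) == 0) stop("correction sequence is empty")
  if (!any(correction$ann > 0)) {
    correction$snp_sites <- empty_snp_sites()
    return(correction)
  }
  ratio <- nchar(correction$sequence) / nchar(region_subseq)
  if (ratio < 1 / (1 + F) || ratio > 1 + F) {
    correction$flagged <- TRUE
    correction$snp_sites <- empty_snp_sites()
    return(correction)
  }
  s <- strsplit(region_subseq, "")[[1]]
  p <- strsplit(correction$sequence, "")[[1]]
  ops <- strsplit(cpp_align_global(correction$sequence, region_subseq)$ops, "")[[1]]
  nc <- length(ops)
  ci <- ri <- 0L
  col_ci <- col_ri <- rep(NA_integer_, nc)
  for (j in seq_len(nc)) {
    if (ops[j] != "D") { ci <- ci + 1L; col_ci[j] <- ci }
    if (ops[j] != "I") { ri <- ri + 1L; col_ri[j] <- ri }
  }
  sites <- list()
  m_cols <- which(ops == "M")
  for (j in m_cols) {
    cp <- col_ci[j]; rp <- col_ri[j]
    mask <- correction$ann[cp]
    if (mask > 0 && base_in_mask(s[rp], mask)) {
      strongly <- p[cp] == s[rp]
      p[cp] <- s[rp]
      sites[[length(sites) + 1L]] <- list(offset = cp, symbol = iupac_symbol(mask),
                                          unitig = correction$ann_unitig[cp],
                                          strongly_compatible = strongly)
      if (strongly) {
        # maximal insertion runs touching this column
        for (dir in c(-1L, 1L)) {
          jj <- j + dir
          while (jj >= 1 && jj <= nc && ops[jj] == "I") {
            qc <- col_ci[jj]
            qmask <- correction$ann[qc]
            same_unitig <- !is.na(correction$ann_unitig[qc]) &&
              !is.na(correction$ann_unitig[cp]) &&
              correction$ann_unitig[qc] == correction$ann_unitig[cp]
            if (qmask > 0 && same_unitig) {
              raw_i <- rp + (qc - cp)
              if (raw_i >= 1 && raw_i <= length(s) && base_in_mask(s[raw_i], qmask)) {
                p[qc] <- s[raw_i]
              }
            }
            jj <- jj + dir
          }
        }
      }
    }
  }
  correction$sequence <- paste(p, collapse = "")
  correction$snp_sites <- if (length(sites)) {
    tibble::tibble(
      offset = vapply(sites, function(x) x$offset, integer(1)),
      symbol = vapply(sites, function(x) x$symbol, character(1)),
      unitig = vapply(sites, function(x) x$unitig, integer(1)),
      strongly_compatible = vapply(sites, function(x) x$strongly_compatible, logical(1))
    )
  } else empty_snp_sites()
  correction
}

empty_snp_sites <- function() {
  tibble::tibble(offset = integer(0), symbol = character(0), unitig = integer(0),
                 strongly_compatible = logical(0))
}

# pass-2 color guidance: union of the per-side color intersections over solid
# matches within B bases of each region boundary
side_intersection_colors <- function(solid, region, B, graph) {
  side <- function(lo, hi) {
    m <- solid[solid$pos >= lo & solid$pos <= hi, , drop = FALSE]
    if (nrow(m) == 0) return(integer(0))
    Reduce(intersect, kmer_colors(graph, m$unitig, m$offset))
  }
  Cs <- if (!is.null(region$source)) side(region$source$pos - B, region$source$pos) else integer(0)
  Ct <- if (!is.null(region$target)) side(region$target$pos, region$target$pos + B) else integer(0)
  sort(union(Cs, Ct))
}

# drop solid matches belonging to runs spanning fewer than min_bases bases
filter_short_solid_runs <- function(solid, k, min_bases) {
  if (nrow(solid) == 0 || min_bases <= k) return(solid)
  run_id <- cumsum(c(1L, diff(solid$pos) != 1L))
  span <- stats::ave(solid$pos, run_id, FUN = function(x) max(x) - min(x) + k)
  solid[span >= min_bases, , drop = FALSE]
}

region_row <- function(regions, i) {
  list(start = regions$start[i], end = regions$end[i], l = regions$l[i],
       l_min = regions$l_min[i], l_max = regions$l_max[i],
       source = regions$source[[i]], target = regions$target[[i]],
       unsms = regions$unsms[[i]])
}

#' Correct one long read against the graph
#'
#' Classifies the read's k-mers, delimits its non-solid regions, extracts a
#' forward candidate path per region (and a backward one when the forward
#' path is absent or incomplete), reconciles the two, restores candidate-SNP
#' alleles from the raw read, and splices the region corrections between the
#' untouched solid regions. Reads without any solid anchor are returned
#' unchanged and flagged.
#'
#' @param read a DNA string
#' @param graph a colored, annotated `ccdbg`
#' @param params a [traversal_params()] set
#' @param pass_cfg a [pass_config()]; decides the color guidance mode
#'   (pass 1: window union; pass 2: side intersections), the minimum solid
#'   region span and the frontier mode
#' @return list with `corrected` (DNA string), `stats` (per-region tibble)
#'   and `flagged` (TRUE when the read could not be anchored)
#' @export
correct_read <- function(read, graph, params = traversal_params(),
                         pass_cfg = pass_config(1, graph$k)) {
  k <- graph$k
  q_ok <- "5"; q_gap <- "("  # Q20 for corrected/verified bases, Q7 for raw gap bases
  if (nchar(read) < k) {
    return(list(corrected = read, qual = strrep(q_gap, nchar(read)),
                stats = empty_region_stats(), flagged = TRUE))
  }
  cls <- classify_kmers(read, graph)
  solid <- filter_short_solid_runs(cls$solid, k, pass_cfg$min_solid_region)
  near <- cls$near_solid
  if (nrow(solid) == 0) {
    return(list(corrected = read, qual = strrep(q_gap, nchar(read)),
                stats = empty_region_stats(), flagged = TRUE))
  }
  eff_params <- params
  eff_params$B <- pass_cfg$B
  eff_params$frontier_mode <- pass_cfg$frontier_mode
  regions <- delimit_regions(solid, near, nchar(read), k, params$F)
  # one color query for all matches of the read; regions reuse the result
  n_solid <- nrow(solid)
  all_pos <- c(solid$pos, near$pos)
  all_colors <- if (length(all_pos)) {
    kmer_colors(graph, c(solid$unitig, near$unitig), c(solid$offset, near$offset))
  } else list()
  all_sizes <- lengths(all_colors)
  parts <- character(0)
  qparts <- character(0)
  cursor <- 1L
  stats <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    region <- region_row(regions, i)
    region_seq <- substr(read, region$start, region$end)
    B <- pass_cfg$B
    lo <- if (is.null(region$source)) -Inf else region$source$pos - B
    hi <- if (is.null(region$target)) Inf else region$target$pos + B
    win <- which(all_pos >= lo & all_pos <= hi)
    C <- if (pass_cfg$color_mode == "pair_union") {
      sort(unique(unlist(all_colors[win], use.names = FALSE)))
    } else {
      # per-side intersections over solid matches only
      side <- function(a, b) {
        idx <- which(all_pos <= b & all_pos >= a & seq_along(all_pos) <= n_solid)
        if (length(idx) == 0) integer(0) else Reduce(intersect, all_colors[idx])
      }
      Cs <- if (!is.null(region$source)) side(region$source$pos - B, region$source$pos) else integer(0)
      Ct <- if (!is.null(region$target)) side(region$target$pos, region$target$pos + B) else integer(0)
      sort(union(Cs, Ct))
    }
    T_C <- if (length(C) == 0 || length(win) == 0) 0L else {
      as.integer(floor(params$D * min(all_sizes[win])))
    }
    fwd <- find_region_path(graph, region, read, solid, near, eff_params,
                            "forward", C, T_C)
    corr <- if (is.null(fwd)) {
      reconcile_directions(NULL, NULL, region_seq)
    } else if (isTRUE(fwd$complete)) {
      path_to_correction(fwd, "forward")
    } else {
      bwd <- find_region_path(graph, region, read, solid, near, eff_params,
                              "backward", C, T_C)
      reconcile_directions(fwd, bwd, region_seq)
    }
    corr <- restore_snps(region_seq, corr, graph, params$F)
    # splice: solid and non-solid regions overlap by up to k bases (the shared
    # anchor k-mers); drop the leading correction bases already emitted
    emit <- corr$sequence
    emit_fromg <- corr$from_graph
    if (region$start >= cursor) {
      parts <- c(parts, substr(read, cursor, region$start - 1L))
      qparts <- c(qparts, strrep(q_ok, region$start - cursor))
    } else {
      overlap <- cursor - region$start
      emit <- substr(emit, overlap + 1L, nchar(emit))
      emit_fromg <- emit_fromg[-seq_len(min(overlap, length(emit_fromg)))]
    }
    parts <- c(parts, emit)
    qparts <- c(qparts, paste(ifelse(emit_fromg[seq_len(nchar(emit))],
                                     q_ok, q_gap), collapse = ""))
    cursor <- max(cursor, region$end + 1L)
    stats[[i]] <- list(region$start, region$end, region$l, nchar(corr$sequence),
                       corr$complete, corr$source_direction,
                       nrow(corr$snp_sites), sum(!corr$from_graph))
  }
  parts <- c(parts, substr(read, cursor, nchar(read)))
  qparts <- c(qparts, strrep(q_ok, max(0L, nchar(read) - cursor + 1L)))
  stats_tbl <- tibble::tibble(
    start = vapply(stats, function(x) x[[1]], integer(1)),
    end = vapply(stats, function(x) x[[2]], integer(1)),
    l = vapply(stats, function(x) x[[3]], integer(1)),
    corrected_len = vapply(stats, function(x) x[[4]], integer(1)),
    complete = vapply(stats, function(x) x[[5]], logical(1)),
    direction = vapply(stats, function(x) x[[6]], character(1)),
    n_snp_sites = vapply(stats, function(x) x[[7]], integer(1)),
    n_gap_bases = vapply(stats, function(x) x[[8]], integer(1))
  )
  list(corrected = paste(parts, collapse = ""),
       qual = paste(qparts, collapse = ""), stats = stats_tbl, flagged = FALSE)
}

empty_region_stats <- function() {
  tibble::tibble(start = integer(0), end = integer(0), l = integer(0),
                 corrected_len = integer(0), complete = logical(0),
                 direction = character(0), n_snp_sites = integer(0),
                 n_gap_bases = integer(0))
}
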