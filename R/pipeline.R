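#' Correction pass configuration
#'
#' Pass 1 anchors with the short k-mer (`k1`) graph colored by short-read
#' pairs, guides traversal with the window *union* of colors, uses a
#' unitig-count search frontier and accepts solid regions of any span. Pass 2
#' anchors with the long k-mer (`k2`) graph colored by the pass-1 corrected
#' long reads, guides with the *intersection* of colors on each side of a
#' region, uses a base-length frontier, and requires solid regions to span at
#' least `B > k2` bases.
#'
#' @param pass_id 1 or 2
#' @param k graph k-mer length for the pass
#' @param B color buffer (pass 1) or base-length frontier and minimum solid
#'   region span (pass 2), in bases
#' @param min_solid_region minimum solid region span in bases
#' @param color_mode,frontier_mode overrides; defaults follow the pass id
#' @return a `pass_config` list
#' @export
pass_config <- function(pass_id, k, B = if (pass_id == 1) 1000L else 2L * k,
                        min_solid_region = if (pass_id == 1) k else B,
                        color_mode = if (pass_id == 1) "pair_union" else "side_intersection",
                        frontier_mode = if (pass_id == 1) "unitig_count" else "base_length") {
  stopifnot(pass_id %in% c(1L, 2L))
  if (pass_id == 2 && B <= k) stop("pass 2 requires B > k2")
  structure(list(pass_id = as.integer(pass_id), k = as.integer(k), B = as.integer(B),
                 min_solid_region = as.integer(min_solid_region),
                 color_mode = color_mode, frontier_mode = frontier_mode),
            class = "pass_config")
}

#' Run configuration for the full two-pass pipeline
#'
#' `k2 >= 2 * k1` is required: the long k-mer graph must be strictly coarser
#' so that its unitigs untangle repeat structure the short k-mer graph cannot.
#'
#' @param k1,k2 odd k-mer lengths for pass 1 and pass 2
#' @param min_count minimum k-mer multiplicity in graph construction
#' @param F error-rate upper bound
#' @param B1,B2 color buffer (pass 1) / frontier length (pass 2), bases
#' @param P_max unitigs per search stage (pass 1)
#' @param D color-floor factor
#' @param mapq_min minimum mapping quality for confident binning
#' @param bin_size reference bin size in bases
#' @param seed integer seed for any randomized step
#' @return a `run_config` list
#' @export
run_config <- function(k1 = 31, k2 = 63, min_count = 2, F = 0.4, B1 = 1000,
                       B2 = 2 * k2, P_max = 4, D = 0.2, mapq_min = 30,
                       bin_size = 5e6, seed = 1L) {
  stopifnot(k1 %% 2 == 1, k2 %% 2 == 1, k1 >= 3)
  if (k2 < 2 * k1) stop("k2 must be at least 2 * k1")
  if (B2 <= k2) stop("B2 must exceed k2")
  structure(list(k1 = as.integer(k1), k2 = as.integer(k2),
                 min_count = as.integer(min_count), F = F, B1 = as.integer(B1),
                 B2 = as.integer(B2), P_max = as.integer(P_max), D = D,
                 mapq_min = as.integer(mapq_min), bin_size = as.integer(bin_size),
                 seed = as.integer(seed)),
            class = "run_config")
}

params_from_config <- function(config) {
  traversal_params(F = config$F, B = config$B1, P_max = config$P_max, D = config$D)
}

# read sets are tibbles with columns id, seq (and optionally qual)
as_read_set <- function(x) {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("read", seq_along(x))
    return(tibble::tibble(id = ids, seq = unname(x)))
  }
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  tibble::as_tibble(x)
}

# pair up interleaved short reads: mates (1,2), (3,4), ...
srs_pairs <- function(srs) {
  srs <- as_read_set(srs)
  if (nrow(srs) %% 2 != 0) {
    stop("short reads must be paired: expected an even number of interleaved mates")
  }
  n <- nrow(srs) / 2
  lapply(seq_len(n), function(i) c(srs$seq[2 * i - 1], srs$seq[2 * i]))
}

# build + color + annotate the pass-1 graph (k1 subgraph of the k2 graph)
build_pass1_graph <- function(srs, config) {
  g2 <- suppressWarnings(build_graph(as_read_set(srs)$seq, config$k2, config$min_count))
  g1 <- build_subgraph_from_unitigs(g2, config$k1)
  units <- srs_pairs(srs)
  if (length(units) > 0) color_graph(g1, units, seq_along(units))
  annotate_candidate_snps(g1)
  list(g1 = g1, g2 = g2)
}

correct_all <- function(lrs, graph, params, cfg) {
  lrs <- as_read_set(lrs)
  out <- lrs
  out$qual <- rep(NA_character_, nrow(lrs))
  flagged <- logical(nrow(lrs))
  complete_frac <- numeric(nrow(lrs))
  for (i in seq_len(nrow(lrs))) {
    res <- correct_read(lrs$seq[i], graph, params, cfg)
    out$seq[i] <- res$corrected
    out$qual[i] <- res$qual
    flagged[i] <- res$flagged
    complete_frac[i] <- if (nrow(res$stats)) mean(res$stats$complete) else 1
  }
  attr(out, "flagged") <- flagged
  attr(out, "complete_frac") <- complete_frac
  out
}

#' First correction pass
#'
#' Builds the long k-mer graph `G2` from the short reads (k-mers seen fewer
#' than `min_count` times discarded), derives the short k-mer graph `G1` from
#' its unitigs, colors `G1` with the short-read pairs, annotates candidate
#' SNPs, and corrects every long read independently with window-union color
#' guidance.
#'
#' @param srs paired short reads: a read-set tibble (`id`, `seq`) or character
#'   vector with mates interleaved (mate 1 of pair i at row 2i-1)
#' @param lrs long reads (read-set tibble or character vector)
#' @param config a [run_config()]
#' @return corrected long reads as a read-set tibble, with attributes
#'   `flagged` (reads that could not be anchored) and `complete_frac`
#' @export
run_pass1 <- function(srs, lrs, config = run_config()) {
  lrs <- as_read_set(lrs)
  if (nrow(lrs) == 0) return(lrs)
  srs <- as_read_set(srs)
  if (nrow(srs) == 0) {
    attr(lrs, "flagged") <- rep(TRUE, nrow(lrs))
    warning("no short reads: long reads returned uncorrected")
    return(lrs)
  }
  gs <- build_pass1_graph(srs, config)
  params <- params_from_config(config)
  cfg <- pass_config(1, config$k1, B = config$B1)
  correct_all(lrs, gs$g1, params, cfg)
}

#' Second correction pass
#'
#' Rebuilds the long k-mer graph `G2` from the short reads, colors it with
#' the pass-1 corrected long reads (one color per read; no similar-read
#' removal is performed), annotates candidate SNPs, and corrects the reads
#' again, anchoring with `k2`-mers. Solid regions shorter than `B2` bases are
#' discarded as anchors, color guidance uses the per-side intersections, and
#' the search frontier is a base length rather than a unitig count.
#'
#' @param srs paired short reads (graph construction)
#' @param lrs pass-1 corrected long reads
#' @param config a [run_config()]
#' @param helper_lrs optional additional corrected long reads that assist the
#'   coloring but are not themselves corrected (used for the ambiguous bin in
#'   reference-guided mode)
#' @return corrected long reads as a read-set tibble
#' @export
run_pass2 <- function(srs, lrs, config = run_config(), helper_lrs = NULL) {
  lrs <- as_read_set(lrs)
  if (nrow(lrs) == 0) return(lrs)
  srs <- as_read_set(srs)
  if (nrow(srs) == 0) {
    attr(lrs, "flagged") <- rep(TRUE, nrow(lrs))
    warning("no short reads: long reads returned uncorrected")
    return(lrs)
  }
  g2 <- suppressWarnings(build_graph(srs$seq, config$k2, config$min_count))
  units <- as.list(lrs$seq)
  if (!is.null(helper_lrs)) units <- c(units, as.list(as_read_set(helper_lrs)$seq))
  if (length(units) > 0) color_graph(g2, units, seq_along(units))
  annotate_candidate_snps(g2)
  params <- traversal_params(F = config$F, B = config$B2, P_max = config$P_max,
                             D = config$D, frontier_mode = "base_length")
  cfg <- pass_config(2, config$k2, B = config$B2)
  correct_all(lrs, g2, params, cfg)
}

#' Two-pass correction
#'
#' Convenience wrapper running [run_pass1()] then [run_pass2()].
#'
#' @inheritParams run_pass1
#' @param passes `"both"`, `"1"` or `"2"`
#' @return corrected long reads as a read-set tibble
#' @export
correct_reads <- function(srs, lrs, config = run_config(), passes = "both") {
  passes <- as.character(passes)
  out <- as_read_set(lrs)
  if (passes %in% c("1", "both")) out <- run_pass1(srs, out, config)
  if (passes %in% c("2", "both")) out <- run_pass2(srs, out, config)
  out
}

#' Bin reads along a reference from their alignments
#'
#' Long reads (unpaired alignment records) are binned by the start of their
#' primary alignment into fixed-size reference windows; reads that are
#' unmapped or map with quality below `mapq_min` go to the ambiguous bin.
#' Short reads (records with the paired FLAG bit) are binned as pairs by
#' either mate's primary alignment (an unmapped mate follows its mapped
#' mate); pairs with both mates unmapped are collected separately for
#' [recover_unmapped()].
#'
#' @param alignments tibble from [parse_alignments()]: `qname`, `flag`,
#'   `rname`, `pos`, `mapq`
#' @param bin_size reference window size in bases (default 5 Mbp)
#' @param mapq_min minimum mapping quality for confident binning
#' @return list with `bins` (tibble: `rname`, `start`, `end`, `lrs_ids`,
#'   `srs_ids` list columns, `ambiguous` flag; the ambiguous bin has
#'   `rname = NA`) and `srs_unmapped` (character vector of unmapped
#'   short-read ids)
#' @export
bin_reads <- function(alignments, bin_size = 5e6, mapq_min = 30) {
  al <- tibble::as_tibble(alignments)
  stopifnot(all(c("qname", "flag", "rname", "pos", "mapq") %in% names(al)))
  primary <- bitwAnd(al$flag, 0x100L) == 0L & bitwAnd(al$flag, 0x800L) == 0L
  al <- al[primary, , drop = FALSE]
  unmapped <- bitwAnd(al$flag, 0x4L) == 1L * 0x4L
  paired <- bitwAnd(al$flag, 0x1L) == 1L

  key <- function(rname, pos) {
    b <- (pos - 1L) %/% as.integer(bin_size)
    paste0(rname, ":", b)
  }
  bins <- new.env(parent = emptyenv())
  add <- function(k, id, what) {
    if (is.null(bins[[k]])) bins[[k]] <- list(lrs = character(0), srs = character(0))
    bins[[k]][[what]] <- c(bins[[k]][[what]], id)
  }

  lr <- al[!paired, , drop = FALSE]
  lr_amb <- unmapped[!paired] | lr$mapq < mapq_min
  for (i in which(!lr_amb)) add(key(lr$rname[i], lr$pos[i]), lr$qname[i], "lrs")
  ambiguous_lrs <- lr$qname[lr_amb]

  sr <- al[paired, , drop = FALSE]
  sr_unmapped <- unmapped[paired]
  srs_unmapped <- character(0)
  for (qn in unique(sr$qname)) {
    rows <- which(sr$qname == qn)
    mapped <- rows[!sr_unmapped[rows]]
    if (length(mapped) == 0) {
      srs_unmapped <- c(srs_unmapped, qn)
    } else {
      i <- mapped[1]  # either mate's primary alignment decides the bin
      add(key(sr$rname[i], sr$pos[i]), qn, "srs")
    }
  }

  keys <- sort(ls(bins))
  parse_key <- function(k) {
    parts <- strsplit(k, ":")[[1]]
    b <- as.integer(parts[length(parts)])
    list(rname = paste(parts[-length(parts)], collapse = ":"), b = b)
  }
  rows <- lapply(keys, function(k) {
    pk <- parse_key(k)
    tibble::tibble(rname = pk$rname, start = pk$b * as.integer(bin_size) + 1L,
                   end = (pk$b + 1L) * as.integer(bin_size),
                   lrs_ids = list(unique(bins[[k]]$lrs)),
                   srs_ids = list(unique(bins[[k]]$srs)), ambiguous = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(out, tibble::tibble(
    rname = NA_character_, start = NA_integer_, end = NA_integer_,
    lrs_ids = list(unique(ambiguous_lrs)), srs_ids = list(character(0)),
    ambiguous = TRUE
  ))
  list(bins = out, srs_unmapped = unique(srs_unmapped))
}

#' Recover unmapped short reads into a bin
#'
#' Builds a k1-mer graph from the bin's short reads and one from its long
#' reads (k-mers occurring at least twice). The long-read graph is pruned by
#' iteratively removing its lowest-mean-coverage unitig stratum until it is
#' at most 10% larger than the short-read graph, which strips k-mers that are
#' merely recurrent sequencing errors. An unmapped short read is recovered
#' into the bin when more than half of its k1-mers occur in the pruned
#' long-read graph but not in the short-read graph -- the signature of a
#' sequence (e.g. a large insertion absent from the reference) that the bin's
#' long reads cover but its mapped short reads do not.
#'
#' @param bin_srs,bin_lrs read-set tibbles of the bin's short and long reads
#' @param srs_unmapped read-set tibble of unmapped short reads
#' @param k1 k-mer length
#' @param ratio size tolerance for the pruning stop rule (default 1.1)
#' @param min_frac fraction of k-mers required for recovery (default 0.5,
#'   strict inequality)
#' @return character vector of recovered read ids
#' @export
recover_unmapped <- function(bin_srs, bin_lrs, srs_unmapped, k1,
                             ratio = 1.1, min_frac = 0.5) {
  bin_srs <- as_read_set(bin_srs); bin_lrs <- as_read_set(bin_lrs)
  srs_unmapped <- as_read_set(srs_unmapped)
  if (nrow(srs_unmapped) == 0 || nrow(bin_lrs) == 0) return(character(0))
  g_s <- suppressWarnings(build_graph(bin_srs$seq, k1, 2))
  g_l <- suppressWarnings(build_graph(bin_lrs$seq, k1, 2))
  if (n_kmers(g_l) == 0 || n_kmers(g_s) == 0) return(character(0))

  ut <- unitigs(g_l)
  keep <- rep(TRUE, nrow(ut))
  kmer_count <- sum(ut$n_kmers)
  target <- ratio * n_kmers(g_s)
  while (kmer_count > target && any(keep)) {
    lowest <- min(ut$mean_cov[keep])
    drop <- keep & ut$mean_cov == lowest
    if (all(ut$mean_cov[keep] == lowest)) break  # refuse to empty the graph
    keep[drop] <- FALSE
    kmer_count <- sum(ut$n_kmers[keep])
  }
  kept_ids <- ut$unitig[keep]

  recovered <- character(0)
  for (i in seq_len(nrow(srs_unmapped))) {
    runs <- split_at_ambiguous(srs_unmapped$seq[i])
    kmers <- unlist(lapply(runs[nchar(runs) >= k1], function(s) {
      substring(s, 1:(nchar(s) - k1 + 1), k1:nchar(s))
    }))
    if (length(kmers) == 0) next
    in_l <- graph_lookup(g_l, kmers)
    in_l_kept <- in_l$present & in_l$unitig %in% kept_ids
    in_s <- graph_lookup(g_s, kmers)$present
    if (mean(in_l_kept & !in_s) > min_frac) {
      recovered <- c(recovered, srs_unmapped$id[i])
    }
  }
  recovered
}

#' Reference-guided binned correction
#'
#' Bins the reads by their alignments ([bin_reads()]), recovers likely
#' missing unmapped short reads into each bin ([recover_unmapped()]),
#' corrects every non-ambiguous bin independently (bins share no state, so
#' their processing order cannot change the result), then corrects the
#' ambiguous bin against all short reads with pass-2 coloring assisted by the
#' already-corrected non-ambiguous long reads. Output is merged in input read
#' order, one record per input long read.
#'
#' @param srs,lrs read-set tibbles (short reads interleaved by pair)
#' @param alignments alignment tibble from [parse_alignments()] covering both
#'   read sets (paired FLAG distinguishes short from long records)
#' @param config a [run_config()]
#' @param passes `"both"`, `"1"` or `"2"`
#' @return corrected long reads, one row per input long read, input order
#' @export
run_binned <- function(srs, lrs, alignments, config = run_config(), passes = "both") {
  srs <- as_read_set(srs); lrs <- as_read_set(lrs)
  binned <- bin_reads(alignments, config$bin_size, config$mapq_min)
  bins <- binned$bins
  aligned_ids <- unique(unlist(c(bins$lrs_ids, bins$srs_ids)))
  # long reads absent from the alignments are ambiguous by definition
  missing_lrs <- setdiff(lrs$id, unlist(bins$lrs_ids))
  amb_row <- which(bins$ambiguous)
  bins$lrs_ids[[amb_row]] <- c(bins$lrs_ids[[amb_row]], missing_lrs)
  srs_unmapped_reads <- srs[srs$id %in% binned$srs_unmapped, , drop = FALSE]

  corrected <- list()
  helper <- list()
  for (i in which(!bins$ambiguous)) {
    lrs_b <- lrs[lrs$id %in% bins$lrs_ids[[i]], , drop = FALSE]
    if (nrow(lrs_b) == 0) next
    srs_b <- srs[srs$id %in% bins$srs_ids[[i]], , drop = FALSE]
    rec <- recover_unmapped(srs_b, lrs_b, srs_unmapped_reads, config$k1)
    srs_b <- dplyr::bind_rows(srs_b, srs[srs$id %in% rec, , drop = FALSE])
    out_b <- correct_reads(srs_b, lrs_b, config, passes)
    corrected[[length(corrected) + 1L]] <- out_b
    helper[[length(helper) + 1L]] <- out_b
  }
  amb_ids <- bins$lrs_ids[[amb_row]]
  lrs_amb <- lrs[lrs$id %in% amb_ids, , drop = FALSE]
  if (nrow(lrs_amb) > 0) {
    helper_reads <- if (length(helper)) dplyr::bind_rows(helper) else NULL
    out_a <- as_read_set(lrs_amb)
    if (passes %in% c("1", "both")) out_a <- run_pass1(srs, out_a, config)
    if (passes %in% c("2", "both")) out_a <- run_pass2(srs, out_a, config,
                                                       helper_lrs = helper_reads)
    corrected[[length(corrected) + 1L]] <- out_a
  }
  merged <- dplyr::bind_rows(corrected)
  out <- merged[match(lrs$id, merged$id), , drop = FALSE]
  if (anyNA(out$id)) stop("internal error: some long reads were lost during binning")
  out
}
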