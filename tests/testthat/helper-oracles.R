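# Independent brute-force oracles used to validate the compiled implementation.
# All of them work directly on canonical k-mer string sets in plain R.

oracle_split_runs <- function(reads) {
  unlist(strsplit(reads, "[^ACGT]+"), use.names = FALSE)
}

oracle_kmer_counts <- function(reads, k) {
  runs <- oracle_split_runs(reads)
  runs <- runs[nchar(runs) >= k]
  kmers <- unlist(lapply(runs, function(s) {
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  }), use.names = FALSE)
  if (length(kmers) == 0) return(table(character(0)))
  table(canonicalize(kmers))
}

oracle_kmer_set <- function(reads, k, min_count = 1) {
  tab <- oracle_kmer_counts(reads, k)
  sort(names(tab)[tab >= min_count])
}

# k-mers spelled by a set of unitig sequences, canonical
unitig_kmer_list <- function(seqs, k) {
  kmers <- unlist(lapply(seqs, function(s) {
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  }), use.names = FALSE)
  canonicalize(kmers)
}

# oriented successor loci of an oriented k-mer within a canonical k-mer set
oracle_successors <- function(okmer, kmer_set, k) {
  out <- list()
  for (b in c("A", "C", "G", "T")) {
    cand <- paste0(substr(okmer, 2, k), b)
    if (canonicalize(cand) %in% kmer_set) out[[length(out) + 1L]] <- cand
  }
  out
}

# TRUE when no two distinct unitigs could be merged without creating a branch:
# an ordered oriented pair (a, b) is mergeable iff a's unique successor is b's
# head k-mer and b's head's unique predecessor is a's tail
oracle_check_maximality <- function(seqs, k) {
  kmer_set <- unitig_kmer_list(seqs, k)
  oriented <- list()
  for (i in seq_along(seqs)) {
    for (o in c(1L, -1L)) {
      s <- if (o > 0) seqs[i] else revcomp(seqs[i])
      oriented[[length(oriented) + 1L]] <- list(
        i = i, head = substr(s, 1, k), tail = substr(s, nchar(s) - k + 1L, nchar(s)))
    }
  }
  for (a in oriented) {
    succ <- oracle_successors(a$tail, kmer_set, k)
    if (length(succ) != 1) next
    for (b in oriented) {
      if (a$i == b$i) next
      if (succ[[1]] != b$head) next
      preds <- oracle_successors(revcomp(b$head), kmer_set, k)
      if (length(preds) == 1 && preds[[1]] == revcomp(a$tail)) return(FALSE)
    }
  }
  TRUE
}

# brute-force all-pairs Hamming-distance-1 candidate-SNP annotation:
# returns a data.frame (unitig, pos, mask) over the unitigs of `seqs`
oracle_snp_annotation <- function(seqs, k) {
  occ <- list()  # canonical kmer -> (unitig, offset)
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    for (p in 1:(nchar(s) - k + 1)) {
      occ[[length(occ) + 1L]] <- list(u = i, p = p, slice = substr(s, p, p + k - 1))
    }
  }
  mask <- list()
  add <- function(u, pos, bases) {
    key <- paste(u, pos)
    bits <- sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[bases])
    mask[[key]] <<- bitwOr(if (is.null(mask[[key]])) 0L else mask[[key]], bits)
  }
  n <- length(occ)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- occ[[i]]$slice
      for (b_or in c(occ[[j]]$slice, revcomp(occ[[j]]$slice))) {
        d <- which(strsplit(a, "")[[1]] != strsplit(b_or, "")[[1]])
        if (length(d) == 1) {
          add(occ[[i]]$u, occ[[i]]$p + d - 1L,
              c(substr(a, d, d), substr(b_or, d, d)))
        }
      }
    }
  }
  if (length(mask) == 0) {
    return(data.frame(unitig = integer(0), pos = integer(0), mask = integer(0)))
  }
  keys <- names(mask)
  parts <- strsplit(keys, " ")
  df <- data.frame(unitig = as.integer(vapply(parts, `[`, "", 1)),
                   pos = as.integer(vapply(parts, `[`, "", 2)),
                   mask = unlist(mask, use.names = FALSE))
  df[order(df$unitig, df$pos), ]
}

# all length-k strings at edit distance exactly <= 1 from window w, given the
# following read base (or NA at the read end); mirrors the near-solid contract
oracle_distance1_candidates <- function(w, next_base = NA) {
  k <- nchar(w)
  out <- character(0)
  ch <- strsplit(w, "")[[1]]
  for (i in 1:k) {
    for (b in setdiff(c("A", "C", "G", "T"), ch[i])) {
      x <- ch; x[i] <- b
      out <- c(out, paste(x, collapse = ""))
    }
  }
  if (!is.na(next_base)) {
    for (i in 1:k) out <- c(out, paste0(paste(ch[-i], collapse = ""), next_base))
  }
  for (i in 1:k) {
    for (b in c("A", "C", "G", "T")) {
      cand <- paste0(substr(w, 1, i - 1), b, substr(w, i, k - 1))
      out <- c(out, cand)
    }
  }
  setdiff(unique(out), w)
}

# exhaustive enumeration of all k-mer walks from one locus to another with a
# sequence length bound; returns candidate sequences (graphs must be small)
oracle_all_paths <- function(graph, from, to, max_bases, min_bases = 0) {
  k <- graph$k
  start_info <- unitig_info(graph, from$unitig)
  slice <- substr(start_info$seq, from$offset, from$offset + k - 1)
  start_seq <- if (from$strand > 0) slice else revcomp(slice)
  tgt_info <- unitig_info(graph, to$unitig)
  tslice <- substr(tgt_info$seq, to$offset, to$offset + k - 1)
  tgt_seq <- if (to$strand > 0) tslice else revcomp(tslice)
  found <- character(0)
  recurse <- function(seq) {
    if (nchar(seq) > max_bases) return()
    tail_km <- substr(seq, nchar(seq) - k + 1, nchar(seq))
    if (tail_km == tgt_seq && nchar(seq) >= max(min_bases, k + 1)) {
      found <<- c(found, seq)
      # a walk may also pass through the target and return; bounded by max_bases
    }
    for (b in c("A", "C", "G", "T")) {
      cand <- paste0(substr(tail_km, 2, k), b)
      if (graph_lookup(graph, cand)$present[1]) recurse(paste0(seq, b))
    }
  }
  recurse(start_seq)
  unique(found)
}

# deterministic small random genome
random_genome <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# error-free tiling read pairs over a sequence (for small graph fixtures)
tiling_pairs <- function(seq, read_len = 40, frag = 100, step = 7) {
  n <- nchar(seq)
  starts <- seq(1, max(1, n - frag + 1), by = step)
  srs <- unlist(lapply(starts, function(s) {
    f <- substr(seq, s, min(s + frag - 1, n))
    c(substr(f, 1, read_len), revcomp(substr(f, max(1, nchar(f) - read_len + 1), nchar(f))))
  }))
  tibble::tibble(id = rep(sprintf("p%04d", seq_along(starts)), each = 2), seq = srs)
}
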