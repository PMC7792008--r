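#' Simulate a diploid genome with heterozygous variants
#'
#' Haplotype 1 is iid uniform ACGT; haplotype 2 is obtained by placing
#' heterozygous SNPs and short indels at Poisson-spaced sites (exponential
#' inter-site distances at rate `snp_rate + indel_rate`). By default variant
#' sites are kept at least `min_spacing` bases apart and indels never overlap,
#' so that truth-based evaluation is unambiguous per site; set
#' `enforce_spacing = FALSE` to disable. Fully deterministic under
#' `(parameters, seed)`.
#'
#' @param length haplotype-1 length in bases (>= 10 * 63)
#' @param snp_rate,indel_rate per-base variant rates, each in \[0, 0.05\]
#' @param seed integer seed
#' @param min_spacing minimum distance between variant sites (default 63, the
#'   default pass-2 k-mer length, so no k-mer spans two variants)
#' @param enforce_spacing keep variant sites at least `min_spacing` apart
#' @return a `diploid_truth` list: `hap1`, `hap2`, `variants` tibble (`pos`
#'   on haplotype 1, `pos_hap2`, `type`, `ref`, `alt`) and an empty
#'   `read_provenance` tibble filled by [simulate_reads()]
#' @export
simulate_diploid <- function(length, snp_rate, indel_rate, seed,
                             min_spacing = 63L, enforce_spacing = TRUE) {
  stopifnot(length >= 10 * 63)
  if (snp_rate < 0 || snp_rate > 0.05 || indel_rate < 0 || indel_rate > 0.05) {
    stop("variant rates must lie in [0, 0.05]")
  }
  with_seed(seed, {
    hap1 <- random_dna(length)
    rate <- snp_rate + indel_rate
    sites <- integer(0)
    if (rate > 0) {
      pos <- 0
      min_gap <- if (enforce_spacing) min_spacing else 1L
      repeat {
        gap <- max(ceiling(rexp(1, rate)), min_gap)
        pos <- pos + gap
        if (pos > length - 10) break
        sites <- c(sites, as.integer(pos))
      }
    }
    variants <- make_variants(hap1, sites, snp_rate, indel_rate)
    hap2 <- apply_variants(hap1, variants)$seq
    variants$pos_hap2 <- apply_variants(hap1, variants)$pos_map[variants$pos]
    structure(list(hap1 = hap1, hap2 = hap2, variants = variants,
                   read_provenance = empty_provenance()),
              class = "diploid_truth")
  })
}

make_variants <- function(hap1, sites, snp_rate, indel_rate) {
  h <- strsplit(hap1, "")[[1]]
  bases <- c("A", "C", "G", "T")
  n <- length(sites)
  if (n == 0) {
    return(tibble::tibble(pos = integer(0), type = character(0),
                          ref = character(0), alt = character(0)))
  }
  type <- sample(c("SNP", "indel"), n, replace = TRUE,
                 prob = c(snp_rate, indel_rate) / (snp_rate + indel_rate))
  is_ins <- runif(n) < 0.5
  type[type == "indel"] <- ifelse(is_ins[type == "indel"], "insertion", "deletion")
  len <- pmin(1L + rgeom(n, 0.5), 6L)
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    p <- sites[i]
    if (type[i] == "SNP") {
      ref[i] <- h[p]
      alt[i] <- sample(setdiff(bases, h[p]), 1)
    } else if (type[i] == "insertion") {
      ref[i] <- h[p]
      alt[i] <- paste0(h[p], paste(sample(bases, len[i], replace = TRUE), collapse = ""))
    } else {
      ref[i] <- paste(h[p:min(p + len[i], length(h))], collapse = "")
      alt[i] <- h[p]
    }
  }
  tibble::tibble(pos = sites, type = type, ref = ref, alt = alt)
}

#' Apply a variant table to a haplotype
#'
#' Returns the alternate haplotype plus the coordinate map from input to
#' output positions (`pos_map[i]` is the output position of input base i, NA
#' for deleted bases).
#'
#' @param hap DNA string
#' @param variants tibble with `pos`, `type`, `ref`, `alt` (VCF-style alleles)
#' @return list with `seq` and `pos_map`
#' @export
apply_variants <- function(hap, variants) {
  n <- nchar(hap)
  pos_map <- rep(NA_integer_, n)
  parts <- character(0)
  cur <- 1L  # input cursor
  out <- 0L  # output length so far
  ord <- order(variants$pos)
  for (i in ord) {
    p <- variants$pos[i]
    if (p < cur) stop("overlapping variants at position ", p)
    if (substr(hap, p, p + nchar(variants$ref[i]) - 1L) != variants$ref[i]) {
      stop("variant REF mismatch at position ", p)
    }
    if (p > cur) {
      parts <- c(parts, substr(hap, cur, p - 1L))
      pos_map[cur:(p - 1L)] <- out + seq_len(p - cur)
      out <- out + (p - cur)
    }
    parts <- c(parts, variants$alt[i])
    ref_len <- nchar(variants$ref[i]); alt_len <- nchar(variants$alt[i])
    # the leading (shared) base maps through; the rest of REF is consumed
    pos_map[p] <- out + 1L
    if (variants$type[i] == "SNP" || variants$type[i] == "insertion") {
      # single REF base
    } else if (ref_len > 1) {
      # deleted bases have no image
    }
    out <- out + alt_len
    cur <- p + ref_len
  }
  if (cur <= n) {
    parts <- c(parts, substr(hap, cur, n))
    pos_map[cur:n] <- out + seq_len(n - cur + 1L)
  }
  list(seq = paste(parts, collapse = ""), pos_map = pos_map)
}

empty_provenance <- function() {
  tibble::tibble(id = character(0), haplotype = integer(0), start = integer(0),
                 strand = character(0), true_length = integer(0))
}

# introduce substitution/insertion/deletion errors into one sequence
mutate_sequence <- function(seq, sub, ins, del) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  bases <- c("A", "C", "G", "T")
  r <- runif(n)
  out <- ch
  is_del <- r < del
  is_sub <- !is_del & r < del + sub
  if (any(is_sub)) {
    out[is_sub] <- vapply(ch[is_sub], function(b) sample(setdiff(bases, b), 1), "")
  }
  out[is_del] <- ""
  has_ins <- runif(n) < ins
  if (any(has_ins)) {
    out[has_ins] <- paste0(out[has_ins], sample(bases, sum(has_ins), replace = TRUE))
  }
  paste(out, collapse = "")
}

#' Simulate paired short reads and noisy long reads from a diploid truth
#'
#' Reads are drawn uniformly from both haplotypes and strands. Short reads
#' are error-free except substitutions at rate `srs_err`; fragments are
#' normal around `insert_mean` and mates are reported in FR orientation,
#' interleaved (mate 1, mate 2) and sharing a pair id. Long-read lengths are
#' log-normal, truncated to \[1 kb, 4 x mean\] (and to the genome length);
#' long-read errors mix substitutions, insertions and deletions at the given
#' per-base rates, uniformly along the read (no homopolymer bias is
#' modelled). Per-read provenance (haplotype, start, strand, truth length)
#' is recorded in the returned truth object.
#'
#' @param truth a `diploid_truth`
#' @param srs_cov,lrs_cov target coverages (per diploid genome), > 0
#' @param srs_len short-read length (default 151)
#' @param insert_mean mean short-read fragment length
#' @param srs_err short-read substitution rate
#' @param lrs_len_mean mean long-read length
#' @param lrs_err numeric vector `c(sub, ins, del)` of long-read error rates
#' @param seed integer seed
#' @return list with `srs`, `lrs` (read-set tibbles) and `truth` (updated
#'   with `read_provenance`)
#' @export
simulate_reads <- function(truth, srs_cov = 40, srs_len = 151L,
                           insert_mean = 400L, srs_err = 0.002,
                           lrs_cov = 20, lrs_len_mean = 8000L,
                           lrs_err = c(sub = 0.04, ins = 0.03, del = 0.03),
                           seed = 1L) {
  stopifnot(inherits(truth, "diploid_truth"), srs_cov > 0, lrs_cov > 0)
  haps <- c(truth$hap1, truth$hap2)
  glen <- nchar(truth$hap1)
  if (srs_len > min(nchar(haps)) || lrs_len_mean > min(nchar(haps))) {
    stop("read length exceeds genome length")
  }
  with_seed(seed, {
    # --- short read pairs ---
    n_pairs <- ceiling(srs_cov * glen / (2 * srs_len))
    sr_rows <- vector("list", 2 * n_pairs)
    for (i in seq_len(n_pairs)) {
      h <- sample(1:2, 1)
      hl <- nchar(haps[h])
      flen <- max(srs_len, round(stats::rnorm(1, insert_mean, 0.1 * insert_mean)))
      flen <- min(flen, hl)
      fs <- sample.int(hl - flen + 1L, 1)
      frag <- substr(haps[h], fs, fs + flen - 1L)
      if (runif(1) < 0.5) frag <- revcomp(frag)
      m1 <- mutate_sequence(substr(frag, 1, srs_len), srs_err, 0, 0)
      m2 <- mutate_sequence(revcomp(substr(frag, flen - srs_len + 1L, flen)), srs_err, 0, 0)
      id <- sprintf("sr%06d", i)
      sr_rows[[2 * i - 1]] <- tibble::tibble(id = id, seq = m1)
      sr_rows[[2 * i]] <- tibble::tibble(id = id, seq = m2)
    }
    srs <- dplyr::bind_rows(sr_rows)

    # --- long reads ---
    target <- lrs_cov * glen
    meanlog <- log(lrs_len_mean) - 0.5 * 0.25^2
    lr_rows <- list(); prov <- list()
    total <- 0; i <- 0
    while (total < target) {
      i <- i + 1
      len <- round(rlnorm(1, meanlog, 0.25))
      len <- max(1000L, min(len, 4L * lrs_len_mean))
      h <- sample(1:2, 1)
      hl <- nchar(haps[h])
      len <- min(len, hl)
      st <- sample.int(hl - len + 1L, 1)
      tru <- substr(haps[h], st, st + len - 1L)
      strand <- if (runif(1) < 0.5) "+" else "-"
      oriented <- if (strand == "-") revcomp(tru) else tru
      noisy <- mutate_sequence(oriented, lrs_err[[1]], lrs_err[[2]], lrs_err[[3]])
      id <- sprintf("lr%05d", i)
      lr_rows[[i]] <- tibble::tibble(id = id, seq = noisy)
      prov[[i]] <- tibble::tibble(id = id, haplotype = h, start = st,
                                  strand = strand, true_length = len)
      total <- total + len
    }
    truth$read_provenance <- dplyr::bind_rows(prov)
    list(srs = srs, lrs = dplyr::bind_rows(lr_rows), truth = truth)
  })
}

# forward-haplotype truth substring for one provenance row
truth_subseq <- function(truth, prov_row) {
  hap <- if (prov_row$haplotype == 1) truth$hap1 else truth$hap2
  substr(hap, prov_row$start, prov_row$start + prov_row$true_length - 1L)
}

#' Write a diploid truth set to disk
#'
#' Haplotypes as FASTA, variants as a minimal VCF 4.2 (CHROM/POS/REF/ALT),
#' read provenance as TSV.
#'
#' @param truth a `diploid_truth`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  haps <- Biostrings::DNAStringSet(c(hap1 = truth$hap1, hap2 = truth$hap2))
  Biostrings::writeXStringSet(haps, file.path(dir, "haplotypes.fa"))
  vcf <- file.path(dir, "variants.vcf")
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=hap1>",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("hap1\t%d\t.\t%s\t%s\t.\tPASS\t.",
                  truth$variants$pos, truth$variants$ref, truth$variants$alt)
  writeLines(c(header, body), vcf)
  utils::write.table(truth$read_provenance, file.path(dir, "provenance.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Reload a diploid truth set written by [write_truth()]
#' @param dir directory
#' @return a `diploid_truth`
#' @export
read_truth <- function(dir) {
  haps <- Biostrings::readDNAStringSet(file.path(dir, "haplotypes.fa"))
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading truth sets requires the vcfR package")
  }
  v <- vcfR::read.vcfR(file.path(dir, "variants.vcf"), verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ref <- fix$REF; alt <- fix$ALT
  type <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP",
                 ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  variants <- tibble::tibble(pos = as.integer(fix$POS), type = type,
                             ref = ref, alt = alt)
  prov <- tibble::as_tibble(utils::read.delim(file.path(dir, "provenance.tsv"),
                                              stringsAsFactors = FALSE))
  hap1 <- as.character(haps[["hap1"]])
  variants$pos_hap2 <- apply_variants(hap1, variants)$pos_map[variants$pos]
  structure(list(hap1 = hap1, hap2 = as.character(haps[["hap2"]]),
                 variants = variants,
                 read_provenance = if (nrow(prov)) prov else empty_provenance()),
            class = "diploid_truth")
}
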