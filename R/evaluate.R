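#' Truth-based error rate of (corrected) reads
#'
#' For every read with provenance, the edit distance between the read and its
#' true haplotype subsequence is computed with free end gaps on the read side
#' (a trimmed read end is not penalized) and divided by the truth length.
#' This is a truth-based re-specification of the usual alignment-based error
#' rate: it requires simulated data and is exact per read.
#'
#' @param reads a read-set tibble (`id`, `seq`)
#' @param truth a `diploid_truth` with filled `read_provenance`
#' @return an `error_report` list: `per_read` tibble (`id`, `edit_distance`,
#'   `truth_length`, `error_rate`), `mean_rate`, `median_rate`, `n_skipped`
#' @export
error_rate <- function(reads, truth) {
  reads <- as_read_set(reads)
  stopifnot(inherits(truth, "diploid_truth"))
  prov <- truth$read_provenance
  rows <- vector("list", nrow(reads))
  n_skipped <- 0L
  for (i in seq_len(nrow(reads))) {
    pr <- prov[prov$id == reads$id[i], , drop = FALSE]
    if (nrow(pr) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    tru <- truth_subseq(truth, pr[1, ])
    if (pr$strand[1] == "-") tru <- revcomp(tru)
    d <- cpp_edit_dist(reads$seq[i], tru, FALSE)  # free end gaps on the read side
    rows[[i]] <- tibble::tibble(id = reads$id[i], edit_distance = d,
                                truth_length = nchar(tru),
                                error_rate = d / nchar(tru))
  }
  if (n_skipped > 0) {
    warning(n_skipped, " read(s) without provenance were skipped")
  }
  per_read <- dplyr::bind_rows(rows)
  structure(list(per_read = per_read,
                 mean_rate = mean(per_read$error_rate),
                 median_rate = stats::median(per_read$error_rate),
                 n_skipped = n_skipped),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("error_report: %d reads, mean %.4f%%, median %.4f%%\n",
              nrow(x$per_read), 100 * x$mean_rate, 100 * x$median_rate))
  invisible(x)
}

#' Heterozygous-allele retention of corrected reads
#'
#' Over all (read, covered heterozygous SNP site) pairs where the corrected
#' read aligns across the site (a match/mismatch column in its global
#' alignment to the truth subsequence), the fraction of pairs in which the
#' read carries its own haplotype's allele. A correction that smears reads
#' onto the wrong haplotype drives this towards 0.5 (or below); haplotype-
#' preserving correction keeps it near 1.
#'
#' @param reads a read-set tibble
#' @param truth a `diploid_truth` with at least one SNP and filled provenance
#' @return fraction in \[0, 1\] with attribute `n_sites`; `NA` when no site
#'   is covered
#' @export
het_retention <- function(reads, truth) {
  reads <- as_read_set(reads)
  stopifnot(inherits(truth, "diploid_truth"))
  snps <- truth$variants[truth$variants$type == "SNP", , drop = FALSE]
  if (nrow(snps) == 0) stop("truth has no heterozygous SNP")
  prov <- truth$read_provenance
  n_sites <- 0L
  n_true <- 0L
  for (i in seq_len(nrow(reads))) {
    pr <- prov[prov$id == reads$id[i], , drop = FALSE]
    if (nrow(pr) == 0) next
    pr <- pr[1, ]
    tru <- truth_subseq(truth, pr)
    # site positions within the truth subsequence, and the true alleles
    if (pr$haplotype == 1) {
      site_pos <- snps$pos - pr$start + 1L
      allele <- snps$ref
    } else {
      site_pos <- snps$pos_hap2 - pr$start + 1L
      allele <- substr(snps$alt, 1L, 1L)
    }
    inside <- !is.na(site_pos) & site_pos >= 1 & site_pos <= nchar(tru)
    if (!any(inside)) next
    site_pos <- site_pos[inside]; allele <- allele[inside]
    read_fwd <- if (pr$strand == "-") revcomp(reads$seq[i]) else reads$seq[i]
    ops <- strsplit(cpp_align_global(read_fwd, tru)$ops, "")[[1]]
    # map truth positions to read bases through M columns
    ci <- cumsum(ops != "D")
    ri <- cumsum(ops != "I")
    read_at <- rep(NA_integer_, nchar(tru))
    is_m <- ops == "M"
    read_at[ri[is_m]] <- ci[is_m]
    rb <- read_at[site_pos]
    across <- !is.na(rb)
    if (!any(across)) next
    got <- substring(read_fwd, rb[across], rb[across])
    n_sites <- n_sites + sum(across)
    n_true <- n_true + sum(got == allele[across])
  }
  if (n_sites == 0) {
    return(structure(NA_real_, n_sites = 0L))
  }
  structure(n_true / n_sites, n_sites = n_sites)
}
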