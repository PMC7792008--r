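# minimal SAM writer for binning fixtures (unavailable fields left as '*')
write_sam_fixture <- function(path, sq, records) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  unmapped <- bitwAnd(records$flag, 4L) == 4L
  cigar <- ifelse(unmapped, "*", "1M")
  seqf <- ifelse(unmapped, "*", "A")
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, cigar, seqf)
  writeLines(c(hdr, body), path)
  path
}

# alignment records for a read set mapped at known positions (flags: 0 for
# long reads; paired flags for short-read mates)
sam_record <- function(qname, flag, rname, pos, mapq = 60L) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos, mapq = mapq,
             stringsAsFactors = FALSE)
}

# small diploid correction fixture shared by pipeline tests
pipeline_fixture <- function(seed = 301, glen = 3000, lrs_cov = 4) {
  tr <- simulate_diploid(glen, 0.002, 0.0005, seed = seed, min_spacing = 19)
  sim <- simulate_reads(tr, srs_cov = 30, srs_len = 100, insert_mean = 250,
                        srs_err = 0.001, lrs_cov = lrs_cov, lrs_len_mean = 1000,
                        lrs_err = c(0.03, 0.02, 0.02), seed = seed + 1)
  sim$config <- run_config(k1 = 9, k2 = 19, B2 = 48)
  sim
}
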