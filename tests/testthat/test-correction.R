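synthetic_path <- function(sequence, from_graph = rep(TRUE, nchar(sequence)),
                           ann = rep(0L, nchar(sequence)),
                           ann_unitig = rep(1L, nchar(sequence)),
                           complete = all(from_graph)) {
  graphpolish:::new_graph_path(sequence, ann, ann_unitig, from_graph,
                               tibble::tibble(unitig = 1L, strand = 1L),
                               complete, colors = integer(0))
}

test_that("reconciliation prefers the complete direction", {
  region <- "ACGTACGTACGTACGTACGT"
  fwd <- synthetic_path(region, complete = TRUE)
  bwd <- synthetic_path(chartr("A", "T", region), complete = FALSE)
  out <- reconcile_directions(fwd, bwd, region)
  expect_equal(out$sequence, region)
  expect_equal(out$source_direction, "forward")
  out2 <- reconcile_directions(bwd, fwd, region)
  expect_equal(out2$sequence, region)
  expect_equal(out2$source_direction, "backward")
  # neither produced a path: uncorrected
  out3 <- reconcile_directions(NULL, NULL, region)
  expect_equal(out3$sequence, region)
  expect_equal(out3$source_direction, "uncorrected")
  expect_false(out3$complete)
})

test_that("incomplete directions merge by graph provenance along the region", {
  truth <- "ACGTTGCAGGATCCATTGCA"
  # raw region carries two errors, one in each half
  raw <- truth
  substr(raw, 5, 5) <- "A"
  substr(raw, 15, 15) <- "C"
  # forward correction fixed the left half, carries the raw right half as gap
  fwd_seq <- paste0(substr(truth, 1, 10), substr(raw, 11, 20))
  fwd <- synthetic_path(fwd_seq, from_graph = c(rep(TRUE, 10), rep(FALSE, 10)),
                        complete = FALSE)
  # backward correction fixed the right half
  bwd_seq <- paste0(substr(raw, 1, 10), substr(truth, 11, 20))
  bwd <- synthetic_path(bwd_seq, from_graph = c(rep(FALSE, 10), rep(TRUE, 10)),
                        complete = FALSE)
  out <- reconcile_directions(fwd, bwd, raw)
  expect_equal(out$source_direction, "merged")
  expect_equal(out$sequence, truth)
})

test_that("SNP restoration writes only raw bases compatible with the symbol", {
  raw <- "ACGTAAGGTACC"
  corr_seq <- "ACGTAGGGTACC"  # G at position 6 where the raw has A
  ann <- rep(0L, 12)
  ann[6] <- iupac_mask("R")  # A/G candidate site
  corr <- graphpolish:::new_region_correction(corr_seq, ann, rep(1L, 12),
                                              rep(TRUE, 12), "forward", TRUE)
  g <- graph_from_unitigs("ACGTAGG", 5)
  out <- restore_snps(raw, corr, g)
  expect_equal(substr(out$sequence, 6, 6), "A")  # raw allele restored
  expect_equal(out$snp_sites$symbol, "R")
  expect_false(out$snp_sites$strongly_compatible)

  # raw base incompatible with the symbol: unchanged
  raw2 <- "ACGTACGGTACC"  # C at the annotated site, C not in {A,G}
  out2 <- restore_snps(raw2, corr, g)
  expect_equal(out2$sequence, corr_seq)

  # a strongly compatible site leaves the base as is and is flagged
  raw3 <- corr_seq
  out3 <- restore_snps(raw3, corr, g)
  expect_equal(out3$sequence, corr_seq)
  expect_true(out3$snp_sites$strongly_compatible)
})

test_that("annotated bases in insertions next to strong sites are restored", {
  # corrected sequence has a 2-base insertion right after a strongly
  # compatible R site; the inserted annotated base disagrees with the raw
  raw <- "TTTTGACCCC"
  corr_seq <- "TTTTGAGCCCC"  # insertion of "G" after position 6 (A = strong R site? )
  ann <- rep(0L, 11)
  ann[6] <- iupac_mask("R")   # matches raw A at aligned position: strongly compatible
  ann[7] <- iupac_mask("K")   # inserted base, annotated G/T, raw offset base is C -> no
  corr <- graphpolish:::new_region_correction(corr_seq, ann, rep(1L, 11),
                                              rep(TRUE, 11), "forward", TRUE)
  g <- graph_from_unitigs(corr_seq, 5)
  out <- restore_snps(raw, corr, g)
  # the strong site kept, the K-annotated inserted base compared against the
  # raw base one step right of the anchor (raw C, not in {G,T}) -> unchanged
  expect_equal(nchar(out$sequence), 11)
  expect_true(any(out$snp_sites$strongly_compatible))
})

test_that("correct_read is idempotent on error-free reads and fixes one error", {
  genome <- random_genome(2500, seed = 91)
  g <- build_graph(genome, 9, 1)
  pairs <- tiling_pairs(genome)
  color_graph(g, graphpolish:::srs_pairs(pairs),
              seq_len(nrow(pairs) / 2))
  annotate_candidate_snps(g)
  read <- substr(genome, 301, 1300)
  res <- correct_read(read, g)
  expect_equal(res$corrected, read)
  expect_false(res$flagged)
  expect_equal(nrow(res$stats), 0)

  read2 <- read
  substr(read2, 500, 500) <- setdiff(c("A", "C", "G", "T"), substr(read, 500, 500))[1]
  res2 <- correct_read(read2, g)
  expect_equal(res2$corrected, read)

  # solid bases are never modified
  cls <- classify_kmers(read2, g)
  regions <- delimit_regions(cls$solid, cls$near_solid, nchar(read2), 9)
  before <- substr(read2, 1, regions$start[1] - 1)
  expect_equal(substr(res2$corrected, 1, nchar(before)), before)
})

test_that("a genomic gap in short-read coverage keeps the raw subsequence", {
  genome <- random_genome(2000, seed = 93)
  covered <- c(substr(genome, 1, 900), substr(genome, 1101, 2000))
  g <- build_graph(covered, 9, 1)
  annotate_candidate_snps(g)
  read <- substr(genome, 700, 1400)
  res <- correct_read(read, g)
  # the uncovered stretch survives (a few bases may be perturbed by spurious
  # single-edit waypoints at this small k, but the hole is not invented)
  d <- edit_distance(res$corrected, read)
  expect_lt(d / nchar(read), 0.02)
  expect_true(any(res$stats$n_gap_bases > 0))
  expect_false(all(res$stats$complete))
})

test_that("unanchorable and too-short reads are returned unchanged, flagged", {
  g <- build_graph(random_genome(500, seed = 95), 9, 1)
  res <- correct_read("ACGT", g)
  expect_true(res$flagged)
  expect_equal(res$corrected, "ACGT")
  alien <- strrep("AT", 50)
  res2 <- correct_read(alien, g)
  expect_true(res2$flagged)
  expect_equal(res2$corrected, alien)
})
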