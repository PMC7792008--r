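test_that("error-free reads are fully solid", {
  genome <- random_genome(400, seed = 41)
  g <- build_graph(genome, 9, 1)
  read <- substr(genome, 50, 250)
  cls <- classify_kmers(read, g)
  expect_equal(nrow(cls$solid), nchar(read) - 9 + 1)
  expect_equal(nrow(cls$near_solid), 0)
  expect_equal(cls$solid$pos, seq_len(nchar(read) - 8))
})

test_that("tiny example classifies solid and near-solid windows", {
  g <- build_graph("ATGGC", 3, 1)
  cls <- classify_kmers("ATGGC", g)
  expect_equal(nrow(cls$solid), 3)
  expect_equal(nrow(cls$near_solid), 0)
  # one substitution: window TGA is near-solid onto the TGG locus
  cls2 <- classify_kmers("ATGAC", g)
  expect_true(any(cls2$near_solid$edit == "substitution"))
})

test_that("near-solid matches agree with the exhaustive distance-1 oracle", {
  genome <- random_genome(600, seed = 43)
  k <- 11
  g <- build_graph(genome, k, 1)
  read <- withr::with_seed(44, {
    r <- substr(genome, 100, 400)
    ch <- strsplit(r, "")[[1]]
    for (p in seq(15, length(ch) - 15, by = 37)) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    paste(ch, collapse = "")
  })
  cls <- classify_kmers(read, g)
  # oracle: per window, all distance-1 candidate strings, count distinct loci
  for (p in seq_len(nchar(read) - k + 1)) {
    w <- substr(read, p, p + k - 1)
    if (graph_lookup(g, w)$present) {
      expect_false(p %in% cls$near_solid$pos)  # solid wins
      next
    }
    nb <- if (p + k <= nchar(read)) substr(read, p + k, p + k) else NA
    cands <- oracle_distance1_candidates(w, nb)
    hits <- graph_lookup(g, cands)
    hits <- hits[hits$present, c("unitig", "offset", "strand")]
    n_loci <- nrow(unique(hits[, c("unitig", "offset")]))
    in_out <- p %in% cls$near_solid$pos
    if (n_loci == 1) {
      expect_true(in_out)
      row <- cls$near_solid[cls$near_solid$pos == p, ]
      expect_equal(c(row$unitig, row$offset), c(hits$unitig[1], hits$offset[1]))
    } else {
      expect_false(in_out)  # zero hits (weak) or ambiguous (non-unique)
    }
  }
})

test_that("two distinct near-solid hits at one position are discarded", {
  # two unitigs, each one substitution away from the query window
  g <- graph_from_unitigs(c("AAGGTACGGTT", "AACGTAAGGTT"), 11)
  cls <- classify_kmers("AACGTACGGTT", g)  # distance 1 from both
  expect_equal(nrow(cls$solid), 0)
  expect_equal(nrow(cls$near_solid), 0)
})

test_that("regions follow the successive-solid-pair rule", {
  solid <- tibble::tibble(pos = c(1L, 2L, 3L, 8L), unitig = 1L, offset = 1L,
                          strand = 1L)
  near <- tibble::tibble(pos = integer(0), unitig = integer(0),
                         offset = integer(0), strand = integer(0),
                         edit = character(0))
  regions <- delimit_regions(solid, near, read_len = 10, k = 3, F = 0.25)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$source[[1]]$pos, 3)
  expect_equal(regions$target[[1]]$pos, 8)
  expect_equal(regions$l, 8)  # p_t - p_s + k

  # l bounds: l = 100, F = 0.25
  solid2 <- tibble::tibble(pos = c(1L, 98L), unitig = 1L, offset = 1L, strand = 1L)
  r2 <- delimit_regions(solid2, near, read_len = 100, k = 3, F = 0.25)
  expect_equal(r2$l, 100)
  expect_equal(r2$l_min, 80)
  expect_equal(r2$l_max, 125)

  # fully solid read: no region
  solid3 <- tibble::tibble(pos = 1:8, unitig = 1L, offset = 1L, strand = 1L)
  expect_equal(nrow(delimit_regions(solid3, near, 10, 3)), 0)

  # no solid match at all: one full-read region
  r4 <- delimit_regions(solid3[0, ], near, 50, 3)
  expect_equal(nrow(r4), 1)
  expect_null(r4$source[[1]])
  expect_null(r4$target[[1]])
  expect_equal(r4$l, 50)
})

test_that("head and tail regions arise at read extremities", {
  solid <- tibble::tibble(pos = c(10L, 11L, 12L), unitig = 1L, offset = 1L,
                          strand = 1L)
  near <- tibble::tibble(pos = c(3L, 30L), unitig = 2L, offset = 1L,
                         strand = 1L, edit = "substitution")
  regions <- delimit_regions(solid, near, read_len = 40, k = 5, F = 0.4)
  expect_equal(nrow(regions), 2)
  expect_null(regions$source[[1]])
  expect_equal(regions$target[[1]]$pos, 10)
  expect_equal(regions$start[1], 1)
  expect_equal(regions$end[1], 14)  # p_t + k - 1
  # head region UNSM window: pos <= p_t - k
  expect_equal(regions$unsms[[1]]$pos, 3)
  expect_null(regions$target[[2]])
  expect_equal(regions$start[2], 12)
  expect_equal(regions$end[2], 40)
  expect_equal(regions$unsms[[2]]$pos, 30)
})

test_that("every weak k-mer lies inside exactly one region", {
  genome <- random_genome(2000, seed = 47)
  g <- build_graph(genome, 9, 1)
  read <- withr::with_seed(48, {
    r <- substr(genome, 200, 1200)
    graphpolish:::mutate_sequence(r, 0.05, 0.02, 0.02)
  })
  cls <- classify_kmers(read, g)
  regions <- delimit_regions(cls$solid, cls$near_solid, nchar(read), 9, 0.4)
  n_win <- nchar(read) - 9 + 1
  weak <- setdiff(seq_len(n_win), c(cls$solid$pos, cls$near_solid$pos))
  for (p in weak) {
    containing <- sum(regions$start <= p & regions$end - 9 + 1 >= p)
    expect_equal(containing, 1)
  }
})
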