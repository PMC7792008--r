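# a small colored fixture: linear genome, tiling pair coloring
make_colored_fixture <- function(seed = 61, n = 500, k = 9) {
  genome <- random_genome(n, seed)
  g <- build_graph(genome, k, 1)
  pairs <- tiling_pairs(genome)
  units <- graphpolish:::srs_pairs(pairs)
  color_graph(g, units, seq_along(units))
  list(genome = genome, g = g, units = units, k = k)
}

test_that("path probability conflates the two evidence sources", {
  expect_equal(path_probability(0.5, 0.5), 0.5)
  expect_equal(path_probability(0.3, 1.0), 1.0)
  expect_equal(path_probability(0.8, 0.9), 0.72 / 0.74)
  expect_equal(path_probability(0, 1), 0)  # degenerate 0/0 case
  grid <- seq(0, 1, length.out = 21)
  sp <- outer(grid, grid, path_probability)
  expect_true(all(sp >= 0 & sp <= 1))
  expect_true(all(diff(sp) >= 0))        # monotone in s_c (rows)
  expect_true(all(apply(sp, 1, diff) >= 0))  # monotone in s_q
})

test_that("color union over the window matches a brute-force scan", {
  fx <- make_colored_fixture()
  read <- substr(fx$genome, 100, 300)
  cls <- classify_kmers(read, fx$g)
  regions <- delimit_regions(cls$solid[cls$solid$pos %% 50 != 0, ][c(1, 20), ],
                             cls$near_solid, nchar(read), fx$k)
  # make one artificial region between two arbitrary solid matches
  s <- cls$solid
  region <- list(source = list(pos = s$pos[20], unitig = s$unitig[20],
                               offset = s$offset[20], strand = s$strand[20]),
                 target = list(pos = s$pos[120], unitig = s$unitig[120],
                               offset = s$offset[120], strand = s$strand[120]),
                 start = s$pos[20], end = s$pos[120] + fx$k - 1)
  for (B in c(0L, 25L, 1000L)) {
    got <- collect_color_union(s, cls$near_solid, region, B, fx$g)
    lo <- region$source$pos - B; hi <- region$target$pos + B
    keep <- s[s$pos >= lo & s$pos <= hi, ]
    want <- sort(unique(unlist(kmer_colors_at(fx$g, keep$unitig, keep$offset))))
    expect_identical(got, want)
  }
  # single match with a known color set
  one <- s[1, ]
  region1 <- list(source = list(pos = one$pos, unitig = one$unitig,
                                offset = one$offset, strand = one$strand),
                  target = list(pos = one$pos, unitig = one$unitig,
                                offset = one$offset, strand = one$strand))
  got1 <- collect_color_union(one, cls$near_solid[0, ], region1, 0L, fx$g)
  expect_identical(got1, sort(unique(unlist(kmer_colors_at(fx$g, one$unitig, one$offset)))))
})

test_that("color floor is floor(D * min window color count)", {
  fx <- make_colored_fixture()
  read <- substr(fx$genome, 60, 260)
  cls <- classify_kmers(read, fx$g)
  s <- cls$solid
  region <- list(source = list(pos = s$pos[5], unitig = s$unitig[5],
                               offset = s$offset[5], strand = s$strand[5]),
                 target = list(pos = s$pos[100], unitig = s$unitig[100],
                               offset = s$offset[100], strand = s$strand[100]))
  for (D in c(0, 0.5, 1)) {
    got <- color_floor(s, cls$near_solid, region, 10L, D, fx$g)
    keep <- s[s$pos >= region$source$pos - 10 & s$pos <= region$target$pos + 10, ]
    sizes <- lengths(kmer_colors_at(fx$g, keep$unitig, keep$offset))
    expect_identical(got, as.integer(floor(D * min(sizes))))
  }
  # no matches in window -> 0
  empty <- s[0, ]
  expect_identical(color_floor(empty, cls$near_solid[0, ], region, 0L, 1, fx$g), 0L)
})

test_that("score_path fills s_c, s_q and their conflation", {
  p <- graphpolish:::new_graph_path("ACGTACGTACGTACGTACGT", rep(0L, 20),
                                    rep(1L, 20), rep(TRUE, 20),
                                    tibble::tibble(unitig = 1L, strand = 1L),
                                    TRUE, colors = c(1L, 2L, 3L))
  s1 <- score_path(p, c(1L, 2L, 3L), p$sequence)
  expect_equal(c(s1$s_c, s1$s_q, s1$s_P), c(1, 1, 1))
  s2 <- score_path(p, c(9L, 10L), p$sequence)
  expect_equal(c(s2$s_c, s2$s_P), c(0, 0))
  # 2 mismatches over 20 bases, 60% color overlap
  region <- "ACGTACGTATGTACGTACGA"
  s3 <- score_path(p, c(1L, 2L, 3L, 4L, 5L), region)
  expect_equal(s3$s_c, 0.6)
  expect_equal(s3$s_q, 1 - 2 / 20)
  expect_equal(s3$s_P, (0.6 * 0.9) / (0.6 * 0.9 + 0.4 * 0.1))
})

test_that("greedy walk follows the unique path of a linear graph", {
  genome <- random_genome(200, seed = 71)
  g <- build_graph(genome, 9, 1)
  cls <- classify_kmers(genome, g)
  s <- cls$solid
  from <- list(unitig = s$unitig[1], offset = s$offset[1], strand = s$strand[1])
  to <- list(unitig = s$unitig[100], offset = s$offset[100], strand = s$strand[100])
  region <- substr(genome, 1, 100 + 8)
  p <- greedy_bfs_extend(g, from, to, max_bases = 200, C = integer(0), T_C = 0L,
                         region_subseq = region, params = traversal_params())
  expect_true(p$complete)
  expect_equal(p$sequence, region)
})

test_that("the greedy walk picks the bubble branch favored by the region", {
  # two-haplotype bubble: shared flanks, one-substitution center
  withr::with_seed(73, {
    left <- graphpolish:::random_dna(60)
    right <- graphpolish:::random_dna(60)
    mid <- graphpolish:::random_dna(21)
  })
  mid2 <- mid
  substr(mid2, 11, 11) <- setdiff(c("A", "C", "G", "T"), substr(mid, 11, 11))[1]
  hapA <- paste0(left, mid, right)
  hapB <- paste0(left, mid2, right)
  g <- build_graph(c(hapA, hapB), 9, 1)
  cls <- classify_kmers(hapA, g)
  s <- cls$solid
  from <- list(unitig = s$unitig[1], offset = s$offset[1], strand = s$strand[1])
  n <- nrow(s)
  to <- list(unitig = s$unitig[n], offset = s$offset[n], strand = s$strand[n])
  for (target_hap in c(hapA, hapB)) {
    p <- greedy_bfs_extend(g, from, to, max_bases = 300, C = integer(0), T_C = 0L,
                           region_subseq = target_hap, params = traversal_params())
    expect_true(p$complete)
    expect_equal(p$sequence, target_hap)
    # agreement with the exhaustive bounded-path arg-max of (s_P, s_q), ties
    # to the lexicographically smallest sequence
    all_paths <- sort(oracle_all_paths(g, from, to, 300))
    expect_true(p$sequence %in% all_paths)
    scored <- lapply(all_paths, function(sq) {
      pp <- graphpolish:::new_graph_path(sq, rep(0L, nchar(sq)), rep(1L, nchar(sq)),
                                         rep(TRUE, nchar(sq)),
                                         tibble::tibble(unitig = 1L, strand = 1L),
                                         TRUE, colors = integer(0))
      score_path(pp, integer(0), target_hap)
    })
    sp <- vapply(scored, function(x) x$s_P, numeric(1))
    sq_ <- vapply(scored, function(x) x$s_q, numeric(1))
    best <- order(-sp, -sq_, all_paths)[1]
    expect_equal(p$sequence, all_paths[best])
  }
})

test_that("a color floor above every color count stops the walk immediately", {
  fx <- make_colored_fixture()
  read <- substr(fx$genome, 100, 200)
  cls <- classify_kmers(read, fx$g)
  s <- cls$solid
  from <- list(unitig = s$unitig[1], offset = s$offset[1], strand = s$strand[1])
  to <- list(unitig = s$unitig[50], offset = s$offset[50], strand = s$strand[50])
  p <- greedy_bfs_extend(fx$g, from, to, max_bases = 200,
                         C = seq_len(1000L), T_C = 999L,
                         region_subseq = read, params = traversal_params())
  expect_false(p$complete)
  expect_equal(nchar(p$sequence), fx$k)  # nothing beyond the source k-mer
})

test_that("find_region_path rebuilds a region holding one error", {
  fx <- make_colored_fixture(seed = 75, n = 800)
  truth <- substr(fx$genome, 200, 520)
  read <- truth
  substr(read, 160, 160) <- setdiff(c("A", "C", "G", "T"), substr(truth, 160, 160))[1]
  cls <- classify_kmers(read, fx$g)
  regions <- delimit_regions(cls$solid, cls$near_solid, nchar(read), fx$k)
  expect_equal(nrow(regions), 1)
  region <- graphpolish:::region_row(regions, 1)
  C <- collect_color_union(cls$solid, cls$near_solid, region, 1000L, fx$g)
  for (dir in c("forward", "backward")) {
    p <- find_region_path(fx$g, region, read, cls$solid, cls$near_solid,
                          traversal_params(), dir, C = C, T_C = 0L)
    expect_true(p$complete)
    expect_equal(p$sequence, substr(truth, region$start, region$end))
    expect_gte(nchar(p$sequence), region$l_min)
    expect_lte(nchar(p$sequence), region$l_max)
  }
})

test_that("a coverage hole yields an incomplete path with one gap", {
  genome <- random_genome(700, seed = 77)
  # cover everything except a central hole
  left <- substr(genome, 1, 300)
  right <- substr(genome, 401, 700)
  g <- build_graph(c(left, right), 9, 1)
  read <- substr(genome, 150, 550)
  cls <- classify_kmers(read, g)
  regions <- delimit_regions(cls$solid, cls$near_solid, nchar(read), 9)
  expect_equal(nrow(regions), 1)
  region <- graphpolish:::region_row(regions, 1)
  p <- find_region_path(g, region, read, cls$solid, cls$near_solid,
                        traversal_params(), "forward")
  expect_false(p$complete)
  expect_true(any(!p$from_graph))
  # gaps carry the raw read across the hole: the result stays close to the
  # region (spurious single-edit waypoints may perturb a few bases at this
  # small k, but the hole interior itself is not invented)
  region_seq <- substr(read, region$start, region$end)
  d <- edit_distance(p$sequence, region_seq)
  expect_lt(d / nchar(region_seq), 0.1)
})
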