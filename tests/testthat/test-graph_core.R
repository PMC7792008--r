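test_that("canonicalize returns the lexicographic minimum and is idempotent", {
  expect_equal(canonicalize("ACG"), "ACG")
  expect_equal(canonicalize("TTT"), "AAA")
  km <- withr::with_seed(5, vapply(1:50, function(i) {
    paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
  }, ""))
  expect_equal(canonicalize(canonicalize(km)), canonicalize(km))
  expect_true(all(canonicalize(km) <= revcomp(canonicalize(km))))
  expect_error(canonicalize("ACNGT"), "A,C,G,T")
})

test_that("build_graph keeps exactly the filtered canonical k-mers", {
  g <- build_graph("ATGGC", 3, min_count = 1)
  expect_equal(n_unitigs(g), 1)
  expect_setequal(unitig_kmer_list(unitig_seqs(g), 3), c("ATG", "CCA", "GCC"))

  # count filter: singleton read k-mers are discarded
  g2 <- build_graph(c("ATGGC", "ATGGC", "TTACG"), 3, min_count = 2)
  expect_setequal(unitig_kmer_list(unitig_seqs(g2), 3), c("ATG", "CCA", "GCC"))
  expect_warning(build_graph(c("ATG", "CGT"), 3, min_count = 2), "empty")
})

test_that("branching reads compact exactly as the naive oracle", {
  g <- build_graph(c("ATGGA", "ATGGC"), 3, min_count = 1)
  expect_setequal(unitig_kmer_list(unitig_seqs(g), 3),
                  oracle_kmer_set(c("ATGGA", "ATGGC"), 3))
  expect_gt(n_unitigs(g), 1)  # branch after the shared prefix
  expect_true(oracle_check_maximality(unitig_seqs(g), 3))
})

test_that("compaction decompacts to the naive k-mer set on random genomes", {
  k <- 9
  for (i in 1:30) {
    genome <- random_genome(500, seed = 1000 + i)
    g <- build_graph(genome, k, min_count = 1)
    seqs <- unitig_seqs(g)
    kl <- unitig_kmer_list(seqs, k)
    expect_equal(anyDuplicated(kl), 0L)
    expect_setequal(kl, oracle_kmer_set(genome, k))
    expect_true(oracle_check_maximality(seqs, k))
  }
})

test_that("reads are split at non-ACGT symbols before k-merization", {
  g <- build_graph("ATGGCNNNTTACGA", 3, min_count = 1)
  expect_setequal(unitig_kmer_list(unitig_seqs(g), 3),
                  oracle_kmer_set(c("ATGGC", "TTACGA"), 3))
})

test_that("subgraph from unitigs has the k_small-mer content of the parent", {
  parent <- graph_from_unitigs("ATGGC", 5)
  child <- build_subgraph_from_unitigs(parent, 3)
  ref <- build_graph("ATGGC", 3, 1)
  expect_setequal(unitig_kmer_list(unitig_seqs(child), 3),
                  unitig_kmer_list(unitig_seqs(ref), 3))
  expect_error(build_subgraph_from_unitigs(parent, 7), "smaller")

  # shared k_small-mers between parent unitigs appear once (set semantics)
  genome <- random_genome(400, seed = 77)
  p <- build_graph(genome, 19, 1)
  ch <- build_subgraph_from_unitigs(p, 9)
  expect_setequal(unitig_kmer_list(unitig_seqs(ch), 9),
                  oracle_kmer_set(unitig_seqs(p), 9))
  expect_equal(anyDuplicated(unitig_kmer_list(unitig_seqs(ch), 9)), 0L)
})

test_that("lookup finds each k-mer at one locus, strand-aware", {
  g <- build_graph("ATGGC", 3, 1)
  hit <- graph_lookup(g, "ATG")
  expect_true(hit$present)
  rc <- graph_lookup(g, "CAT")
  expect_true(rc$present)
  expect_equal(hit$unitig, rc$unitig)
  expect_equal(hit$offset, rc$offset)
  expect_equal(hit$strand, -rc$strand)
  expect_false(graph_lookup(g, "TTT")$present)
  expect_error(graph_lookup(g, "ATGA"), "length")
})

test_that("coloring is per k-mer position, order-independent, collision-checked", {
  genome <- random_genome(300, seed = 3)
  g <- build_graph(genome, 9, 1)
  u1 <- substr(genome, 1, 60)
  u2 <- substr(genome, 40, 110)
  color_graph(g, list(u1, u2), ids = c(1L, 2L))
  # brute-force per-k-mer membership scan
  for (uid in seq_len(n_unitigs(g))) {
    info <- unitig_info(g, uid)
    nk <- nchar(info$seq) - 9 + 1
    for (off in seq_len(nk)) {
      km <- canonicalize(substr(info$seq, off, off + 8))
      expected <- c(1L, 2L)[c(km %in% canonicalize(substring(u1, 1:(nchar(u1) - 8), 9:nchar(u1))),
                              km %in% canonicalize(substring(u2, 1:(nchar(u2) - 8), 9:nchar(u2))))]
      expect_identical(info$colors[[off]], expected)
    }
  }
  # order independence
  ga <- build_graph(genome, 9, 1)
  gb <- build_graph(genome, 9, 1)
  units <- list(u1, u2, substr(genome, 150, 260))
  color_graph(ga, units, 1:3)
  color_graph(gb, rev(units), 3:1)
  for (uid in seq_len(n_unitigs(ga))) {
    expect_identical(unitig_info(ga, uid)$colors, unitig_info(gb, uid)$colors)
  }
  expect_error(color_graph(ga, list("AAA"), 2L), "collision")

  # a unit sharing no k-mer changes nothing
  gc <- build_graph(genome, 9, 1)
  before <- lapply(seq_len(n_unitigs(gc)), function(i) unitig_info(gc, i)$colors)
  color_graph(gc, list(strrep("A", 30)), 9L)
  after <- lapply(seq_len(n_unitigs(gc)), function(i) unitig_info(gc, i)$colors)
  expect_identical(before, after)
})

test_that("pruning drops low-color k-mers and re-compacts", {
  genome <- random_genome(200, seed = 8)
  g <- build_graph(genome, 9, 1)
  expect_identical(prune_low_color_kmers(g, 0), g)
  # color only a middle stretch: the uncovered k-mers must disappear
  mid <- substr(genome, 50, 150)
  color_graph(g, list(mid), 1L)
  pruned <- prune_low_color_kmers(g, 1)
  expect_setequal(unitig_kmer_list(unitig_seqs(pruned), 9),
                  oracle_kmer_set(mid, 9))
  expect_true(oracle_check_maximality(unitig_seqs(pruned), 9))
  # single unitig with one uncolored interior k-mer splits in two
  u <- "ACCTTCACCAATT"
  g2 <- graph_from_unitigs(u, 5)
  kms <- substring(u, 1:(nchar(u) - 4), 5:nchar(u))
  color_graph(g2, as.list(canonicalize(kms[-5])), seq_along(kms[-5]))
  p2 <- prune_low_color_kmers(g2, 1)
  expect_equal(n_unitigs(p2), 2)
  # everything below threshold: empty graph with a warning
  expect_warning(pr <- prune_low_color_kmers(g2, 99), "empty")
  expect_equal(n_kmers(pr), 0)
})

test_that("candidate-SNP annotation matches the worked A/G example", {
  g <- graph_from_unitigs(c("GCGATT", "GCA"), 3)
  annotate_candidate_snps(g)
  i1 <- unitig_info(g, 1)
  i2 <- unitig_info(g, 2)
  expect_true(3 %in% i1$snp_pos[i1$snp_symbol == "R"])
  expect_identical(i2$snp_pos[i2$snp_symbol == "R"], 3L)
})

test_that("annotation equals the all-pairs Hamming-1 oracle and is symmetric", {
  for (seed in c(21, 22, 23)) {
    genome <- random_genome(150, seed = seed)
    g <- build_graph(genome, 7, 1)
    annotate_candidate_snps(g)
    seqs <- unitig_seqs(g)
    got <- do.call(rbind, lapply(seq_along(seqs), function(i) {
      info <- unitig_info(g, i)
      if (length(info$snp_pos) == 0) return(NULL)
      data.frame(unitig = i, pos = info$snp_pos, mask = info$snp_mask)
    }))
    want <- oracle_snp_annotation(seqs, 7)
    if (is.null(got)) {
      expect_equal(nrow(want), 0)
    } else {
      got <- got[order(got$unitig, got$pos), ]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
  # a single unitig with no Hamming-1 partner gets no annotation
  g1 <- graph_from_unitigs("ACGTTAGC", 5)
  annotate_candidate_snps(g1)
  expect_length(unitig_info(g1, 1)$snp_pos, 0)
})

test_that("GFA round trip preserves unitigs, links and annotations", {
  genome <- random_genome(300, seed = 12)
  g <- build_graph(c(genome, substr(genome, 1, 150)), 9, 1)
  annotate_candidate_snps(g)
  path <- file.path(tempdir(), "toy.gfa")
  export_gfa(g, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "S\t")), n_unitigs(g))
  g2 <- import_gfa(path, 9)
  expect_setequal(unitig_seqs(g2), unitig_seqs(g))
  ann <- function(gr) {
    rows <- lapply(seq_len(n_unitigs(gr)), function(i) {
      info <- unitig_info(gr, i)
      if (length(info$snp_pos) == 0) return(NULL)
      data.frame(seq = info$seq, pos = info$snp_pos, mask = info$snp_mask)
    })
    out <- do.call(rbind, rows)
    out[order(out$seq, out$pos), ]
  }
  a1 <- ann(g); a2 <- ann(g2)
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a2, a1)
})

test_that("GFA links match an adjacency oracle on a 3-unitig toy graph", {
  g <- build_graph(c("ATGGA", "ATGGC"), 3, 1)
  expect_equal(n_unitigs(g), 3)
  path <- file.path(tempdir(), "toy3.gfa")
  export_gfa(g, path)
  l_lines <- grep("^L\t", readLines(path), value = TRUE)
  norm_key <- function(u1, o1, u2, o2) {
    a <- paste(u1, o1, u2, o2)
    b <- paste(u2, chartr("+-", "-+", o2), u1, chartr("+-", "-+", o1))
    min(a, b)
  }
  got <- vapply(strsplit(l_lines, "\t"), function(f) {
    norm_key(f[2], f[3], f[4], f[5])
  }, "")
  # oracle: every oriented unitig pair overlapping by k-1 bases is an edge
  seqs <- unitig_seqs(g)
  orient <- function(i, o) if (o == "+") seqs[i] else revcomp(seqs[i])
  want <- character(0)
  for (i in seq_along(seqs)) {
    for (oi in c("+", "-")) {
      suffix <- substr(orient(i, oi), nchar(seqs[i]) - 1, nchar(seqs[i]))
      for (j in seq_along(seqs)) {
        for (oj in c("+", "-")) {
          if (substr(orient(j, oj), 1, 2) == suffix) {
            want <- c(want, norm_key(i, oi, j, oj))
          }
        }
      }
    }
  }
  expect_setequal(got, unique(want))
})
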