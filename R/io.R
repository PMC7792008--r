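sniff_format <- function(path) {
  p <- sub("\\.gz$", "", path)
  ext <- tolower(tools::file_ext(p))
  if (ext %in% c("fa", "fasta", "fna")) return("fasta")
  if (ext %in% c("fq", "fastq")) return("fastq")
  if (ext == "sam") return("sam")
  if (ext == "paf") return("paf")
  if (ext == "gfa") return("gfa")
  stop("unknown file extension '.", ext,
       "'; supported: .fa/.fasta/.fna, .fq/.fastq (optionally .gz), .sam, .paf, .gfa")
}

#' Read sequences from FASTA or FASTQ
#'
#' Format is sniffed from the extension (gzip allowed). FASTQ qualities are
#' preserved in a `qual` column, so write/read round trips are lossless.
#'
#' @param path input file
#' @return a read-set tibble (`id`, `seq`, and `qual` for FASTQ)
#' @export
parse_reads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- sniff_format(path)
  if (fmt == "fasta") {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    tibble::tibble(id = names(x), seq = as.character(unname(x)))
  } else if (fmt == "fastq") {
    # Biostrings warns about dropping its own metadata columns here; harmless
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    tibble::tibble(id = names(x), seq = as.character(unname(x)),
                   qual = as.character(unname(Biostrings::quality(x))))
  } else {
    stop("parse_reads() expects FASTA or FASTQ, got ", fmt)
  }
}

#' Write sequences as FASTA or FASTQ
#'
#' Output format follows the extension. When writing FASTQ without stored
#' qualities, a flat Q20 is emitted.
#'
#' @param reads a read-set tibble
#' @param path output file (`.fa`/`.fasta` or `.fq`/`.fastq`)
#' @return `path`, invisibly
#' @export
write_reads <- function(reads, path) {
  reads <- as_read_set(reads)
  fmt <- sniff_format(path)
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  if (fmt == "fasta") {
    Biostrings::writeXStringSet(x, path)
  } else if (fmt == "fastq") {
    qual <- if ("qual" %in% names(reads) && !anyNA(reads$qual) &&
                all(nchar(reads$qual) == nchar(reads$seq))) {
      reads$qual
    } else {
      # no usable qualities (e.g. sequences changed length during correction):
      # emit flat Q20
      vapply(nchar(reads$seq), function(n) strrep("5", n), "")
    }
    qx <- Biostrings::QualityScaledDNAStringSet(
      x, Biostrings::PhredQuality(qual))
    Biostrings::writeQualityScaledXStringSet(qx, path)
  } else {
    stop("write_reads() expects a FASTA or FASTQ path")
  }
  invisible(path)
}

#' Parse alignment records from SAM or PAF
#'
#' SAM files are converted and read through Rsamtools, keeping standard FLAG
#' and MAPQ semantics (secondary and supplementary records are kept in the
#' table and filtered where relevant). The minimal 12-column PAF dialect is
#' supported for unpaired (long-read) alignments; PAF has no FLAG column, so
#' records are treated as primary, mapped, unpaired.
#'
#' @param path `.sam` or `.paf`
#' @return tibble with `qname`, `flag`, `rname`, `pos` (1-based), `mapq`
#' @export
parse_alignments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- sniff_format(path)
  if (fmt == "sam") {
    bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos", "mapq"))
    b <- Rsamtools::scanBam(bam, param = p)[[1]]
    tibble::tibble(qname = b$qname, flag = as.integer(b$flag),
                   rname = as.character(b$rname), pos = as.integer(b$pos),
                   mapq = as.integer(b$mapq))
  } else if (fmt == "paf") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t")
    bad <- vapply(fields, length, integer(1)) < 12
    if (any(bad)) {
      warning(sum(bad), " malformed PAF record(s) skipped")
      fields <- fields[!bad]
    }
    tibble::tibble(
      qname = vapply(fields, `[`, "", 1),
      flag = 0L,
      rname = vapply(fields, `[`, "", 6),
      pos = as.integer(vapply(fields, `[`, "", 8)) + 1L,  # PAF is 0-based
      mapq = as.integer(vapply(fields, `[`, "", 12))
    )
  } else {
    stop("parse_alignments() expects SAM or PAF, got ", fmt)
  }
}

# oriented ends of a unitig and their adjacency in the graph
graph_links <- function(graph) {
  k <- graph$k
  seqs <- unitig_seqs(graph)
  links <- list()
  emit <- function(u1, o1, u2, o2) {
    # normalize the edge so each adjacency appears once
    a <- c(u1, o1, u2, o2)
    b <- c(u2, chartr("+-", "-+", o2), u1, chartr("+-", "-+", o1))
    key <- paste(a, collapse = " ")
    keyb <- paste(b, collapse = " ")
    links[[min(key, keyb)]] <<- if (key <= keyb) a else b
  }
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    for (o in c("+", "-")) {
      os <- if (o == "+") s else revcomp(s)
      tail_km <- substr(os, nchar(os) - k + 1L, nchar(os))
      for (b in c("A", "C", "G", "T")) {
        cand <- paste0(substr(tail_km, 2, k), b)
        hit <- cpp_lookup(graph$ptr, cand)
        if (!hit$present[1]) next
        u2 <- hit$unitig[1]
        len2 <- nchar(seqs[u2])
        # the successor k-mer must sit at an end of its unitig in walk orientation
        if (hit$strand[1] == 1 && hit$offset[1] == 1) emit(i, o, u2, "+")
        else if (hit$strand[1] == -1 && hit$offset[1] == len2 - k + 1L) emit(i, o, u2, "-")
      }
    }
  }
  links
}

#' Export a graph as GFA1 (plus a candidate-SNP sidecar)
#'
#' S-lines carry the unitig sequences, L-lines the `(k-1)M` overlaps implied
#' by shared (k-1)-mers at unitig ends. When the graph carries candidate-SNP
#' annotations, a tab-separated sidecar `<path>.snp.tsv` (unitig id, 1-based
#' offset, IUPAC symbol) is written alongside.
#'
#' @param graph a `ccdbg`
#' @param path output `.gfa` path
#' @return `path`, invisibly
#' @export
export_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "ccdbg"))
  seqs <- unitig_seqs(graph)
  lines <- c("H\tVN:Z:1.0",
             sprintf("S\t%d\t%s", seq_along(seqs), seqs))
  links <- graph_links(graph)
  for (l in links) {
    lines <- c(lines, sprintf("L\t%s\t%s\t%s\t%s\t%dM",
                              l[1], l[2], l[3], l[4], graph$k - 1L))
  }
  writeLines(lines, path)
  if (graph$annotated) {
    ann <- list()
    for (i in seq_along(seqs)) {
      info <- unitig_info(graph, i)
      if (length(info$snp_pos)) {
        ann[[length(ann) + 1L]] <- tibble::tibble(
          unitig = i, offset = info$snp_pos, symbol = info$snp_symbol)
      }
    }
    ann <- if (length(ann)) dplyr::bind_rows(ann) else {
      tibble::tibble(unitig = integer(0), offset = integer(0), symbol = character(0))
    }
    utils::write.table(ann, paste0(path, ".snp.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Import a graph from GFA1
#'
#' Rebuilds a `ccdbg` from the S-lines (the k-mer index is reconstructed; the
#' adjacency is implied by the sequences). A `<path>.snp.tsv` sidecar written
#' by [export_gfa()] is reloaded when present.
#'
#' @param path `.gfa` file
#' @param k the graph's k-mer length
#' @return a `ccdbg`
#' @export
import_gfa <- function(path, k) {
  lines <- readLines(path)
  s_lines <- lines[startsWith(lines, "S\t")]
  fields <- strsplit(s_lines, "\t")
  ids <- as.integer(vapply(fields, `[`, "", 2))
  seqs <- vapply(fields, `[`, "", 3)[order(ids)]
  g <- graph_from_unitigs(seqs, k)
  sidecar <- paste0(path, ".snp.tsv")
  if (file.exists(sidecar)) {
    ann <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
    if (nrow(ann)) {
      cpp_set_snp_annotations(g$ptr, as.integer(ann$unitig), as.integer(ann$offset),
                              iupac_mask(ann$symbol))
    }
    g$annotated <- TRUE
  }
  g
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seed, package version and R version needed to
#' reproduce a run byte-identically.
#'
#' @param config a [run_config()]
#' @param path output JSON path
#' @param extra optional named list of additional fields
#' @return `path`, invisibly
#' @export
write_manifest <- function(config, path, extra = list()) {
  manifest <- c(list(package = "graphpolish",
                     version = as.character(utils::packageVersion("graphpolish")),
                     r_version = as.character(getRversion()),
                     timestamp = format(Sys.time(), tz = "UTC"),
                     config = unclass(config)),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
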