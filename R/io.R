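#' Read alignment hits from a PAF file
#'
#' Parses the 12 mandatory PAF columns. Percent identity is derived from
#' columns 10/11 (residue matches over alignment block length) unless the
#' file carries an explicit `de:f:` divergence tag, in which case
#' `100 * (1 - de)` is used.
#'
#' @param path Path to a PAF file (plain text).
#' @return Alignment-hit data frame (see [filter_hits()]) with the extra
#'   columns `strand` and `target_length`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(query_id = character(0), query_length = integer(0),
                      query_start = integer(0), query_end = integer(0),
                      target_id = character(0), identity = numeric(0),
                      alignment_length = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 12)
  if (length(bad) > 0) {
    stop("PAF line ", bad[1], " has fewer than 12 columns")
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i) {
    x <- suppressWarnings(as.numeric(get(i)))
    if (any(is.na(x))) {
      stop("PAF line ", which(is.na(x))[1], ": non-numeric field ", i)
    }
    x
  }
  nmatch <- num(10)
  alen <- num(11)
  identity <- 100 * nmatch / alen
  de <- vapply(fields, function(f) {
    tag <- grep("^de:f:", f[-seq_len(12)], value = TRUE)
    if (length(tag) > 0) as.numeric(sub("^de:f:", "", tag[1])) else NA_real_
  }, numeric(1))
  identity[!is.na(de)] <- 100 * (1 - de[!is.na(de)])
  hits <- data.frame(
    query_id = get(1), query_length = as.integer(num(2)),
    query_start = as.integer(num(3)), query_end = as.integer(num(4)),
    strand = get(5), target_id = get(6),
    target_length = as.integer(num(7)),
    identity = identity, alignment_length = as.integer(alen),
    stringsAsFactors = FALSE
  )
  validate_hits(hits)
  hits
}

#' Write alignment hits as PAF
#'
#' Emits the 12 mandatory columns; residue matches (column 10) are
#' reconstructed as `round(identity / 100 * alignment_length)`, so
#' identity round-trips to within 100/(2 * alignment_length) percent.
#'
#' @param hits Alignment-hit data frame.
#' @param path Output path.
#' @export
write_paf <- function(hits, path) {
  validate_hits(hits)
  strand <- if ("strand" %in% names(hits)) hits$strand else
    rep("+", nrow(hits))
  tlen <- if ("target_length" %in% names(hits)) hits$target_length else
    hits$alignment_length
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   hits$query_id, hits$query_length, hits$query_start,
                   hits$query_end, strand, hits$target_id, tlen, 0L,
                   hits$alignment_length,
                   as.integer(round(hits$identity / 100 *
                                      hits$alignment_length)),
                   hits$alignment_length, 60L)
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-base depth track from a bedGraph file
#'
#' @param path Path to a bedGraph file.
#' @return Data frame `seqid`, `start`, `end` (0-based half-open),
#'   `depth`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             depth = as.numeric(gr$score),
             stringsAsFactors = FALSE)
}

#' Write a depth track as bedGraph
#'
#' @param track Data frame `seqid`, `start`, `end`, `depth`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = track$seqid,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    score = track$depth
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read gene models (exon intervals) from GFF3
#'
#' Keeps `exon` features and assigns each to the gene named by its
#' `Parent` attribute (falling back to `ID` when no parent is recorded).
#' GFF3 1-based closed coordinates are converted to the package's
#' 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return Exon table `gene_id`, `seqid`, `start`, `end`.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  parent <- vapply(seq_along(ex), function(i) {
    p <- ex$Parent[[i]]
    if (length(p) > 0) p[1] else
      if (!is.null(ex$ID) && !is.na(ex$ID[i])) ex$ID[i] else
        stop("exon without Parent or ID in ", path)
  }, character(1))
  data.frame(gene_id = parent,
             seqid = as.character(GenomicRanges::seqnames(ex)),
             start = GenomicRanges::start(ex) - 1L,
             end = GenomicRanges::end(ex),
             stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#'
#' Emits one `gene` feature per gene plus its `exon` children.
#'
#' @param gene_models Exon table `gene_id`, `seqid`, `start`, `end`
#'   (0-based half-open).
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(gene_models, path) {
  gm <- gene_models
  gene_rows <- do.call(rbind, lapply(split(gm, gm$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], seqid = d$seqid[1],
               start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  genes <- GenomicRanges::GRanges(
    seqnames = gene_rows$seqid,
    ranges = IRanges::IRanges(start = gene_rows$start + 1L,
                              end = gene_rows$end),
    type = "gene", ID = gene_rows$gene_id
  )
  exons <- GenomicRanges::GRanges(
    seqnames = gm$seqid,
    ranges = IRanges::IRanges(start = gm$start + 1L, end = gm$end),
    type = "exon", Parent = gm$gene_id
  )
  rtracklayer::export(c(genes, exons), path, format = "gff3")
  invisible(path)
}

#' Read/write a PAV matrix as TSV
#'
#' The TSV layout has `gene_id` as first column and one 0/1 column per
#' accession. Metadata profiles are carried in a separate TSV (see
#' [read_metadata_tsv()]).
#'
#' @param path Path to the TSV.
#' @param profiles Optional accession metadata to attach on read.
#' @return [read_pav_tsv()]: a [pav_matrix()].
#' @export
read_pav_tsv <- function(path, profiles = NULL) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  pav_matrix(m, profiles)
}

#' @rdname read_pav_tsv
#' @param pav A [pav_matrix()].
#' @export
write_pav_tsv <- function(pav, path) {
  stopifnot_pav(pav)
  d <- data.frame(gene_id = gene_ids(pav), pav$presence,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write accession metadata as TSV
#'
#' @param path Path to the TSV (columns `accession_id`, `mean_depth`,
#'   `group`, `clade`, `ploidy`, `in_vitro`, or any subset including
#'   `accession_id`).
#' @return [read_metadata_tsv()]: a data frame.
#' @export
read_metadata_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_metadata_tsv
#' @param profiles Metadata data frame.
#' @export
write_metadata_tsv <- function(profiles, path) {
  write.table(profiles, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read/write sequences as FASTA
#'
#' Thin wrappers over Biostrings returning/accepting plain named
#' character vectors.
#'
#' @param path Path to a FASTA file.
#' @return [read_fasta()]: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read/write trees as Newick
#'
#' Wrappers over ape preserving branch lengths and internal node labels
#' (bootstrap supports).
#'
#' @param path Path to a Newick file.
#' @return [read_newick()]: an `ape::phylo`.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' @rdname read_newick
#' @param tree An `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
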