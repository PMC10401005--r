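#' Filter alignment hits by length and identity
#'
#' Keeps hits with `alignment_length >= min_len` and
#' `identity >= min_identity` (both boundaries inclusive). The defaults are
#' the conventional map-to-pan settings of a minimum 300 bp alignment at
#' 90% identity.
#'
#' @param hits Data frame of alignment hits with columns `query_id`,
#'   `query_length`, `query_start`, `query_end` (0-based half-open on the
#'   query), `target_id`, `identity` (percent, 0--100) and
#'   `alignment_length` (bases, including indels).
#' @param min_len Minimum alignment length in bases.
#' @param min_identity Minimum percent identity.
#'
#' @return The subset of `hits` passing both thresholds, original order
#'   preserved.
#' @export
filter_hits <- function(hits, min_len = 300, min_identity = 90) {
  validate_hits(hits)
  hits[hits$alignment_length >= min_len & hits$identity >= min_identity, ,
       drop = FALSE]
}

validate_hits <- function(hits) {
  req <- c("query_id", "query_length", "query_start", "query_end",
           "target_id", "identity", "alignment_length")
  miss <- setdiff(req, names(hits))
  if (length(miss) > 0) {
    stop("hit table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!(hits$query_start >= 0 &
                   hits$query_start < hits$query_end &
                   hits$query_end <= hits$query_length))
  if (length(bad) > 0) {
    stop("malformed hit coordinates at row(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  bad_len <- which(hits$alignment_length < 1)
  if (length(bad_len) > 0) {
    stop("non-positive alignment_length at row(s): ",
         paste(head(bad_len, 5), collapse = ", "))
  }
  invisible(hits)
}

#' Merge query intervals covered by alignment hits
#'
#' Computes the union of the `[query_start, query_end)` intervals of a set
#' of hits on one query: sorted, non-overlapping, with adjacent intervals
#' merged.
#'
#' @param hits Data frame of hits sharing a single `query_id` (columns
#'   `query_start`, `query_end`, 0-based half-open).
#'
#' @return Data frame with columns `start`, `end` (0-based half-open).
#' @export
covered_intervals <- function(hits) {
  if (nrow(hits) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  if (length(unique(hits$query_id)) > 1) {
    stop("covered_intervals() expects hits for a single query")
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = hits$query_start + 1L,
                                         end = hits$query_end))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Extract unaligned regions from a contig
#'
#' Returns the maximal intervals of a contig not covered by any alignment,
#' keeping only those of at least `min_unaligned` bases. A contig with no
#' coverage at all is returned whole if long enough. This is the
#' non-reference discovery step of map-to-pan pangenome construction: any
#' aligned contig contributes its continuous unaligned regions of at least
#' 500 bp (default), fully unaligned contigs contribute entirely.
#'
#' @param contig A single named character string (or `DNAString` with a
#'   name supplied via `contig_id`) holding the contig sequence. May also
#'   be `NULL`, in which case `contig_length` must be given and the
#'   returned segments carry no sequence.
#' @param covered Data frame of merged covered intervals as produced by
#'   [covered_intervals()] (columns `start`, `end`, 0-based half-open).
#' @param min_unaligned Minimum length in bases of a reported segment.
#' @param contig_id Identifier of the source contig; defaults to
#'   `names(contig)`.
#' @param contig_length Length of the contig; defaults to `nchar(contig)`.
#'
#' @return Data frame with columns `source_contig`, `start`, `end`
#'   (0-based half-open) and `sequence` (NA when no sequence was given).
#' @export
extract_unaligned <- function(contig, covered, min_unaligned = 500,
                              contig_id = NULL, contig_length = NULL) {
  if (!is.null(contig)) {
    if (is.null(contig_id)) contig_id <- names(contig)
    contig <- as.character(contig)
    if (is.null(contig_length)) contig_length <- nchar(contig[[1]])
  }
  if (is.null(contig_id) || is.null(contig_length)) {
    stop("contig identity/length unavailable; supply `contig_id` and ",
         "`contig_length` when `contig` is NULL or unnamed")
  }
  if (nrow(covered) > 0 &&
      (min(covered$start) < 0 || max(covered$end) > contig_length)) {
    stop("covered interval out of contig bounds for ", contig_id)
  }
  whole <- IRanges::IRanges(start = 1L, end = contig_length)
  if (nrow(covered) == 0) {
    gaps <- whole
  } else {
    cov <- IRanges::reduce(IRanges::IRanges(start = covered$start + 1L,
                                            end = covered$end))
    gaps <- IRanges::setdiff(whole, cov)
  }
  gaps <- gaps[IRanges::width(gaps) >= min_unaligned]
  out <- data.frame(
    source_contig = rep(contig_id[[1]], length(gaps)),
    start = IRanges::start(gaps) - 1L,
    end = IRanges::end(gaps),
    sequence = rep(NA_character_, length(gaps)),
    stringsAsFactors = FALSE
  )
  if (!is.null(contig) && nrow(out) > 0) {
    out$sequence <- substring(contig[[1]], out$start + 1L, out$end)
  }
  out
}

#' Classify a contig as plant-derived or contaminant
#'
#' Applies the taxonomic screening rule used on unaligned contigs: a
#' contig with hits only to green plants is kept, one with hits only to
#' other taxa is removed, and one with hits to both is kept when at least
#' `green_fraction_min` of the query-covered region (union of all hit
#' intervals) is covered by green-plant hits. A contig with no hits at all
#' is kept: the screen removes identified contaminants, not unclassified
#' sequence.
#'
#' @param contig_id Identifier of the contig under test.
#' @param taxon_hits Data frame with columns `query_id`, `query_start`,
#'   `query_end` (0-based half-open) and `taxon_class` (`"green_plant"` or
#'   `"other"`).
#' @param green_fraction_min Minimum green-plant fraction of the covered
#'   region for mixed-hit contigs.
#'
#' @return `"keep"` or `"remove"`.
#' @export
classify_contamination <- function(contig_id, taxon_hits,
                                   green_fraction_min = 0.90) {
  th <- taxon_hits[taxon_hits$query_id == contig_id, , drop = FALSE]
  if (nrow(th) == 0) return("keep")
  if (!all(th$taxon_class %in% c("green_plant", "other"))) {
    stop("taxon_class must be 'green_plant' or 'other'")
  }
  classes <- unique(th$taxon_class)
  if (identical(classes, "green_plant")) return("keep")
  if (identical(classes, "other")) return("remove")
  as_ir <- function(d) {
    IRanges::reduce(IRanges::IRanges(start = d$query_start + 1L,
                                     end = d$query_end))
  }
  all_cov <- as_ir(th)
  green_cov <- as_ir(th[th$taxon_class == "green_plant", , drop = FALSE])
  frac <- sum(IRanges::width(green_cov)) / sum(IRanges::width(all_cov))
  if (frac >= green_fraction_min) "keep" else "remove"
}

#' Alignment identity and coverage of two sequences
#'
#' Aligns the shorter sequence globally against its best-matching region
#' of the longer one (a fitting alignment, Needleman--Wunsch scoring:
#' match +1, mismatch -1, gap -2 linear), then reports identity as
#' matches over all alignment columns (gap columns count as non-matches)
#' and coverage as the fraction of the shorter sequence's bases aligned
#' to bases of the longer. This reproduces the cd-hit-style semantics in
#' which a shorter sequence fully contained in a longer one scores
#' 100/100, while a truly global alignment would dilute identity with the
#' unavoidable end gaps of the length difference. Intended for
#' synthetic-scale sequences (up to a few tens of kb).
#'
#' @param seq_a,seq_b Non-empty nucleotide strings (A/C/G/T). Order is
#'   irrelevant: the shorter sequence is always the fitted one.
#'
#' @return Named numeric vector `c(identity = ..., coverage = ...)`, both
#'   in percent.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  seq_a <- as.character(seq_a)
  seq_b <- as.character(seq_b)
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    stop("sequences must be non-empty")
  }
  if (nchar(seq_a) > nchar(seq_b)) {
    tmp <- seq_a
    seq_a <- seq_b
    seq_b <- tmp
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 2,
    type = "global-local"
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  n_cols <- length(pa)
  paired <- pa != "-" & sa != "-"
  n_match <- sum(pa[paired] == sa[paired])
  c(identity = 100 * n_match / n_cols,
    coverage = 100 * sum(paired) / nchar(seq_a))
}

#' Greedy redundancy removal over sequence segments
#'
#' Clusters segments by single-pass greedy assignment in decreasing length
#' order: each segment joins the first existing representative against
#' which it reaches both `min_identity` and `min_coverage` (per
#' [pairwise_identity()], coverage measured on the shorter sequence);
#' otherwise it founds a new cluster. By construction no two
#' representatives satisfy both thresholds against each other, and
#' applying the procedure to its own representatives is a no-op.
#'
#' @param segments Named character vector of nucleotide sequences (names
#'   are segment identifiers), or a data frame with columns `segment_id`
#'   and `sequence`.
#' @param min_identity,min_coverage Thresholds in percent (inclusive).
#' @param compare Function `(seq_a, seq_b) -> c(identity, coverage)`;
#'   defaults to [pairwise_identity()]. Callers with precomputed
#'   identities may substitute a lookup.
#'
#' @return List with `representatives` (named character vector of kept
#'   sequences) and `cluster_map` (data frame `segment_id`,
#'   `representative`).
#' @export
remove_redundancy <- function(segments, min_identity = 95,
                              min_coverage = 95,
                              compare = pairwise_identity) {
  if (is.data.frame(segments)) {
    segs <- setNames(as.character(segments$sequence), segments$segment_id)
  } else {
    segs <- segments
  }
  if (length(segs) == 0) stop("`segments` must be non-empty")
  if (is.null(names(segs)) || anyDuplicated(names(segs))) {
    stop("segments must carry unique names")
  }
  ord <- order(-nchar(segs), seq_along(segs))
  segs <- segs[ord]
  reps <- character(0)
  assignment <- character(length(segs))
  names(assignment) <- names(segs)
  for (i in seq_along(segs)) {
    joined <- NA_character_
    for (r in reps) {
      ic <- compare(segs[[i]], segs[[r]])
      if (ic[["identity"]] >= min_identity &&
          ic[["coverage"]] >= min_coverage) {
        joined <- r
        break
      }
    }
    if (is.na(joined)) {
      reps <- c(reps, names(segs)[i])
      assignment[i] <- names(segs)[i]
    } else {
      assignment[i] <- joined
    }
  }
  list(
    representatives = segs[reps],
    cluster_map = data.frame(segment_id = names(assignment),
                             representative = unname(assignment),
                             stringsAsFactors = FALSE)
  )
}

#' Assemble a pangenome from reference sequences and novel segments
#'
#' Concatenates the reference sequences with the non-redundant
#' non-reference representatives, namespacing the latter as
#' `nonref|<source>:<start>-<end>` (or `nonref|<id>` when no coordinates
#' are attached), and returns a manifest mapping every pangenome record to
#' its source.
#'
#' @param reference_sequences Named character vector (or `DNAStringSet`)
#'   of reference sequences.
#' @param nonref_representatives Data frame with columns `source_contig`,
#'   `start`, `end`, `sequence` (as from [extract_unaligned()]), or a
#'   named character vector of sequences.
#'
#' @return List with `pangenome` (named character vector of sequences,
#'   reference first) and `manifest` (data frame `seq_id`, `source`,
#'   `start`, `end`, `origin` with origin `"reference"` or `"nonref"`).
#' @export
build_pangenome <- function(reference_sequences, nonref_representatives) {
  refs <- vapply(as.list(reference_sequences), as.character, character(1))
  if (is.null(names(refs)) || anyDuplicated(names(refs))) {
    stop("reference sequences must carry unique names")
  }
  if (is.data.frame(nonref_representatives)) {
    nr <- nonref_representatives
    ids <- sprintf("nonref|%s:%d-%d", nr$source_contig, nr$start, nr$end)
    nonref <- setNames(as.character(nr$sequence), ids)
    manifest_nr <- data.frame(seq_id = ids, source = nr$source_contig,
                              start = nr$start, end = nr$end,
                              origin = rep("nonref", nrow(nr)),
                              stringsAsFactors = FALSE)
  } else {
    nonref <- vapply(as.list(nonref_representatives), as.character,
                     character(1))
    if (length(nonref) > 0 &&
        (is.null(names(nonref)) || anyDuplicated(names(nonref)))) {
      stop("non-reference segments must carry unique names")
    }
    ids <- if (length(nonref) > 0) paste0("nonref|", names(nonref))
           else character(0)
    names(nonref) <- ids
    manifest_nr <- data.frame(seq_id = ids,
                              source = sub("^nonref\\|", "", ids),
                              start = NA_integer_, end = NA_integer_,
                              origin = rep("nonref", length(ids)),
                              stringsAsFactors = FALSE)
  }
  pan <- c(refs, nonref)
  if (anyDuplicated(names(pan))) {
    stop("duplicate sequence ids in pangenome")
  }
  manifest <- rbind(
    data.frame(seq_id = names(refs), source = names(refs),
               start = 0L, end = nchar(refs), origin = "reference",
               stringsAsFactors = FALSE),
    manifest_nr
  )
  rownames(manifest) <- NULL
  list(pangenome = pan, manifest = manifest)
}

#' Run the full non-reference extraction pipeline
#'
#' Chains the four stages over a contig set: filter alignment hits,
#' screen contigs for contamination, extract unaligned regions of at
#' least `min_unaligned` bases from the surviving contigs, and collapse
#' redundant segments by greedy clustering.
#'
#' @param contigs Named character vector of contig sequences.
#' @param hits Alignment-hit data frame (see [filter_hits()]).
#' @param taxon_hits Taxon-hit data frame (see
#'   [classify_contamination()]).
#' @param min_len,min_identity Hit-filter thresholds.
#' @param min_unaligned Minimum unaligned-segment length.
#' @param green_fraction_min Contamination threshold.
#' @param redundancy_identity,redundancy_coverage Clustering thresholds.
#'
#' @return List with `segments` (all extracted segments),
#'   `representatives` (non-redundant named sequences), `cluster_map`,
#'   and `contamination` (named keep/remove vector per contig).
#' @export
extract_nonref <- function(contigs, hits, taxon_hits,
                           min_len = 300, min_identity = 90,
                           min_unaligned = 500,
                           green_fraction_min = 0.90,
                           redundancy_identity = 95,
                           redundancy_coverage = 95) {
  kept_hits <- filter_hits(hits, min_len, min_identity)
  contamination <- vapply(names(contigs), classify_contamination,
                          character(1), taxon_hits = taxon_hits,
                          green_fraction_min = green_fraction_min)
  keep_ids <- names(contigs)[contamination == "keep"]
  segments <- do.call(rbind, lapply(keep_ids, function(id) {
    ch <- kept_hits[kept_hits$query_id == id, , drop = FALSE]
    extract_unaligned(setNames(contigs[id], id), covered_intervals(ch),
                      min_unaligned = min_unaligned)
  }))
  if (is.null(segments) || nrow(segments) == 0) {
    return(list(segments = segments,
                representatives = setNames(character(0), character(0)),
                cluster_map = data.frame(segment_id = character(0),
                                         representative = character(0)),
                contamination = contamination))
  }
  seg_ids <- sprintf("%s:%d-%d", segments$source_contig, segments$start,
                     segments$end)
  red <- remove_redundancy(setNames(segments$sequence, seg_ids),
                           min_identity = redundancy_identity,
                           min_coverage = redundancy_coverage)
  list(segments = segments, representatives = red$representatives,
       cluster_map = red$cluster_map, contamination = contamination)
}
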