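#' Depth-adaptive minimum read threshold
#'
#' Maps an accession's mean sequencing depth to the minimum per-base read
#' count n used by the absence rule: n = 2, 4, 6, 8 or 10 for mean depth
#' in [0,10], (10,20], (20,40], (40,80] and above 80 respectively. The
#' adaptive threshold keeps absence calls comparable between shallow and
#' deeply sequenced accessions.
#'
#' @param mean_depth Non-negative mean read depth(s) against the
#'   pangenome; vectorized.
#'
#' @return Integer vector of thresholds.
#' @export
#'
#' @examples
#' min_reads_threshold(c(5, 15, 30, 60, 100))
min_reads_threshold <- function(mean_depth) {
  if (any(is.na(mean_depth)) || any(mean_depth < 0)) {
    stop("mean_depth must be non-negative")
  }
  ifelse(mean_depth <= 10, 2L,
    ifelse(mean_depth <= 20, 4L,
      ifelse(mean_depth <= 40, 6L,
        ifelse(mean_depth <= 80, 8L, 10L))))
}

#' Fraction of exonic bases covered at depth >= n
#'
#' For one gene model and one accession's depth track, computes the
#' proportion of exonic bases (union of exon intervals) whose per-base
#' depth is at least `n`.
#'
#' @param gene_model Data frame of exon rows for a single gene: columns
#'   `gene_id`, `seqid`, `start`, `end` (0-based half-open).
#' @param depth_track Data frame with columns `seqid`, `start`, `end`
#'   (0-based half-open) and `depth`; bases not listed have depth 0.
#'   Intervals on one seqid must not overlap.
#' @param n Minimum per-base read count (inclusive).
#'
#' @return Fraction in [0, 1].
#' @export
covered_exon_fraction <- function(gene_model, depth_track, n) {
  if (nrow(gene_model) == 0) stop("gene model has no exons")
  if (length(unique(gene_model$gene_id)) > 1) {
    stop("covered_exon_fraction() expects a single gene")
  }
  seqid <- unique(gene_model$seqid)
  if (length(seqid) != 1) stop("gene exons must lie on one sequence")
  exons <- IRanges::reduce(IRanges::IRanges(start = gene_model$start + 1L,
                                            end = gene_model$end))
  total <- sum(IRanges::width(exons))
  if (total < 1) stop("gene model has zero exonic length")
  dt <- depth_track[depth_track$seqid == seqid & depth_track$depth >= n, ,
                    drop = FALSE]
  if (nrow(dt) == 0) return(0)
  cov <- IRanges::reduce(IRanges::IRanges(start = dt$start + 1L,
                                          end = dt$end))
  hit <- IRanges::intersect(exons, cov)
  sum(IRanges::width(hit)) / total
}

#' Call a single gene present or absent
#'
#' A gene is called absent when strictly less than 20% of its exonic bases
#' are covered by at least n reads, with n chosen from the accession's
#' mean depth by [min_reads_threshold()]; otherwise it is present.
#'
#' @param gene_model Exon rows for one gene (see
#'   [covered_exon_fraction()]).
#' @param accession_profile One-row data frame (or list) with at least
#'   `mean_depth`.
#' @param depth_track The accession's depth track.
#' @param absent_max Absence boundary on the covered fraction (strict
#'   inequality).
#'
#' @return `"present"` or `"absent"`.
#' @export
call_gene <- function(gene_model, accession_profile, depth_track,
                      absent_max = 0.20) {
  n <- min_reads_threshold(accession_profile$mean_depth)
  frac <- covered_exon_fraction(gene_model, depth_track, n)
  if (frac < absent_max) "absent" else "present"
}

#' Build the full PAV matrix from coverage tracks
#'
#' Applies the absence rule of [call_gene()] to every gene in every
#' accession. The per-accession work is vectorized over genes via
#' interval overlap, which is exactly equivalent to calling
#' [covered_exon_fraction()] gene by gene.
#'
#' @param gene_models Data frame of exon rows for all genes: columns
#'   `gene_id`, `seqid`, `start`, `end`.
#' @param profiles Data frame of accession metadata with `accession_id`
#'   and `mean_depth` (plus any further columns, carried through).
#' @param depth_tracks Named list of depth tracks (one per accession; see
#'   [covered_exon_fraction()]). An accession present in `profiles` but
#'   missing from `depth_tracks` is a hard error; an accession with an
#'   empty track gets an all-absent column.
#' @param absent_max Absence boundary on the covered fraction.
#'
#' @return A [pav_matrix()].
#' @export
build_pav_matrix <- function(gene_models, profiles, depth_tracks,
                             absent_max = 0.20) {
  genes <- unique(gene_models$gene_id)
  accs <- profiles$accession_id
  missing <- setdiff(accs, names(depth_tracks))
  if (length(missing) > 0) {
    stop("no depth track for accession(s): ",
         paste(head(missing, 5), collapse = ", "))
  }
  exon_gr <- GenomicRanges::GRanges(
    seqnames = gene_models$seqid,
    ranges = IRanges::IRanges(start = gene_models$start + 1L,
                              end = gene_models$end)
  )
  exon_gr <- unlist(GenomicRanges::reduce(
    GenomicRanges::split(exon_gr, factor(gene_models$gene_id,
                                         levels = genes))))
  e_gene <- match(names(exon_gr), genes)
  e_start <- GenomicRanges::start(exon_gr)
  e_end <- GenomicRanges::end(exon_gr)
  totals <- as.numeric(rowsum(e_end - e_start + 1, e_gene)[, 1])
  pres <- matrix(0L, nrow = length(genes), ncol = length(accs),
                 dimnames = list(genes, accs))
  thresholds <- min_reads_threshold(profiles$mean_depth)
  for (j in seq_along(accs)) {
    dt <- depth_tracks[[accs[j]]]
    n <- thresholds[j]
    dt <- dt[dt$depth >= n, , drop = FALSE]
    if (nrow(dt) == 0) next
    cov_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      seqnames = dt$seqid,
      ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end)
    ))
    ov <- GenomicRanges::findOverlaps(exon_gr, cov_gr)
    if (length(ov) == 0) next
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    c_start <- GenomicRanges::start(cov_gr)
    c_end <- GenomicRanges::end(cov_gr)
    w <- pmin(e_end[q], c_end[s]) - pmax(e_start[q], c_start[s]) + 1L
    covered <- rowsum(w, e_gene[q])
    frac <- numeric(length(genes))
    frac[as.integer(rownames(covered))] <- covered[, 1]
    frac <- frac / totals
    pres[, j] <- as.integer(frac >= absent_max)
  }
  pav_matrix(pres, profiles)
}
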