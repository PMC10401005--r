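#' Per-gene presence frequency in an accession subset
#'
#' @param pav A [pav_matrix()].
#' @param accession_subset Non-empty character vector of accession ids.
#'
#' @return Named numeric vector of frequencies in [0, 1], one per gene.
#' @export
presence_frequency <- function(pav, accession_subset) {
  stopifnot_pav(pav)
  if (length(accession_subset) == 0) stop("accession subset is empty")
  idx <- match_accessions(pav, accession_subset)
  rowMeans(pav$presence[, idx, drop = FALSE])
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `[[a, b], [c, d]]` by summation
#' of hypergeometric point probabilities, with margins fixed, over all
#' tables whose point probability does not exceed that of the observed
#' table (the minimum-likelihood convention of mainstream
#' implementations; ties are admitted within relative tolerance 1e-12).
#' The odds ratio is the sample ratio `(a d) / (b c)`, `Inf` when
#' `b c == 0` with `a d > 0`, and `NaN` when both products vanish.
#'
#' @param a,b,c,d Non-negative integer cell counts; rows are presence
#'   states, columns are groups.
#'
#' @return List with `p_value` and `odds_ratio`.
#' @export
#'
#' @examples
#' fisher_exact_2x2(3, 0, 0, 3)$p_value  # 0.1
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("all-zero table")
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  lo <- max(0, k - r2)
  hi <- min(r1, k)
  support <- lo:hi
  probs <- dhyper(support, r1, r2, k)
  p_obs <- probs[support == a]
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  p <- min(1, p)
  odds <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  list(p_value = p, odds_ratio = odds)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment of raw p-values, returned in input order. Thin
#' wrapper over `stats::p.adjust(method = "BH")` with the input domain
#' checked.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted values in the original order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Gene-frequency selection scan between two accession groups
#'
#' For every gene, builds the 2x2 table of presence/absence counts in the
#' wild and domesticated accession sets, computes a two-sided Fisher
#' exact p-value, adjusts across all genes by Benjamini-Hochberg, and
#' derives the fold change as the ratio of the larger to the smaller
#' presence frequency (`Inf` when the smaller is 0 and the larger
#' positive; 1 when both are 0). A gene is *favorable* when
#' `fdr < fdr_max`, `fold_change > fold_min` and the domesticated
#' frequency exceeds the wild frequency; *unfavorable* with the same
#' thresholds in the opposite direction; *none* otherwise.
#'
#' @param pav A [pav_matrix()].
#' @param wild_set,domesticated_set Disjoint non-empty accession id
#'   vectors.
#' @param fdr_max FDR threshold (strict).
#' @param fold_min Fold-change threshold (strict).
#'
#' @return Data frame with one row per gene: `gene_id`, the table cells
#'   `present_dom`, `absent_dom`, `present_wild`, `absent_wild`,
#'   frequencies `freq_dom` and `freq_wild`, `p_value`, `fdr`,
#'   `fold_change`, `direction` (`dom_higher`/`wild_higher`/`equal`) and
#'   `category` (`favorable`/`unfavorable`/`none`).
#' @export
favorable_genes <- function(pav, wild_set, domesticated_set,
                            fdr_max = 0.001, fold_min = 2.0) {
  stopifnot_pav(pav)
  if (length(wild_set) == 0 || length(domesticated_set) == 0) {
    stop("both accession sets must be non-empty")
  }
  if (length(intersect(wild_set, domesticated_set)) > 0) {
    stop("wild and domesticated sets overlap")
  }
  wi <- match_accessions(pav, wild_set)
  di <- match_accessions(pav, domesticated_set)
  n_w <- length(wi)
  n_d <- length(di)
  pres_w <- rowSums(pav$presence[, wi, drop = FALSE])
  pres_d <- rowSums(pav$presence[, di, drop = FALSE])
  freq_w <- pres_w / n_w
  freq_d <- pres_d / n_d
  p <- vapply(seq_along(pres_w), function(i) {
    fisher_exact_2x2(pres_d[i], n_d - pres_d[i],
                     pres_w[i], n_w - pres_w[i])$p_value
  }, numeric(1))
  fdr <- bh_fdr(p)
  lo <- pmin(freq_w, freq_d)
  hi <- pmax(freq_w, freq_d)
  fold <- ifelse(hi == 0, 1, ifelse(lo == 0, Inf, hi / lo))
  direction <- ifelse(freq_d > freq_w, "dom_higher",
                      ifelse(freq_w > freq_d, "wild_higher", "equal"))
  signif <- fdr < fdr_max & fold > fold_min
  category <- ifelse(signif & direction == "dom_higher", "favorable",
                     ifelse(signif & direction == "wild_higher",
                            "unfavorable", "none"))
  data.frame(gene_id = gene_ids(pav),
             present_dom = pres_d, absent_dom = n_d - pres_d,
             present_wild = pres_w, absent_wild = n_w - pres_w,
             freq_dom = unname(freq_d), freq_wild = unname(freq_w),
             p_value = p, fdr = fdr, fold_change = unname(fold),
             direction = direction, category = category,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Split favorable genes into landrace- and cultivar-specific sets
#'
#' Among genes already called favorable, compares presence frequencies in
#' the landrace and cultivar accession sets: strictly higher landrace
#' frequency makes the gene landrace-favorable, strictly higher cultivar
#' frequency cultivar-favorable, and exact ties are reported separately.
#'
#' @param pav A [pav_matrix()].
#' @param favorable_table Result of [favorable_genes()] (only rows with
#'   `category == "favorable"` are used).
#' @param landrace_set,cultivar_set Disjoint accession id vectors.
#'
#' @return List of gene-id vectors `landrace_favorable`,
#'   `cultivar_favorable` and `ties`.
#' @export
partition_favorable <- function(pav, favorable_table, landrace_set,
                                cultivar_set) {
  stopifnot_pav(pav)
  if (length(intersect(landrace_set, cultivar_set)) > 0) {
    stop("landrace and cultivar sets overlap")
  }
  fav <- favorable_table$gene_id[favorable_table$category == "favorable"]
  if (length(fav) == 0) {
    return(list(landrace_favorable = character(0),
                cultivar_favorable = character(0),
                ties = character(0)))
  }
  fl <- presence_frequency(pav, landrace_set)[fav]
  fc <- presence_frequency(pav, cultivar_set)[fav]
  list(landrace_favorable = fav[fl > fc],
       cultivar_favorable = fav[fc > fl],
       ties = fav[fl == fc])
}

#' Fisher-based term enrichment
#'
#' Classic per-term Fisher enrichment of a gene set against a background:
#' for each term, the 2x2 table of (in set / not in set) x (annotated
#' with the term / not) is tested with [fisher_exact_2x2()] and the
#' p-values are adjusted across terms by Benjamini-Hochberg. The term map
#' is flat (no ontology-graph propagation).
#'
#' @param gene_set Non-empty character vector, a subset of
#'   `background_genes`.
#' @param background_genes Character vector of all genes considered.
#' @param term_map Data frame with columns `gene_id` and `term`.
#' @param fdr_max Threshold used only to flag the `enriched` column.
#'
#' @return Data frame sorted by FDR then p: `term`, `set_with_term`,
#'   `set_total`, `bg_with_term`, `bg_total`, `p_value`, `fdr`,
#'   `enriched`.
#' @export
term_enrichment <- function(gene_set, background_genes, term_map,
                            fdr_max = 0.05) {
  if (length(gene_set) == 0) stop("gene_set is empty")
  if (!all(gene_set %in% background_genes)) {
    stop("gene_set must be a subset of background_genes")
  }
  tm <- term_map[term_map$gene_id %in% background_genes, , drop = FALSE]
  terms <- sort(unique(tm$term))
  in_set <- background_genes %in% gene_set
  n_set <- sum(in_set)
  n_bg <- length(background_genes)
  res <- do.call(rbind, lapply(terms, function(t) {
    with_term <- background_genes %in% tm$gene_id[tm$term == t]
    a <- sum(in_set & with_term)
    b <- sum(in_set & !with_term)
    c_ <- sum(!in_set & with_term)
    d <- sum(!in_set & !with_term)
    data.frame(term = t, set_with_term = a, set_total = n_set,
               bg_with_term = a + c_, bg_total = n_bg,
               p_value = fisher_exact_2x2(a, b, c_, d)$p_value,
               stringsAsFactors = FALSE)
  }))
  res$fdr <- bh_fdr(res$p_value)
  res$enriched <- res$fdr < fdr_max
  res[order(res$fdr, res$p_value, res$term), , drop = FALSE]
}
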