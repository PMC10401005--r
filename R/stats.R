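#' Classify genes into core, shell and cloud
#'
#' A gene's presence frequency is its row mean over accessions. Genes
#' with frequency strictly above `core_min` are core, strictly below
#' `cloud_max` cloud, and shell otherwise, so the three categories
#' partition the gene set for any thresholds.
#'
#' @param pav A [pav_matrix()].
#' @param core_min Core boundary (default 0.97, exclusive: core genes are
#'   present in more than 97% of accessions).
#' @param cloud_max Cloud boundary (default 0.03, exclusive).
#'
#' @return Data frame with columns `gene_id`, `frequency`, `category`
#'   (factor with levels core, shell, cloud).
#' @export
classify_genes <- function(pav, core_min = 0.97, cloud_max = 0.03) {
  stopifnot_pav(pav)
  if (ncol(pav$presence) < 1) stop("PAV matrix has no accessions")
  freq <- rowMeans(pav$presence)
  category <- ifelse(freq > core_min, "core",
                     ifelse(freq < cloud_max, "cloud", "shell"))
  data.frame(gene_id = gene_ids(pav), frequency = unname(freq),
             category = factor(category, levels = c("core", "shell",
                                                    "cloud")),
             stringsAsFactors = FALSE)
}

#' Pan- and core-genome rarefaction curves
#'
#' For each of `n_permutations` random orderings of the accessions,
#' computes the pangenome size (union of gene sets of the first k
#' accessions) and core size (intersection) as k grows, then summarizes
#' across permutations. Sampling is without replacement (each permutation
#' uses every accession once).
#'
#' @param pav A [pav_matrix()].
#' @param n_permutations Number of random accession orderings.
#' @param seed Integer seed controlling the orderings.
#'
#' @return Object of class `rarefaction_result`: list with `summary`
#'   (data frame `k`, `pan_mean`, `pan_min`, `pan_max`, `core_mean`,
#'   `core_min`, `core_max`), `pan_curves` and `core_curves`
#'   (permutations x k integer matrices), `n_permutations` and `seed`.
#' @export
rarefaction <- function(pav, n_permutations = 100, seed = 1) {
  stopifnot_pav(pav)
  n_acc <- ncol(pav$presence)
  if (n_acc < 2) stop("rarefaction needs at least 2 accessions")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  set.seed(seed)
  pan_curves <- matrix(0L, n_permutations, n_acc)
  core_curves <- matrix(0L, n_permutations, n_acc)
  pres <- pav$presence
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(n_acc)
    cum <- pres[, ord[1]]
    pan_curves[p, 1] <- sum(cum > 0)
    core_curves[p, 1] <- sum(cum > 0)
    run_pan <- cum > 0
    run_core <- cum > 0
    for (k in seq_len(n_acc)[-1]) {
      col <- pres[, ord[k]] > 0
      run_pan <- run_pan | col
      run_core <- run_core & col
      pan_curves[p, k] <- sum(run_pan)
      core_curves[p, k] <- sum(run_core)
    }
  }
  summary <- data.frame(
    k = seq_len(n_acc),
    pan_mean = colMeans(pan_curves),
    pan_min = apply(pan_curves, 2, min),
    pan_max = apply(pan_curves, 2, max),
    core_mean = colMeans(core_curves),
    core_min = apply(core_curves, 2, min),
    core_max = apply(core_curves, 2, max)
  )
  structure(list(summary = summary, pan_curves = pan_curves,
                 core_curves = core_curves,
                 n_permutations = n_permutations, seed = seed),
            class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  n <- nrow(x$summary)
  cat(sprintf("rarefaction over %d accessions, %d permutations\n",
              n, x$n_permutations))
  cat(sprintf("  pan: %.0f -> %.0f, core: %.0f -> %.0f\n",
              x$summary$pan_mean[1], x$summary$pan_mean[n],
              x$summary$core_mean[1], x$summary$core_mean[n]))
  pk <- plateau_k(x)
  if (!is.na(pk)) cat(sprintf("  pan curve plateaus at k = %d\n", pk))
  invisible(x)
}

#' Smallest accession count at which the pan curve plateaus
#'
#' Reports the smallest k at which the mean pangenome size gains less
#' than `gain_frac` of its value over the preceding `window` accessions.
#'
#' @param rar A `rarefaction_result`.
#' @param window Lookback in accessions.
#' @param gain_frac Relative gain defining "flat".
#' @return Integer k, or NA when the curve never flattens.
#' @export
plateau_k <- function(rar, window = 10, gain_frac = 0.005) {
  pm <- rar$summary$pan_mean
  ks <- seq_along(pm)
  ok <- ks > window & (pm - c(rep(NA, window), pm)[ks]) < gain_frac * pm
  k <- which(ok)[1]
  if (is.na(k)) NA_integer_ else as.integer(k)
}

#' Shared-gene count matrix
#'
#' Entry (i, j) counts the genes present in both accessions i and j; the
#' diagonal holds per-accession gene counts.
#'
#' @param pav A [pav_matrix()].
#' @return Symmetric integer matrix, accessions x accessions.
#' @export
shared_gene_matrix <- function(pav) {
  stopifnot_pav(pav)
  m <- crossprod(pav$presence)
  storage.mode(m) <- "integer"
  m
}

#' Per-clade presence sets, unique sets and Venn partition
#'
#' A gene is present in a clade when at least one member accession has
#' it. `unique` sets subtract the union of all other clades; `venn`
#' counts genes by the exact combination of clades they are present in,
#' so the counts sum to the number of genes present anywhere.
#'
#' @param pav A [pav_matrix()].
#' @param clade_map Named character vector mapping every accession to a
#'   clade label.
#'
#' @return List with `present` (named list of gene-id vectors), `unique`
#'   (same shape) and `venn` (named integer vector; names are clade
#'   combinations joined with `&`).
#' @export
clade_presence_sets <- function(pav, clade_map) {
  stopifnot_pav(pav)
  accs <- accession_ids(pav)
  missing <- setdiff(accs, names(clade_map))
  if (length(missing) > 0) {
    stop("accession(s) without clade: ",
         paste(head(missing, 5), collapse = ", "))
  }
  clades <- sort(unique(unname(clade_map[accs])))
  memb <- vapply(clades, function(cl) {
    cols <- accs[clade_map[accs] == cl]
    rowSums(pav$presence[, cols, drop = FALSE]) > 0
  }, logical(nrow(pav$presence)))
  present <- lapply(clades, function(cl) gene_ids(pav)[memb[, cl]])
  names(present) <- clades
  uniq <- lapply(clades, function(cl) {
    others <- memb[, setdiff(clades, cl), drop = FALSE]
    gene_ids(pav)[memb[, cl] & rowSums(others) == 0]
  })
  names(uniq) <- clades
  anywhere <- rowSums(memb) > 0
  key <- apply(memb[anywhere, , drop = FALSE], 1, function(r) {
    paste(clades[r], collapse = "&")
  })
  venn_all <- vapply(venn_cell_names(clades), function(nm) {
    sum(key == nm)
  }, integer(1))
  list(present = present, unique = uniq, venn = venn_all)
}

venn_cell_names <- function(clades) {
  k <- length(clades)
  cells <- character(0)
  for (size in seq_len(k)) {
    combos <- utils::combn(clades, size, simplify = FALSE)
    cells <- c(cells, vapply(combos, paste, character(1), collapse = "&"))
  }
  cells
}

#' Per-group core gene sets and unique-core sets
#'
#' A gene is core within a group when its presence frequency among that
#' group's accessions exceeds `core_min`; the unique-core set of a group
#' subtracts the core sets of all other groups.
#'
#' @param pav A [pav_matrix()].
#' @param group_map Named character vector mapping accessions to group
#'   labels; every group must have at least one accession.
#' @param core_min Within-group core boundary (exclusive).
#'
#' @return List with `core` and `unique_core`, each a named list of
#'   gene-id vectors.
#' @export
group_core_sets <- function(pav, group_map, core_min = 0.97) {
  stopifnot_pav(pav)
  accs <- accession_ids(pav)
  missing <- setdiff(accs, names(group_map))
  if (length(missing) > 0) {
    stop("accession(s) without group: ",
         paste(head(missing, 5), collapse = ", "))
  }
  groups <- sort(unique(unname(group_map[accs])))
  core <- lapply(groups, function(g) {
    cols <- accs[group_map[accs] == g]
    if (length(cols) == 0) stop("empty group: ", g)
    freq <- rowMeans(pav$presence[, cols, drop = FALSE])
    gene_ids(pav)[freq > core_min]
  })
  names(core) <- groups
  uniq <- lapply(groups, function(g) {
    others <- unique(unlist(core[setdiff(groups, g)]))
    setdiff(core[[g]], others)
  })
  names(uniq) <- groups
  list(core = core, unique_core = uniq)
}

#' Per-group summaries of gene counts and annotation counts
#'
#' Summarizes per-accession gene counts (and any further per-accession
#' numeric columns, e.g. transposable-element counts) within groups:
#' count, mean, depth-weighted mean, median and quartiles. The weighted
#' mean uses the accessions' mean sequencing depth as weight, so shallow
#' accessions - whose PAV calls are the noisiest - contribute less.
#'
#' @param pav A [pav_matrix()].
#' @param group_col Metadata column of `pav$profiles` to group by.
#' @param annotation_counts Optional data frame with `accession_id` plus
#'   numeric columns to summarize alongside the gene counts.
#'
#' @return Data frame with one row per group and variable.
#' @export
group_summaries <- function(pav, group_col = "group",
                            annotation_counts = NULL) {
  stopifnot_pav(pav)
  prof <- pav$profiles
  if (!group_col %in% names(prof)) {
    stop("metadata column not found: ", group_col)
  }
  values <- data.frame(accession_id = accession_ids(pav),
                       gene_count = as.numeric(accession_gene_counts(pav)),
                       stringsAsFactors = FALSE)
  if (!is.null(annotation_counts)) {
    if (!"accession_id" %in% names(annotation_counts)) {
      stop("annotation_counts must have an accession_id column")
    }
    extra <- annotation_counts[match(values$accession_id,
                                     annotation_counts$accession_id), ,
                               drop = FALSE]
    num_cols <- setdiff(names(extra), "accession_id")
    for (cl in num_cols) {
      if (!is.numeric(extra[[cl]])) {
        stop("annotation column is not numeric: ", cl)
      }
      values[[cl]] <- extra[[cl]]
    }
  }
  wts <- if ("mean_depth" %in% names(prof)) prof$mean_depth else
    rep(1, nrow(prof))
  groups <- prof[[group_col]]
  vars <- setdiff(names(values), "accession_id")
  out <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    idx <- which(groups == g)
    do.call(rbind, lapply(vars, function(v) {
      x <- values[[v]][idx]
      w <- wts[idx]
      data.frame(group = g, variable = v, n = length(idx),
                 mean = mean(x),
                 weighted_mean = weighted.mean(x, w),
                 median = median(x),
                 q1 = unname(quantile(x, 0.25)),
                 q3 = unname(quantile(x, 0.75)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
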