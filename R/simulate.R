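#' Simulation configuration for synthetic pangenome panels
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe the standard study conditions used throughout the
#' package's validation: a 3-clade panel of 20 accessions each, 5,000
#' genes split 2,000 core / 2,500 shell / 500 cloud, 30x mean depth, and
#' 0.5% spurious-coverage and dropout noise.
#'
#' @param seed Integer master seed; every generator operation derives its
#'   RNG state from it, so identical configurations reproduce identical
#'   outputs.
#' @param n_clades,accessions_per_clade Panel structure (>= 2 each).
#' @param n_core_genes,n_shell_genes,n_cloud_genes Gene counts per truth
#'   category.
#' @param loss_rate,gain_rate Per-branch Bernoulli probabilities of a
#'   shell gene switching present -> absent / absent -> present.
#' @param root_present_prob Probability a shell gene is present at the
#'   root of the guide tree.
#' @param cloud_max_frac A cloud gene is placed in at most
#'   `max(1, floor(cloud_max_frac * n_accessions))` accessions.
#' @param ploidy_map Named integer vector (accession -> ploidy in 2..5) or
#'   `NULL` for all-diploid.
#' @param ploidy_gene_bonus Expected number of extra present genes per
#'   ploidy step above diploid.
#' @param selection_genes Optional data frame `gene_id`, `wild_freq`,
#'   `dom_freq`: genes drawn i.i.d. with group-dependent presence
#'   probability, planted for selection-scan validation.
#' @param depth_map Mean read depth: a single value for all accessions or
#'   a named vector covering every accession.
#' @param noise_fp Probability an absent gene receives spurious coverage
#'   that passes the presence rule.
#' @param noise_fn Probability a present gene drops out of coverage.
#' @param group_map Named character vector (accession -> `"wild"`,
#'   `"landrace"` or `"cultivar"`) or `NULL` for a balanced round-robin
#'   assignment within each clade (groups then carry no clade signal,
#'   which is the correct null for selection-scan calibration).
#' @param in_vitro_map Named logical vector or `NULL` for all-`FALSE`.
#'
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1,
                       n_clades = 3,
                       accessions_per_clade = 20,
                       n_core_genes = 2000,
                       n_shell_genes = 2500,
                       n_cloud_genes = 500,
                       loss_rate = 0.08,
                       gain_rate = 0.04,
                       root_present_prob = 0.5,
                       cloud_max_frac = 0.03,
                       ploidy_map = NULL,
                       ploidy_gene_bonus = 0,
                       selection_genes = NULL,
                       depth_map = 30,
                       noise_fp = 0.005,
                       noise_fn = 0.005,
                       group_map = NULL,
                       in_vitro_map = NULL) {
  cfg <- list(seed = as.integer(seed), n_clades = n_clades,
              accessions_per_clade = accessions_per_clade,
              n_core_genes = n_core_genes, n_shell_genes = n_shell_genes,
              n_cloud_genes = n_cloud_genes, loss_rate = loss_rate,
              gain_rate = gain_rate, root_present_prob = root_present_prob,
              cloud_max_frac = cloud_max_frac, ploidy_map = ploidy_map,
              ploidy_gene_bonus = ploidy_gene_bonus,
              selection_genes = selection_genes, depth_map = depth_map,
              noise_fp = noise_fp, noise_fn = noise_fn,
              group_map = group_map, in_vitro_map = in_vitro_map)
  probs <- c(loss_rate, gain_rate, root_present_prob, noise_fp, noise_fn,
             cloud_max_frac)
  if (any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  counts <- c(n_core_genes, n_shell_genes, n_cloud_genes)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("gene counts must be non-negative integers")
  }
  if (n_clades < 2 || accessions_per_clade < 2) {
    stop("need at least 2 clades and 2 accessions per clade")
  }
  if (!is.null(selection_genes)) {
    req <- c("gene_id", "wild_freq", "dom_freq")
    if (!all(req %in% names(selection_genes))) {
      stop("selection_genes needs columns gene_id, wild_freq, dom_freq")
    }
    f <- c(selection_genes$wild_freq, selection_genes$dom_freq)
    if (any(f < 0) || any(f > 1)) {
      stop("selection gene frequencies must lie in [0, 1]")
    }
  }
  if (ploidy_gene_bonus < 0) stop("ploidy_gene_bonus must be >= 0")
  if (!is.null(ploidy_map) && !all(ploidy_map %in% 2:5)) {
    stop("ploidy values must be in 2..5")
  }
  if (any(depth_map < 0)) stop("depths must be non-negative")
  structure(cfg, class = "sim_config")
}

sim_accession_labels <- function(n_clades, accessions_per_clade) {
  unlist(lapply(seq_len(n_clades), function(cl) {
    sprintf("c%d_a%02d", cl, seq_len(accessions_per_clade))
  }))
}

#' Clade of each accession label
#'
#' Synthetic accession labels encode their clade as a `c<k>_` prefix;
#' this recovers the named clade map used by the set-algebra and
#' tree-validation functions.
#'
#' @param labels Character vector of accession labels.
#' @return Named character vector, accession -> clade label.
#' @export
sim_clade_map <- function(labels) {
  setNames(sub("^(c\\d+)_.*$", "clade_\\1", labels), labels)
}

random_binary_newick <- function(labels, bl_min, bl_max) {
  frags <- labels
  while (length(frags) > 1) {
    pair <- sample.int(length(frags), 2)
    bl <- runif(2, bl_min, bl_max)
    merged <- sprintf("(%s:%.6f,%s:%.6f)", frags[pair[1]], bl[1],
                      frags[pair[2]], bl[2])
    frags <- c(frags[-pair], merged)
  }
  frags
}

#' Simulate a clade-structured guide tree
#'
#' Builds a random binary tree whose leaves fall into `n_clades`
#' monophyletic clades of `accessions_per_clade` accessions each: a
#' random binary subtree is grown per clade and the clade subtrees are
#' joined by a random binary backbone with longer branches. Branch
#' lengths are cosmetic (gene gain/loss acts per branch, not per unit
#' length).
#'
#' @param n_clades Number of clades (>= 2).
#' @param accessions_per_clade Accessions per clade (>= 2).
#' @param seed Integer seed.
#'
#' @return An `ape::phylo` tree with tip labels `c<k>_a<j>`.
#' @export
simulate_guide_tree <- function(n_clades, accessions_per_clade, seed = 1) {
  if (n_clades < 2 || accessions_per_clade < 2) {
    stop("need at least 2 clades and 2 accessions per clade")
  }
  set.seed(seed)
  clade_frags <- vapply(seq_len(n_clades), function(cl) {
    labs <- sprintf("c%d_a%02d", cl, seq_len(accessions_per_clade))
    random_binary_newick(labs, 0.02, 0.08)
  }, character(1))
  backbone <- random_binary_newick(clade_frags, 0.15, 0.30)
  ape::read.tree(text = paste0(backbone, ";"))
}

resolve_map <- function(map, labels, default, what) {
  if (is.null(map)) {
    return(setNames(rep(default, length(labels)), labels))
  }
  if (length(map) == 1 && is.null(names(map))) {
    return(setNames(rep(map, length(labels)), labels))
  }
  missing <- setdiff(labels, names(map))
  if (length(missing) > 0) {
    stop("accession(s) missing from ", what, ": ",
         paste(head(missing, 5), collapse = ", "))
  }
  map[labels]
}

default_group_map <- function(labels, clade_map) {
  groups <- c("wild", "landrace", "cultivar")
  out <- character(length(labels))
  names(out) <- labels
  for (cl in unique(clade_map)) {
    members <- labels[clade_map == cl]
    out[members] <- groups[(seq_along(members) - 1) %% 3 + 1]
  }
  out
}

#' Simulate a PAV matrix with known truth on a guide tree
#'
#' Core genes are present everywhere. Shell genes evolve on the tree by
#' a per-branch Bernoulli gain/loss process (a present gene is lost with
#' `loss_rate`, an absent one gained with `gain_rate`, independently per
#' branch and gene), which produces clade-structured presence patterns.
#' Cloud genes are placed in at most `max(1, floor(cloud_max_frac * N))`
#' random accessions. Polyploid accessions then gain additional genes
#' (expectation `ploidy_gene_bonus * (ploidy - 2)`, Poisson) from their
#' absent shell/cloud pool, and planted selection genes are drawn
#' i.i.d. with group-dependent presence probabilities.
#'
#' @param tree Guide tree from [simulate_guide_tree()]; its tip set must
#'   match the panel implied by `config`.
#' @param config A [sim_config()].
#'
#' @return List with `pav` (a [pav_matrix()]) and `truth`: `true_pav`
#'   (identical to `pav`; coverage noise is applied downstream),
#'   `true_tree`, `true_categories` (named factor gene ->
#'   core/shell/cloud), `true_favorable` (planted selection genes whose
#'   domesticated frequency exceeds the wild frequency) and `clade_map`.
#' @export
simulate_pav <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  labels <- sim_accession_labels(config$n_clades,
                                 config$accessions_per_clade)
  if (!setequal(tree$tip.label, labels)) {
    stop("tree tips do not match the panel implied by `config`")
  }
  accs <- tree$tip.label
  n_acc <- length(accs)
  clade_map <- sim_clade_map(accs)
  group_map <- if (is.null(config$group_map)) {
    default_group_map(accs, clade_map)
  } else {
    resolve_map(config$group_map, accs, NULL, "group_map")
  }
  ploidy <- resolve_map(config$ploidy_map, accs, 2L, "ploidy_map")
  depth <- resolve_map(config$depth_map, accs, 30, "depth_map")
  in_vitro <- resolve_map(config$in_vitro_map, accs, FALSE, "in_vitro_map")

  set.seed(config$seed + 1L)
  ids_core <- sprintf("core_%05d", seq_len(config$n_core_genes))
  ids_shell <- sprintf("shell_%05d", seq_len(config$n_shell_genes))
  ids_cloud <- sprintf("cloud_%05d", seq_len(config$n_cloud_genes))
  sel <- config$selection_genes
  ids_sel <- if (is.null(sel)) character(0) else as.character(sel$gene_id)
  gene_idv <- c(ids_core, ids_shell, ids_cloud, ids_sel)
  if (length(gene_idv) == 0) stop("configuration yields zero genes")
  if (anyDuplicated(gene_idv)) stop("duplicate gene ids in configuration")

  pres <- matrix(0L, nrow = length(gene_idv), ncol = n_acc,
                 dimnames = list(gene_idv, accs))
  if (length(ids_core) > 0) pres[ids_core, ] <- 1L

  if (length(ids_shell) > 0) {
    pres[ids_shell, ] <- evolve_on_tree(tree, length(ids_shell),
                                        config$loss_rate,
                                        config$gain_rate,
                                        config$root_present_prob)[, accs]
  }

  if (length(ids_cloud) > 0) {
    k_max <- max(1L, floor(config$cloud_max_frac * n_acc))
    for (g in ids_cloud) {
      k <- sample.int(k_max, 1)
      pres[g, sample.int(n_acc, k)] <- 1L
    }
  }

  if (config$ploidy_gene_bonus > 0 && any(ploidy > 2)) {
    pool <- c(ids_shell, ids_cloud)
    for (j in seq_len(n_acc)) {
      if (ploidy[j] <= 2 || length(pool) == 0) next
      n_extra <- rpois(1, config$ploidy_gene_bonus * (ploidy[j] - 2))
      absent <- pool[pres[pool, j] == 0L]
      if (n_extra > 0 && length(absent) > 0) {
        add <- sample(absent, min(n_extra, length(absent)))
        pres[add, j] <- 1L
      }
    }
  }

  if (length(ids_sel) > 0) {
    is_wild <- group_map[accs] == "wild"
    for (i in seq_along(ids_sel)) {
      p <- ifelse(is_wild, sel$wild_freq[i], sel$dom_freq[i])
      pres[ids_sel[i], ] <- rbinom(n_acc, 1, p)
    }
  }

  profiles <- data.frame(accession_id = accs,
                         mean_depth = unname(depth),
                         group = unname(group_map),
                         clade = unname(clade_map),
                         ploidy = as.integer(unname(ploidy)),
                         in_vitro = unname(in_vitro),
                         stringsAsFactors = FALSE)
  pav <- pav_matrix(pres, profiles)

  sel_cat <- character(0)
  if (length(ids_sel) > 0) {
    n_wild <- sum(group_map == "wild")
    exp_freq <- (n_wild * sel$wild_freq +
                   (n_acc - n_wild) * sel$dom_freq) / n_acc
    sel_cat <- ifelse(exp_freq > 0.97, "core",
                      ifelse(exp_freq < 0.03, "cloud", "shell"))
  }
  true_categories <- setNames(
    c(rep("core", length(ids_core)), rep("shell", length(ids_shell)),
      rep("cloud", length(ids_cloud)), sel_cat),
    gene_idv
  )
  true_favorable <- if (is.null(sel)) character(0) else
    ids_sel[sel$dom_freq > sel$wild_freq]

  list(pav = pav,
       truth = list(true_pav = pav, true_tree = tree,
                    true_categories = true_categories,
                    true_favorable = true_favorable,
                    clade_map = clade_map))
}

# per-branch Bernoulli gain/loss; returns genes x tips 0/1 matrix
evolve_on_tree <- function(tree, n_genes, loss_rate, gain_rate,
                           root_present_prob) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  root <- n_tip + 1L
  states <- matrix(FALSE, nrow = n_nodes, ncol = n_genes)
  states[root, ] <- runif(n_genes) < root_present_prob
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    s <- states[parent, ]
    u <- runif(n_genes)
    s_new <- ifelse(s, u >= loss_rate, u < gain_rate)
    states[child, ] <- s_new
  }
  out <- t(states[seq_len(n_tip), , drop = FALSE]) * 1L
  colnames(out) <- tree$tip.label
  out
}

#' Deterministic gene models for simulated genes
#'
#' Lays simulated genes out on synthetic pangenome sequences in a fixed
#' grid: `genes_per_seq` genes per sequence, each gene consisting of
#' `exons_per_gene` exons of `exon_length` bases separated by
#' `intron_length`-base introns, with `intergenic` bases between genes.
#' No randomness is involved.
#'
#' @param gene_idv Character vector of gene ids.
#' @param exon_length,exons_per_gene,intron_length,intergenic,genes_per_seq
#'   Layout parameters in bases / counts.
#'
#' @return Data frame of exon rows: `gene_id`, `seqid`, `start`, `end`
#'   (0-based half-open).
#' @export
simulate_gene_models <- function(gene_idv, exon_length = 150,
                                 exons_per_gene = 2, intron_length = 50,
                                 intergenic = 100, genes_per_seq = 100) {
  n <- length(gene_idv)
  gene_span <- exons_per_gene * exon_length +
    (exons_per_gene - 1) * intron_length
  step <- gene_span + intergenic
  seq_idx <- (seq_len(n) - 1) %/% genes_per_seq
  pos_idx <- (seq_len(n) - 1) %% genes_per_seq
  gene_start <- pos_idx * step
  exon_off <- (seq_len(exons_per_gene) - 1) * (exon_length + intron_length)
  starts <- rep(gene_start, each = exons_per_gene) +
    rep(exon_off, times = n)
  data.frame(
    gene_id = rep(gene_idv, each = exons_per_gene),
    seqid = sprintf("panseq_%03d", rep(seq_idx, each = exons_per_gene) + 1),
    start = starts,
    end = starts + exon_length,
    stringsAsFactors = FALSE
  )
}

#' Simulate per-accession exon coverage tracks consistent with a PAV truth
#'
#' Exons are split into `piece_length`-base pieces sharing one depth
#' value. For a present gene the piece depths are Poisson around the
#' accession's mean depth, except that with probability `noise_fn` the
#' gene drops out entirely (no coverage). For an absent gene no coverage
#' is emitted, except that with probability `noise_fp` a spurious-mapping
#' event covers 30% of the gene's pieces at a depth clearing the
#' accession's presence threshold. With both noise rates 0 the downstream
#' absence caller therefore reproduces the truth matrix exactly.
#'
#' @param pav Truth [pav_matrix()] from [simulate_pav()].
#' @param gene_models Exon table from [simulate_gene_models()]; every
#'   gene in `pav` must have a model.
#' @param config A [sim_config()].
#' @param piece_length Bases per constant-depth piece.
#'
#' @return Named list (one element per accession) of depth tracks:
#'   data frames `seqid`, `start`, `end`, `depth` (0-based half-open),
#'   the in-memory equivalent of a bedGraph file.
#' @export
simulate_coverage <- function(pav, gene_models, config,
                              piece_length = 50) {
  stopifnot_pav(pav)
  stopifnot(inherits(config, "sim_config"))
  genes <- gene_ids(pav)
  missing <- setdiff(genes, unique(gene_models$gene_id))
  if (length(missing) > 0) {
    stop("gene(s) without model: ", paste(head(missing, 5), collapse = ", "))
  }
  pieces <- exon_pieces(gene_models[gene_models$gene_id %in% genes, ,
                                    drop = FALSE], piece_length)
  gene_of_piece <- match(pieces$gene_id, genes)
  n_pieces_per_gene <- tabulate(gene_of_piece, nbins = length(genes))
  piece_rank <- sequence(rle(pieces$gene_id)$lengths)
  spurious_cut <- ceiling(0.3 * n_pieces_per_gene)

  set.seed(config$seed + 2L)
  profiles <- pav$profiles
  tracks <- vector("list", nrow(profiles))
  names(tracks) <- profiles$accession_id
  for (j in seq_len(nrow(profiles))) {
    acc <- profiles$accession_id[j]
    mu <- profiles$mean_depth[j]
    thr <- min_reads_threshold(mu)
    present <- pav$presence[, acc] == 1L
    dropout <- runif(length(genes)) < config$noise_fn
    spurious <- runif(length(genes)) < config$noise_fp
    emit_full <- present & !dropout
    emit_spur <- !present & spurious
    keep_full <- emit_full[gene_of_piece]
    keep_spur <- emit_spur[gene_of_piece] &
      piece_rank <= spurious_cut[gene_of_piece]
    depth <- integer(nrow(pieces))
    depth[keep_full] <- rpois(sum(keep_full), mu)
    depth[keep_spur] <- thr + 2L
    sel <- depth > 0L
    tr <- data.frame(seqid = pieces$seqid[sel],
                     start = pieces$start[sel],
                     end = pieces$end[sel],
                     depth = depth[sel],
                     stringsAsFactors = FALSE)
    tracks[[acc]] <- tr[order(tr$seqid, tr$start), , drop = FALSE]
  }
  tracks
}

exon_pieces <- function(gene_models, piece_length) {
  gm <- gene_models[order(match(gene_models$gene_id,
                                unique(gene_models$gene_id))), ,
                    drop = FALSE]
  widths <- gm$end - gm$start
  n_pieces <- ceiling(widths / piece_length)
  idx <- rep(seq_len(nrow(gm)), n_pieces)
  off <- (sequence(n_pieces) - 1) * piece_length
  start <- gm$start[idx] + off
  end <- pmin(start + piece_length, gm$end[idx])
  data.frame(gene_id = gm$gene_id[idx], seqid = gm$seqid[idx],
             start = start, end = end, stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate contigs, alignment hits and taxon hits with planted structure
#'
#' Emits a small synthetic reference plus contigs in four truth classes:
#' fully reference-aligned contigs, partially aligned contigs carrying an
#' internal novel insert of at least 500 bp, mutually redundant novel
#' contig pairs (>= 95% identity and coverage), and contaminant contigs
#' whose taxonomic hits are non-green-plant. Alignment-hit and taxon-hit
#' records are consistent with the planted structure, so every stage of
#' the non-reference extraction pipeline has a known expected output.
#'
#' @param config A [sim_config()] (only its `seed` is used).
#' @param n_aligned,n_insert,n_redundant_pairs,n_contaminant Contig
#'   counts per class.
#' @param insert_lengths Novel insert lengths (recycled over the insert
#'   contigs; all >= 500).
#'
#' @return List with `reference` and `contigs` (named character vectors),
#'   `hits` (alignment-hit data frame), `taxon_hits` (data frame
#'   `query_id`, `query_start`, `query_end`, `taxon_class`) and `truth`:
#'   `labels` (named vector with values `reference-derived`, `novel`,
#'   `redundant`, `contaminant`) and `inserts` (data frame of planted
#'   insert coordinates).
#' @export
simulate_contigs_and_hits <- function(config, n_aligned = 4, n_insert = 3,
                                      n_redundant_pairs = 3,
                                      n_contaminant = 2,
                                      insert_lengths = c(600, 800, 500)) {
  stopifnot(inherits(config, "sim_config"))
  if (any(insert_lengths < 500)) stop("insert lengths must be >= 500")
  set.seed(config$seed + 3L)
  reference <- c(ref_chr1 = random_dna(12000), ref_chr2 = random_dna(10000))
  contigs <- character(0)
  labels <- character(0)
  hits <- list()
  taxon_hits <- list()
  inserts <- list()

  add_hit <- function(qid, qlen, qs, qe, target, identity) {
    hits[[length(hits) + 1]] <<- data.frame(
      query_id = qid, query_length = qlen, query_start = qs,
      query_end = qe, target_id = target, identity = identity,
      alignment_length = qe - qs, stringsAsFactors = FALSE)
  }
  add_tax <- function(qid, qs, qe, cls) {
    taxon_hits[[length(taxon_hits) + 1]] <<- data.frame(
      query_id = qid, query_start = qs, query_end = qe,
      taxon_class = cls, stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_aligned)) {
    id <- sprintf("aligned_%02d", i)
    ref <- names(reference)[(i %% 2) + 1]
    len <- 2000
    pos <- sample.int(nchar(reference[[ref]]) - len, 1)
    seq <- mutate_dna(substr(reference[[ref]], pos, pos + len - 1), 0.01)
    contigs[id] <- seq
    labels[id] <- "reference-derived"
    add_hit(id, len, 0L, len, ref, 98.5)
  }

  flank <- 700L
  for (i in seq_len(n_insert)) {
    id <- sprintf("insert_%02d", i)
    ilen <- as.integer(insert_lengths[(i - 1) %% length(insert_lengths) + 1])
    ref <- names(reference)[(i %% 2) + 1]
    pos <- sample.int(nchar(reference[[ref]]) - 2 * flank, 1)
    left <- mutate_dna(substr(reference[[ref]], pos, pos + flank - 1), 0.01)
    right <- mutate_dna(substr(reference[[ref]], pos + flank,
                               pos + 2 * flank - 1), 0.01)
    novel <- random_dna(ilen)
    contigs[id] <- paste0(left, novel, right)
    labels[id] <- "novel"
    qlen <- 2 * flank + ilen
    add_hit(id, qlen, 0L, flank, ref, 98.0)
    add_hit(id, qlen, flank + ilen, qlen, ref, 98.0)
    add_tax(id, 0L, qlen, "green_plant")
    inserts[[length(inserts) + 1]] <- data.frame(
      contig = id, start = flank, end = flank + ilen, length = ilen,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_redundant_pairs)) {
    id_a <- sprintf("novel_%02d", i)
    id_b <- sprintf("novel_%02d_dup", i)
    len <- sample(800:1500, 1)
    seq_a <- random_dna(len)
    seq_b <- mutate_dna(seq_a, 0.02)
    contigs[id_a] <- seq_a
    contigs[id_b] <- seq_b
    labels[id_a] <- "novel"
    labels[id_b] <- "redundant"
    add_tax(id_a, 0L, len, "green_plant")
    add_tax(id_b, 0L, len, "green_plant")
  }

  for (i in seq_len(n_contaminant)) {
    id <- sprintf("contam_%02d", i)
    len <- sample(700:1200, 1)
    contigs[id] <- random_dna(len)
    labels[id] <- "contaminant"
    add_tax(id, 0L, len, "other")
  }

  list(reference = reference, contigs = contigs,
       hits = do.call(rbind, hits),
       taxon_hits = do.call(rbind, taxon_hits),
       truth = list(labels = labels,
                    inserts = if (length(inserts) > 0)
                      do.call(rbind, inserts) else NULL))
}

#' Simulate a flat gene-to-term annotation map
#'
#' Assigns each gene `terms_per_gene` terms uniformly at random from
#' `n_terms` term ids, then over-represents each entry of
#' `enriched_pairs` by additionally assigning its term to each gene of
#' its gene set with probability
#' `min(1, factor * terms_per_gene / n_terms)`.
#'
#' @param gene_idv Character vector of all gene ids.
#' @param n_terms Number of terms (>= 1).
#' @param enriched_pairs Optional list of `list(term =, genes =,
#'   factor =)` entries; gene ids must exist in `gene_idv`.
#' @param seed Integer seed.
#' @param terms_per_gene Background terms per gene.
#'
#' @return Data frame with columns `gene_id` and `term` (unique rows).
#' @export
simulate_term_map <- function(gene_idv, n_terms = 20,
                              enriched_pairs = NULL, seed = 1,
                              terms_per_gene = 2) {
  if (n_terms < 1) stop("n_terms must be >= 1")
  set.seed(seed)
  terms <- sprintf("term_%03d", seq_len(n_terms))
  k <- min(terms_per_gene, n_terms)
  base <- data.frame(
    gene_id = rep(gene_idv, each = k),
    term = unlist(lapply(gene_idv, function(g) sample(terms, k))),
    stringsAsFactors = FALSE
  )
  extra <- list()
  for (pair in enriched_pairs) {
    unknown <- setdiff(pair$genes, gene_idv)
    if (length(unknown) > 0) {
      stop("unknown gene id(s) in enriched pair: ",
           paste(head(unknown, 5), collapse = ", "))
    }
    p <- min(1, pair$factor * k / n_terms)
    hit <- pair$genes[runif(length(pair$genes)) < p]
    if (length(hit) > 0) {
      extra[[length(extra) + 1]] <- data.frame(
        gene_id = hit, term = pair$term, stringsAsFactors = FALSE)
    }
  }
  out <- rbind(base, if (length(extra) > 0) do.call(rbind, extra))
  unique(out)
}

#' Run the full synthetic study: tree, PAV truth, gene models, coverage
#'
#' Convenience wrapper chaining [simulate_guide_tree()],
#' [simulate_pav()], [simulate_gene_models()] and [simulate_coverage()]
#' under one configuration.
#'
#' @param config A [sim_config()].
#' @return List with `config`, `tree`, `pav` (truth), `truth`,
#'   `gene_models` and `coverage`.
#' @export
simulate_study <- function(config = sim_config()) {
  tree <- simulate_guide_tree(config$n_clades,
                              config$accessions_per_clade,
                              seed = config$seed)
  sim <- simulate_pav(tree, config)
  gm <- simulate_gene_models(gene_ids(sim$pav))
  cov <- simulate_coverage(sim$pav, gm, config)
  list(config = config, tree = tree, pav = sim$pav, truth = sim$truth,
       gene_models = gm, coverage = cov)
}
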