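# Independent brute-force oracles and shared fixtures.
# The oracles deliberately avoid the package's interval/probability code
# paths: they mark individual bases or enumerate tables directly.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# per-base scan: uncovered runs of length >= min_len, 0-based half-open
brute_unaligned <- function(contig_length, covered, min_len) {
  base_covered <- logical(contig_length)
  if (nrow(covered) > 0) {
    for (i in seq_len(nrow(covered))) {
      if (covered$end[i] > covered$start[i]) {
        base_covered[(covered$start[i] + 1):covered$end[i]] <- TRUE
      }
    }
  }
  r <- rle(base_covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- !r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

# per-base scan of the covered-exon fraction
brute_covered_fraction <- function(gene_model, depth_track, n) {
  seqid <- gene_model$seqid[1]
  max_pos <- max(gene_model$end,
                 depth_track$end[depth_track$seqid == seqid], 0)
  depth <- numeric(max_pos)
  dt <- depth_track[depth_track$seqid == seqid, , drop = FALSE]
  for (i in seq_len(nrow(dt))) {
    idx <- (dt$start[i] + 1):dt$end[i]
    depth[idx] <- depth[idx] + dt$depth[i]
  }
  exonic <- logical(max_pos)
  for (i in seq_len(nrow(gene_model))) {
    exonic[(gene_model$start[i] + 1):gene_model$end[i]] <- TRUE
  }
  sum(depth[exonic] >= n) / sum(exonic)
}

# exact hypergeometric enumeration with binomial coefficients
brute_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  n <- r1 + r2
  support <- max(0, k - r2):min(r1, k)
  probs <- choose(r1, support) * choose(r2, k - support) / choose(n, k)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# literal step-up definition
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    q[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

random_hit_set <- function(contig_length, n_hits) {
  if (n_hits == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  start <- sample.int(contig_length, n_hits, replace = TRUE) - 1L
  len <- sample.int(max(1, contig_length %/% 2), n_hits, replace = TRUE)
  data.frame(start = start, end = pmin(start + len, contig_length))
}

# wild/cultivar split balanced within each clade (no clade-group signal)
balanced_group_map <- function(labels) {
  cm <- sim_clade_map(labels)
  out <- character(length(labels))
  names(out) <- labels
  for (cl in unique(cm)) {
    members <- labels[cm == cl]
    half <- length(members) %/% 2
    out[members] <- c(rep("wild", half),
                      rep("cultivar", length(members) - half))
  }
  out
}

# medium noise-free study reused across files (computed once per run)
.fixture_env <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- sim_config(seed = 42, n_clades = 3, accessions_per_clade = 6,
                      n_core_genes = 200, n_shell_genes = 300,
                      n_cloud_genes = 50, noise_fp = 0, noise_fn = 0)
    .fixture_env$small <- simulate_study(cfg)
  }
  .fixture_env$small
}
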