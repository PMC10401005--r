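test_that("guide tree realizes the requested clade structure deterministically", {
  tr <- simulate_guide_tree(3, 4, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_length(tr$tip.label, 12)
  cr <- clade_recovery(tr, sim_clade_map(tr$tip.label))
  expect_length(cr$monophyletic, 3)
  expect_true(all(cr$monophyletic))

  expect_identical(ape::write.tree(simulate_guide_tree(3, 4, seed = 1)),
                   ape::write.tree(tr))
  expect_false(identical(ape::write.tree(simulate_guide_tree(3, 4, seed = 2)),
                         ape::write.tree(tr)))

  tr4 <- simulate_guide_tree(2, 2, seed = 7)
  expect_length(tr4$tip.label, 4)
  expect_true(all(clade_recovery(tr4, sim_clade_map(tr4$tip.label))$monophyletic))

  expect_error(simulate_guide_tree(1, 4, seed = 1), "at least 2")
  expect_error(simulate_guide_tree(3, 0, seed = 1), "at least 2")
})

test_that("PAV simulation honors the no-event limit and truth partition", {
  cfg <- sim_config(seed = 2, n_clades = 2, accessions_per_clade = 3,
                    n_core_genes = 50, n_shell_genes = 40,
                    n_cloud_genes = 10, loss_rate = 0, gain_rate = 0)
  tr <- simulate_guide_tree(2, 3, seed = 2)
  sim <- simulate_pav(tr, cfg)
  pres <- sim$pav$presence

  core <- pres[grepl("^core", rownames(pres)), , drop = FALSE]
  expect_true(all(core == 1L))
  shell <- pres[grepl("^shell", rownames(pres)), , drop = FALSE]
  expect_true(all(apply(shell, 1, function(r) length(unique(r))) == 1))
  cloud <- pres[grepl("^cloud", rownames(pres)), , drop = FALSE]
  expect_true(all(rowSums(cloud) <= max(1, floor(0.03 * 6))))

  expect_setequal(names(sim$truth$true_categories), rownames(pres))
  expect_true(all(sim$truth$true_categories %in% c("core", "shell", "cloud")))
  expect_identical(table(sim$truth$true_categories)[["core"]], 50L)

  sim2 <- simulate_pav(tr, cfg)
  expect_identical(sim2$pav$presence, pres)
})

test_that("planted selection genes realize their target group frequencies", {
  sel <- data.frame(gene_id = sprintf("sel_%02d", 1:10),
                    wild_freq = 0.2, dom_freq = 0.9)
  labels <- panpav:::sim_accession_labels(3, 20)
  cfg <- sim_config(seed = 11, n_clades = 3, accessions_per_clade = 20,
                    n_core_genes = 10, n_shell_genes = 10, n_cloud_genes = 0,
                    selection_genes = sel,
                    group_map = balanced_group_map(labels))
  tr <- simulate_guide_tree(3, 20, seed = 11)
  sim <- simulate_pav(tr, cfg)
  groups <- setNames(sim$pav$profiles$group, sim$pav$profiles$accession_id)
  wild <- names(groups)[groups == "wild"]
  dom <- names(groups)[groups == "cultivar"]
  expect_length(wild, 30)
  expect_length(dom, 30)

  # realized counts inside central 99% binomial bands at the stated n
  w_lo <- qbinom(0.005, 30, 0.2); w_hi <- qbinom(0.995, 30, 0.2)
  d_lo <- qbinom(0.005, 30, 0.9); d_hi <- qbinom(0.995, 30, 0.9)
  for (g in sel$gene_id) {
    nw <- sum(sim$pav$presence[g, wild])
    nd <- sum(sim$pav$presence[g, dom])
    expect_gte(nw, w_lo); expect_lte(nw, w_hi)
    expect_gte(nd, d_lo); expect_lte(nd, d_hi)
  }
  expect_setequal(sim$truth$true_favorable, sel$gene_id)

  bad <- sel; bad$dom_freq[1] <- 1.4
  expect_error(sim_config(selection_genes = bad), "\\[0, 1\\]")
})

test_that("ploidy bonus inflates polyploid gene content additively", {
  labels <- panpav:::sim_accession_labels(2, 10)
  ploidy <- setNames(rep(c(2L, 4L), 10), labels)
  cfg <- sim_config(seed = 5, n_clades = 2, accessions_per_clade = 10,
                    n_core_genes = 100, n_shell_genes = 400,
                    n_cloud_genes = 0, ploidy_map = ploidy,
                    ploidy_gene_bonus = 40)
  tr <- simulate_guide_tree(2, 10, seed = 5)
  sim <- simulate_pav(tr, cfg)
  counts <- accession_gene_counts(sim$pav)
  gain <- mean(counts[names(ploidy)[ploidy == 4]]) -
    mean(counts[names(ploidy)[ploidy == 2]])
  # expectation 40 * (4 - 2) = 80 extra genes, allow generous sampling slack
  expect_gt(gain, 40)
  expect_lt(gain, 120)
})

test_that("coverage simulation is exact in the noise-free limit", {
  st <- small_study()
  called <- build_pav_matrix(st$gene_models, st$pav$profiles, st$coverage)
  expect_identical(called$presence, st$truth$true_pav$presence)

  # absent gene with noise_fp = 0 has zero exonic depth
  pres <- st$pav$presence
  hit <- which(pres == 0L, arr.ind = TRUE)[1, ]
  g <- rownames(pres)[hit[1]]
  acc <- colnames(pres)[hit[2]]
  gm <- st$gene_models[st$gene_models$gene_id == g, ]
  expect_identical(covered_exon_fraction(gm, st$coverage[[acc]], 1), 0)
})

test_that("present genes clear the coverage rule at the default noise", {
  cfg <- sim_config(seed = 13, n_clades = 2, accessions_per_clade = 5,
                    n_core_genes = 300, n_shell_genes = 0, n_cloud_genes = 0)
  st <- simulate_study(cfg)
  called <- build_pav_matrix(st$gene_models, st$pav$profiles, st$coverage)
  # all 3000 cells truly present; failures only through the 0.5% dropout
  miss_rate <- mean(called$presence == 0L)
  expect_lte(miss_rate, 0.015)
})

test_that("coverage simulation is reproducible and track-complete", {
  st <- small_study()
  cov2 <- simulate_coverage(st$pav, st$gene_models, st$config)
  expect_identical(cov2, st$coverage)
  expect_setequal(names(st$coverage), accession_ids(st$pav))
})

test_that("contig fixture carries consistent truth labels", {
  cfg <- sim_config(seed = 3)
  cs <- simulate_contigs_and_hits(cfg)
  expect_setequal(names(cs$truth$labels), names(cs$contigs))
  expect_true(all(cs$truth$labels %in%
                    c("reference-derived", "novel", "redundant",
                      "contaminant")))
  expect_true(all(cs$hits$query_id %in% names(cs$contigs)))
  expect_true(all(cs$truth$inserts$length >= 500))
  cs2 <- simulate_contigs_and_hits(cfg)
  expect_identical(cs2$contigs, cs$contigs)
})

test_that("term map is deterministic, uniform by default, enrichable", {
  genes <- sprintf("g%03d", 1:400)
  tm1 <- simulate_term_map(genes, n_terms = 10, seed = 4)
  tm2 <- simulate_term_map(genes, n_terms = 10, seed = 4)
  expect_identical(tm1, tm2)

  counts <- table(factor(tm1$term, levels = sprintf("term_%03d", 1:10)))
  gof <- chisq.test(as.numeric(counts))
  expect_gt(gof$p.value, 0.001)

  enriched <- list(list(term = "term_002", genes = genes[1:40],
                        factor = 10))
  tm3 <- simulate_term_map(genes, n_terms = 10,
                           enriched_pairs = enriched, seed = 4)
  en <- term_enrichment(genes[1:40], genes, tm3)
  expect_lt(en$fdr[en$term == "term_002"], 0.05)

  expect_error(simulate_term_map(genes, n_terms = 10, seed = 1,
                                 enriched_pairs = list(list(
                                   term = "t", genes = "nope",
                                   factor = 2))),
               "unknown gene")
})
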