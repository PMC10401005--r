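make_hits <- function(...) {
  do.call(rbind, lapply(list(...), function(r) {
    data.frame(query_id = r$q, query_length = r$ql, query_start = r$s,
               query_end = r$e, target_id = "ref", identity = r$id,
               alignment_length = r$al, stringsAsFactors = FALSE)
  }))
}

test_that("hit filter applies inclusive length and identity thresholds", {
  hits <- make_hits(
    list(q = "a", ql = 10000, s = 0, e = 250, id = 95, al = 250),
    list(q = "b", ql = 10000, s = 0, e = 300, id = 90.0, al = 300),
    list(q = "c", ql = 20000, s = 0, e = 10000, id = 89.9, al = 10000)
  )
  kept <- filter_hits(hits)
  expect_identical(kept$query_id, "b")

  # monotonicity: raising either threshold never enlarges the kept set
  set.seed(1)
  rnd <- data.frame(query_id = "q", query_length = 5000L,
                    query_start = 0L, query_end = 100L, target_id = "r",
                    identity = runif(200, 80, 100),
                    alignment_length = sample(100:1000, 200, TRUE))
  for (ml in c(200, 300, 500)) {
    for (mi in c(85, 90, 95)) {
      a <- filter_hits(rnd, ml, mi)
      b <- filter_hits(rnd, ml + 100, mi)
      c_ <- filter_hits(rnd, ml, mi + 2)
      expect_true(all(rownames(b) %in% rownames(a)))
      expect_true(all(rownames(c_) %in% rownames(a)))
    }
  }

  bad <- make_hits(list(q = "x", ql = 100, s = 50, e = 40, id = 99, al = 10))
  expect_error(filter_hits(bad), "row")
})

test_that("covered_intervals merges overlap and adjacency", {
  h <- make_hits(list(q = "q", ql = 1000, s = 0, e = 700, id = 99, al = 700),
                 list(q = "q", ql = 1000, s = 600, e = 900, id = 99, al = 300))
  expect_identical(covered_intervals(h),
                   data.frame(start = 0L, end = 900L))
  h2 <- make_hits(list(q = "q", ql = 300, s = 0, e = 100, id = 99, al = 100),
                  list(q = "q", ql = 300, s = 100, e = 200, id = 99, al = 100))
  expect_identical(covered_intervals(h2),
                   data.frame(start = 0L, end = 200L))
  expect_identical(nrow(covered_intervals(h[0, ])), 0L)
})

test_that("unaligned-region extraction keeps complements >= 500 bp", {
  set.seed(2)
  contig <- setNames(rand_seq(2000), "ctg")
  covered <- data.frame(start = c(0L, 1300L), end = c(700L, 2000L))
  seg <- extract_unaligned(contig, covered)
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$start, 700L)
  expect_identical(seg$end, 1300L)
  expect_identical(seg$sequence, unname(substr(contig, 701, 1300)))

  short <- setNames(rand_seq(400), "short")
  expect_identical(nrow(extract_unaligned(short,
                                          data.frame(start = integer(0),
                                                     end = integer(0)))),
                   0L)
  all_cov <- data.frame(start = 0L, end = 2000L)
  expect_identical(nrow(extract_unaligned(contig, all_cov)), 0L)
  expect_error(extract_unaligned(contig, data.frame(start = 0, end = 3000)),
               "bounds")
})

test_that("unaligned-region extraction equals the per-base brute force", {
  set.seed(3)
  for (i in 1:200) {
    len <- sample(400:8000, 1)
    hs <- random_hit_set(len, sample(0:6, 1))
    hits <- data.frame(query_id = rep("q", nrow(hs)),
                       query_start = hs$start, query_end = hs$end)
    covered <- covered_intervals(hits)
    got <- extract_unaligned(NULL, covered, contig_id = "q",
                             contig_length = len)
    want <- brute_unaligned(len, covered, 500)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("contamination rule follows green-plant covered fraction", {
  th <- data.frame(
    query_id = c("m", "m", "o", "g"),
    query_start = c(0L, 920L, 0L, 0L),
    query_end = c(920L, 1000L, 500L, 500L),
    taxon_class = c("green_plant", "other", "other", "green_plant")
  )
  expect_identical(classify_contamination("m", th), "keep")    # 0.92
  expect_identical(classify_contamination("o", th), "remove")  # only other
  expect_identical(classify_contamination("g", th), "keep")    # only green
  expect_identical(classify_contamination("none", th), "keep") # no hits

  th_bad <- data.frame(query_id = "m", query_start = 0L,
                       query_end = c(890L, 1000L),
                       taxon_class = c("green_plant", "other"))
  expect_identical(classify_contamination("m", th_bad), "remove")  # 0.89
})

test_that("pairwise identity/coverage behaves on planted cases", {
  set.seed(4)
  x <- rand_seq(100)
  expect_equal(unname(pairwise_identity(x, x)), c(100, 100))

  y <- x
  substr(y, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                               substr(x, 50, 50))[1]
  expect_equal(unname(pairwise_identity(x, y))[1], 99)

  long <- rand_seq(3000)
  short <- substr(long, 1001, 1800)
  expect_equal(unname(pairwise_identity(short, long)), c(100, 100))

  # unrelated random sequences stay far below the 95% threshold
  for (i in 1:25) {
    ic <- pairwise_identity(rand_seq(1000), rand_seq(1000))
    expect_lt(ic[["identity"]], 95)
  }
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
})

test_that("redundancy removal clusters duplicates, is idempotent and total", {
  set.seed(5)
  a <- rand_seq(1200)
  segs <- c(s1 = a, s2 = a,                        # byte-identical pair
            s3 = substr(a, 101, 700),              # contained in a
            s4 = rand_seq(900), s5 = rand_seq(800))
  red <- remove_redundancy(segs)
  expect_setequal(names(red$representatives), c("s1", "s4", "s5"))
  cm <- red$cluster_map
  expect_setequal(cm$segment_id, names(segs))            # totality
  expect_identical(cm$representative[cm$segment_id == "s2"], "s1")
  expect_identical(cm$representative[cm$segment_id == "s3"], "s1")

  # idempotence: clustering the representatives changes nothing
  red2 <- remove_redundancy(red$representatives)
  expect_identical(red2$representatives, red$representatives)
  expect_identical(red2$cluster_map$segment_id,
                   red2$cluster_map$representative)

  # three mutually distinct random segments stay separate
  three <- c(t1 = rand_seq(1000), t2 = rand_seq(1000), t3 = rand_seq(1000))
  expect_length(remove_redundancy(three)$representatives, 3)
})

test_that("pangenome assembly concatenates and manifests every record", {
  set.seed(6)
  refs <- c(chr1 = rand_seq(5000), chr2 = rand_seq(4000))
  segs <- data.frame(source_contig = c("ctgA", "ctgB", "ctgC"),
                     start = c(0L, 100L, 0L), end = c(600L, 800L, 500L),
                     sequence = c(rand_seq(600), rand_seq(700),
                                  rand_seq(500)))
  pg <- build_pangenome(refs, segs)
  expect_length(pg$pangenome, 5)
  expect_identical(nrow(pg$manifest), 5L)
  expect_identical(pg$manifest$origin, c("reference", "reference",
                                         "nonref", "nonref", "nonref"))
  expect_identical(unname(nchar(pg$pangenome)),
                   unname(c(nchar(refs), nchar(segs$sequence))))

  empty <- build_pangenome(refs, segs[0, ])
  expect_identical(empty$pangenome, refs)

  dup <- refs
  names(dup) <- c("chr1", "chr1")
  expect_error(build_pangenome(dup, segs), "unique")
})

test_that("extraction pipeline recovers the planted contig structure", {
  cfg <- sim_config(seed = 3)
  cs <- simulate_contigs_and_hits(cfg)
  res <- extract_nonref(cs$contigs, cs$hits, cs$taxon_hits)

  contaminants <- names(cs$truth$labels)[cs$truth$labels == "contaminant"]
  expect_setequal(names(res$contamination)[res$contamination == "remove"],
                  contaminants)

  # every planted insert is recovered at its planted coordinates
  for (i in seq_len(nrow(cs$truth$inserts))) {
    ins <- cs$truth$inserts[i, ]
    hit <- res$segments[res$segments$source_contig == ins$contig, ]
    expect_identical(nrow(hit), 1L)
    expect_equal(hit$start, ins$start)
    expect_equal(hit$end, ins$end)
  }

  # planted duplicate contigs collapse onto their originals
  dups <- names(cs$truth$labels)[cs$truth$labels == "redundant"]
  reps_src <- sub(":.*$", "", names(res$representatives))
  expect_length(intersect(reps_src, dups), 0)
  originals <- sub("_dup$", "", dups)
  expect_true(all(originals %in% reps_src))

  # end to end: added sequence equals the planted novel inserts
  cs2 <- simulate_contigs_and_hits(cfg, n_aligned = 2, n_insert = 3,
                                   n_redundant_pairs = 0,
                                   n_contaminant = 0)
  res2 <- extract_nonref(cs2$contigs, cs2$hits, cs2$taxon_hits)
  pg <- build_pangenome(cs2$reference, res2$segments)
  added <- sum(nchar(pg$pangenome)) - sum(nchar(cs2$reference))
  expect_equal(added, sum(cs2$truth$inserts$length))
})
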