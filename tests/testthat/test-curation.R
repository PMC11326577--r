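test_that("length filter is strict below 200 and keeps order", {
  recs <- list(flat_record("a", 199L), flat_record("b", 200L),
               flat_record("c", 201L))
  kept <- filter_by_length(recs)
  expect_equal(vapply(kept, `[[`, character(1), "id"), c("b", "c"))
  expect_identical(filter_by_length(list()), list())
})

test_that("homology hit rule: bit score strict, aligned columns inclusive", {
  cfg <- curation_config()
  expect_true(call_homology_hit(homology_hit("q", "e", 20.1, 30L), cfg))
  expect_false(call_homology_hit(homology_hit("q", "e", 20.0, 100L), cfg))
  expect_false(call_homology_hit(homology_hit("q", "e", 500, 29L), cfg))
})

test_that("structure hit rule: strict 0.5, beta-helix exception strict 0.2", {
  cfg <- curation_config()
  expect_true(call_structure_hit(structure_hit("q", "TIM_BARREL", 0.51), cfg))
  expect_false(call_structure_hit(structure_hit("q", "TOROID", 0.50), cfg))
  expect_true(call_structure_hit(structure_hit("q", "BETA_HELIX", 0.21), cfg))
  expect_false(call_structure_hit(structure_hit("q", "BETA_HELIX", 0.20), cfg))
  expect_false(call_structure_hit(structure_hit("q", "BETA_PROPELLER", 0.30),
                                  cfg))
})

test_that("hit calling is monotone in its scores", {
  cfg <- curation_config()
  set.seed(42)
  for (i in 1:200) {
    bs <- runif(1, 0, 50); ac <- sample(0:60, 1)
    base <- call_homology_hit(homology_hit("q", "e", bs, ac), cfg)
    up <- call_homology_hit(homology_hit("q", "e", bs + runif(1, 0, 10),
                                         ac + sample(0:10, 1)), cfg)
    if (base) expect_true(up)
    fold <- sample(setdiff(curation_folds(), "NONE"), 1)
    p <- runif(1)
    sbase <- call_structure_hit(structure_hit("q", fold, p), cfg)
    sup <- call_structure_hit(structure_hit("q", fold,
                                            min(1, p + runif(1, 0, 0.3))),
                              cfg)
    if (sbase) expect_true(sup)
  }
})

test_that("cluster representative is the longest member, ties by id", {
  a <- flat_record("A", 300L); b <- flat_record("B", 250L)
  expect_equal(select_representative(list(a, b))$id, "A")
  b300 <- flat_record("B", 300L)
  expect_equal(select_representative(list(b300, a))$id, "A")
  expect_equal(select_representative(list(b))$id, "B")
  expect_error(select_representative(list()), "empty")
})

test_that("annotation cap keeps at most five longest per cluster and annotation", {
  recs <- lapply(1:7, function(i)
    flat_record(sprintf("t%d", i), 200L + i, "tail spike"))
  cl <- list(protein_cluster("c1", vapply(recs, `[[`, character(1), "id"),
                             "t7"))
  kept <- cap_by_annotation(cl, recs, "tail spike")
  expect_length(kept, 5L)
  expect_setequal(vapply(kept, `[[`, character(1), "id"),
                  c("t3", "t4", "t5", "t6", "t7"))  # the 5 longest

  expect_length(cap_by_annotation(cl, recs[1:3], "tail spike"), 3L)
  expect_length(cap_by_annotation(cl, recs, "terminase"), 0L)
  expect_error(cap_by_annotation(list(), recs, "tail spike"),
               "no cluster assignment")
})

test_that("annotation cap matches a brute-force enumerator on random inputs", {
  set.seed(9)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    anns <- c("tail spike", "tail fiber", "other")
    recs <- lapply(seq_len(n), function(i)
      flat_record(sprintf("r%02d", i), 200L + sample(0:50, 1),
                  sample(anns, 1)))
    ids <- vapply(recs, `[[`, character(1), "id")
    clmap <- sample(c("c1", "c2"), n, replace = TRUE)
    clusters <- lapply(unique(clmap), function(c)
      protein_cluster(c, ids[clmap == c], ids[clmap == c][1]))
    allowed <- c("tail spike", "tail fiber")
    kept <- cap_by_annotation(clusters, recs, allowed)
    # brute force: per (cluster, annotation) expected count min(count, 5)
    expected <- 0L
    for (c in unique(clmap)) for (a in allowed) {
      cnt <- sum(clmap == c &
                   vapply(recs, `[[`, character(1), "annotation") == a)
      expected <- expected + min(cnt, 5L)
    }
    expect_length(kept, expected)
  }
})

test_that(".clstr parsing: blocks, sizes, representative flag, id truncation", {
  f <- tempfile(fileext = ".clstr")
  writeLines(c(">Cluster 0",
               "0\t300aa, >seqA... *",
               "1\t250aa, >seqB... at 95.5%",
               "2\t240aa, >seqC.v2... at 97.1%",
               ">Cluster 1",
               "0\t500aa, >lone_sequence... *"), f)
  cl <- parse_cdhit_clstr(f)
  expect_length(cl, 2L)
  expect_equal(lengths(lapply(cl, `[[`, "member_ids")), c(3L, 1L))
  expect_equal(cl[[1]]$member_ids, c("seqA", "seqB", "seqC.v2"))
  expect_equal(cl[[1]]$representative_id, "seqA")
  expect_equal(cl[[2]]$representative_id, "lone_sequence")

  writeLines(c(">Cluster 0", "0\t300aa, seqA *"), f)
  expect_error(parse_cdhit_clstr(f), "malformed")
  writeLines(c(">Cluster 0", "0\t300aa, >seqA... at 95%"), f)
  expect_error(parse_cdhit_clstr(f), "representative")
  file.create(f2 <- tempfile())
  expect_identical(parse_cdhit_clstr(f2), list())
})

test_that("structure-hit table parsing maps folds and validates probabilities", {
  f <- tempfile()
  writeLines(c("q1\tbh_db\t0.92\t10\t200",
               "q2\tprop_db\t0.41\t5\t150",
               "q3\tbh_db\t0.22\t1\t90"), f)
  fold_map <- c(bh_db = "BETA_HELIX", prop_db = "BETA_PROPELLER")
  hits <- parse_structure_hits(f, fold_map)
  expect_equal(vapply(hits, `[[`, numeric(1), "probability"),
               c(0.92, 0.41, 0.22))
  expect_equal(hits[[1]]$target_fold, "BETA_HELIX")

  writeLines("q1\tbh_db\t1.2\t10\t200", f)
  expect_error(parse_structure_hits(f, fold_map), "\\[0, 1\\]")
  writeLines("q1\tunknown_db\t0.5\t10\t200", f)
  expect_error(parse_structure_hits(f, fold_map), "fold-map")
  file.create(f2 <- tempfile())
  expect_identical(parse_structure_hits(f2, fold_map), list())
})

test_that("group shuffle split: 10 singletons give a 7/2/1 partition", {
  ids <- sprintf("s%02d", 1:10)
  cm <- setNames(ids, ids)
  sp <- group_shuffle_split(ids, cm, seed = 3L)
  expect_equal(lengths(sp), c(token_train = 7L, binary_train = 2L,
                              eval = 1L))
  expect_setequal(unlist(sp), ids)
  expect_identical(sp, group_shuffle_split(ids, cm, seed = 3L))
})

test_that("group shuffle split keeps one giant cluster atomic, with warning", {
  ids <- sprintf("s%03d", 1:100)
  cm <- setNames(rep("c1", 100), ids)
  expect_warning(sp <- group_shuffle_split(ids, cm, seed = 1L), "single")
  expect_equal(unname(sort(lengths(sp), decreasing = TRUE))[1], 100L)
})

test_that("group shuffle split is a cluster-atomic partition for random maps", {
  set.seed(12)
  for (rep in 1:40) {
    n <- sample(10:60, 1)
    ids <- sprintf("r%03d", seq_len(n))
    cm <- setNames(sample(sprintf("c%d", 1:sample(2:12, 1)), n,
                          replace = TRUE), ids)
    sp <- group_shuffle_split(ids, cm, seed = rep)
    all_out <- unlist(sp, use.names = FALSE)
    expect_setequal(all_out, ids)          # covers
    expect_equal(length(all_out), n)       # disjoint
    for (cl in unique(cm)) {               # cluster-atomic
      members <- ids[cm == cl]
      in_split <- vapply(sp, function(s) any(members %in% s), logical(1))
      expect_equal(sum(in_split), 1L)
    }
  }
})

test_that("the curation funnel reproduces the hand-traced fixture counts", {
  fx <- curation_fixture()
  records <- read_fasta(fx$fasta)
  out <- curate_records(records,
                        parse_homology_hits(fx$homology),
                        parse_structure_hits(fx$structure, fx$fold_map),
                        parse_cdhit_clstr(fx$clstr),
                        with(utils::read.delim(fx$ap_clusters, header = FALSE,
                                               colClasses = "character"),
                             setNames(V2, V1)),
                        c("tail spike", "tail fiber"))
  got <- setNames(out$funnel$n, out$funnel$stage)
  expect_equal(got, fx$expected_funnel)
  expect_setequal(vapply(out$curated, `[[`, character(1), "id"),
                  fx$expected_curated)
  expect_equal(unname(out$folds[c("r06", "r09", "r15")]),
               c("BETA_HELIX", "BETA_PROPELLER", "TIM_BARREL"))
})
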