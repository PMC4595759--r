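test_that("read trimming follows the quality and poly-A rules", {
  q <- function(n) strrep("F", n)             # Q37
  # high-quality read with no 3' A-run: unchanged
  tr <- trim_reads("ACGTCGTG", quals = q(8))
  expect_equal(tr$seq, "ACGTCGTG")
  # terminal A-run of 4 removed (more than three consecutive A's)
  tr <- trim_reads("ACGTCGAAAA", quals = q(10))
  expect_equal(tr$seq, "ACGTCG")
  # a run of exactly three A's is kept
  tr <- trim_reads("ACGTCGAAA", quals = q(9))
  expect_equal(tr$seq, "ACGTCGAAA")
  # low-quality terminal bases (Q15 = '0') trimmed from both ends
  tr <- trim_reads("TACGTACGA", quals = paste0("0", q(7), "0"))
  expect_equal(tr$seq, "ACGTACG")
  # reads shorter than min_len after trimming are dropped
  tr <- trim_reads(c("ACGTACGTAA", "ACG"), quals = c(q(10), q(3)),
                   min_len = 5)
  expect_equal(tr$seq, "ACGTACGTAA")
  expect_equal(tr$kept, 1L)
})

test_that("graph construction counts every window once per read", {
  set.seed(21)
  read <- paste(sample(c("A", "C", "G", "T"), 130, TRUE), collapse = "")
  g <- build_graph(read, k = 120, include_rc = FALSE)
  st <- graph_stats(g)
  expect_equal(st$n_edges, 130 - 120 + 1)   # 11 k-mers
  expect_equal(st$n_nodes, 130 - 117 + 1)   # 14 (k-3)-mers
  expect_equal(st$sum_edge_depth, 11)
  expect_equal(st$sum_node_depth, 14)
  # presenting the read twice doubles all depths
  g2 <- build_graph(c(read, read), k = 120, include_rc = FALSE)
  t1 <- graph_tables(g)
  t2 <- graph_tables(g2)
  m <- match(t1$edges$kmer, t2$edges$kmer)
  expect_equal(t2$edges$depth[m], 2L * t1$edges$depth)
})

test_that("edge-depth conservation holds with reverse complements", {
  set.seed(22)
  reads <- random_dna(20, 80)
  k <- 30
  g <- build_graph(reads, k)
  st <- graph_stats(g)
  expect_equal(st$sum_edge_depth, 2 * sum(nchar(reads) - k + 1))
  expect_equal(st$sum_node_depth, 2 * sum(nchar(reads) - (k - 3) + 1))
})

test_that("binned construction merges to the single-pass graph exactly", {
  set.seed(23)
  reads <- random_dna(40, 70)
  g1 <- build_graph(reads, 30)
  g4 <- build_graph(reads, 30, bins = 4)
  t1 <- graph_tables(g1)
  t4 <- graph_tables(g4)
  for (part in c("nodes", "edges")) {
    a <- t1[[part]][order(t1[[part]]$kmer), ]
    b <- t4[[part]][order(t4[[part]]$kmer), ]
    expect_equal(a$kmer, b$kmer)
    expect_equal(a$depth, b$depth)
  }
  # the construction-time min_count filter equals build-then-prune
  gf <- build_graph(reads, 30, min_count = 2)
  tf <- graph_tables(gf)
  full <- graph_tables(g1)
  expect_setequal(tf$nodes$kmer[tf$nodes$depth >= 2],
                  full$nodes$kmer[full$nodes$depth >= 2])
})

test_that("pruning applies the singleton and 1/50 relative-depth rules", {
  # node AAA with outgoing edges of depth {100, 3}: 3 >= 100/50 -> kept
  reads <- c(rep("AAACCC", 100), rep("AAAGGG", 3))
  g <- build_graph(reads, 6, include_rc = FALSE)
  p <- graph_tables(prune_graph(g, assembly_params(k = 6, min_seed_anchor = 1)))
  expect_true("AAAGGG" %in% p$edges$kmer)
  # depths {200, 3}: 3 < 200/50 -> pruned
  reads <- c(rep("AAACCC", 200), rep("AAAGGG", 3))
  g <- build_graph(reads, 6, include_rc = FALSE)
  p <- graph_tables(prune_graph(g, assembly_params(k = 6, min_seed_anchor = 1)))
  expect_false("AAAGGG" %in% p$edges$kmer)
  expect_true("AAACCC" %in% p$edges$kmer)
  # singletons eliminated, and their dangling nodes with them
  g <- build_graph("ACGTGCAT", 6, include_rc = FALSE)
  p <- prune_graph(g, assembly_params(k = 6, min_seed_anchor = 1))
  st <- graph_stats(p)
  expect_equal(st$n_nodes + st$n_edges, 0)
  # an error-free evenly covered template survives pruning unchanged:
  # all depths >= 2 and one outgoing edge per node
  d <- mini_design(n_aa = 40)
  seq1 <- paste0(d$fwd, realize_template(d$template, seed = 24), d$rev)
  g <- build_graph(tiling_reads(seq1, 2, 60), 30)
  st_raw <- graph_stats(g)
  st_pr <- graph_stats(prune_graph(g, mini_params()))
  expect_equal(st_pr$n_edges, st_raw$n_edges)
  expect_equal(st_pr$n_nodes, st_raw$n_nodes)
})

test_that("seed detection anchors on the flanks and applies the depth cut-off", {
  pool <- mini_pool(n_variants = 1, depth = 30, seq_error = 0)
  g <- prune_graph(build_graph(pool$reads, 30), pool$params)
  seeds <- detect_seeds(g, pool$design$fwd, pool$design$rev, pool$params)
  expect_gte(nrow(seeds$initial), 1)
  expect_gte(nrow(seeds$terminal), 1)
  # every initial seed's prefix really is a flank suffix
  for (i in seq_len(nrow(seeds$initial))) {
    b <- seeds$initial$overlap[i]
    expect_gte(b, pool$params$min_seed_anchor)
    expect_equal(substr(seeds$initial$node[i], 1, b),
                 substring(pool$design$fwd, nchar(pool$design$fwd) - b + 1))
  }
  for (i in seq_len(nrow(seeds$terminal))) {
    b <- seeds$terminal$overlap[i]
    nd <- seeds$terminal$node[i]
    expect_equal(substring(nd, nchar(nd) - b + 1),
                 substr(pool$design$rev, 1, b))
  }
})

test_that("rare seeds are discarded or rescued by the depth ratio", {
  # two molecules at 2000:8, sharing flanks; k = 30
  d <- mini_design(n_aa = 40)
  vs <- realize_template(d$template, 2, seed = 31)
  seqs <- paste0(d$fwd, vs, d$rev)
  reads <- c(tiling_reads(seqs[1], 1, 60), tiling_reads(seqs[2], 1, 60))
  mult <- c(rep(2000L, nchar(seqs[1]) - 59), rep(8L, nchar(seqs[2]) - 59))
  g <- build_graph(rep(reads, mult), 30)
  strict <- mini_params(seed_prune_ratio = 1 / 200)
  gp <- prune_graph(g, strict)
  s_strict <- detect_seeds(gp, d$fwd, d$rev, strict)
  # depth 8 < 2000/200 = 10 -> rare variant's seeds all discarded
  expect_lt(max(s_strict$initial$depth) / min(s_strict$initial$depth), 200)
  relaxed <- mini_params(seed_prune_ratio = 1 / 300)
  s_rel <- detect_seeds(gp, d$fwd, d$rev, relaxed)
  expect_gt(nrow(s_rel$initial), nrow(s_strict$initial))
  # rescued seeds let the rare molecule assemble
  cand <- traverse_graph(gp, s_rel, relaxed, nchar(vs[1]))
  expect_setequal(cand$insert, vs)
  cand_strict <- traverse_graph(gp, s_strict, strict, nchar(vs[1]))
  expect_equal(cand_strict$insert, vs[1])
})

test_that("detect_seeds aborts with a diagnostic when no seed survives", {
  g <- build_graph(random_dna(5, 60), 30)
  expect_error(detect_seeds(g, strrep("A", 60), strrep("C", 60),
                            mini_params()),
               "no .* seeds")
})

test_that("traversal reconstructs single and barcode-distinct templates", {
  # linear graph from one template: exactly one candidate, equal to it
  pool <- mini_pool(n_variants = 1, depth = 30)
  g <- prune_graph(build_graph(pool$reads, 30), pool$params)
  seeds <- detect_seeds(g, pool$design$fwd, pool$design$rev, pool$params)
  cand <- traverse_graph(g, seeds, pool$params)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$insert, pool$truth$variants$insert)
  # two dense-barcode templates: exactly two candidates, no chimeras
  pool2 <- mini_pool(n_variants = 2, depth = 30, seed = 33)
  g2 <- prune_graph(build_graph(pool2$reads, 30), pool2$params)
  seeds2 <- detect_seeds(g2, pool2$design$fwd, pool2$design$rev, pool2$params)
  cand2 <- traverse_graph(g2, seeds2, pool2$params)
  expect_setequal(cand2$insert, pool2$truth$variants$insert)
  # inserts of one design share the codon frame
  expect_length(unique(nchar(cand2$insert) %% 3), 1)
})

test_that("templates sharing an internal stretch yield chimeric candidates", {
  # two molecules share a 45 nt interior stretch >= k - 3 = 27
  set.seed(34)
  shared <- paste(sample(c("A", "C", "G", "T"), 45, TRUE), collapse = "")
  u1 <- random_dna(2, 60)
  u2 <- random_dna(2, 60)
  fl <- random_flanks(60, seed = 35)
  ins <- c(paste0(u1[1], shared, u1[2]), paste0(u2[1], shared, u2[2]))
  seqs <- paste0(fl$fwd, ins, fl$rev)
  reads <- rep(tiling_reads(seqs, 1, 60), 3L)
  params <- mini_params()
  g <- prune_graph(build_graph(reads, 30), params)
  seeds <- detect_seeds(g, fl$fwd, fl$rev, params)
  cand <- traverse_graph(g, seeds, params, nchar(ins[1]))
  chim <- c(paste0(u1[1], shared, u2[2]), paste0(u2[1], shared, u1[2]))
  expect_setequal(cand$insert, c(ins, chim))  # 2 true + 2 chimeric
})

test_that("traversal equals exhaustive path enumeration on small graphs", {
  for (s in c(36, 37, 38)) {
    pool <- mini_pool(n_variants = 3, depth = 20, n_aa = 40, seed = s)
    params <- pool$params
    g <- prune_graph(build_graph(pool$reads, 30), params)
    seeds <- detect_seeds(g, pool$design$fwd, pool$design$rev, params)
    tabs <- graph_tables(g)
    cand <- traverse_graph(g, seeds, params, roots_only = FALSE)
    oracle <- oracle_enumerate_paths(tabs, seeds$initial$node,
                                     seeds$terminal$node, 30)
    # compare deduplicated insert sets with per-insert copy numbers
    otrim <- substr(oracle$paths,
                    seeds$initial$overlap[match(substr(oracle$paths, 1, 27),
                                                seeds$initial$node)] + 1,
                    nchar(oracle$paths) -
                      seeds$terminal$overlap[match(substring(oracle$paths,
                                                             nchar(oracle$paths) - 26),
                                                   seeds$terminal$node)])
    ocopy <- tapply(oracle$copy, otrim, max)
    expect_setequal(cand$insert, names(ocopy))
    expect_equal(cand$copy_number, as.vector(ocopy[cand$insert]),
                 ignore_attr = TRUE)
  }
})

test_that("CV filter passes flat profiles and rejects depth steps", {
  # constant profile -> cv 0 -> passed
  d <- mini_design(n_aa = 50, seed = 39)
  v <- realize_template(d$template, 1, seed = 40)
  seqs <- paste0(d$fwd, v, d$rev)
  reads <- tiling_reads(seqs, 2, 60)
  cand <- structure(data.frame(insert = v, copy_number = 2L,
                               n_paths = 1L, cv = NA_real_,
                               status = "candidate",
                               stringsAsFactors = FALSE),
                    class = c("contig_set", "data.frame"))
  out <- cv_filter(cand, read_set_from(reads), d$fwd, d$rev, mini_params())
  expect_lt(out$cv, 0.02)
  expect_equal(out$status, "passed")
  # candidate with no aligned reads: flagged, failed
  fake <- cand
  fake$insert <- paste(rep("CCG", 50), collapse = "")
  out2 <- cv_filter(fake, read_set_from(reads), d$fwd, d$rev, mini_params())
  expect_true(is.na(out2$cv))
  expect_equal(out2$status, "failed_cv")
})

test_that("chimeras joining unequal-abundance templates fail the CV cut-off", {
  # k = 120 (the calibrated regime); shared interior stretch of 150 nt
  set.seed(41)
  shared <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  fl <- random_flanks(150, seed = 42)
  ins <- paste0(random_dna(2, 150), shared, random_dna(2, 150))[1:2]
  truth <- structure(list(
    variants = data.frame(id = c("a", "b"), insert = ins,
                          sequence = paste0(fl$fwd, ins, fl$rev),
                          copies = c(60L, 12L), n_mutations = 0L,
                          mutations = "", stringsAsFactors = FALSE),
    template = NULL, fwd_flank = fl$fwd, rev_flank = fl$rev,
    mutation_rate = 0, n_collapsed = 0L), class = "truth_set")
  reads <- simulate_reads(truth, read_sim_config(seq_error_rate = 0),
                          coverage_for_depth(sum(c(60, 12) * 0.5)),
                          seed = 43)
  params <- assembly_params()
  trm <- trim_reads(reads, min_len = 117)
  g <- prune_graph(build_graph(trm, 120), params)
  seeds <- detect_seeds(g, fl$fwd, fl$rev, params)
  cand <- traverse_graph(g, seeds, params, nchar(ins[1]))
  expect_equal(nrow(cand), 4)  # 2 true + 2 chimeric
  out <- cv_filter(cand, trm, fl$fwd, fl$rev, params)
  is_true <- out$insert %in% ins
  expect_true(all(out$status[is_true] == "passed"))
  expect_true(all(out$status[!is_true] == "failed_cv"))
  # two-level profile: cv approx |d1 - d2| / (d1 + d2) for equal arm lengths
  expect_gt(min(out$cv[!is_true]), 0.2163)
})

test_that("Needleman-Wunsch variant calls match the affine scoring scheme", {
  v <- call_variants("ACGT", "ACGT")
  expect_equal(nrow(v), 0)
  expect_equal(attr(v, "score"), 8)
  v <- call_variants("ACTT", "ACGT")
  expect_equal(attr(v, "score"), 5)
  expect_equal(v$pos, 2)
  expect_equal(v$ref, "G")
  expect_equal(v$alt, "T")
  expect_equal(v$type, "substitution")
  v <- call_variants("ACGGT", "ACGT")
  expect_equal(attr(v, "score"), 5)
  expect_equal(v$type, "insertion")
  v <- call_variants("ACGT", "ACGGT")
  expect_equal(v$type, "deletion")
  expect_equal(attr(v, "score"), 5)
})

test_that("alignment scores equal the exhaustive-enumeration oracle", {
  set.seed(44)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:8, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:8, 1), TRUE),
               collapse = "")
    expect_equal(attr(call_variants(a, b), "score"), oracle_nw_score(a, b),
                 label = paste(a, "vs", b))
  }
})

test_that("backbone-internal reads are removed, junction reads kept", {
  set.seed(45)
  backbone <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
  site <- 600L
  insert <- random_dna(1, 300)
  plasmid <- paste0(substr(backbone, 1, site), insert,
                    substring(backbone, site + 1))
  reads <- c(substr(backbone, 100, 199),    # deep backbone: drop
             substr(backbone, 980, 1079),   # deep backbone: drop
             substr(plasmid, 551, 650),     # straddles junction: keep
             substr(insert, 50, 149),       # insert interior: keep
             substr(backbone, 480, 579))    # inside the 150 nt window: keep
  kept <- filter_backbone_reads(reads, backbone, site)
  expect_setequal(kept, reads[3:5])
  # reverse-complement backbone reads are recognised too
  rc <- reverse_complement(reads[1])
  expect_length(filter_backbone_reads(rc, backbone, site), 0)
})

test_that("end-to-end assembly recovers an error-free pool exactly", {
  pool <- mini_pool(n_variants = 20, depth = 30, seq_error = 0, seed = 46)
  rep <- assemble(pool$reads, pool$design$fwd, pool$design$rev, pool$params,
                  expected_insert_len = nchar(pool$truth$variants$insert[1]))
  ev <- compare_to_truth(rep, pool$truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  # deterministic: re-running gives identical output
  rep2 <- assemble(pool$reads, pool$design$fwd, pool$design$rev, pool$params,
                   expected_insert_len = nchar(pool$truth$variants$insert[1]))
  expect_identical(rep$contigs, rep2$contigs)
  # copy numbers reflect the (uniform) molecule depth scale
  expect_gt(min(rep$contigs$copy_number), 0.3 * 30)
  # empty input errors
  expect_error(assemble(read_set_from(character(0)), pool$design$fwd,
                        pool$design$rev, pool$params), "empty")
})

test_that("recall is non-decreasing in coverage on a fixed pool", {
  recalls <- vapply(c(4, 10, 30), function(d) {
    pool <- mini_pool(n_variants = 25, depth = d, seq_error = 0.001,
                      n_aa = 100, seed = 47)
    rep <- assemble(pool$reads, pool$design$fwd, pool$design$rev,
                    pool$params,
                    expected_insert_len = nchar(pool$truth$variants$insert[1]))
    compare_to_truth(rep, pool$truth)$recall
  }, 0)
  expect_true(all(diff(recalls) >= 0))
  expect_lt(recalls[1], 1)
  expect_equal(recalls[3], 1)
})

test_that("precision increases with k on pools sharing identical stretches", {
  # molecules share a fixed 60 nt interior stretch; at k = 30 chimeras of
  # equal-abundance templates appear (flat CV profiles pass the filter),
  # at k = 90 the stretch is shorter than a node and cannot bridge
  set.seed(48)
  shared <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  fl <- random_flanks(90, seed = 49)
  ins <- paste0(random_dna(3, 90), shared, random_dna(3, 90))[1:3]
  seqs <- paste0(fl$fwd, ins, fl$rev)
  reads <- read_set_from(rep(tiling_reads(seqs, 1, 120), 3L))
  prec <- vapply(c(30L, 90L), function(k) {
    # CV off: this property isolates the graph stage (with single-length
    # reads, any chimera that a larger k removes is also CV-detectable,
    # which would mask the k effect)
    params <- assembly_params(k = k, min_seed_anchor = 12L, cv_anchor = 15L,
                              cv_flank_context = 90L,
                              apply_cv_filter = FALSE)
    rep <- assemble(reads, fl$fwd, fl$rev, params,
                    expected_insert_len = nchar(ins[1]))
    compare_to_truth(rep, ins)$precision
  }, 0)
  expect_lt(prec[1], 1)
  expect_equal(prec[2], 1)
})
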