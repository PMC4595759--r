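# Shared fixtures and independent oracles, all generated in code.

# small design used by most assembler tests: k = 30, 60 nt flanks.
# The CV cutoff is calibrated for k = 120 only, so the mini fixtures skip
# that stage by default; CV behaviour is tested explicitly at k = 120 or on
# constructed profiles.
mini_params <- function(...) {
  assembly_params(k = 30L, min_seed_anchor = 12L, cv_anchor = 15L,
                  apply_cv_filter = FALSE, ...)
}

mini_design <- function(n_aa = 60L, seed = 42L) {
  tpl <- reverse_translate(synthetic_protein(n_aa, seed = seed))
  fl <- random_flanks(60L, seed = seed + 1L)
  list(template = tpl, fwd = fl$fwd, rev = fl$rev)
}

# simulate a pool and assemble it with the mini design
mini_pool <- function(n_variants = 20L, depth = 30, mutation_rate = 0,
                      seq_error = 0, n_aa = 60L, seed = 7L,
                      params = mini_params(), model = "uniform",
                      dispersion = 2) {
  d <- mini_design(n_aa = n_aa, seed = seed)
  truth <- generate_library(d$template, n_variants, mutation_rate,
                            d$fwd, d$rev, seed = seed + 1L)
  truth <- assign_copy_numbers(truth, coverage_model(model, depth, dispersion),
                               seed = seed + 2L)
  cfg <- read_sim_config(seq_error_rate = seq_error)
  reads <- simulate_reads(truth, cfg,
                          coverage_for_depth(depth, 150L, params$k),
                          seed = seed + 3L)
  list(design = d, truth = truth, reads = reads, params = params)
}

# reads tiling a set of flanked molecules at an exact per-molecule depth:
# every window start is emitted `depth` times (deterministic, error-free)
tiling_reads <- function(seqs, depth = 1L, read_len = 60L, step = 1L) {
  out <- unlist(lapply(seqs, function(s) {
    starts <- seq(1L, nchar(s) - read_len + 1L, by = step)
    rep(substring(s, starts, starts + read_len - 1L), depth)
  }))
  unname(out)
}

read_set_from <- function(seqs) {
  structure(list(mate1 = seqs, qual1 = strrep("F", nchar(seqs)),
                 id1 = as.character(seq_along(seqs)),
                 mate2 = character(0), qual2 = character(0),
                 id2 = character(0),
                 read_len = if (length(seqs)) max(nchar(seqs)) else 0L),
            class = "read_set")
}

# ---- independent oracles ----------------------------------------------

# exhaustive path enumeration over an explicit edge table (naive recursion);
# returns the set of full path strings from initial to terminal seed nodes
oracle_enumerate_paths <- function(tabs, init_nodes, term_nodes, k,
                                   max_len = 10000L) {
  nl <- k - 3L
  edges <- tabs$edges$kmer
  node_depth <- setNames(tabs$nodes$depth, tabs$nodes$kmer)
  adj <- split(edges, substr(edges, 1L, nl))
  term <- unique(term_nodes)
  paths <- character(0)
  copy <- integer(0)
  recurse <- function(node, seq, visited, mind) {
    if (node %in% term && nchar(seq) > 0) {
      paths[[length(paths) + 1L]] <<- seq
      copy[[length(copy) + 1L]] <<- mind
      return(invisible())
    }
    if (nchar(seq) >= max_len) return(invisible())
    for (e in adj[[node]] %||% character(0)) {
      nxt <- substr(e, 4L, k)
      if (nxt %in% visited) next
      if (is.na(node_depth[nxt])) next
      recurse(nxt, paste0(seq, substr(e, nl + 1L, k)),
              c(visited, nxt), min(mind, node_depth[[nxt]]))
    }
  }
  for (s in unique(init_nodes)) {
    if (s %in% term) { paths[[length(paths) + 1L]] <- s; copy[[length(copy) + 1L]] <- node_depth[[s]] }
    recurse(s, s, s, node_depth[[s]])
  }
  list(paths = paths, copy = copy)
}

# exhaustive global alignment scorer: match +2, mismatch -1, gap -3 for the
# first base of a run and -1 for each further base; enumerates all
# alignments recursively (feasible for sequences <= 8 nt)
oracle_nw_score <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) 2 else -1
      best <- max(best, s + rec(i + 1L, j + 1L, "m"))
    }
    if (i <= length(av)) {   # gap in b
      g <- if (prev == "a") -1 else -3
      best <- max(best, g + rec(i + 1L, j, "a"))
    }
    if (j <= length(bv)) {   # gap in a
      g <- if (prev == "b") -1 else -3
      best <- max(best, g + rec(i, j + 1L, "b"))
    }
    best
  }
  rec(1L, 1L, "m")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), "")
}
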