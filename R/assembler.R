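# Codon-frame de Bruijn assembly: quality trimming, graph construction over
# (k-3)-mer nodes / k-mer edges, depth pruning, flank-anchored seeds,
# exhaustive seed-to-seed traversal and the CV chimera filter.

#' Assembly parameters
#'
#' All thresholds of the assembly method. Defaults are the method's standard
#' operating point: `k = 120` with singleton elimination, per-node relative
#' edge pruning at 1/50 of the strongest outgoing edge, seed depth cut-off at
#' 1/200 of the strongest seed, and a contig depth-CV cut-off of 0.2163
#' (calibrated for `k = 120`; other `k` require recalibration and trigger a
#' log flag).
#'
#' @param k Edge k-mer length; must be a multiple of 3 (nodes are
#'   `(k-3)`-mers so each traversal step advances one codon).
#' @param min_depth Depth below which nodes/edges are treated as errors and
#'   removed (default 2: singletons eliminated).
#' @param edge_prune_ratio Outgoing edges weaker than this fraction of the
#'   strongest outgoing edge at the same node are pruned (default 1/50).
#' @param seed_prune_ratio Seeds weaker than this fraction of the strongest
#'   seed are discarded, separately for initial and terminal sets (default
#'   1/200; 1/150 is a common relaxed preset for skewed initial pools).
#' @param cv_cutoff Maximum allowed coefficient of variation (sd/mean) of the
#'   exact-match read-depth profile of a candidate contig.
#' @param min_seed_anchor Minimum exact flank overlap (nt) for a node to act
#'   as a seed (default 30).
#' @param max_contig_len Traversal path-length guard; defaults to
#'   `expected_insert_len + 2k + 300` when an expected length is available.
#' @param max_candidates,max_steps Exploration budgets guarding against
#'   degenerate (barcode-poor) graphs with exponentially many paths.
#' @param bins Number of bins for partitioned graph construction (an
#'   associative map-merge; has no effect on the result).
#' @param cv_anchor Anchor length for exact-match read re-alignment.
#' @param cv_flank_context Flank context (nt) re-attached to each candidate
#'   insert for read re-alignment. Keeping it `read_len - 30` forces every
#'   counted read to overlap the insert by at least 30 nt (about ten codon
#'   barcodes), so junction reads are only credited to the variant they
#'   belong to; flank-only reads, which are shared by the whole pool, cannot
#'   distort any candidate's depth profile.
#' @param apply_cv_filter Whether to run the CV chimera filter (default on).
#' @export
assembly_params <- function(k = 120L, min_depth = 2L, edge_prune_ratio = 1 / 50,
                            seed_prune_ratio = 1 / 200, cv_cutoff = 0.2163,
                            min_seed_anchor = 30L, max_contig_len = NULL,
                            max_candidates = 20000L, max_steps = 5e6,
                            bins = 1L, cv_anchor = 30L,
                            cv_flank_context = 120L,
                            apply_cv_filter = TRUE) {
  k <- as.integer(k)
  if (k %% 3L != 0L) stop("k must be a multiple of 3 (codon frame)")
  if (k <= min_seed_anchor + 3L) stop("k must exceed min_seed_anchor + 3")
  stopifnot(edge_prune_ratio > 0, edge_prune_ratio < 1,
            seed_prune_ratio > 0, seed_prune_ratio < 1, cv_cutoff > 0)
  structure(list(k = k, min_depth = as.integer(min_depth),
                 edge_prune_ratio = edge_prune_ratio,
                 seed_prune_ratio = seed_prune_ratio, cv_cutoff = cv_cutoff,
                 min_seed_anchor = as.integer(min_seed_anchor),
                 max_contig_len = max_contig_len,
                 max_candidates = as.integer(max_candidates),
                 max_steps = max_steps, bins = as.integer(bins),
                 cv_anchor = as.integer(cv_anchor),
                 cv_flank_context = as.integer(cv_flank_context),
                 apply_cv_filter = isTRUE(apply_cv_filter)),
            class = "assembly_params")
}

#' Quality- and poly-A-trim reads
#'
#' Leading and trailing bases with Phred quality below `min_q` are removed;
#' a remaining 3' homopolymer run of more than three `A`s is then stripped.
#' Reads shorter than `min_len` after trimming are dropped.
#'
#' @param reads A `read_set`, or a character vector of sequences (then
#'   `quals` must be supplied).
#' @param quals Phred+33 quality strings (ignored for a `read_set`).
#' @param min_q Quality threshold (default 20).
#' @param min_len Minimum surviving length (default 1; the assembler passes
#'   `k - 3`).
#' @return Same shape as the input, trimmed; dropped reads removed.
#' @export
trim_reads <- function(reads, quals = NULL, min_q = 20L, min_len = 1L) {
  if (inherits(reads, "read_set")) {
    t1 <- trim_reads_cpp(reads$mate1, reads$qual1, min_q, min_len, 4L)
    t2 <- trim_reads_cpp(reads$mate2, reads$qual2, min_q, min_len, 4L)
    return(structure(list(mate1 = t1$seq, qual1 = t1$qual,
                          id1 = reads$id1[t1$kept],
                          mate2 = t2$seq, qual2 = t2$qual,
                          id2 = reads$id2[t2$kept],
                          read_len = reads$read_len,
                          kept1 = t1$kept, kept2 = t2$kept),
                     class = "read_set"))
  }
  if (is.null(quals)) stop("quals required when reads is a character vector")
  tr <- trim_reads_cpp(as.character(reads), as.character(quals),
                       min_q, min_len, 4L)
  list(seq = tr$seq, qual = tr$qual, kept = tr$kept)
}

new_kmer_graph <- function(ptr, k) {
  structure(list(ptr = ptr, k = as.integer(k)), class = "kmer_graph")
}

#' Build the codon-frame de Bruijn graph
#'
#' Every length `(k-3)` substring of every read increments a node and every
#' length `k` substring increments an edge; an edge connects the node equal
#' to its first `k-3` bases to the node equal to its last `k-3` bases, a
#' 3 nt (one codon) step. Reads and their reverse complements are both
#' inserted, so the graph contains both strands and is later oriented by the
#' flank seeds. Construction is partitionable: with `bins > 1` reads are
#' split into bins whose graphs are merged associatively, with a result
#' identical to single-pass construction.
#'
#' @param reads Character vector of read sequences (or a `read_set`; mates
#'   are treated as independent reads).
#' @param k Edge k-mer length (multiple of 3).
#' @param include_rc Insert reverse complements as well (default `TRUE`).
#' @param bins Number of construction bins.
#' @param min_count Drop k-mers with final depth below this during
#'   construction (backed by an exact-preserving counting filter; 1 keeps
#'   everything). The assembly pipeline uses its `min_depth` here, which is
#'   equivalent to building the full graph and then removing low-depth keys,
#'   but bounds memory on error-rich data.
#' @return A `kmer_graph` handle.
#' @export
build_graph <- function(reads, k, include_rc = TRUE, bins = 1L,
                        min_count = 1L) {
  reads <- all_reads(reads)
  k <- as.integer(k)
  bins <- max(1L, as.integer(bins))
  if (bins == 1L)
    return(new_kmer_graph(kg_build_cpp(reads, k, include_rc,
                                       as.integer(min_count), 0L), k))
  grp <- rep_len(seq_len(bins), length(reads))
  parts <- lapply(split(reads, grp), function(r)
    kg_build_cpp(r, k, include_rc, 1L, 0L))
  acc <- parts[[1]]
  for (i in seq_along(parts)[-1]) acc <- kg_merge_cpp(acc, parts[[i]])
  g <- new_kmer_graph(acc, k)
  if (min_count > 1L) g <- prune_low_depth(g, min_count)
  g
}

# depth-only filter used to reconcile binned construction with min_count
prune_low_depth <- function(g, min_count) {
  new_kmer_graph(kg_prune_cpp(g$ptr, as.integer(min_count), 0), g$k)
}

#' Merge two k-mer graphs (depths add)
#' @param g1,g2 `kmer_graph` objects built with the same `k`.
#' @export
merge_graphs <- function(g1, g2) {
  new_kmer_graph(kg_merge_cpp(g1$ptr, g2$ptr), g1$k)
}

#' Graph summary statistics
#' @param g A `kmer_graph`.
#' @return List with node/edge counts and total depths.
#' @export
graph_stats <- function(g) kg_stats_cpp(g$ptr)

#' Materialise a (small) graph as node/edge tables
#' @param g A `kmer_graph`.
#' @param max_entries Refuse to materialise larger graphs.
#' @export
graph_tables <- function(g, max_entries = 2e5) kg_tables_cpp(g$ptr, max_entries)

#' Depth lookup
#' @param g A `kmer_graph`.
#' @param kmers Character vector of `(k-3)`-mers or `k`-mers.
#' @param type `"node"` or `"edge"`.
#' @export
graph_depth <- function(g, kmers, type = c("node", "edge")) {
  type <- match.arg(type)
  kg_depth_cpp(g$ptr, as.character(kmers), type == "edge")
}

#' @export
print.kmer_graph <- function(x, ...) {
  s <- graph_stats(x)
  cat("Codon-frame de Bruijn graph: k =", s$k, "|", s$n_nodes, "nodes,",
      s$n_edges, "edges\n")
  invisible(x)
}

#' Prune the graph
#'
#' Nodes and edges below `min_depth` are treated as sequencing errors and
#' removed (default: singletons). Then, at every node, outgoing edges weaker
#' than `edge_prune_ratio` times the strongest outgoing edge at that node are
#' pruned, and nodes left without any incident edge are dropped.
#'
#' @param g A `kmer_graph`.
#' @param params An [assembly_params()].
#' @return A new, pruned `kmer_graph` (the input is untouched).
#' @export
prune_graph <- function(g, params = assembly_params(k = g$k)) {
  new_kmer_graph(kg_prune_cpp(g$ptr, params$min_depth,
                              params$edge_prune_ratio), g$k)
}

#' Detect flank-anchored seeds
#'
#' A node is an initial seed if its first `b` bases exactly match the
#' 3'-terminal `b` bases of the forward flank for some
#' `b in [min_seed_anchor, k-6]` (the largest such `b` is recorded as the
#' flank overlap); terminal seeds are defined symmetrically on the node
#' suffix against the start of the reverse flank. Rare seeds with depth
#' below `seed_prune_ratio` times the strongest seed are then discarded,
#' separately for the two sets.
#'
#' @param g A pruned `kmer_graph`.
#' @param fwd_flank,rev_flank Backbone flank sequences adjacent to the
#'   insert.
#' @param params An [assembly_params()].
#' @return A `seed_set`: list of `initial` and `terminal` data frames
#'   (`node`, `overlap`, `depth`).
#' @export
detect_seeds <- function(g, fwd_flank, rev_flank,
                         params = assembly_params(k = g$k)) {
  res <- kg_seed_scan_cpp(g$ptr, fwd_flank, rev_flank, params$min_seed_anchor)
  cut <- function(df) {
    if (nrow(df) == 0) return(df)
    df[df$depth >= params$seed_prune_ratio * max(df$depth), , drop = FALSE]
  }
  ini <- cut(res$initial)
  ter <- cut(res$terminal)
  if (nrow(ini) == 0 || nrow(ter) == 0)
    stop("assembly aborted: no ", if (nrow(ini) == 0) "initial" else "terminal",
         " seeds survive (", nrow(res$initial), " initial / ",
         nrow(res$terminal), " terminal before depth cut-off)")
  structure(list(initial = ini, terminal = ter,
                 raw_counts = c(initial = nrow(res$initial),
                                terminal = nrow(res$terminal))),
            class = "seed_set")
}

#' Traverse the graph from initial to terminal seeds
#'
#' Depth-first exhaustive path exploration, extending 3 nt (one edge) per
#' step; a path terminates successfully on reaching any terminal seed. The
#' candidate's insert is the path string minus the recorded flank overlaps,
#' and its copy-number estimate is the minimum node depth along the path.
#' Paths exceeding the length guard or revisiting a node are abandoned;
#' exploration budgets (`max_steps`, `max_candidates`) guard degenerate
#' graphs and are reported as truncation in the log. Initial seeds reachable
#' from another initial seed in one step are redundant roots (their paths
#' trim to the same inserts) and are skipped.
#'
#' @param g A pruned `kmer_graph`.
#' @param seeds A `seed_set` from [detect_seeds()].
#' @param params An [assembly_params()].
#' @param expected_insert_len Optional expected insert length used for the
#'   default path-length guard.
#' @param roots_only Skip redundant roots (default). With `FALSE` every
#'   initial seed is explored, which enumerates each molecule's path once
#'   per seed; used by the path-enumeration equivalence tests.
#' @return A `contig_set` data frame (`insert`, `copy_number`, `status`,
#'   dedup count) with a traversal log attached as attribute `log`.
#' @export
traverse_graph <- function(g, seeds, params = assembly_params(k = g$k),
                           expected_insert_len = NULL, roots_only = TRUE) {
  max_len <- params$max_contig_len %||%
    (if (!is.null(expected_insert_len))
       expected_insert_len + 2L * params$k + 300L else 100000L)
  tr <- kg_traverse_cpp(g$ptr, seeds$initial$node, seeds$initial$overlap,
                        seeds$terminal$node, seeds$terminal$overlap,
                        as.integer(max_len), params$max_steps,
                        params$max_candidates, isTRUE(roots_only))
  insert <- substr(tr$sequence, tr$init_overlap + 1L,
                   nchar(tr$sequence) - tr$term_overlap)
  cand <- data.frame(insert = insert, copy_number = tr$copy_number,
                     stringsAsFactors = FALSE)
  # the same molecule is found once per rooted phase; collapse by sequence
  if (nrow(cand)) {
    ord <- order(cand$insert, -cand$copy_number)
    cand <- cand[ord, , drop = FALSE]
    first <- !duplicated(cand$insert)
    n_paths <- as.integer(table(factor(cand$insert,
                                       levels = cand$insert[first])))
    cand <- cand[first, , drop = FALSE]
    cand$n_paths <- n_paths
  } else {
    cand$n_paths <- integer(0)
  }
  cand$cv <- NA_real_
  cand$status <- rep("candidate", nrow(cand))
  rownames(cand) <- NULL
  structure(cand, class = c("contig_set", "data.frame"),
            log = list(n_raw_paths = length(tr$sequence),
                       steps = tr$steps, truncated = tr$truncated))
}

#' Chimera filtering by depth coefficient of variation
#'
#' Raw reads are re-aligned to each candidate by exact substring matching
#' (forward or reverse complement) against the candidate insert with its two
#' flanks re-attached; the per-base depth profile over the insert span is
#' summarised by its coefficient of variation (sd/mean). True contigs of
#' randomly sheared molecules have flat profiles; chimeras joining templates
#' of unequal abundance show a depth step and fail the cut-off.
#'
#' @param candidates A `contig_set`.
#' @param reads The (trimmed) reads used for assembly.
#' @param fwd_flank,rev_flank Flank sequences (give reads spanning the
#'   insert boundary a full-length context to match into).
#' @param params An [assembly_params()]; `cv_cutoff` is calibrated for
#'   `k = 120`.
#' @return The `contig_set` with `cv` filled in and `status` set to
#'   `"passed"` or `"failed_cv"`; candidates with no aligned reads are
#'   failed with `cv = NA` and flagged.
#' @export
cv_filter <- function(candidates, reads, fwd_flank, rev_flank,
                      params = assembly_params()) {
  if (nrow(candidates) == 0) return(candidates)
  ctx <- params$cv_flank_context
  nf <- nchar(fwd_flank)
  fwd_ctx <- substr(fwd_flank, max(1L, nf - ctx + 1L), nf)
  rev_ctx <- substr(rev_flank, 1L, ctx)
  evalseq <- paste0(fwd_ctx, candidates$insert, rev_ctx)
  al <- cv_align_cpp(evalseq, all_reads(reads), params$cv_anchor)
  off <- nchar(fwd_ctx)
  cv <- vapply(seq_len(nrow(candidates)), function(i) {
    prof <- al$profile[[i]]
    span <- prof[(off + 1L):(off + nchar(candidates$insert[i]))]
    m <- mean(span)
    if (m <= 0) return(NA_real_)
    sd(span) / m
  }, numeric(1))
  candidates$cv <- cv
  candidates$n_reads <- al$n_reads
  candidates$status <- ifelse(is.na(cv), "failed_cv",
                              ifelse(cv <= params$cv_cutoff, "passed",
                                     "failed_cv"))
  candidates
}

#' Call variants between a contig and a reference
#'
#' Global (Needleman-Wunsch) alignment with match +2, mismatch -1, gap
#' initiation -3 and gap propagation -1, as used for contig-vs-reference
#' comparison; substitutions and indels are reported in 0-based reference
#' coordinates.
#'
#' @param contig,reference DNA strings.
#' @return Data frame with `pos` (0-based on the reference), `ref`, `alt`,
#'   `type`; the alignment score is attached as attribute `score`.
#' @export
call_variants <- function(contig, reference) {
  stopifnot(nchar(contig) > 0, nchar(reference) > 0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(contig, reference,
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1,
                                       type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pos <- ref <- alt <- type <- character(0)
  ref_i <- 0L  # bases of reference consumed
  i <- 1L
  n <- length(p)
  out <- list()
  while (i <= n) {
    if (s[i] != "-" && p[i] != "-") {
      if (s[i] != p[i])
        out[[length(out) + 1L]] <- data.frame(pos = ref_i, ref = s[i],
                                              alt = p[i],
                                              type = "substitution")
      ref_i <- ref_i + 1L
      i <- i + 1L
    } else if (s[i] == "-") {           # insertion relative to the reference
      j <- i
      while (j <= n && s[j] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        pos = ref_i, ref = "", alt = paste(p[i:(j - 1L)], collapse = ""),
        type = "insertion")
      i <- j
    } else {                            # deletion of reference bases
      j <- i
      while (j <= n && p[j] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        pos = ref_i, ref = paste(s[i:(j - 1L)], collapse = ""), alt = "",
        type = "deletion")
      ref_i <- ref_i + (j - i)
      i <- j
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(pos = integer(0), ref = character(0), alt = character(0),
               type = character(0))
  attr(res, "score") <- Biostrings::score(aln)
  res
}

#' Remove reads internal to the vector backbone
#'
#' Reads whose best (approximate, exact-seeded) alignment lies entirely
#' within the backbone outside the two junction windows adjacent to the
#' insertion site are discarded; junction-straddling and insert-derived
#' reads are kept, matching the practice of sequencing whole plasmids but
#' assembling only the region of interest.
#'
#' @param reads A `read_set` or character vector.
#' @param backbone Backbone plasmid sequence (without the insert).
#' @param insert_site 1-based position in `backbone` after which the insert
#'   is cloned.
#' @param flank_window Size of the retained junction windows (default 150).
#' @param max_mismatch_frac Maximum mismatch fraction for a read to count as
#'   backbone-aligned.
#' @return Filtered reads (same shape as input).
#' @export
filter_backbone_reads <- function(reads, backbone, insert_site,
                                  flank_window = 150L,
                                  max_mismatch_frac = 0.1) {
  drop_mask <- function(seqs) {
    al <- backbone_align_cpp(as.character(seqs), backbone, 20L,
                             max_mismatch_frac)
    st <- al$start
    en <- st + nchar(seqs) - 1L
    win_lo <- insert_site - flank_window + 1L
    win_hi <- insert_site + flank_window
    aligned <- st > 0
    in_window <- aligned & (en >= win_lo & st <= win_hi)
    aligned & !in_window
  }
  if (inherits(reads, "read_set")) {
    # mates are filtered independently (they are independent observations
    # downstream); pairing ids are not preserved
    d1 <- drop_mask(reads$mate1)
    d2 <- drop_mask(reads$mate2)
    structure(list(mate1 = reads$mate1[!d1], qual1 = reads$qual1[!d1],
                   id1 = reads$id1[!d1],
                   mate2 = reads$mate2[!d2], qual2 = reads$qual2[!d2],
                   id2 = reads$id2[!d2],
                   read_len = reads$read_len),
              class = "read_set")
  } else {
    reads[!drop_mask(reads)]
  }
}

#' Assemble full-length variants from short reads
#'
#' End-to-end pipeline: quality/poly-A trimming, optional backbone read
#' removal, codon-frame graph construction, depth pruning, flank seed
#' detection, exhaustive seed-to-seed traversal, and the CV chimera filter.
#'
#' @param reads A `read_set`, or a length-2 character vector of paired FASTQ
#'   paths.
#' @param fwd_flank,rev_flank Backbone flank sequences adjacent to the
#'   insert (>= `min_seed_anchor` nt each).
#' @param params An [assembly_params()].
#' @param backbone,backbone_insert_site Optional backbone filtering inputs
#'   (see [filter_backbone_reads()]).
#' @param expected_insert_len Optional expected insert length (tightens the
#'   traversal length guard).
#' @return A `contig_report`: list with `contigs` (insert sequence,
#'   copy_number, cv, status), `log` (stage statistics) and the inputs
#'   needed downstream.
#' @export
assemble <- function(reads, fwd_flank, rev_flank,
                     params = assembly_params(), backbone = NULL,
                     backbone_insert_site = NULL,
                     expected_insert_len = NULL) {
  if (is.character(reads) && length(reads) == 2L)
    reads <- read_fastq_pair(reads[1], reads[2])
  stopifnot(inherits(reads, "read_set"))
  if (length(reads$mate1) == 0 && length(reads$mate2) == 0)
    stop("no reads supplied: empty input")
  log <- list(k = params$k)
  if (params$apply_cv_filter && params$k != 120L &&
      abs(params$cv_cutoff - 0.2163) < 1e-12)
    log$cv_warning <- paste("cv_cutoff 0.2163 was calibrated for k = 120;",
                            "recalibrate for k =", params$k)
  trimmed <- trim_reads(reads, min_len = params$k - 3L)
  log$n_reads_in <- length(reads$mate1) + length(reads$mate2)
  log$n_reads_trimmed <- length(trimmed$mate1) + length(trimmed$mate2)
  if (!is.null(backbone)) {
    trimmed <- filter_backbone_reads(trimmed, backbone,
                                     backbone_insert_site %||%
                                       stop("backbone_insert_site required"))
    log$n_reads_backbone_filtered <- length(trimmed$mate1) +
      length(trimmed$mate2)
  }
  g <- build_graph(trimmed, params$k, include_rc = TRUE, bins = params$bins,
                   min_count = params$min_depth)
  st <- graph_stats(g)
  log$graph_raw <- st[c("n_nodes", "n_edges")]
  gp <- prune_graph(g, params)
  log$graph_pruned <- graph_stats(gp)[c("n_nodes", "n_edges")]
  seeds <- detect_seeds(gp, fwd_flank, rev_flank, params)
  log$n_seeds <- c(initial = nrow(seeds$initial),
                   terminal = nrow(seeds$terminal))
  cand <- traverse_graph(gp, seeds, params, expected_insert_len)
  log$traversal <- attr(cand, "log")
  log$n_candidates <- nrow(cand)
  if (params$apply_cv_filter) {
    cand <- cv_filter(cand, trimmed, fwd_flank, rev_flank, params)
  } else {
    cand$status <- rep("passed", nrow(cand))
  }
  log$n_passed <- sum(cand$status == "passed")
  contigs <- cand[order(-cand$copy_number), , drop = FALSE]
  rownames(contigs) <- NULL
  if (nrow(contigs))
    contigs <- cbind(id = sprintf("contig_%04d", seq_len(nrow(contigs))),
                     contigs, stringsAsFactors = FALSE)
  structure(list(contigs = contigs, log = log, params = params,
                 fwd_flank = fwd_flank, rev_flank = rev_flank),
            class = "contig_report")
}

#' @export
print.contig_report <- function(x, ...) {
  cat("Contig report: ", nrow(x$contigs), " candidates, ",
      sum(x$contigs$status == "passed"), " passed (k = ", x$params$k,
      ")\n", sep = "")
  invisible(x)
}

#' Write assembled contigs to FASTA
#'
#' Headers carry the copy-number estimate, depth CV and filter status.
#' @param report A `contig_report`.
#' @param file Output path.
#' @param passed_only Write only contigs that passed the CV filter.
#' @export
write_contigs_fasta <- function(report, file, passed_only = TRUE) {
  ct <- report$contigs
  if (passed_only) ct <- ct[ct$status == "passed", , drop = FALSE]
  hdr <- sprintf("%s copy_number=%d cv=%s status=%s", ct$id, ct$copy_number,
                 ifelse(is.na(ct$cv), "NA", sprintf("%.4f", ct$cv)),
                 ct$status)
  write_dna_fasta(setNames(ct$insert, hdr), file)
}

#' Write a run log as JSON
#' @param report A `contig_report`.
#' @param file Output path.
#' @export
write_run_log <- function(report, file) {
  jsonlite::write_json(report$log, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}
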