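# Ground-truthed library simulation: template realization, error-prone-PCR
# style substitutions, per-variant copy numbers (uniform or negative
# binomial) and 150 bp paired-end read generation with substitution errors.

#' Coverage (copy-number) model for a simulated pool
#'
#' `"uniform"` assigns every variant the same copy weight (no cell-growth
#' bias); `"negative_binomial"` draws independent zero-truncated NB weights
#' (mean `mean`, size `dispersion`), reproducing the right-skewed abundance
#' distribution of transformed pools where clones grow unevenly.
#'
#' @param kind `"uniform"` or `"negative_binomial"`.
#' @param mean Mean copy weight (> 0).
#' @param dispersion NB size parameter (> 0); smaller is more overdispersed.
#' @export
coverage_model <- function(kind = c("uniform", "negative_binomial"),
                           mean = 60, dispersion = 2) {
  kind <- match.arg(kind)
  stopifnot(mean > 0, kind == "uniform" || dispersion > 0)
  structure(list(kind = kind, mean = mean, dispersion = dispersion),
            class = "coverage_model")
}

#' Read-simulation configuration
#'
#' @param read_len Read length (default 150).
#' @param fragment_min,fragment_max Sheared fragment size range (default
#'   200-400 nt). Fragments shorter than `read_len` are permitted; mates
#'   then overlap or truncate.
#' @param seq_error_rate Per-base substitution error probability.
#' @export
read_sim_config <- function(read_len = 150L, fragment_min = 200L,
                            fragment_max = 400L, seq_error_rate = 0.001) {
  stopifnot(read_len > 0, fragment_min > 0, fragment_max >= fragment_min,
            seq_error_rate >= 0, seq_error_rate < 1)
  structure(list(read_len = as.integer(read_len),
                 fragment_min = as.integer(fragment_min),
                 fragment_max = as.integer(fragment_max),
                 seq_error_rate = seq_error_rate),
            class = "read_sim_config")
}

new_truth_set <- function(variants, template, fwd_flank, rev_flank,
                          mutation_rate = 0) {
  # collapse string-identical molecules, summing copies
  dup <- duplicated(variants$sequence)
  n_dup <- sum(dup)
  if (n_dup) {
    agg <- tapply(variants$copies, variants$sequence, sum)
    keep <- variants[!dup, , drop = FALSE]
    keep$copies <- as.integer(agg[keep$sequence])
    variants <- keep
  }
  rownames(variants) <- NULL
  structure(list(variants = variants, template = template,
                 fwd_flank = fwd_flank, rev_flank = rev_flank,
                 mutation_rate = mutation_rate, n_collapsed = n_dup),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Truth set: ", nrow(x$variants), " unique variants, insert ",
      nchar(x$variants$insert[1]), " nt, flanks ",
      nchar(x$fwd_flank), "/", nchar(x$rev_flank), " nt\n", sep = "")
  if (x$n_collapsed) cat("  (", x$n_collapsed, " duplicate molecules collapsed)\n")
  invisible(x)
}

#' Generate a ground-truthed variant library
#'
#' Produces `n_variants` molecules by (1) independently realizing the
#' degenerate template, (2) injecting independent per-base substitutions at
#' `mutation_rate` (uniform over the three alternative bases), mimicking an
#' error-prone PCR library, and (3) attaching the fixed backbone flanks.
#' Injected mutations are recorded (0-based insert coordinates, `pos:ref>alt`).
#'
#' @param template A `degenerate_template`.
#' @param n_variants Library size.
#' @param mutation_rate Per-base substitution probability (0 for a plain PCR
#'   library).
#' @param fwd_flank,rev_flank Fixed flank sequences (150 nt backbone context
#'   by default; see [random_flanks()]).
#' @param seed Optional integer seed.
#' @return A `truth_set`.
#' @export
generate_library <- function(template, n_variants, mutation_rate = 0,
                             fwd_flank, rev_flank, seed = NULL) {
  stopifnot(inherits(template, "degenerate_template"), n_variants >= 1,
            mutation_rate >= 0, mutation_rate < 1)
  with_seed(seed, {
    inserts <- realize_template(template, n_variants)
    gl <- nchar(template$dna)
    muts <- character(n_variants)
    n_mut <- integer(n_variants)
    if (mutation_rate > 0) {
      nm <- rbinom(n_variants, gl, mutation_rate)
      idx <- which(nm > 0)
      for (i in idx) {
        pos <- sample.int(gl, nm[i])
        s <- strsplit(inserts[i], "")[[1]]
        ref <- s[pos]
        alt <- vapply(ref, function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        s[pos] <- alt
        inserts[i] <- paste(s, collapse = "")
        ord <- order(pos)
        muts[i] <- paste(sprintf("%d:%s>%s", pos[ord] - 1L, ref[ord],
                                 alt[ord]), collapse = ",")
      }
      n_mut <- nm
    }
    variants <- data.frame(
      id = sprintf("v%04d", seq_len(n_variants)),
      insert = inserts,
      sequence = paste0(fwd_flank, inserts, rev_flank),
      copies = 1L, n_mutations = n_mut, mutations = muts,
      stringsAsFactors = FALSE)
    new_truth_set(variants, template, fwd_flank, rev_flank, mutation_rate)
  })
}

#' Generate a two-region missense library
#'
#' Each variant carries exactly one missense substitution in each of two
#' disjoint codon windows (e.g. two 34-codon regions placed > 800 bp apart),
#' sampled uniformly without replacement from the full combination space
#' (positions x 19 non-wild-type residues, squared); all remaining positions
#' are realized from the degenerate template. This emulates programmed
#' double-site mutagenesis whose long-range phasing only full-length
#' reconstruction can resolve.
#'
#' @param template A `degenerate_template`.
#' @param region_a,region_b 1-based codon indices of the two regions
#'   (disjoint).
#' @param n_variants Number of distinct combinations to sample.
#' @param fwd_flank,rev_flank Flank sequences.
#' @param seed Optional integer seed.
#' @return A `truth_set` whose `variants` carry `mut_a`/`mut_b` codon
#'   annotations.
#' @export
generate_two_region_library <- function(template, region_a, region_b,
                                        n_variants, fwd_flank, rev_flank,
                                        seed = NULL) {
  stopifnot(inherits(template, "degenerate_template"),
            length(intersect(region_a, region_b)) == 0)
  aa <- strsplit(template$protein, "")[[1]]
  n_aa <- length(aa)
  stopifnot(max(region_a, region_b) <= n_aa)
  space_a <- length(region_a) * 19L
  space_b <- length(region_b) * 19L
  total <- as.numeric(space_a) * space_b
  if (n_variants > total)
    stop("n_variants exceeds the ", format(total, big.mark = ","),
         "-combination space")
  with_seed(seed, {
    combo <- sample.int(total, n_variants)  # distinct tuples
    ia <- (combo - 1) %% space_a            # 0-based index into region A space
    ib <- (combo - 1) %/% space_a
    pos_a <- region_a[ia %/% 19L + 1L]
    pos_b <- region_b[ib %/% 19L + 1L]
    alt_rank_a <- ia %% 19L + 1L
    alt_rank_b <- ib %% 19L + 1L
    res_a <- vapply(seq_len(n_variants), function(i)
      setdiff(AA_LETTERS, aa[pos_a[i]])[alt_rank_a[i]], "")
    res_b <- vapply(seq_len(n_variants), function(i)
      setdiff(AA_LETTERS, aa[pos_b[i]])[alt_rank_b[i]], "")
    inserts <- realize_template(template, n_variants)
    tab <- degenerate_codon_table()
    sub_codon <- function(seqs, pos, res) {
      # replace codon `pos` with a realization of the new residue's family
      cod <- unname(tab[res])
      cod3 <- t(vapply(strsplit(cod, ""), identity, character(3)))
      third <- vapply(seq_along(res), function(i) {
        e <- IUPAC_EXPAND[[cod3[i, 3]]]
        e[sample.int(length(e), 1L)]
      }, "")
      substr(seqs, 3L * pos - 2L, 3L * pos) <- paste0(cod3[, 1], cod3[, 2], third)
      seqs
    }
    inserts <- sub_codon(inserts, pos_a, res_a)
    inserts <- sub_codon(inserts, pos_b, res_b)
    variants <- data.frame(
      id = sprintf("v%05d", seq_len(n_variants)),
      insert = inserts,
      sequence = paste0(fwd_flank, inserts, rev_flank),
      copies = 1L,
      n_mutations = 2L,
      mutations = sprintf("%s%d%s,%s%d%s", aa[pos_a], pos_a, res_a,
                          aa[pos_b], pos_b, res_b),
      mut_a = sprintf("%s%d%s", aa[pos_a], pos_a, res_a),
      mut_b = sprintf("%s%d%s", aa[pos_b], pos_b, res_b),
      stringsAsFactors = FALSE)
    new_truth_set(variants, template, fwd_flank, rev_flank)
  })
}

#' Assign per-variant copy numbers under a coverage model
#'
#' Uniform: every variant receives the same integer weight. Negative
#' binomial: i.i.d. draws from NB(mean, size = dispersion), zero-truncated so
#' no variant silently vanishes from the truth (rarity is exercised through
#' low weights instead).
#'
#' @param truth A `truth_set`.
#' @param model A [coverage_model()].
#' @param seed Optional integer seed.
#' @return The `truth_set` with updated `copies`.
#' @export
assign_copy_numbers <- function(truth, model, seed = NULL) {
  stopifnot(inherits(truth, "truth_set"), inherits(model, "coverage_model"))
  n <- nrow(truth$variants)
  with_seed(seed, {
    truth$variants$copies <- if (model$kind == "uniform") {
      rep(max(1L, as.integer(round(model$mean))), n)
    } else {
      pmax(1L, rnbinom(n, size = model$dispersion, mu = model$mean))
    }
    truth$coverage_model <- model
    truth
  })
}

#' Simulate paired-end reads from a truth set
#'
#' Fragments are drawn per variant with counts multinomial in the copy
#' weights and lengths uniform in `[fragment_min, fragment_max]`; mate 1 is
#' the first `read_len` bases of the fragment and mate 2 the reverse
#' complement of its last `read_len` bases. Because the molecules are
#' sheared as whole (circular) plasmids, fragment positions are drawn on
#' the plasmid axis: a fragment may overhang the retained flank+insert
#' window, and a mate is emitted only when the read lies entirely inside
#' the window (the overhanging mate is a backbone read that the real
#' pipeline discards). This makes read-start positions uniform across the
#' whole window for both mates, so depth profiles carry no end bias. The
#' total fragment count is scaled so that mean per-base read coverage over
#' the truth sequences is approximately `target_mean_coverage`. Each
#' emitted base is substituted independently with probability
#' `seq_error_rate`; qualities are constant Q37.
#'
#' @param truth A `truth_set` (after [assign_copy_numbers()] if a biased pool
#'   is wanted).
#' @param cfg A [read_sim_config()].
#' @param target_mean_coverage Desired mean read-base coverage (total emitted
#'   bases / total truth bases).
#' @param seed Optional integer seed.
#' @param keep_provenance Record each emitted read's variant, window
#'   coordinates and mate (used by sampling tests).
#' @return A `read_set`: list with `mate1`, `qual1`, `id1`, `mate2`,
#'   `qual2`, `id2`. Mate counts differ slightly because boundary
#'   fragments contribute a single read.
#' @export
simulate_reads <- function(truth, cfg = read_sim_config(),
                           target_mean_coverage = 60, seed = NULL,
                           keep_provenance = FALSE) {
  stopifnot(inherits(truth, "truth_set"), inherits(cfg, "read_sim_config"))
  v <- truth$variants
  lens <- nchar(v$sequence)
  rl <- cfg$read_len
  if (any(lens < rl))
    stop("variant sequence shorter than the read length")
  with_seed(seed, {
    fbar <- (cfg$fragment_min + min(cfg$fragment_max, min(lens))) / 2
    lbar <- mean(lens)
    # expected emitted mates per fragment = 2 (L - rl + 1) / (L + f - 2 rl + 1)
    mates_per_frag <- 2 * (lbar - rl + 1) / (lbar + fbar - 2 * rl + 1)
    n_frag <- max(1L, round(target_mean_coverage * sum(lens) /
                              (rl * mates_per_frag)))
    counts <- as.integer(rmultinom(1L, n_frag, prob = v$copies))
    vi <- rep.int(seq_len(nrow(v)), counts)
    n <- length(vi)
    f <- sample.int(cfg$fragment_max - cfg$fragment_min + 1L, n,
                    replace = TRUE) + cfg$fragment_min - 1L
    f <- pmin(f, lens[vi])
    rle <- pmin(rl, f)
    # fragment start on the plasmid axis; may overhang the window
    lo <- rl + 1L - f
    hi <- lens[vi] - rl + 1L
    s <- lo + floor(runif(n) * (hi - lo + 1))
    e <- s + f - 1L
    keep1 <- s >= 1L
    keep2 <- e <= lens[vi]
    s1 <- s[keep1]
    e1 <- s1 + rle[keep1] - 1L
    s2 <- e[keep2] - rle[keep2] + 1L
    e2 <- e[keep2]
    m1 <- substring(v$sequence[vi[keep1]], s1, e1)
    m2 <- as.character(revcomp_cpp(substring(v$sequence[vi[keep2]], s2, e2)))
    if (cfg$seq_error_rate > 0) {
      m1 <- as.character(add_subst_errors_cpp(m1, cfg$seq_error_rate))
      m2 <- as.character(add_subst_errors_cpp(m2, cfg$seq_error_rate))
    }
    out <- list(mate1 = m1, qual1 = strrep("F", nchar(m1)),
                id1 = sprintf("%s:%d", v$id[vi[keep1]], which(keep1)),
                mate2 = m2, qual2 = strrep("F", nchar(m2)),
                id2 = sprintf("%s:%d", v$id[vi[keep2]], which(keep2)),
                read_len = rl)
    if (keep_provenance)
      out$provenance <- data.frame(
        variant = c(vi[keep1], vi[keep2]),
        start = c(s1, s2), end = c(e1, e2),
        mate = rep(c(1L, 2L), c(sum(keep1), sum(keep2))))
    structure(out, class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat("Read set: ", length(x$mate1), " + ", length(x$mate2), " reads, ",
      sum(nchar(x$mate1)) + sum(nchar(x$mate2)), " bases\n", sep = "")
  invisible(x)
}

# All reads of a read_set as one vector (mates treated independently).
all_reads <- function(reads) {
  if (inherits(reads, "read_set")) c(reads$mate1, reads$mate2) else
    as.character(reads)
}

#' Write a read set as paired FASTQ files
#' @param reads A `read_set`.
#' @param file1,file2 Output paths for mate 1 / mate 2.
#' @export
write_fastq_pair <- function(reads, file1, file2) {
  stopifnot(inherits(reads, "read_set"))
  wr <- function(seqs, quals, ids, file, mate) {
    if (is.null(ids)) ids <- as.character(seq_along(seqs))
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(seqs, paste0(ids, "/", mate))),
      Biostrings::PhredQuality(quals))
    # writer warns about dropping the (empty) metadata columns
    suppressWarnings(Biostrings::writeQualityScaledXStringSet(x, file))
  }
  wr(reads$mate1, reads$qual1, reads$id1, file1, 1L)
  wr(reads$mate2, reads$qual2, reads$id2, file2, 2L)
  invisible(c(file1, file2))
}

#' Read paired FASTQ files into a read set
#' @param file1,file2 Paths to the two mate files.
#' @export
read_fastq_pair <- function(file1, file2) {
  rd <- function(f) {
    x <- Biostrings::readQualityScaledDNAStringSet(f)
    list(seq = as.character(x), qual = as.character(Biostrings::quality(x)))
  }
  a <- rd(file1)
  b <- rd(file2)
  structure(list(mate1 = unname(a$seq), qual1 = unname(a$qual),
                 id1 = sub("/1$", "", names(a$seq)),
                 mate2 = unname(b$seq), qual2 = unname(b$qual),
                 id2 = sub("/2$", "", names(b$seq)),
                 read_len = max(nchar(c(a$seq, b$seq)))),
            class = "read_set")
}

#' Write the truth table of a simulated library
#'
#' Emits the truth FASTA (flanked sequences) and a TSV of per-variant
#' metadata (id, copies, mutation list).
#' @param truth A `truth_set`.
#' @param fasta,tsv Output paths (either may be `NULL`).
#' @export
write_truth_set <- function(truth, fasta = NULL, tsv = NULL) {
  if (!is.null(fasta))
    write_dna_fasta(setNames(truth$variants$sequence, truth$variants$id), fasta)
  if (!is.null(tsv))
    write.table(truth$variants[, c("id", "copies", "n_mutations", "mutations")],
                tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(truth)
}
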