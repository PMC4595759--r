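test_that("reverse translation produces the expected degenerate codons", {
  expect_equal(reverse_translate("G", mode = "n_only",
                                 append_stop = FALSE)$dna, "GGN")
  tpl <- reverse_translate("MW", append_stop = FALSE)
  expect_equal(tpl$dna, "ATGTGG")
  expect_length(tpl$barcode_positions, 0)
  expect_equal(reverse_translate("KF", append_stop = FALSE)$dna, "AARTTY")
  expect_equal(reverse_translate("M")$dna, "ATGTAA")  # stop appended, fixed
  expect_error(reverse_translate("MXZ"), "unknown amino-acid")
})

test_that("degenerate symbols sit only at third codon positions", {
  tpl <- reverse_translate(synthetic_protein(80, seed = 3))
  expect_true(all(tpl$barcode_positions %% 3L == 2L))
  chars <- strsplit(tpl$dna, "")[[1]]
  expect_setequal(which(chars %in% c("N", "R", "Y")) - 1L,
                  tpl$barcode_positions)
})

test_that("chosen codon families are maximally degenerate (brute force)", {
  # oracle: enumerate all 64 codons and find, per residue, the largest
  # synonymous third-base family expressible as N, R, Y or a fixed base
  gc_tab <- Biostrings::GENETIC_CODE
  tab <- codasm:::degenerate_codon_table()
  exp_sets <- list(N = c("A", "C", "G", "T"), R = c("A", "G"),
                   Y = c("C", "T"), A = "A", C = "C", G = "G", T = "T")
  for (aa in setdiff(unique(gc_tab), "*")) {
    best_deg <- 0L
    for (pre in unique(substr(names(gc_tab), 1, 2))) {
      for (sym in names(exp_sets)) {
        cods <- paste0(pre, exp_sets[[sym]])
        if (all(gc_tab[cods] == aa))
          best_deg <- max(best_deg, length(exp_sets[[sym]]))
      }
    }
    chosen <- tab[[aa]]
    chosen_deg <- length(exp_sets[[substr(chosen, 3, 3)]])
    expect_equal(chosen_deg, best_deg, label = paste("degeneracy for", aa))
    third <- exp_sets[[substr(chosen, 3, 3)]]
    expect_true(all(gc_tab[paste0(substr(chosen, 1, 2), third)] == aa),
                label = paste("synonymy for", aa))
  }
})

test_that("realization round-trips through translation for random proteins", {
  set.seed(11)
  for (i in 1:5) {
    prot <- paste(sample(codasm:::AA_LETTERS, 40, TRUE), collapse = "")
    tpl <- reverse_translate(prot)
    seqs <- realize_template(tpl, n = 8)
    expect_true(all(translate_dna(seqs) == paste0(prot, "*")))
  }
  # degenerate-free template realizes to itself
  expect_equal(realize_template(reverse_translate("MW", append_stop = FALSE)),
               "ATGTGG")
})

test_that("realization samples each expansion uniformly", {
  tpl <- reverse_translate("G", append_stop = FALSE)  # GGN
  third <- substr(realize_template(tpl, n = 40000, seed = 99), 3, 3)
  freq <- table(factor(third, levels = c("A", "C", "G", "T"))) / 40000
  expect_true(all(abs(freq - 0.25) < 0.01))
  chi <- suppressWarnings(stats::chisq.test(table(third)))
  expect_gt(chi$p.value, 1e-4)
})

test_that("barcode down-sampling follows the binomial retention model", {
  tpl <- reverse_translate(synthetic_protein(101, seed = 5))
  n_max <- length(tpl$barcode_positions)
  expect_gte(n_max, 90)

  same <- downsample_barcodes(tpl, 1, seed = 1)
  expect_equal(same$template$dna, tpl$dna)
  expect_equal(same$template$barcode_positions, tpl$barcode_positions)

  none <- downsample_barcodes(tpl, 0, seed = 1)
  expect_length(none$template$barcode_positions, 0)
  expect_false(grepl("[NRY]", none$template$dna))
  # fixed bases stay synonymous
  expect_equal(translate_dna(realize_template(none$template)),
               paste0(tpl$protein, "*"))

  # retained counts fall in the central binomial region over repeated seeds
  counts <- vapply(1:200, function(s)
    sum(downsample_barcodes(tpl, 0.5, seed = s)$mask$retained), 0L)
  bounds <- qbinom(c(0.005, 0.995), n_max, 0.5)
  frac_in <- mean(counts >= bounds[1] & counts <= bounds[2])
  expect_gte(frac_in, 0.94)

  # monotone in P
  mean_ret <- vapply(c(0.2, 0.5, 0.8), function(p)
    mean(vapply(1:40, function(s)
      sum(downsample_barcodes(tpl, p, seed = s)$mask$retained), 0L)), 0)
  expect_true(all(diff(mean_ret) > 0))
})

test_that("retrieval primers are prefix/suffix with barcode counts", {
  tpl <- reverse_translate(synthetic_protein(20, seed = 2))
  v <- realize_template(tpl, seed = 3)
  pp <- design_retrieval_primers(v, tpl)
  expect_equal(pp$forward, substr(v, 1, 24))
  expect_equal(pp$reverse, reverse_complement(substr(v, nchar(v) - 21,
                                                     nchar(v))))
  expect_equal(pp$n_degenerate_fwd, sum(tpl$barcode_positions < 24))
  expect_equal(pp$n_degenerate_rev,
               sum(tpl$barcode_positions >= nchar(tpl$dna) - 22))
  # dense NRY barcodes make the pair specific within a library
  lib <- realize_template(tpl, n = 96, seed = 4)
  pp2 <- design_retrieval_primers(lib[1], tpl, library = lib)
  manual <- sum(substr(lib, 1, 24) == substr(lib[1], 1, 24) &
                substring(lib, nchar(lib) - 21) == substring(lib[1],
                                                             nchar(lib[1]) - 21))
  expect_equal(pp2$n_library_matches, manual)
  expect_error(design_retrieval_primers("ATG"), "shorter")
})

test_that("oligo tiling reconstructs the template and bridges junctions", {
  tpl <- reverse_translate(synthetic_protein(40, seed = 6))  # 123 nt
  ol <- tile_oligos(tpl, 60)
  expect_equal(paste(ol$sense, collapse = ""), tpl$dna)
  # antisense oligos reverse-complement-match the template
  for (i in seq_along(ol$antisense)) {
    r <- ol$antisense_ranges[i, ]
    expect_equal(reverse_complement(ol$antisense[i]),
                 substr(tpl$dna, r$start, r$end))
  }
  # every sense junction is strictly inside an antisense oligo
  junctions <- ol$sense_ranges$end[-nrow(ol$sense_ranges)]
  for (j in junctions)
    expect_true(any(ol$antisense_ranges$start <= j &
                    ol$antisense_ranges$end >= j + 1L))
  expect_error(tile_oligos(tpl, 10), "oligo_len")
})

test_that("template FASTA round-trips with its barcode sidecar", {
  tpl <- reverse_translate(synthetic_protein(25, seed = 9))
  fa <- tempfile(fileext = ".fasta")
  bed <- tempfile(fileext = ".bed")
  write_template_fasta(tpl, fa, bed_file = bed)
  back <- read_dna_fasta(fa)
  expect_equal(unname(back[1]), tpl$dna)
  bedtab <- read.delim(bed, header = FALSE)
  expect_equal(bedtab$V2, tpl$barcode_positions)
  expect_equal(bedtab$V3, tpl$barcode_positions + 1L)
  unlink(c(fa, bed))
})
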