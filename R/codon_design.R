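# Degenerate (codon-barcoded) template design: reverse translation with
# IUPAC N/R/Y at third codon positions, template realization, barcode
# down-sampling, retrieval primers and assembly oligonucleotides.

IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), N = c("A", "C", "G", "T")
)
DEGENERATE_SYMBOLS <- c("N", "R", "Y")
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")

# For every amino acid pick the degenerate codon XY<s>, s in {N,R,Y,fixed},
# whose expansion set is the largest fully synonymous family; ties broken by
# the lexicographically smallest codon prefix, then by symbol preference
# N > R > Y > fixed base. Deterministic; derived from the standard code.
build_degenerate_codon_table <- function() {
  gc_tab <- Biostrings::GENETIC_CODE
  prefixes <- sort(apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                     stringsAsFactors = FALSE)[, 2:1],
                         1, paste, collapse = ""))
  syms <- c("N", "R", "Y", "A", "C", "G", "T")
  best <- list()
  for (aa in unique(gc_tab)) {
    pick <- NULL
    pick_deg <- 0L
    for (pre in prefixes) {
      for (sym in syms) {
        third <- IUPAC_EXPAND[[sym]]
        codons <- paste0(pre, third)
        if (!all(gc_tab[codons] == aa)) next
        deg <- length(third)
        if (deg > pick_deg) {
          pick <- paste0(pre, sym)
          pick_deg <- deg
        }
        break  # syms are ordered by degeneracy then preference
      }
    }
    best[[aa]] <- pick
  }
  unlist(best)
}

degenerate_codon_env <- new.env(parent = emptyenv())

degenerate_codon_table <- function() {
  if (is.null(degenerate_codon_env$tab))
    degenerate_codon_env$tab <- build_degenerate_codon_table()
  degenerate_codon_env$tab
}

#' Reverse-translate a protein into a degenerate codon-barcoded template
#'
#' Each residue is encoded by the maximally degenerate fully synonymous codon
#' family expressible with a single IUPAC symbol (`N` = A/C/G/T, `R` = A/G,
#' `Y` = C/T) in the third position; residues whose codons do not admit any
#' degeneracy (Met, Trp) receive their single codon. The degenerate third
#' positions act as intrinsic molecular barcodes: every concrete realization
#' of the template translates to the same protein while carrying a (with high
#' probability) unique combination of synonymous codons.
#'
#' Six-codon residues use their four-fold box (Leu `CTN`, Ser `TCN`,
#' Arg `CGN`); Ile uses `ATY` (the only synonymous multi-codon family
#' expressible here, since `ATN` would admit Met). The appended stop codon is
#' fixed to `TAA`. In `"n_only"` mode a degenerate third base is used only
#' when all four `N` expansions are synonymous; other residues fall back to
#' the same R/Y/fixed rule, so on the standard genetic code the two modes
#' produce identical templates and the mode is recorded for provenance.
#'
#' @param protein Amino-acid string (standard 20 letters), or a named
#'   character vector of length 1.
#' @param mode `"nry"` (default) or `"n_only"`.
#' @param append_stop Append a terminal stop codon (`TAA`). Default `TRUE`.
#' @return A `degenerate_template`: list with `protein`, `dna` (IUPAC string),
#'   `barcode_positions` (0-based indices of degenerate symbols, all
#'   congruent to 2 mod 3) and `mode`.
#' @examples
#' tpl <- reverse_translate("MKF", append_stop = FALSE)
#' tpl$dna  # "ATGAARTTY"
#' @export
reverse_translate <- function(protein, mode = c("nry", "n_only"),
                              append_stop = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.character(protein), length(protein) == 1L)
  protein <- toupper(protein)
  aas <- strsplit(protein, "")[[1]]
  bad <- setdiff(aas, AA_LETTERS)
  if (length(bad))
    stop("unknown amino-acid letter(s): ", paste(unique(bad), collapse = ", "))
  tab <- degenerate_codon_table()
  codons <- unname(tab[aas])
  if (mode == "n_only") {
    # keep N codons; all others already follow the fallback rule
    codons <- codons
  }
  if (append_stop) codons <- c(codons, "TAA")
  dna <- paste(codons, collapse = "")
  chars <- strsplit(dna, "")[[1]]
  bpos <- which(chars %in% DEGENERATE_SYMBOLS) - 1L
  structure(list(protein = protein, dna = dna,
                 barcode_positions = bpos, mode = mode),
            class = "degenerate_template")
}

#' @export
print.degenerate_template <- function(x, ...) {
  cat("Degenerate template (", x$mode, " mode)\n", sep = "")
  cat("  protein: ", nchar(x$protein), " aa\n", sep = "")
  cat("  dna:     ", nchar(x$dna), " nt, ",
      length(x$barcode_positions), " barcode positions (",
      sum(strsplit(x$dna, "")[[1]] == "N"), " N)\n", sep = "")
  cat("  5': ", substr(x$dna, 1, min(60, nchar(x$dna))),
      if (nchar(x$dna) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Realize concrete sequences from a degenerate template
#'
#' Every degenerate position is replaced independently and uniformly over its
#' IUPAC expansion set, emulating the synthesis of a synonymous library.
#'
#' @param template A `degenerate_template`.
#' @param n Number of independent realizations.
#' @param seed Optional integer seed (uses and restores the R RNG).
#' @return Character vector of `n` concrete DNA sequences.
#' @export
realize_template <- function(template, n = 1L, seed = NULL) {
  stopifnot(inherits(template, "degenerate_template"))
  with_seed(seed, {
    chars <- strsplit(template$dna, "")[[1]]
    m <- matrix(rep(chars, n), nrow = length(chars), ncol = n)
    for (i in template$barcode_positions + 1L) {
      exp_set <- IUPAC_EXPAND[[chars[i]]]
      m[i, ] <- exp_set[sample.int(length(exp_set), n, replace = TRUE)]
    }
    apply(m, 2L, paste, collapse = "")
  })
}

#' Down-sample barcode positions of a template
#'
#' Each barcode position is independently retained with probability `p`;
#' non-retained positions are fixed to one concrete base drawn uniformly from
#' the symbol's expansion set (the same base for all library members derived
#' from the returned template). Models libraries synthesised with reduced
#' barcode density.
#'
#' @param template A `degenerate_template`.
#' @param p Retention probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return List with `template` (the down-sampled template) and `mask`, a
#'   `barcode_mask` recording `p`, the per-position retention flags and the
#'   maximum possible barcode count.
#' @export
downsample_barcodes <- function(template, p, seed = NULL) {
  stopifnot(inherits(template, "degenerate_template"),
            is.numeric(p), p >= 0, p <= 1)
  with_seed(seed, {
    bpos <- template$barcode_positions
    n_max <- length(bpos)
    retained <- runif(n_max) < p
    chars <- strsplit(template$dna, "")[[1]]
    for (i in which(!retained)) {
      exp_set <- IUPAC_EXPAND[[chars[bpos[i] + 1L]]]
      chars[bpos[i] + 1L] <- exp_set[sample.int(length(exp_set), 1L)]
    }
    out <- template
    out$dna <- paste(chars, collapse = "")
    out$barcode_positions <- bpos[retained]
    mask <- structure(list(p = p, retained = retained, n_max = n_max),
                      class = "barcode_mask")
    list(template = out, mask = mask)
  })
}

#' Design codon-barcode retrieval primers for one variant
#'
#' The forward primer is the variant's prefix (default 24 nt including the
#' start codon) and the reverse primer the reverse complement of its suffix
#' (default 22 nt including the stop codon). Barcode positions of the source
#' template that fall under a primer make the pair variant-specific.
#'
#' @param variant Concrete DNA sequence of the target variant.
#' @param template Optional source `degenerate_template`, used to count the
#'   degenerate (specificity-bearing) positions under each primer.
#' @param library Optional character vector of other library members; the
#'   number of members matched exactly by the pair is reported.
#' @param fwd_len,rev_len Primer lengths.
#' @return A `primer_pair` list.
#' @export
design_retrieval_primers <- function(variant, template = NULL, library = NULL,
                                     fwd_len = 24L, rev_len = 22L) {
  L <- nchar(variant)
  if (L < fwd_len + rev_len)
    stop("variant (", L, " nt) shorter than combined primer lengths")
  fwd <- substr(variant, 1L, fwd_len)
  rev3 <- substr(variant, L - rev_len + 1L, L)
  ndf <- ndr <- NA_integer_
  if (!is.null(template)) {
    stopifnot(inherits(template, "degenerate_template"))
    bp <- template$barcode_positions
    ndf <- sum(bp < fwd_len)
    ndr <- sum(bp >= nchar(template$dna) - rev_len)
  }
  n_matched <- NA_integer_
  if (!is.null(library)) {
    n_matched <- sum(substr(library, 1L, fwd_len) == fwd &
                     substr(library, nchar(library) - rev_len + 1L,
                            nchar(library)) == rev3)
  }
  structure(list(forward = fwd,
                 reverse = as.character(revcomp_cpp(rev3)),
                 n_degenerate_fwd = ndf, n_degenerate_rev = ndr,
                 n_library_matches = n_matched),
            class = "primer_pair")
}

#' Tile a template into sense and antisense assembly oligonucleotides
#'
#' The sense strand is partitioned into consecutive gap-free segments of
#' approximately `oligo_len`; antisense oligos tile the complementary strand
#' offset by half a segment, so every sense junction is bridged by an
#' antisense oligo (and vice versa), as required for ligation-based gene
#' assembly.
#'
#' @param template A `degenerate_template`.
#' @param oligo_len Target oligo length (>= 20 nt).
#' @return List with `sense`, `antisense` (IUPAC sequences; antisense in
#'   reverse-complement orientation) and their 1-based template coordinates.
#' @export
tile_oligos <- function(template, oligo_len) {
  stopifnot(inherits(template, "degenerate_template"), oligo_len >= 20)
  L <- nchar(template$dna)
  n_seg <- max(1L, ceiling(L / oligo_len))
  cuts <- round(seq(0, L, length.out = n_seg + 1L))
  sense_start <- cuts[-length(cuts)] + 1L
  sense_end <- cuts[-1L]
  # antisense boundaries at the midpoints of the sense segments
  mids <- round((sense_start + sense_end) / 2)
  acuts <- unique(c(0L, mids[mids > 0 & mids < L], L))
  anti_start <- acuts[-length(acuts)] + 1L
  anti_end <- acuts[-1L]
  seg <- function(s, e) substr(rep(template$dna, length(s)), s, e)
  sense <- seg(sense_start, sense_end)
  anti <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seg(anti_start, anti_end))))
  list(sense = sense, antisense = anti,
       sense_ranges = data.frame(start = sense_start, end = sense_end),
       antisense_ranges = data.frame(start = anti_start, end = anti_end))
}

# ---- sequence utilities ------------------------------------------------

#' Translate DNA to protein
#'
#' Thin wrapper around [Biostrings::translate()] returning plain characters;
#' terminal stops translate to `*`.
#' @param x Character vector of DNA sequences (length multiple of 3).
#' @export
translate_dna <- function(x) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                     no.init.codon = TRUE))
}

#' Reverse complement
#' @param x Character vector of DNA (IUPAC codes allowed).
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a random backbone flank sequence
#'
#' Fixed (non-degenerate) sequence standing in for the +/-150 nt of vector
#' backbone flanking the cloned insert, used to anchor initial and terminal
#' assembly seeds.
#' @param len Flank length (default 150).
#' @param seed Optional integer seed.
#' @export
random_flanks <- function(len = 150L, seed = NULL) {
  with_seed(seed, {
    list(fwd = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
         rev = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
  })
}

# ---- FASTA / sidecar IO ------------------------------------------------

#' Read protein sequences from FASTA
#' @param file Path to a FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(file) {
  x <- Biostrings::readAAStringSet(file)
  setNames(as.character(x), names(x))
}

#' Read DNA sequences from FASTA
#' @param file Path to a FASTA file.
#' @export
read_dna_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  setNames(as.character(x), names(x))
}

#' Write a degenerate template to FASTA (plus optional BED sidecar)
#'
#' The template is written with its IUPAC codes; barcode positions can be
#' emitted as a BED-like 0-based half-open interval file.
#' @param template A `degenerate_template`.
#' @param file Output FASTA path.
#' @param bed_file Optional path for the barcode-position sidecar.
#' @param name Sequence name.
#' @export
write_template_fasta <- function(template, file, bed_file = NULL,
                                 name = "template") {
  x <- Biostrings::DNAStringSet(setNames(template$dna, name))
  Biostrings::writeXStringSet(x, file)
  if (!is.null(bed_file)) {
    bp <- template$barcode_positions
    chars <- strsplit(template$dna, "")[[1]]
    df <- data.frame(chrom = name, start = bp, end = bp + 1L,
                     name = chars[bp + 1L])
    write.table(df, bed_file, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}

#' Write DNA sequences to FASTA
#' @param x Named character vector of DNA sequences.
#' @param file Output path.
#' @export
write_dna_fasta <- function(x, file) {
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), file)
  invisible(file)
}
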