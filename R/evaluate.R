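# Scoring assemblies against truth, functional-variant classification,
# codon adaptation index and depth-based enrichment ratios.

#' Compare assembled contigs with a truth set
#'
#' A contig is a true positive iff its insert sequence exactly equals a
#' truth sequence (string identity, both sets deduplicated). Precision is
#' TP / (TP + FP) over assembled contigs, recall the fraction of truth
#' variants recovered.
#'
#' @param contigs A `contig_report`, `contig_set`, or character vector of
#'   insert sequences. For reports, only contigs with status `"passed"` are
#'   scored.
#' @param truth A `truth_set` or character vector of truth insert sequences.
#' @param near_miss Also compute, for each false positive, the minimum edit
#'   distance to any truth sequence (diagnostic; quadratic, off by default).
#' @return An `eval_report` list: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   and the per-contig match table.
#' @export
compare_to_truth <- function(contigs, truth, near_miss = FALSE) {
  cs <- contig_sequences(contigs)
  ts <- truth_sequences(truth)
  cs <- unique(cs)
  ts <- unique(ts)
  is_tp <- cs %in% ts
  tp <- sum(is_tp)
  fp <- sum(!is_tp)
  fn <- sum(!(ts %in% cs))
  tab <- data.frame(insert = cs, matched = is_tp, stringsAsFactors = FALSE)
  if (near_miss && fp > 0 && length(ts)) {
    d <- utils::adist(cs[!is_tp], ts)
    tab$min_edit_distance <- NA_integer_
    tab$min_edit_distance[!is_tp] <- apply(d, 1L, min)
  }
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 matches = tab),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("TP %d | FP %d | FN %d | precision %s | recall %s\n",
              x$tp, x$fp, x$fn, format(x$precision, digits = 4),
              format(x$recall, digits = 4)))
  invisible(x)
}

contig_sequences <- function(x) {
  if (inherits(x, "contig_report")) {
    ct <- x$contigs
    return(ct$insert[ct$status == "passed"])
  }
  if (inherits(x, "contig_set") || is.data.frame(x)) return(x$insert)
  as.character(x)
}
truth_sequences <- function(x) {
  if (inherits(x, "truth_set")) x$variants$insert else as.character(x)
}

#' Classify a contig as a functional variant
#'
#' A functional variant is an in-frame contig without mutations, such as
#' insertions or deletions, that would truncate the protein: its length must
#' be congruent to the design length mod 3, its translation must contain no
#' internal stop codon, and the translated length must equal the design
#' protein length.
#'
#' @param insert Contig insert DNA.
#' @param template The design `degenerate_template` (supplies the expected
#'   protein).
#' @return A `functional_call`: list with `functional` (logical) and
#'   `reasons` (subset of `frameshift`, `premature_stop`,
#'   `length_mismatch`; empty iff functional).
#' @export
classify_functional <- function(insert, template) {
  stopifnot(inherits(template, "degenerate_template"))
  ref_len <- nchar(template$dna)
  len <- nchar(insert)
  reasons <- character(0)
  if ((len - ref_len) %% 3L != 0L) {
    reasons <- c(reasons, "frameshift")
  } else {
    aa <- translate_dna(substr(insert, 1L, len - len %% 3L))
    body <- sub("\\*+$", "", aa)
    if (grepl("*", body, fixed = TRUE))
      reasons <- c(reasons, "premature_stop")
    if (len != ref_len)
      reasons <- c(reasons, "length_mismatch")
    else if (!length(reasons) && nchar(body) != nchar(template$protein))
      reasons <- c(reasons, "length_mismatch")
  }
  structure(list(functional = length(reasons) == 0L, reasons = reasons),
            class = "functional_call")
}

#' Fraction of functional variants in a contig report
#' @param contigs A `contig_report` or character vector of inserts.
#' @param template The design `degenerate_template`.
#' @export
functional_fraction <- function(contigs, template) {
  cs <- contig_sequences(contigs)
  if (!length(cs)) return(NA_real_)
  mean(vapply(cs, function(s) classify_functional(s, template)$functional,
              logical(1)))
}

#' Codon relative-adaptiveness weights for E. coli
#'
#' The bundled relative adaptiveness table (w per codon) derived from the
#' `seqinr` codon-usage compilation for *Escherichia coli*.
#' @return Named numeric vector, names are uppercase DNA codons.
#' @export
cai_weights_ecoli <- function() {
  e <- new.env()
  utils::data("caitab", package = "seqinr", envir = e)
  w <- e$caitab[["ec"]]
  setNames(w, toupper(rownames(e$caitab)))
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness w over the codons of a coding
#' sequence. Following the standard convention, stop codons and the
#' single-codon families ATG (Met) and TGG (Trp) are excluded, as are
#' zero-weight codons (with a warning).
#'
#' @param seq Coding DNA sequence (length a multiple of 3).
#' @param weights Named codon weight vector; defaults to
#'   [cai_weights_ecoli()].
#' @return CAI in (0, 1].
#' @export
compute_cai <- function(seq, weights = NULL) {
  if (nchar(seq) %% 3L != 0L) stop("sequence length is not a multiple of 3")
  weights <- weights %||% cai_weights_ecoli()
  codons <- substring(seq, seq(1L, nchar(seq) - 2L, 3L),
                      seq(3L, nchar(seq), 3L))
  codons <- toupper(codons)
  stops <- c("TAA", "TAG", "TGA")
  codons <- codons[!codons %in% c(stops, "ATG", "TGG")]
  w <- weights[codons]
  if (anyNA(w)) stop("codon(s) missing from the weight table: ",
                     paste(unique(codons[is.na(w)]), collapse = ", "))
  if (any(w == 0)) {
    warning(sum(w == 0), " zero-weight codon(s) excluded from CAI")
    w <- w[w > 0]
  }
  if (!length(w)) return(NA_real_)
  exp(mean(log(w)))
}

#' Depth-based enrichment ratios between two pools
#'
#' For contigs present in both reports, the ratio of normalised copy-number
#' shares after/before; contigs absent from the after pool get ratio 0.
#' Functionally selected clones are expected to show ratios above 1.
#'
#' @param pool_before,pool_after `contig_report`s (or data frames with
#'   `insert` and `copy_number`).
#' @return Data frame with `insert`, `share_before`, `share_after`, `ratio`.
#' @export
enrichment_ratio <- function(pool_before, pool_after) {
  tab <- function(x) {
    if (inherits(x, "contig_report")) {
      ct <- x$contigs[x$contigs$status == "passed", , drop = FALSE]
    } else ct <- x
    ct[, c("insert", "copy_number")]
  }
  b <- tab(pool_before)
  a <- tab(pool_after)
  b$share <- b$copy_number / sum(b$copy_number)
  a$share <- a$copy_number / sum(a$copy_number)
  m <- match(b$insert, a$insert)
  share_after <- ifelse(is.na(m), 0, a$share[m])
  data.frame(insert = b$insert, share_before = b$share,
             share_after = share_after,
             ratio = ifelse(b$share > 0, share_after / b$share, NA_real_),
             stringsAsFactors = FALSE)
}

#' Write an evaluation report
#' @param report An `eval_report`.
#' @param tsv,json Optional output paths for the match table / summary.
#' @export
write_eval_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    write.table(report$matches, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(report[c("tp", "fp", "fn", "precision", "recall")],
                         json, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
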