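# FASTA path / DNAStringSet / named character -> named character vector
.read_seqs <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    return(as.character(Biostrings::readDNAStringSet(genome)))
  if (inherits(genome, "DNAStringSet")) return(as.character(genome))
  nm <- names(genome)
  out <- as.character(genome)
  names(out) <- nm
  out
}

# N50: length at which cumulative sorted-descending lengths reach half the total
n50 <- function(lengths) {
  if (!length(lengths)) return(NA_real_)
  s <- sort(unname(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Assembly span, N50 and gap metrics with the >= 10-N splitting rule
#'
#' Scaffolds are the FASTA records; contigs are obtained by splitting each
#' scaffold at runs of 10 or more consecutive Ns (shorter N runs do not
#' split). Gap count and N span refer to the splitting runs.
#'
#' @param genome Path to a FASTA file, a `Biostrings::DNAStringSet`, or a
#'   named character vector of sequences.
#' @return Object of class `assembly_stats`: `span_bp`, `n_scaffolds`,
#'   `scaffold_n50`, `n_contigs`, `contig_n50`, `n_gaps`, `n_span_bp`,
#'   `contig_lengths`, `scaffold_lengths`.
#' @export
assembly_metrics <- function(genome) {
  seqs <- .read_seqs(genome)
  if (!length(seqs) || all(!nzchar(seqs))) stop("empty assembly")
  scaffold_lengths <- nchar(seqs)
  contig_lengths <- integer(0)
  n_gaps <- 0L
  n_span <- 0L
  for (s in seqs) {
    runs <- gregexpr("[Nn]{10,}", s)[[1]]
    if (runs[1] == -1L) {
      contig_lengths <- c(contig_lengths, nchar(s))
      next
    }
    gl <- attr(runs, "match.length")
    n_gaps <- n_gaps + length(runs)
    n_span <- n_span + as.integer(sum(gl))
    starts <- c(1L, runs + gl)
    ends <- c(runs - 1L, nchar(s))
    lens <- ends - starts + 1L
    contig_lengths <- c(contig_lengths, lens[lens > 0])
  }
  structure(list(span_bp = sum(scaffold_lengths),
                 n_scaffolds = length(seqs),
                 scaffold_n50 = n50(scaffold_lengths),
                 n_contigs = length(contig_lengths),
                 contig_n50 = n50(contig_lengths),
                 n_gaps = n_gaps,
                 n_span_bp = n_span,
                 contig_lengths = contig_lengths,
                 scaffold_lengths = scaffold_lengths),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly:", x$n_scaffolds, "scaffold(s),", x$span_bp, "bp;",
      "scaffold N50", x$scaffold_n50, "\n")
  cat("Contigs (split at >= 10 Ns):", x$n_contigs, "; contig N50",
      x$contig_n50, ";", x$n_gaps, "gap(s) spanning", x$n_span_bp, "bp\n")
  invisible(x)
}

#' Convert between Phred-scaled QV and bases-per-error
#'
#' QV = -10 log10(per-base error rate); bases per error = 10^(QV/10).
#'
#' @param value A QV score (for `"qv_to_bases"`) or a bases-per-error spacing
#'   (for `"bases_to_qv"`); must be positive.
#' @param direction `"qv_to_bases"` or `"bases_to_qv"`.
#' @return The converted value.
#' @examples
#' qv_error_conversion(36200, "bases_to_qv")  # 45.6 at 1 decimal
#' @export
qv_error_conversion <- function(value, direction = c("qv_to_bases", "bases_to_qv")) {
  direction <- match.arg(direction)
  if (any(value <= 0)) stop("value must be positive")
  if (direction == "qv_to_bases") {
    10^(value / 10)       # 1 / error rate
  } else {
    if (any(value < 1)) stop("bases-per-error must be >= 1")
    10 * log10(value)
  }
}

#' Estimate the true copy number of a collapsed tandem repeat from coverage
#'
#' Assemblers collapse tandem arrays (such as the rDNA cistron cluster); the
#' excess of read coverage inside the assembled region over the genome-wide
#' average estimates the true copy number: assembled copies x coverage ratio,
#' rounded to the nearest integer.
#'
#' @param region_coverage Mean read coverage inside the repeat region (> 0).
#' @param genomewide_coverage Genome- or chromosome-wide mean coverage (> 0).
#' @param assembled_copies Number of repeat units present in the assembly.
#' @return List `ratio` (coverage ratio) and `estimated_copies`.
#' @export
estimate_repeat_copy_number <- function(region_coverage, genomewide_coverage,
                                        assembled_copies) {
  if (genomewide_coverage <= 0) stop("genome-wide coverage must be positive")
  stopifnot(region_coverage > 0, assembled_copies > 0)
  ratio <- region_coverage / genomewide_coverage
  list(ratio = ratio,
       estimated_copies = round(assembled_copies * ratio))
}

# fraction of a window covered by (possibly tandem) matches of a motif,
# checked in both orientations
.motif_coverage <- function(window_seq, motifs) {
  nchar_w <- nchar(window_seq)
  if (nchar_w == 0) return(0)
  covered <- logical(nchar_w)
  for (mo in motifs) {
    hits <- gregexpr(mo, toupper(window_seq), fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    len <- attr(hits, "match.length")
    for (k in seq_along(hits))
      covered[hits[k]:(hits[k] + len[k] - 1)] <- TRUE
  }
  mean(covered)
}

#' Scan scaffold ends for telomeric repeat sequence
#'
#' An end is called telomeric when at least `min_fraction` of its terminal
#' window is covered by matches of the telomere motif (default the nematode
#' hexamer `TTAGGC`); both the forward motif and its reverse complement are
#' checked at each end. Scaffolds shorter than the window are scanned over
#' their full length with a warning.
#'
#' @param genome Path to FASTA, `DNAStringSet`, or named character vector.
#' @param motif Telomere repeat unit (default `"TTAGGC"`).
#' @param terminal_window_bp Window size at each end (default 1000).
#' @param min_fraction Coverage fraction required to call an end telomeric.
#' @return Data frame `scaffold`, `left_telomeric`, `right_telomeric`,
#'   `left_fraction`, `right_fraction`.
#' @export
telomere_scan <- function(genome, motif = "TTAGGC", terminal_window_bp = 1000,
                          min_fraction = 0.5) {
  stopifnot(nzchar(motif))
  seqs <- .read_seqs(genome)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  motifs <- unique(c(toupper(motif), rc))
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    w <- terminal_window_bp
    if (nchar(s) < w) {
      warning("scaffold ", nm[i], " shorter than the terminal window; window shrunk")
      w <- nchar(s)
    }
    lf <- .motif_coverage(substr(s, 1, w), motifs)
    rf <- .motif_coverage(substr(s, nchar(s) - w + 1, nchar(s)), motifs)
    data.frame(scaffold = nm[i],
               left_telomeric = lf >= min_fraction,
               right_telomeric = rf >= min_fraction,
               left_fraction = lf, right_fraction = rf)
  })
  do.call(rbind, rows)
}

# best hits per query: minimal e-value, ties by maximal bit score,
# exact ties all retained
.best_hits <- function(hits) {
  hits <- as.data.frame(hits)
  stopifnot(all(c("query_id", "subject_id", "e_value", "bit_score") %in% names(hits)))
  split_hits <- split(hits, hits$query_id)
  lapply(split_hits, function(h) {
    h <- h[h$e_value == min(h$e_value), , drop = FALSE]
    h <- h[h$bit_score == max(h$bit_score), , drop = FALSE]
    unique(h$subject_id)
  })
}

#' Reciprocal best hits between two proteomes
#'
#' Per query the best hit minimizes e-value with ties broken by maximal bit
#' score; exactly tied hits are all retained. A pair (a, b) is a reciprocal
#' best hit (RBH) iff b is among a's best hits and a is among b's best hits
#' (so sequences with multiple tied bests are reciprocal if any of their
#' hits are reciprocal).
#'
#' @param hits_ab,hits_ba Hit tables for the two search directions, with
#'   columns `query_id`, `subject_id`, `e_value`, `bit_score` and optionally
#'   `query_length`, `subject_length` (see [read_blast_tab()]).
#' @return Data frame of RBH pairs `a`, `b` and, when lengths are available,
#'   `len_a`, `len_b`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  best_ab <- .best_hits(hits_ab)
  best_ba <- .best_hits(hits_ba)
  pairs <- do.call(rbind, lapply(names(best_ab), function(a) {
    bs <- best_ab[[a]]
    keep <- vapply(bs, function(b) a %in% (best_ba[[b]] %||% character(0)),
                   logical(1))
    if (!any(keep)) return(NULL)
    data.frame(a = a, b = bs[keep])
  }))
  if (is.null(pairs)) pairs <- data.frame(a = character(0), b = character(0))
  hits_ab <- as.data.frame(hits_ab)
  if (all(c("query_length", "subject_length") %in% names(hits_ab)) && nrow(pairs)) {
    key <- paste(hits_ab$query_id, hits_ab$subject_id)
    idx <- match(paste(pairs$a, pairs$b), key)
    pairs$len_a <- hits_ab$query_length[idx]
    pairs$len_b <- hits_ab$subject_length[idx]
  }
  rownames(pairs) <- NULL
  pairs
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Protein-length concordance of reciprocal best hits
#'
#' Counts, at the gene level, queries with at least one reciprocal partner
#' (`total`), with an exactly length-matched partner (`exact`), and with a
#' partner within 5% of the reference-species protein length
#' (`|len_a - len_b| / len_b <= tolerance`, `len_b` the reference length).
#' A gene counts once if any of its reciprocal partners qualifies.
#'
#' @param rbh_pairs Data frame from [reciprocal_best_hits()] with `len_a`,
#'   `len_b` (lengths > 0; `len_b` is the reference-species length).
#' @param tolerance Relative length tolerance (default 0.05).
#' @return List `total`, `exact`, `within_tol`.
#' @export
protein_length_concordance <- function(rbh_pairs, tolerance = 0.05) {
  rbh_pairs <- as.data.frame(rbh_pairs)
  stopifnot(all(c("a", "len_a", "len_b") %in% names(rbh_pairs)),
            all(rbh_pairs$len_a > 0), all(rbh_pairs$len_b > 0))
  exact <- rbh_pairs$len_a == rbh_pairs$len_b
  within <- abs(rbh_pairs$len_a - rbh_pairs$len_b) / rbh_pairs$len_b <= tolerance
  list(total = length(unique(rbh_pairs$a)),
       exact = length(unique(rbh_pairs$a[exact])),
       within_tol = length(unique(rbh_pairs$a[within])))
}
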