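#' Amino-acid identity of a pairwise protein alignment
#'
#' Identity = matching columns / columns in which both rows carry a residue;
#' columns with a gap in either row are excluded from both numerator and
#' denominator.
#'
#' @param a,b Aligned sequences of equal length (character strings; `-` is
#'   the gap character).
#' @return Identity fraction in `[0, 1]`.
#' @export
protein_identity <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) stop("aligned sequences must have equal length")
  both <- ca != "-" & cb != "-"
  if (!any(both)) stop("no column has residues in both rows")
  sum(ca[both] == cb[both]) / sum(both)
}

#' Compute identities for a set of anchored alignments
#'
#' @param alignments Data frame with columns `orthogroup_id`, `seq_a`,
#'   `seq_b`, `chrom`, `pos_bp` (reference anchor: chromosome and gene start
#'   of the reference-species member).
#' @return The input with an added `identity` column.
#' @export
protein_identity_table <- function(alignments) {
  alignments <- as.data.frame(alignments)
  alignments$identity <- mapply(protein_identity,
                                alignments$seq_a, alignments$seq_b,
                                USE.NAMES = FALSE)
  alignments
}

#' Positionally smoothed amino-acid identity track
#'
#' Locally weighted linear regression (tricube weights, degree 1) of identity
#' against reference position per chromosome, the standard presentation of
#' ortholog divergence along a genome. Raw points are retained; chromosomes
#' with fewer than 10 points are emitted unsmoothed with a warning.
#'
#' @param identities Data frame with `chrom`, `pos_bp`, `identity`.
#' @param smoothing_span LOESS span as a fraction of points (default 0.3).
#' @return Data frame `chrom`, `pos_bp`, `identity`, `smoothed`.
#' @export
identity_track <- function(identities, smoothing_span = 0.3) {
  identities <- as.data.frame(identities)
  out <- lapply(unique(identities$chrom), function(ch) {
    sub <- identities[identities$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos_bp), , drop = FALSE]
    if (nrow(sub) < 10) {
      warning("chromosome ", ch, " has fewer than 10 points; raw values only")
      sub$smoothed <- NA_real_
      return(sub)
    }
    fit <- stats::loess(identity ~ pos_bp, data = sub, span = smoothing_span,
                        degree = 1, family = "gaussian")
    sub$smoothed <- stats::predict(fit, sub$pos_bp)
    sub
  })
  do.call(rbind, out)
}

#' SNV density per chromosome and chromosome class
#'
#' Computes SNV counts and mean spacing (bp per SNV = span / count) per
#' chromosome, and optionally per chromosome class (e.g., autosomes vs the X
#' chromosome) by aggregating counts and lengths before dividing.
#'
#' @param variants Data frame with columns `chrom` and `pos` (biallelic SNVs;
#'   see [read_biallelic_snvs()]).
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param classes Optional named character vector mapping chromosome ->
#'   class label.
#' @return List with data frames `per_chromosome` and (when `classes` is
#'   given) `per_class`, each with `n_snvs` and `bp_per_snv` (`NA` when the
#'   count is zero).
#' @export
snv_density <- function(variants, chrom_lengths, classes = NULL) {
  variants <- as.data.frame(variants)
  stopifnot(!is.null(names(chrom_lengths)))
  counts <- table(factor(variants$chrom, levels = names(chrom_lengths)))
  per_chrom <- data.frame(chrom = names(chrom_lengths),
                          length_bp = as.numeric(chrom_lengths),
                          n_snvs = as.integer(counts),
                          row.names = NULL)
  per_chrom$bp_per_snv <- ifelse(per_chrom$n_snvs > 0,
                                 per_chrom$length_bp / per_chrom$n_snvs, NA_real_)
  out <- list(per_chromosome = per_chrom)
  if (!is.null(classes)) {
    stopifnot(all(names(chrom_lengths) %in% names(classes)))
    cl <- classes[per_chrom$chrom]
    agg_len <- tapply(per_chrom$length_bp, cl, sum)
    agg_n <- tapply(per_chrom$n_snvs, cl, sum)
    out$per_class <- data.frame(class = names(agg_len),
                                length_bp = as.numeric(agg_len),
                                n_snvs = as.integer(agg_n),
                                bp_per_snv = ifelse(agg_n > 0,
                                                    as.numeric(agg_len) / as.numeric(agg_n),
                                                    NA_real_),
                                row.names = NULL)
  }
  out
}

#' Filter structural variants to large inversions
#'
#' Keeps records of type `INV` with length at least `min_len_bp` (default
#' 50 kb; rerun with another threshold for secondary cutoffs such as 100 kb)
#' and reports their count and mean length.
#'
#' @param svs Data frame with columns `chrom`, `start`, `end`, `type` and
#'   optionally `length_bp` (computed as `end - start` when absent).
#' @param min_len_bp Minimum inversion length in bp.
#' @return List `count`, `mean_length_bp`, `records`.
#' @export
filter_inversions <- function(svs, min_len_bp = 50000) {
  svs <- as.data.frame(svs)
  if (!nrow(svs))
    return(list(count = 0L, mean_length_bp = NA_real_, records = svs))
  if (!"length_bp" %in% names(svs)) svs$length_bp <- svs$end - svs$start
  keep <- svs$type == "INV" & svs$length_bp >= min_len_bp
  rec <- svs[keep, , drop = FALSE]
  list(count = nrow(rec),
       mean_length_bp = if (nrow(rec)) mean(rec$length_bp) else NA_real_,
       records = rec)
}
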