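#' Read and write RIL genotype matrices and marker tables
#'
#' Genotype CSV: first column the line ID, remaining columns marker IDs,
#' cells in `P1`/`P2`/`HET`/`NA`. Marker CSV: `marker_id`, `chrom`, `pos_bp`
#' (1-based).
#'
#' @param path File path.
#' @return `read_genotypes()` returns a line x marker character matrix;
#'   `read_markers()` a data frame.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  bad <- !(m %in% c("P1", "P2", "HET") | is.na(m))
  if (any(bad)) stop("genotype cells must be P1, P2, HET or NA")
  m
}

#' @rdname read_genotypes
#' @param genotypes Line x marker character matrix.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(line_id = rownames(genotypes), genotypes,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname read_genotypes
#' @export
read_markers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("marker_id", "chrom", "pos_bp") %in% names(df)))
  df
}

#' @rdname read_genotypes
#' @param markers Marker data frame.
#' @export
write_markers <- function(markers, path) {
  utils::write.csv(markers[, c("marker_id", "chrom", "pos_bp")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read and write allele-count matrices
#'
#' CSV layout: first column the line ID, then paired columns
#' `<marker>_P1`, `<marker>_P2` of read counts.
#'
#' @param path File path.
#' @return An `allele_counts` object.
#' @export
read_allele_counts <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- names(df)[-1]
  m1 <- grep("_P1$", cols, value = TRUE)
  markers <- sub("_P1$", "", m1)
  if (!all(paste0(markers, "_P2") %in% cols))
    stop("every marker needs paired <marker>_P1 and <marker>_P2 columns")
  p1 <- as.matrix(df[, paste0(markers, "_P1"), drop = FALSE])
  p2 <- as.matrix(df[, paste0(markers, "_P2"), drop = FALSE])
  dimnames(p1) <- dimnames(p2) <- list(df[[1]], markers)
  structure(list(p1 = p1, p2 = p2), class = "allele_counts")
}

#' @rdname read_allele_counts
#' @param counts An `allele_counts` object.
#' @export
write_allele_counts <- function(counts, path) {
  markers <- colnames(counts$p1)
  out <- data.frame(line_id = rownames(counts$p1), check.names = FALSE)
  for (m in markers) {
    out[[paste0(m, "_P1")]] <- counts$p1[, m]
    out[[paste0(m, "_P2")]] <- counts$p2[, m]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a genetic map or filter report as TSV
#'
#' @param map A `genetic_map` object.
#' @param path File path.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(map$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genetic_map
#' @param report A `filter_report`.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report$removed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an OrthoFinder-style orthogroup table
#'
#' Tab-separated `Orthogroups.tsv` dialect: first column the orthogroup ID,
#' one column per species, gene IDs comma-separated within cells.
#'
#' @param path File path.
#' @return Data frame (one column per species, character cells).
#' @export
read_orthogroups <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' @rdname read_orthogroups
#' @param orthogroups Orthogroup data frame.
#' @export
write_orthogroups <- function(orthogroups, path) {
  utils::write.table(orthogroups, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write simulated gene tables as GFF3 (gene features only)
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start_bp`, `end_bp`,
#'   `strand`), 1-based inclusive coordinates.
#' @param path File path.
#' @param source Value for the GFF3 source column.
#' @export
write_gene_gff3 <- function(genes, path, source = "selfsynt") {
  genes <- as.data.frame(genes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, source, as.integer(genes$start_bp),
                     as.integer(genes$end_bp), genes$strand, genes$gene_id),
             con)
  invisible(path)
}

#' Read biallelic SNVs from a VCF
#'
#' Keeps records whose REF and ALT are single nucleotides with a single ALT
#' allele.
#'
#' @param path VCF file path (plain or bgzipped).
#' @return Data frame `chrom`, `pos`, `ref`, `alt`.
#' @export
read_biallelic_snvs <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 & !grepl(",", fix$ALT)
  data.frame(chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
             ref = fix$REF[keep], alt = fix$ALT[keep])
}

#' Read a BLAST outfmt-6-style tabular hit file
#'
#' Expects (at least) the columns qseqid, sseqid, evalue, bitscore and
#' optionally qlen, slen, in that order or named in a header.
#'
#' @param path File path.
#' @param col_names Column names when the file has no header.
#' @return Data frame with `query_id`, `subject_id`, `e_value`, `bit_score`
#'   and, when present, `query_length`, `subject_length`.
#' @export
read_blast_tab <- function(path,
                           col_names = c("qseqid", "sseqid", "evalue",
                                         "bitscore", "qlen", "slen")) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- col_names[seq_len(ncol(df))]
  out <- data.frame(query_id = df$qseqid, subject_id = df$sseqid,
                    e_value = as.numeric(df$evalue),
                    bit_score = as.numeric(df$bitscore))
  if (!is.null(df$qlen)) out$query_length <- as.numeric(df$qlen)
  if (!is.null(df$slen)) out$subject_length <- as.numeric(df$slen)
  out
}

#' Read a structural-variant table and a chromosome-length table
#'
#' SV TSV columns: `chrom`, `start`, `end`, `type` (INV/DEL/INS/DUP/...).
#' Chromosome-length TSV columns: `chrom`, `length_bp`.
#'
#' @param path File path.
#' @return Data frame (`read_sv_table`) or named numeric vector
#'   (`read_chrom_lengths`).
#' @export
read_sv_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "type") %in% names(df)))
  df
}

#' @rdname read_sv_table
#' @export
read_chrom_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "length_bp") %in% names(df)))
  stats::setNames(as.numeric(df$length_bp), df$chrom)
}

#' Read a multi-pair aligned protein FASTA
#'
#' A combined file of pairwise alignments: two records per orthogroup with
#' headers `<orthogroup>|<species>|<chrom>|<start_bp>`.
#'
#' @param path Aligned FASTA path.
#' @param ref_species Species whose coordinates anchor each pair.
#' @return Data frame suitable for [protein_identity_table()].
#' @export
read_alignment_pairs <- function(path, ref_species) {
  aln <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(aln), "|", fixed = TRUE)
  meta <- data.frame(orthogroup_id = vapply(parts, `[`, "", 1),
                     species = vapply(parts, `[`, "", 2),
                     chrom = vapply(parts, `[`, "", 3),
                     start_bp = as.numeric(vapply(parts, `[`, "", 4)),
                     seq = as.character(aln))
  rows <- lapply(split(meta, meta$orthogroup_id), function(g) {
    if (nrow(g) != 2) stop("orthogroup ", g$orthogroup_id[1],
                           " does not have exactly two aligned sequences")
    ref <- g[g$species == ref_species, ]
    oth <- g[g$species != ref_species, ]
    if (nrow(ref) != 1) stop("orthogroup ", g$orthogroup_id[1],
                             " lacks the reference species")
    data.frame(orthogroup_id = ref$orthogroup_id, seq_a = ref$seq,
               seq_b = oth$seq, chrom = ref$chrom, pos_bp = ref$start_bp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
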