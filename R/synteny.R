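#' Extract the representative (longest) isoform per protein-coding gene
#'
#' Parses a GFF3 gene -> mRNA -> CDS hierarchy and keeps, per gene, the mRNA
#' with the greatest summed CDS length (ties broken by lexicographic isoform
#' ID). Genes without any CDS are excluded. Orphan mRNAs (no gene parent)
#' trigger a warning and are treated as their own gene.
#'
#' @param gff Path to a GFF3 file, or a data frame as returned by
#'   `rtracklayer::readGFF` (columns `seqid`, `type`, `start`, `end`,
#'   `strand`, `ID`, `Parent`).
#' @return Data frame of gene records: `gene_id`, `chrom`, `start_bp`,
#'   `end_bp`, `strand`, `representative_isoform_id`, `cds_length`.
#' @export
extract_longest_isoforms <- function(gff) {
  df <- if (is.character(gff)) {
    as.data.frame(rtracklayer::readGFF(gff))
  } else {
    as.data.frame(gff)
  }
  stopifnot(all(c("seqid", "type", "start", "end", "strand", "ID", "Parent") %in%
                  names(df)))
  parent1 <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  genes <- df[df$type == "gene", , drop = FALSE]
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  mrna_parent <- parent1[df$type %in% c("mRNA", "transcript")]
  orphan <- is.na(mrna_parent) | !(mrna_parent %in% genes$ID)
  if (any(orphan)) {
    warning(sum(orphan), " mRNA record(s) without a gene parent; treated as their own gene")
    mrna_parent[orphan] <- mrna$ID[orphan]
  }
  cds_parent <- parent1[df$type == "CDS"]
  cds_len <- tapply((cds$end - cds$start + 1), cds_parent, sum)
  mrna_cds <- cds_len[mrna$ID]
  keep <- !is.na(mrna_cds)
  if (!any(keep))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      strand = character(0),
                      representative_isoform_id = character(0),
                      cds_length = integer(0)))
  tab <- data.frame(gene_id = mrna_parent[keep],
                    isoform_id = as.character(mrna$ID[keep]),
                    cds_length = as.integer(mrna_cds[keep]))
  # longest CDS wins; lexicographic isoform ID breaks ties
  tab <- tab[order(tab$gene_id, -tab$cds_length, tab$isoform_id), ]
  tab <- tab[!duplicated(tab$gene_id), ]
  gene_rows <- rbind(
    genes[, c("ID", "seqid", "start", "end", "strand")],
    mrna[orphan, c("ID", "seqid", "start", "end", "strand")])
  idx <- match(tab$gene_id, gene_rows$ID)
  out <- data.frame(gene_id = tab$gene_id,
                    chrom = as.character(gene_rows$seqid[idx]),
                    start_bp = gene_rows$start[idx],
                    end_bp = gene_rows$end[idx],
                    strand = as.character(gene_rows$strand[idx]),
                    representative_isoform_id = tab$isoform_id,
                    cds_length = tab$cds_length)
  out[order(out$chrom, out$start_bp), ]
}

#' Rank single-copy orthologs along each chromosome
#'
#' Keeps orthogroups with exactly one gene in every included species and
#' assigns each retained gene an ordinal rank along its chromosome (by
#' `start_bp`, among retained genes only). The ranks are the substrate of
#' the collinearity statistic.
#'
#' @param orthogroups Data frame in the OrthoFinder `Orthogroups.tsv` layout:
#'   first column the orthogroup ID, then one column per species with
#'   comma-separated gene IDs (see [read_orthogroups()]).
#' @param gene_tables Named list of per-species gene tables
#'   (as from [extract_longest_isoforms()] or the simulator).
#' @param species Species (column names) to include; defaults to all species
#'   with a gene table.
#' @return Data frame of class `ortholog_ranks`: `orthogroup_id`, `species`,
#'   `gene_id`, `chrom`, `start_bp`, `rank`.
#' @export
rank_single_copy_orthologs <- function(orthogroups, gene_tables,
                                       species = names(gene_tables)) {
  og <- as.data.frame(orthogroups)
  stopifnot(all(species %in% names(og)), all(species %in% names(gene_tables)))
  split_cell <- function(cell) {
    if (is.na(cell) || !nzchar(cell)) return(character(0))
    trimws(strsplit(cell, ",")[[1]])
  }
  counts <- sapply(species, function(sp)
    vapply(og[[sp]], function(cell) length(split_cell(cell)), integer(1)))
  single <- rowSums(matrix(counts == 1L, nrow = nrow(og))) == length(species)
  og <- og[single, , drop = FALSE]
  rows <- lapply(species, function(sp) {
    gt <- as.data.frame(gene_tables[[sp]])
    ids <- vapply(og[[sp]], function(cell) split_cell(cell)[1], character(1))
    idx <- match(ids, gt$gene_id)
    if (anyNA(idx))
      stop("gene(s) absent from the ", sp, " gene table: ",
           paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
    data.frame(orthogroup_id = og[[1]], species = sp, gene_id = ids,
               chrom = gt$chrom[idx], start_bp = gt$start_bp[idx])
  })
  out <- do.call(rbind, rows)
  out$rank <- stats::ave(out$start_bp, out$species, out$chrom,
                         FUN = function(p) rank(p, ties.method = "first"))
  out <- out[order(out$species, out$chrom, out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("ortholog_ranks", class(out))
  out
}

#' Score gene-order collinearity between two species
#'
#' The neighboring-gene-pair statistic used to compare rearrangement between
#' genomes: for every pair of rank-adjacent single-copy orthologs in the
#' reference species, the pair is collinear iff the two target orthologs lie
#' on the same target chromosome and their ordinal ranks differ by exactly 1
#' (orientation-agnostic). Also reports the proportion of collinear pairs in
#' nonoverlapping windows (pairs assigned by the mean of the two reference
#' genes' start positions), maximal blocks of consecutive collinear pairs,
#' per-chromosome percentages, and the genome-wide percentage.
#'
#' @param ranks An `ortholog_ranks` table containing both species.
#' @param ref_species,target_species Species labels.
#' @param window_bp Window width (default 500 kb, anchored at 0).
#' @return Object of class `synteny_profile`: `pairs`, `windows`, `blocks`,
#'   `chromosomes`, `genome_pct_collinear`, and the species labels.
#' @export
score_collinearity <- function(ranks, ref_species, target_species,
                               window_bp = 500000) {
  stopifnot(all(c(ref_species, target_species) %in% ranks$species))
  ref <- ranks[ranks$species == ref_species, , drop = FALSE]
  tgt <- ranks[ranks$species == target_species, , drop = FALSE]
  ti <- match(ref$orthogroup_id, tgt$orthogroup_id)
  ref$t_chrom <- tgt$chrom[ti]
  ref$t_rank <- tgt$rank[ti]
  pairs <- lapply(unique(ref$chrom), function(ch) {
    sub <- ref[ref$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    if (nrow(sub) < 2) return(NULL)
    i <- seq_len(nrow(sub) - 1)
    data.frame(chrom = ch,
               left_gene = sub$gene_id[i], right_gene = sub$gene_id[i + 1],
               left_rank = sub$rank[i],
               mid_bp = (sub$start_bp[i] + sub$start_bp[i + 1]) / 2,
               collinear = sub$t_chrom[i] == sub$t_chrom[i + 1] &
                 abs(sub$t_rank[i + 1] - sub$t_rank[i]) == 1)
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) stop("no chromosome contributes a neighbor pair")
  pairs$window_start <- floor(pairs$mid_bp / window_bp) * window_bp
  windows <- stats::aggregate(collinear ~ chrom + window_start, data = pairs,
                              FUN = function(z) mean(z))
  names(windows)[3] <- "prop_collinear"
  nwin <- stats::aggregate(collinear ~ chrom + window_start, data = pairs, FUN = length)
  windows$n_pairs <- nwin$collinear
  windows <- windows[order(windows$chrom, windows$window_start), ]
  blocks <- lapply(unique(pairs$chrom), function(ch) {
    sub <- pairs[pairs$chrom == ch, , drop = FALSE]
    r <- rle(sub$collinear)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (!length(keep)) return(NULL)
    data.frame(chrom = ch,
               start_rank = sub$left_rank[starts[keep]],
               n_pairs = r$lengths[keep],
               gene_count = r$lengths[keep] + 1L)
  })
  blocks <- do.call(rbind, blocks)
  if (is.null(blocks))
    blocks <- data.frame(chrom = character(0), start_rank = integer(0),
                         n_pairs = integer(0), gene_count = integer(0))
  chroms <- stats::aggregate(collinear ~ chrom, data = pairs,
                             FUN = function(z) 100 * mean(z))
  names(chroms)[2] <- "pct_collinear"
  chroms$n_pairs <- as.integer(table(pairs$chrom)[chroms$chrom])
  structure(list(pairs = pairs, windows = windows, blocks = blocks,
                 chromosomes = chroms,
                 genome_pct_collinear = 100 * mean(pairs$collinear),
                 ref_species = ref_species, target_species = target_species,
                 window_bp = window_bp),
            class = "synteny_profile")
}

#' @export
print.synteny_profile <- function(x, ...) {
  cat("Collinearity of", x$target_species, "orthologs along", x$ref_species,
      "neighbor pairs\n")
  cat(sprintf("  genome: %.1f%% collinear (%d pairs)\n",
              x$genome_pct_collinear, nrow(x$pairs)))
  print(x$chromosomes, row.names = FALSE)
  invisible(x)
}

#' @export
summary.synteny_profile <- function(object, ...) {
  data.frame(chrom = c(object$chromosomes$chrom, "genome"),
             pct_collinear = c(object$chromosomes$pct_collinear,
                               object$genome_pct_collinear),
             n_pairs = c(object$chromosomes$n_pairs, nrow(object$pairs)))
}

#' @export
plot.synteny_profile <- function(x, ...) {
  w <- x$windows
  chroms <- unique(w$chrom)
  old <- graphics::par(mfrow = c(1, length(chroms)))
  on.exit(graphics::par(old))
  for (ch in chroms) {
    sub <- w[w$chrom == ch, ]
    graphics::plot(sub$window_start / 1e6, sub$prop_collinear, type = "h",
                   ylim = c(0, 1), xlab = "Window start (Mb)",
                   ylab = "Proportion collinear", main = ch, ...)
  }
  invisible(x)
}

#' Compare collinearity profiles between labeled species sets
#'
#' Tabulates per-chromosome and genome-wide percent collinearity for several
#' profiles (e.g., a selfing pair vs an outcrossing pair), the difference
#' between two labeled sets if exactly two labels are given, and the largest
#' collinear blocks per profile.
#'
#' @param profiles List of `synteny_profile` objects.
#' @param labels Character vector, one label per profile.
#' @param n_blocks Number of largest blocks to list per profile.
#' @return List with `table` (chromosome x profile percent collinear; rows
#'   joined on shared chromosomes), `difference` (label-set means and their
#'   difference, when two labels are present), and `largest_blocks`.
#' @export
compare_species_sets <- function(profiles, labels, n_blocks = 3) {
  stopifnot(length(profiles) >= 1, length(labels) == length(profiles))
  chrom_sets <- lapply(profiles, function(p) p$chromosomes$chrom)
  shared <- Reduce(intersect, chrom_sets)
  if (any(vapply(chrom_sets, function(s) length(setdiff(s, shared)) > 0, logical(1))))
    warning("chromosome name mismatch between profiles; joining on shared chromosomes")
  tab <- data.frame(chrom = c(shared, "genome"))
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    v <- p$chromosomes$pct_collinear[match(shared, p$chromosomes$chrom)]
    tab[[paste0(labels[k], ".", p$ref_species, "_vs_", p$target_species)]] <-
      c(v, p$genome_pct_collinear)
  }
  diff_tab <- NULL
  if (length(unique(labels)) == 2 && length(profiles) >= 2) {
    u <- unique(labels)
    m1 <- rowMeans(tab[, -1, drop = FALSE][, labels == u[1], drop = FALSE])
    m2 <- rowMeans(tab[, -1, drop = FALSE][, labels == u[2], drop = FALSE])
    diff_tab <- data.frame(chrom = tab$chrom, m1, m2, difference = m1 - m2)
    names(diff_tab)[2:3] <- u
  }
  lb <- lapply(seq_along(profiles), function(k) {
    b <- profiles[[k]]$blocks
    b <- b[order(-b$gene_count), , drop = FALSE]
    b <- utils::head(b, n_blocks)
    if (nrow(b)) b$profile <- labels[k]
    b
  })
  list(table = tab, difference = diff_tab,
       largest_blocks = do.call(rbind, lb))
}

#' Patristic distance between two taxa in a phylogeny
#'
#' Sum of branch lengths on the unique path between two leaves (for the
#' published nematode phylogenies used here, branch lengths are amino-acid
#' substitutions per site).
#'
#' @param tree An `ape::phylo` object, a newick file path, or a newick string.
#' @param species_a,species_b Tip labels.
#' @return Patristic distance (numeric scalar).
#' @export
patristic_distance <- function(tree, species_a, species_b) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(c(species_a, species_b), tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (species_a == species_b) return(0)
  d <- ape::cophenetic.phylo(tree)
  unname(d[species_a, species_b])
}
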