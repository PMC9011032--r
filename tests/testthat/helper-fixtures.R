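# Shared fixtures and independent oracles, built in code at test time.

# a paper-like five-domain chromosome landscape (chromosome I geometry)
chrom1_landscape <- function() {
  rec_landscape(15541e3, c(388e3, 3191e3, 11208e3, 14970e3),
                c(0, 8.43, 0.40, 7.63, 0))
}

# genotype matrix with prescribed per-marker P1/P2 counts (no HET/NA)
geno_from_counts <- function(n_lines, p1_counts, marker_ids = NULL) {
  m <- length(p1_counts)
  if (is.null(marker_ids)) marker_ids <- sprintf("m%02d", seq_len(m))
  g <- vapply(p1_counts, function(k)
    c(rep("P1", k), rep("P2", n_lines - k)), character(n_lines))
  dimnames(g) <- list(sprintf("L%03d", seq_len(n_lines)), marker_ids)
  g
}

marker_table <- function(chrom, pos_bp, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("m%02d", seq_along(pos_bp))
  data.frame(marker_id = ids, chrom = chrom, pos_bp = pos_bp)
}

# --- independent oracles -----------------------------------------------------

# exhaustive-grid oracle for the two-breakpoint segmented fit: all pairs of
# marker positions between the 3rd and 3rd-from-last points, plain lm per pair
grid_segmented_rss <- function(x, y) {
  n <- length(x)
  cand <- x[x >= x[3] & x <= x[n - 2]]
  best <- Inf
  for (b1 in cand) for (b2 in cand) {
    if (b2 <= b1) next
    fit <- lm(y ~ x + pmax(x - b1, 0) + pmax(x - b2, 0))
    rss <- sum(resid(fit)^2)
    if (rss < best) best <- rss
  }
  best
}

# exact 2-state HMM posterior by brute-force path enumeration
hmm_posterior_enum <- function(n1, n2, q, error_rate) {
  m <- length(n1)
  emis <- function(state, t)
    if (state == 1) (1 - error_rate)^n1[t] * error_rate^n2[t]
    else error_rate^n1[t] * (1 - error_rate)^n2[t]
  paths <- as.matrix(expand.grid(rep(list(1:2), m)))
  pr <- apply(paths, 1, function(s) {
    p <- 0.5 * emis(s[1], 1)
    for (t in seq_len(m - 1)) {
      p <- p * (if (s[t] == s[t + 1]) 1 - q[t] else q[t]) * emis(s[t + 1], t + 1)
    }
    p
  })
  # posterior P(state = P1) per position
  vapply(seq_len(m), function(t) sum(pr[paths[, t] == 1]) / sum(pr), numeric(1))
}

# brute-force neighbor-pair collinearity count from two gene orders
# (list of per-chromosome ID vectors per species)
enumerate_noncollinear <- function(order_a, order_b) {
  rank_b <- list()
  for (ch in names(order_b)) {
    ids <- order_b[[ch]]
    rank_b[ids] <- lapply(seq_along(ids), function(i) list(chrom = ch, rank = i))
  }
  bad <- 0L; total <- 0L
  for (ch in names(order_a)) {
    ids <- order_a[[ch]]
    if (length(ids) < 2) next
    for (i in seq_len(length(ids) - 1)) {
      total <- total + 1L
      u <- rank_b[[ids[i]]]; v <- rank_b[[ids[i + 1]]]
      if (u$chrom != v$chrom || abs(u$rank - v$rank) != 1) bad <- bad + 1L
    }
  }
  list(noncollinear = bad, total = total)
}

# gene orders (per-chromosome ID vectors) from a simulator gene table
gene_orders <- function(gene_table, orthogroups, species_col) {
  # map gene ids to orthogroup ids so both species share a vocabulary
  og_of <- setNames(orthogroups$orthogroup_id, orthogroups[[species_col]])
  tab <- gene_table[order(gene_table$chrom, gene_table$start_bp), ]
  split(unname(og_of[tab$gene_id]), tab$chrom)
}

write_toy_gff3 <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}
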