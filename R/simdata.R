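#' Piecewise recombination landscape
#'
#' Defines the "tips / arms / center" recombination-rate structure of a
#' holocentric nematode chromosome as a piecewise-constant rate (cM/Mb) over
#' physical position. The landscape is the generative truth for
#' [simulate_ril_panel()] and the reference for map- and domain-recovery tests.
#'
#' @param chrom_length_bp Chromosome length in bp.
#' @param domain_bounds_bp Ordered interior breakpoints, strictly increasing and
#'   strictly inside `(0, chrom_length_bp)`. For the canonical five-domain
#'   layout these are the tip/arm, arm/center, center/arm and arm/tip bounds.
#' @param domain_rates_cM_per_Mb One nonnegative rate per domain
#'   (`length(domain_bounds_bp) + 1` values). Tip rates may be 0.
#' @return An object of class `rec_landscape`.
#' @examples
#' land <- rec_landscape(15541e3, c(388e3, 3191e3, 11208e3, 14970e3),
#'                       c(0, 8.43, 0.40, 7.63, 0))
#' landscape_total_cM(land)
#' @export
rec_landscape <- function(chrom_length_bp, domain_bounds_bp, domain_rates_cM_per_Mb) {
  stopifnot(length(chrom_length_bp) == 1L, chrom_length_bp > 0)
  b <- as.numeric(domain_bounds_bp)
  r <- as.numeric(domain_rates_cM_per_Mb)
  if (length(r) != length(b) + 1L)
    stop("need one rate per domain: length(rates) must be length(bounds) + 1")
  if (any(diff(b) <= 0) || any(b <= 0) || any(b >= chrom_length_bp))
    stop("domain bounds must be strictly increasing and inside (0, chrom_length_bp)")
  if (any(r < 0)) stop("domain rates must be nonnegative")
  nodes <- c(0, b, chrom_length_bp)
  # cumulative genetic position (cM) at each node
  cum <- c(0, cumsum(diff(nodes) / 1e6 * r))
  structure(list(chrom_length_bp = chrom_length_bp,
                 domain_bounds_bp = b,
                 domain_rates_cM_per_Mb = r,
                 nodes_bp = nodes,
                 nodes_cM = cum),
            class = "rec_landscape")
}

#' @rdname rec_landscape
#' @param landscape A `rec_landscape`.
#' @export
landscape_total_cM <- function(landscape) {
  stopifnot(inherits(landscape, "rec_landscape"))
  landscape$nodes_cM[length(landscape$nodes_cM)]
}

#' Genetic position (cM) at physical positions under a landscape
#'
#' @param landscape A `rec_landscape`.
#' @param pos_bp Physical positions (bp), clamped to `[0, chrom_length_bp]`.
#' @return Genetic positions in cM measured from the chromosome's left end.
#' @export
landscape_cM_at <- function(landscape, pos_bp) {
  stopifnot(inherits(landscape, "rec_landscape"))
  x <- pmin(pmax(as.numeric(pos_bp), 0), landscape$chrom_length_bp)
  i <- findInterval(x, landscape$nodes_bp, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(landscape$nodes_bp) - 1L)
  rate <- c(landscape$domain_rates_cM_per_Mb)
  landscape$nodes_cM[i] + (x - landscape$nodes_bp[i]) / 1e6 * rate[i]
}

# inverse of landscape_cM_at restricted to positive-rate segments
landscape_bp_at_cM <- function(landscape, cm) {
  nodes <- landscape$nodes_bp
  cum <- landscape$nodes_cM
  rate <- landscape$domain_rates_cM_per_Mb
  i <- findInterval(cm, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(nodes) - 1L)
  # a uniform draw in (0, total cM) lands in zero-rate segments with prob 0;
  # guard division anyway
  out <- nodes[i] + ifelse(rate[i] > 0, (cm - cum[i]) / rate[i] * 1e6, 0)
  pmin(pmax(out, 0), landscape$chrom_length_bp)
}

# one round of gametogenesis for a whole population on one chromosome.
# o1, o2: n_lines x n_markers integer matrices of parental origin (1 = P1, 2 = P2).
# Returns list(g = gamete origin matrix, xo = data.frame(line, pos_bp)).
.gamete_population <- function(o1, o2, landscape, marker_pos) {
  n <- nrow(o1)
  total_cM <- landscape_total_cM(landscape)
  n_xo <- stats::rpois(n, total_cM / 100)
  start <- sample.int(2L, n, replace = TRUE)
  g <- o1
  g[start == 2L, ] <- o2[start == 2L, , drop = FALSE]
  xo_line <- integer(0); xo_pos <- numeric(0)
  for (i in which(n_xo > 0L)) {
    xo <- sort(landscape_bp_at_cM(landscape, stats::runif(n_xo[i], 0, total_cM)))
    k <- findInterval(marker_pos, xo)
    use_first <- ((start[i] - 1L + k) %% 2L) == 0L
    g[i, ] <- ifelse(use_first, o1[i, ], o2[i, ])
    xo_line <- c(xo_line, rep.int(i, length(xo)))
    xo_pos <- c(xo_pos, xo)
  }
  list(g = g, xo = data.frame(line = xo_line, pos_bp = xo_pos))
}

#' Simulate a selfed recombinant inbred line (RIL) genotype panel
#'
#' Simulates a two-parent RIL panel the way such panels are built in the lab:
#' every line starts as a genome-wide F1 heterozygote, an F2 individual is
#' formed by the union of two F1 gametes, and the line is then self-fertilized
#' for `selfing_generations` rounds by explicit two-homolog gametogenesis.
#' Crossovers per meiosis per chromosome are Poisson with mean equal to the
#' landscape's genetic length in Morgans (no interference), with positions
#' drawn in proportion to the local recombination rate. Residual heterozygous
#' sites at the end are emitted as `HET`.
#'
#' @param landscapes Named list of [rec_landscape()] objects, one per chromosome.
#' @param markers Data frame with columns `marker_id`, `chrom`, `pos_bp`
#'   (1-based), sorted by position within each chromosome.
#' @param n_lines Number of RILs.
#' @param selfing_generations Rounds of self-fertilization after the F2 (>= 1).
#' @param genotyping_error Probability that a homozygous call is flipped
#'   P1 <-> P2 after simulation.
#' @param missing_rate Probability that any call is replaced by `NA`,
#'   applied independently.
#' @param artifacts Optional data frame of planted marker artifacts with
#'   columns `marker_id` and `kind` (one of `"distorted"`, `"freq_spike"`,
#'   `"unlinked"`) and optionally `magnitude`. Defaults: `distorted` redraws
#'   each line's call as P1 with probability `magnitude` (0.85); `freq_spike`
#'   forces a `magnitude` (0.15) fraction of lines to P1; `unlinked` redraws
#'   calls iid 50/50. Artifacts are applied after the true genotypes are
#'   recorded, before genotyping error and missingness.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `ril_panel` with elements `genotypes` (line x
#'   marker character matrix in `P1`/`P2`/`HET`/`NA`), `markers`, and `truth`
#'   (class `sim_truth`: `true_genotypes`, `crossovers` per chromosome,
#'   `planted_artifacts`).
#' @export
simulate_ril_panel <- function(landscapes, markers, n_lines,
                               selfing_generations = 10,
                               genotyping_error = 0, missing_rate = 0,
                               artifacts = NULL, seed) {
  stopifnot(n_lines >= 1, selfing_generations >= 1,
            genotyping_error >= 0, genotyping_error <= 1,
            missing_rate >= 0, missing_rate <= 1)
  markers <- as.data.frame(markers)
  stopifnot(all(c("marker_id", "chrom", "pos_bp") %in% names(markers)))
  if (anyDuplicated(markers$marker_id)) stop("marker_id values must be unique")
  chroms <- unique(markers$chrom)
  if (!all(chroms %in% names(landscapes)))
    stop("every marker chromosome needs a landscape")
  for (ch in chroms) {
    if (is.unsorted(markers$pos_bp[markers$chrom == ch], strictly = FALSE))
      stop("marker positions must be sorted within each chromosome")
  }
  totals <- vapply(landscapes[chroms], landscape_total_cM, numeric(1))
  if (all(totals <= 0))
    stop("zero total genetic length on every chromosome: no recombination model")
  if (!is.null(artifacts)) {
    artifacts <- as.data.frame(artifacts)
    stopifnot(all(c("marker_id", "kind") %in% names(artifacts)))
    bad <- setdiff(artifacts$marker_id, markers$marker_id)
    if (length(bad)) stop("artifact references unknown marker(s): ",
                          paste(bad, collapse = ", "))
    if (!all(artifacts$kind %in% c("distorted", "freq_spike", "unlinked")))
      stop("unknown artifact kind")
  }
  set.seed(seed)
  line_ids <- sprintf("RIL%03d", seq_len(n_lines))
  geno <- matrix(NA_character_, n_lines, nrow(markers),
                 dimnames = list(line_ids, markers$marker_id))
  crossovers <- stats::setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) {
    land <- landscapes[[ch]]
    sel <- which(markers$chrom == ch)
    pos <- markers$pos_bp[sel]
    o1 <- matrix(1L, n_lines, length(sel))
    o2 <- matrix(2L, n_lines, length(sel))
    xo_all <- vector("list", selfing_generations + 1L)
    # generation 1 forms the F2; the rest are selfing rounds
    for (g in seq_len(selfing_generations + 1L)) {
      g1 <- .gamete_population(o1, o2, land, pos)
      g2 <- .gamete_population(o1, o2, land, pos)
      o1 <- g1$g; o2 <- g2$g
      xo <- rbind(g1$xo, g2$xo)
      xo$generation <- if (nrow(xo)) g else integer(0)
      xo_all[[g]] <- xo
    }
    crossovers[[ch]] <- do.call(rbind, xo_all)
    calls <- matrix("HET", n_lines, length(sel))
    calls[o1 == 1L & o2 == 1L] <- "P1"
    calls[o1 == 2L & o2 == 2L] <- "P2"
    geno[, sel] <- calls
  }
  truth_geno <- geno
  if (!is.null(artifacts) && nrow(artifacts)) {
    for (k in seq_len(nrow(artifacts))) {
      m <- artifacts$marker_id[k]
      kind <- artifacts$kind[k]
      mag <- if ("magnitude" %in% names(artifacts) && !is.na(artifacts$magnitude[k]))
        artifacts$magnitude[k] else switch(kind, distorted = 0.85, freq_spike = 0.15,
                                           unlinked = 0.5)
      if (kind == "distorted") {
        geno[, m] <- ifelse(stats::runif(n_lines) < mag, "P1", "P2")
      } else if (kind == "freq_spike") {
        hit <- sample.int(n_lines, round(mag * n_lines))
        geno[hit, m] <- "P1"
      } else if (kind == "unlinked") {
        geno[, m] <- sample(c("P1", "P2"), n_lines, replace = TRUE)
      }
    }
  }
  if (genotyping_error > 0) {
    hom <- which(geno %in% c("P1", "P2"))
    flip <- hom[stats::runif(length(hom)) < genotyping_error]
    geno[flip] <- ifelse(geno[flip] == "P1", "P2", "P1")
  }
  if (missing_rate > 0) {
    geno[stats::runif(length(geno)) < missing_rate] <- NA_character_
  }
  truth <- structure(list(true_genotypes = truth_geno,
                          crossovers = crossovers,
                          planted_artifacts = artifacts,
                          rearrangement_events = NULL),
                     class = "sim_truth")
  structure(list(genotypes = geno, markers = markers, truth = truth),
            class = "ril_panel")
}

#' @export
print.ril_panel <- function(x, ...) {
  cat("Simulated RIL panel:", nrow(x$genotypes), "lines x",
      ncol(x$genotypes), "markers on",
      length(unique(x$markers$chrom)), "chromosome(s)\n")
  tab <- table(factor(x$genotypes, levels = c("P1", "P2", "HET")), useNA = "ifany")
  cat("Call counts:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Simulate a pair of gene orders related by known rearrangements
#'
#' Species A carries `genes_per_chrom` genes per chromosome in identity order;
#' species B is A with `n_inversions` contiguous rank-block inversions and
#' `n_translocations` single-gene moves to other chromosomes applied. Events
#' are placed with disjoint, internal, non-adjacent breakpoints so that each
#' inversion disrupts exactly two neighbor pairs under the collinearity
#' statistic. A one-to-one orthogroup table and the full event ledger are
#' returned.
#'
#' @param n_chrom Number of chromosomes (>= 2 if translocations are requested).
#' @param genes_per_chrom Genes per chromosome.
#' @param n_inversions,n_translocations Numbers of events (>= 0).
#' @param inversion_len_range Inclusive range of inversion lengths in gene
#'   ranks (minimum 2).
#' @param seed Integer seed.
#' @param species Character vector of two species labels.
#' @return List with `genes` (named list of per-species gene tables:
#'   `gene_id`, `chrom`, `start_bp`, `end_bp`, `strand`), `orthogroups`
#'   (orthogroup_id plus one gene-ID column per species), and `truth`
#'   (class `sim_truth`, `rearrangement_events` data frame).
#' @export
simulate_rearranged_genomes <- function(n_chrom, genes_per_chrom,
                                        n_inversions = 0, n_translocations = 0,
                                        inversion_len_range = c(2, 6), seed,
                                        species = c("A", "B")) {
  stopifnot(n_chrom >= 1, genes_per_chrom >= 4,
            n_inversions >= 0, n_translocations >= 0,
            length(inversion_len_range) == 2, inversion_len_range[1] >= 2,
            length(species) == 2)
  if (n_translocations > 0 && n_chrom < 2)
    stop("translocations need at least two chromosomes")
  set.seed(seed)
  chrom_names <- paste0("chr", seq_len(n_chrom))
  gene_id <- function(sp, ch, i) sprintf("%s_%s_g%04d", sp, ch, i)

  # per-chromosome occupied rank intervals (inversions + translocated genes,
  # padded by one rank so that event breakpoints stay non-adjacent)
  occupied <- stats::setNames(rep(list(matrix(numeric(0), ncol = 2)), n_chrom),
                              chrom_names)
  free <- function(ch, lo, hi) {
    occ <- occupied[[ch]]
    !nrow(occ) || all(hi < occ[, 1] - 1 | lo > occ[, 2] + 1)
  }
  events <- list()
  for (e in seq_len(n_inversions)) {
    placed <- FALSE
    for (try in seq_len(500)) {
      ch <- sample(chrom_names, 1)
      len <- sample(seq(inversion_len_range[1], inversion_len_range[2]), 1)
      if (genes_per_chrom < len + 2) next
      lo <- sample(seq(2, genes_per_chrom - len), 1)  # internal: 2 .. n-1
      hi <- lo + len - 1
      if (free(ch, lo, hi)) {
        occupied[[ch]] <- rbind(occupied[[ch]], c(lo, hi))
        events[[length(events) + 1L]] <-
          data.frame(kind = "inversion", chrom = ch, start_rank = lo,
                     end_rank = hi, target_chrom = NA, target_rank = NA)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place a disjoint, internal, non-adjacent inversion with ",
           "length in [", inversion_len_range[1], ", ", inversion_len_range[2],
           "] after bounded retries")
  }
  for (e in seq_len(n_translocations)) {
    placed <- FALSE
    for (try in seq_len(500)) {
      ch <- sample(chrom_names, 1)
      g <- sample(seq(2, genes_per_chrom - 1), 1)
      tch <- sample(setdiff(chrom_names, ch), 1)
      trank <- sample(seq(2, genes_per_chrom - 1), 1)
      if (free(ch, g, g) && free(tch, trank, trank)) {
        occupied[[ch]] <- rbind(occupied[[ch]], c(g, g))
        occupied[[tch]] <- rbind(occupied[[tch]], c(trank, trank))
        events[[length(events) + 1L]] <-
          data.frame(kind = "translocation", chrom = ch, start_rank = g,
                     end_rank = g, target_chrom = tch, target_rank = trank)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place a non-adjacent single-gene translocation after bounded retries")
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(0), chrom = character(0), start_rank = integer(0),
               end_rank = integer(0), target_chrom = character(0),
               target_rank = integer(0))

  # species A: identity order; track ortholog identity through the events
  orders <- stats::setNames(lapply(chrom_names, function(ch)
    paste0(ch, ":", seq_len(genes_per_chrom))), chrom_names)
  strands <- stats::setNames(lapply(chrom_names, function(ch)
    rep("+", genes_per_chrom)), chrom_names)
  inv <- events[events$kind == "inversion", , drop = FALSE]
  for (k in seq_len(nrow(inv))) {
    ch <- inv$chrom[k]; lo <- inv$start_rank[k]; hi <- inv$end_rank[k]
    orders[[ch]][lo:hi] <- rev(orders[[ch]][lo:hi])
    strands[[ch]][lo:hi] <- ifelse(rev(strands[[ch]][lo:hi]) == "+", "-", "+")
  }
  tra <- events[events$kind == "translocation", , drop = FALSE]
  for (k in seq_len(nrow(tra))) {
    ch <- tra$chrom[k]; g <- paste0(ch, ":", tra$start_rank[k])
    tch <- tra$target_chrom[k]; at <- tra$target_rank[k]
    src <- orders[[ch]]; i <- match(g, src)
    orders[[ch]] <- src[-i]
    sst <- strands[[ch]]; orig_strand <- sst[i]
    strands[[ch]] <- sst[-i]
    at <- min(at, length(orders[[tch]]) + 1L)
    orders[[tch]] <- append(orders[[tch]], g, after = at - 1L)
    strands[[tch]] <- append(strands[[tch]], orig_strand, after = at - 1L)
  }

  mk_table <- function(sp, orders_sp, strands_sp, label_map) {
    rows <- lapply(chrom_names, function(ch) {
      labs <- orders_sp[[ch]]
      n <- length(labs)
      if (!n) return(NULL)
      data.frame(gene_id = label_map[labs], chrom = ch,
                 start_bp = (seq_len(n) - 1L) * 10000L + 1L,
                 end_bp = (seq_len(n) - 1L) * 10000L + 1500L,
                 strand = strands_sp[[ch]], label = labs)
    })
    do.call(rbind, rows)
  }
  labels <- unlist(lapply(chrom_names, function(ch)
    paste0(ch, ":", seq_len(genes_per_chrom))))
  map_a <- stats::setNames(
    unlist(lapply(chrom_names, function(ch)
      gene_id(species[1], ch, seq_len(genes_per_chrom)))), labels)
  map_b <- stats::setNames(
    unlist(lapply(chrom_names, function(ch)
      gene_id(species[2], ch, seq_len(genes_per_chrom)))), labels)
  orders_a <- stats::setNames(lapply(chrom_names, function(ch)
    paste0(ch, ":", seq_len(genes_per_chrom))), chrom_names)
  strands_a <- stats::setNames(lapply(chrom_names, function(ch)
    rep("+", genes_per_chrom)), chrom_names)
  genes_a <- mk_table(species[1], orders_a, strands_a, map_a)
  genes_b <- mk_table(species[2], orders, strands, map_b)
  og <- data.frame(orthogroup_id = sprintf("OG%06d", seq_along(labels)),
                   a = map_a[labels], b = map_b[labels], row.names = NULL)
  names(og)[2:3] <- species
  genes_a$label <- NULL; genes_b$label <- NULL
  truth <- structure(list(true_genotypes = NULL, crossovers = NULL,
                          planted_artifacts = NULL,
                          rearrangement_events = events),
                     class = "sim_truth")
  out <- list(genes = stats::setNames(list(genes_a, genes_b), species),
              orthogroups = og, truth = truth)
  out
}

#' Simulate low-coverage read counts at genotyped markers
#'
#' Per line and marker, read depth is Poisson(`mean_coverage`); each read
#' reports the true parental allele with probability `1 - base_error`
#' (heterozygous sites draw each allele with probability 1/2 before error).
#'
#' @param true_genotypes Line x marker character matrix in `P1`/`P2`/`HET`.
#' @param mean_coverage Mean read depth (> 0).
#' @param base_error Per-read error probability.
#' @param seed Integer seed.
#' @return An object of class `allele_counts`: list with integer matrices
#'   `p1` and `p2` (reads supporting each parental allele) and the dimnames
#'   of the input.
#' @export
simulate_marker_observations <- function(true_genotypes, mean_coverage,
                                         base_error = 0, seed) {
  stopifnot(is.matrix(true_genotypes), mean_coverage > 0,
            base_error >= 0, base_error <= 1)
  set.seed(seed)
  n <- length(true_genotypes)
  depth <- stats::rpois(n, mean_coverage)
  # probability that a read reports the P1 allele
  p_p1 <- ifelse(true_genotypes == "P1", 1 - base_error,
                 ifelse(true_genotypes == "P2", base_error, 0.5))
  n1 <- stats::rbinom(n, depth, p_p1)
  p1 <- matrix(n1, nrow(true_genotypes), dimnames = dimnames(true_genotypes))
  p2 <- matrix(depth - n1, nrow(true_genotypes), dimnames = dimnames(true_genotypes))
  structure(list(p1 = p1, p2 = p2), class = "allele_counts")
}
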