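#' Haldane map function and selfed-RIL corrections
#'
#' `haldane_cM()` converts a per-meiosis recombination fraction r to map
#' distance d = -50 ln(1 - 2r) (cM, no interference); `haldane_r()` is its
#' inverse. `ril_meiotic_r()` converts the recombination fraction R observed
#' between selfed RILs to the underlying meiotic fraction r = R / (2(1 - R)),
#' and `ril_observed_R()` is the Haldane-Waddington expectation
#' R = 2r / (1 + 2r) for self-fertilizing RILs.
#'
#' @param r Meiotic recombination fraction in `[0, 0.5)`.
#' @param d Map distance in cM.
#' @param R Observed RIL recombination fraction in `[0, 0.5)`.
#' @return Numeric vector.
#' @export
haldane_cM <- function(r) {
  stopifnot(all(r >= 0 & r < 0.5))
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_cM
#' @export
haldane_r <- function(d) {
  stopifnot(all(d >= 0))
  (1 - exp(-d / 50)) / 2
}

#' @rdname haldane_cM
#' @export
ril_meiotic_r <- function(R) {
  stopifnot(all(R >= 0 & R < 0.5))
  R / (2 * (1 - R))
}

#' @rdname haldane_cM
#' @export
ril_observed_R <- function(r) {
  stopifnot(all(r >= 0))
  2 * r / (1 + 2 * r)
}

new_filter_report <- function(removed, surviving, missing_only = character(0)) {
  removed <- as.data.frame(removed)
  if (!nrow(removed))
    removed <- data.frame(marker_id = character(0), reason = character(0))
  structure(list(removed = removed,
                 counts = table(removed$reason),
                 surviving = surviving,
                 missing_only = missing_only),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Marker filter report:", nrow(x$removed), "removed,",
      length(x$surviving), "surviving\n")
  if (nrow(x$removed)) print(x$counts)
  if (length(x$missing_only))
    cat(length(x$missing_only), "marker(s) had no informative calls (not tested)\n")
  invisible(x)
}

# P1 allele frequency per marker; HET counts 1/2, NA excluded
marker_p1_freq <- function(genotypes) {
  n1 <- colSums(genotypes == "P1", na.rm = TRUE)
  n2 <- colSums(genotypes == "P2", na.rm = TRUE)
  nh <- colSums(genotypes == "HET", na.rm = TRUE)
  tot <- n1 + n2 + nh
  ifelse(tot > 0, (n1 + nh / 2) / tot, NA_real_)
}

#' Flag markers with distorted segregation
#'
#' Per marker, a chi-square goodness-of-fit test of homozygous P1/P2 counts
#' against the 1:1 ratio expected in a two-parent RIL panel (HET and missing
#' calls excluded). Markers with Bonferroni-adjusted p below `alpha` are
#' flagged with reason `"distortion"`. Markers with no informative calls are
#' reported separately and not tested.
#'
#' @param genotypes Line x marker character matrix in `P1`/`P2`/`HET`/`NA`.
#' @param alpha Family-wise significance level (Bonferroni over tested markers).
#' @return A `filter_report`.
#' @export
filter_segregation_distortion <- function(genotypes, alpha = 0.05) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) >= 2)
  n1 <- colSums(genotypes == "P1", na.rm = TRUE)
  n2 <- colSums(genotypes == "P2", na.rm = TRUE)
  tot <- n1 + n2
  testable <- tot > 0
  chisq <- ifelse(testable, (n1 - n2)^2 / pmax(tot, 1), NA_real_)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  p_adj <- pmin(p * sum(testable), 1)
  bad <- which(testable & p_adj < alpha)
  removed <- data.frame(marker_id = colnames(genotypes)[bad],
                        reason = rep("distortion", length(bad)))
  new_filter_report(removed,
                    surviving = setdiff(colnames(genotypes)[testable],
                                        removed$marker_id),
                    missing_only = colnames(genotypes)[!testable])
}

# pairwise observed recombination fraction and LOD between all markers.
# Only homozygous parental calls are informative.
pairwise_rf <- function(genotypes) {
  a <- (genotypes == "P1"); a[is.na(a)] <- FALSE
  b <- (genotypes == "P2"); b[is.na(b)] <- FALSE
  mode(a) <- "numeric"; mode(b) <- "numeric"
  n11 <- crossprod(a); n22 <- crossprod(b)
  n12 <- crossprod(a, b); n21 <- crossprod(b, a)
  tot <- n11 + n22 + n12 + n21
  rec <- n12 + n21
  R <- ifelse(tot > 0, rec / tot, NA_real_)
  Rc <- pmin(pmax(R, 1e-9), 1 - 1e-9)
  lod <- rec * log10(2 * Rc) + (tot - rec) * log10(2 * (1 - Rc))
  lod[tot == 0] <- NA_real_
  list(R = R, lod = lod, n = tot)
}

#' Assign markers to linkage groups and flag off-group markers
#'
#' Single-linkage clustering in which two markers join a group when their
#' pairwise recombination fraction is below `max_rf` and the LOD for linkage
#' exceeds `min_lod`. Markers that end up in groups smaller than `min_group`
#' are flagged `"off_linkage_group"`.
#'
#' @inheritParams filter_segregation_distortion
#' @param max_rf Maximum recombination fraction to join two markers.
#' @param min_lod Minimum LOD to join two markers.
#' @param min_group Minimum group size a marker must belong to.
#' @return List with `groups` (named integer vector of group indices) and
#'   `report` (a `filter_report`).
#' @export
form_linkage_groups <- function(genotypes, max_rf = 0.35, min_lod = 6,
                                min_group = 5) {
  prf <- pairwise_rf(genotypes)
  m <- ncol(genotypes)
  adj <- !is.na(prf$R) & prf$R < max_rf & prf$lod > min_lod
  diag(adj) <- FALSE
  group <- rep(NA_integer_, m)
  gid <- 0L
  for (i in seq_len(m)) {
    if (!is.na(group[i])) next
    gid <- gid + 1L
    frontier <- i
    group[i] <- gid
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & is.na(group))
      group[nb] <- gid
      frontier <- nb
    }
  }
  names(group) <- colnames(genotypes)
  sizes <- table(group)
  off <- names(group)[sizes[as.character(group)] < min_group]
  removed <- data.frame(marker_id = off,
                        reason = rep("off_linkage_group", length(off)))
  list(groups = group,
       report = new_filter_report(removed,
                                  surviving = setdiff(colnames(genotypes), off)))
}

# flaggable runs given frequencies f of currently unflagged markers: every
# member must deviate by >= threshold from the nearest unflagged marker on
# each available side of the run. The deviant group is the minority, so the
# SHORTEST qualifying run is flagged first (ties: leftmost); iterating to the
# fixpoint then re-anchors the flanks after each removal. Returns c(i, j)
# or NULL.
.find_freq_run <- function(f, threshold) {
  m <- length(f)
  best <- NULL
  for (i in seq_len(m)) {
    left <- if (i > 1) f[i - 1] else NA_real_
    for (j in i:m) {
      if (i == 1 && j == m) next  # no reference side left
      # once a member fails the fixed left-flank condition, no longer run
      # starting at i can qualify
      if (!is.na(left) && abs(f[j] - left) < threshold) break
      right <- if (j < m) f[j + 1] else NA_real_
      seg <- f[i:j]
      ok_r <- is.na(right) | abs(seg - right) >= threshold
      if (all(ok_r)) {
        if (is.null(best) || (j - i) < (best[2] - best[1])) best <- c(i, j)
        if (best[1] == best[2]) return(best)  # cannot beat a single marker
      }
    }
  }
  best
}

#' Flag markers with local allele-frequency deviations
#'
#' Implements the local allele-frequency rule used to clean RIL marker sets:
#' per chromosome, the P1 frequency of each marker (HET counted 1/2, missing
#' excluded) is compared with the nearest unflagged flanking markers, and a
#' contiguous run of markers in which every member deviates by at least
#' `threshold` from both flanks (chromosome ends use the single available
#' side) is flagged; the shortest qualifying run goes first — the deviant
#' group is the minority — and the search repeats with re-anchored flanks
#' until a fixpoint. Flagged markers carry reason `"freq_deviation"`.
#'
#' @inheritParams filter_segregation_distortion
#' @param markers Marker table (`marker_id`, `chrom`, `pos_bp`) ordered by
#'   position within chromosome.
#' @param threshold Minimum absolute frequency difference (default 0.04).
#' @return A `filter_report`.
#' @export
filter_allele_frequency_deviation <- function(genotypes, markers,
                                              threshold = 0.04) {
  markers <- as.data.frame(markers)
  stopifnot(all(markers$marker_id %in% colnames(genotypes)))
  f_all <- marker_p1_freq(genotypes[, markers$marker_id, drop = FALSE])
  flagged <- character(0)
  for (ch in unique(markers$chrom)) {
    ids <- markers$marker_id[markers$chrom == ch]
    f <- f_all[ids]
    keep <- !is.na(f)
    ids <- ids[keep]; f <- unname(f[keep])
    if (length(ids) < 3) {
      warning("chromosome ", ch, " has fewer than 3 markers; no frequency filtering")
      next
    }
    active <- seq_along(ids)
    repeat {
      run <- .find_freq_run(f[active], threshold)
      if (is.null(run)) break
      flagged <- c(flagged, ids[active[run[1]:run[2]]])
      active <- active[-(run[1]:run[2])]
      if (length(active) < 1) break
    }
  }
  removed <- data.frame(marker_id = flagged,
                        reason = rep("freq_deviation", length(flagged)))
  new_filter_report(removed,
                    surviving = setdiff(markers$marker_id, flagged))
}

# adjacent-interval statistics for one chromosome's genotype submatrix
.adjacent_intervals <- function(genotypes, ids) {
  m <- length(ids)
  if (m < 2) return(NULL)
  g <- genotypes[, ids, drop = FALSE]
  R <- numeric(m - 1); inf <- integer(m - 1)
  for (k in seq_len(m - 1)) {
    x <- g[, k]; y <- g[, k + 1]
    ok <- x %in% c("P1", "P2") & y %in% c("P1", "P2")
    inf[k] <- sum(ok)
    R[k] <- if (inf[k] > 0) sum(x[ok] != y[ok]) / inf[k] else NA_real_
  }
  list(R = R, informative = inf)
}

#' Estimate a genetic map from a selfed-RIL genotype panel
#'
#' For each adjacent marker interval (physical order is trusted), the observed
#' RIL recombination fraction R is the share of lines with opposite homozygous
#' parental calls among lines informative at both markers. R is clamped to
#' `[0, 0.499]`, corrected to the meiotic fraction r = R / (2(1 - R))
#' (Haldane-Waddington, selfing design), and converted to distance
#' d = -50 ln(1 - 2r) cM; positions accumulate from each chromosome's left
#' end. If `high_rec_rate_threshold` (cM/Mb) is set, markers whose removal
#' eliminates an adjacent interval exceeding that rate are flagged
#' `"high_local_recombination"` and the map is re-estimated once.
#'
#' @inheritParams filter_allele_frequency_deviation
#' @param high_rec_rate_threshold Optional cM/Mb threshold; `NULL` disables
#'   the locally-excessive-recombination filter (the default).
#' @return List with `map` (class `genetic_map`) and `report`
#'   (a `filter_report`).
#' @export
estimate_genetic_map <- function(genotypes, markers,
                                 high_rec_rate_threshold = NULL) {
  markers <- as.data.frame(markers)
  stopifnot(all(markers$marker_id %in% colnames(genotypes)))

  build <- function(marker_tab) {
    rows <- lapply(unique(marker_tab$chrom), function(ch) {
      sub <- marker_tab[marker_tab$chrom == ch, , drop = FALSE]
      if (nrow(sub) < 2)
        stop("chromosome ", ch, " has fewer than 2 surviving markers")
      iv <- .adjacent_intervals(genotypes, sub$marker_id)
      if (any(iv$informative == 0)) {
        k <- which(iv$informative == 0)[1]
        stop("interval ", sub$marker_id[k], " -- ", sub$marker_id[k + 1],
             " on ", ch, " has zero informative lines; distance undefined")
      }
      R <- pmin(pmax(iv$R, 0), 0.499)
      r <- ril_meiotic_r(R)
      d <- haldane_cM(r)
      data.frame(chrom = ch, marker_id = sub$marker_id, pos_bp = sub$pos_bp,
                 pos_cM = cumsum(c(0, d)),
                 interval_R = c(NA, R), interval_r = c(NA, r),
                 interval_cM = c(NA, d))
    })
    tab <- do.call(rbind, rows)
    structure(list(table = tab,
                   total_cM = tapply(tab$pos_cM, tab$chrom, max)),
              class = "genetic_map")
  }

  map <- build(markers)
  removed <- data.frame(marker_id = character(0), reason = character(0))
  if (!is.null(high_rec_rate_threshold)) {
    tab <- map$table
    flag <- character(0)
    for (ch in unique(tab$chrom)) {
      sub <- tab[tab$chrom == ch, , drop = FALSE]
      rate <- sub$interval_cM[-1] / (diff(sub$pos_bp) / 1e6)
      offending <- which(rate > high_rec_rate_threshold)
      for (k in offending) {
        # interval k joins markers k and k+1 (row indices in sub)
        merged_rate <- function(i, j) {
          ids <- sub$marker_id[c(i, j)]
          iv <- .adjacent_intervals(genotypes, ids)
          R <- pmin(pmax(iv$R, 0), 0.499)
          haldane_cM(ril_meiotic_r(R)) / (diff(sub$pos_bp[c(i, j)]) / 1e6)
        }
        left_fix <- if (k > 1) merged_rate(k - 1, k + 1) else -Inf
        right_fix <- if (k + 2 <= nrow(sub)) merged_rate(k, k + 2) else -Inf
        cand <- c(left = left_fix, right = right_fix)
        cures <- cand <= high_rec_rate_threshold
        if (any(cures)) {
          pick <- names(cand)[cures][which.min(cand[cures])]
          flag <- c(flag, if (pick == "left") sub$marker_id[k] else sub$marker_id[k + 1])
        } else {
          flag <- c(flag, sub$marker_id[c(k, k + 1)])
        }
      }
    }
    flag <- unique(flag)
    if (length(flag)) {
      removed <- data.frame(marker_id = flag,
                            reason = rep("high_local_recombination", length(flag)))
      map <- build(markers[!markers$marker_id %in% flag, , drop = FALSE])
    }
  }
  list(map = map,
       report = new_filter_report(removed,
                                  surviving = setdiff(markers$marker_id,
                                                      removed$marker_id)))
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", nrow(x$table), "markers on",
      length(x$total_cM), "chromosome(s); total",
      round(sum(x$total_cM), 1), "cM\n")
  print(round(x$total_cM, 2))
  invisible(x)
}

#' @export
summary.genetic_map <- function(object, ...) {
  tab <- object$table
  data.frame(chrom = names(object$total_cM),
             n_markers = as.integer(table(tab$chrom)[names(object$total_cM)]),
             span_bp = tapply(tab$pos_bp, tab$chrom, function(p) diff(range(p)))[names(object$total_cM)],
             total_cM = as.numeric(object$total_cM),
             row.names = NULL)
}

#' @export
plot.genetic_map <- function(x, ...) {
  tab <- x$table
  chroms <- unique(tab$chrom)
  old <- graphics::par(mfrow = c(1, length(chroms)))
  on.exit(graphics::par(old))
  for (ch in chroms) {
    sub <- tab[tab$chrom == ch, ]
    graphics::plot(sub$pos_bp / 1e6, sub$pos_cM, pch = 16, cex = 0.5,
                   xlab = "Physical position (Mb)", ylab = "Genetic position (cM)",
                   main = ch, ...)
  }
  invisible(x)
}

#' Sliding-window allele-frequency profile
#'
#' Mean P1 allele frequency of markers in sliding windows
#' (`[start, start + window_bp)`, starts at `0, step_bp, 2 step_bp, ...`),
#' the panel-wide profile used to spot transmission-ratio skews. Windows with
#' no markers emit no value.
#'
#' @inheritParams filter_allele_frequency_deviation
#' @param window_bp Window width (default 100 kb).
#' @param step_bp Step between window starts (default 5 kb).
#' @return Data frame `chrom`, `window_start`, `n_markers`, `freq`.
#' @export
allele_frequency_profile <- function(genotypes, markers, window_bp = 100000,
                                     step_bp = 5000) {
  markers <- as.data.frame(markers)
  f <- marker_p1_freq(genotypes[, markers$marker_id, drop = FALSE])
  out <- lapply(unique(markers$chrom), function(ch) {
    sub <- markers[markers$chrom == ch, , drop = FALSE]
    fv <- f[sub$marker_id]
    ok <- !is.na(fv)
    sub <- sub[ok, , drop = FALSE]; fv <- fv[ok]
    if (!nrow(sub)) return(NULL)
    starts <- seq(0, max(sub$pos_bp), by = step_bp)
    vals <- lapply(starts, function(s) {
      inwin <- sub$pos_bp >= s & sub$pos_bp < s + window_bp
      if (!any(inwin)) return(NULL)
      data.frame(chrom = ch, window_start = s, n_markers = sum(inwin),
                 freq = mean(fv[inwin]))
    })
    do.call(rbind, vals)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), window_start = numeric(0),
                      n_markers = integer(0), freq = numeric(0))
  out
}

#' Impute RIL genotypes from low-coverage read counts with an HMM
#'
#' Per line and chromosome, a two-state (P1/P2) hidden Markov chain over
#' ordered markers (heterozygous states are excluded for inbred lines).
#' Emissions treat reads as i.i.d. with probability `1 - error_rate` of
#' matching the hidden parent. The switch probability between adjacent
#' markers is `expected_breakpoints_per_chrom * dbp / L` (capped at 0.5),
#' where `L` is the chromosome's marker span, so that the expected number of
#' switches per chromosome matches the supplied breakpoint expectation.
#' Posterior-mode states are reported; calls with maximum posterior below
#' `min_posterior` are emitted as missing.
#'
#' @param counts An `allele_counts` object (matrices `p1`, `p2`).
#' @param markers Marker table sorted by (`chrom`, `pos_bp`).
#' @param error_rate Per-read error probability in (0, 0.5).
#' @param expected_breakpoints_per_chrom Expected genotype switches per
#'   chromosome per line (> 0); about twice the chromosome length in Morgans
#'   for a selfed RIL.
#' @param min_posterior Posterior required to call a genotype (default 0.95).
#' @return Line x marker character matrix in `P1`/`P2`/`NA`.
#' @export
impute_genotypes_hmm <- function(counts, markers, error_rate = 0.01,
                                 expected_breakpoints_per_chrom = 1,
                                 min_posterior = 0.95) {
  stopifnot(inherits(counts, "allele_counts"),
            error_rate > 0, error_rate < 0.5,
            expected_breakpoints_per_chrom > 0)
  markers <- as.data.frame(markers)
  stopifnot(all(markers$marker_id %in% colnames(counts$p1)))
  n <- nrow(counts$p1)
  out <- matrix(NA_character_, n, nrow(markers),
                dimnames = list(rownames(counts$p1), markers$marker_id))
  for (ch in unique(markers$chrom)) {
    sub <- markers[markers$chrom == ch, , drop = FALSE]
    if (is.unsorted(sub$pos_bp)) stop("markers must be sorted by position on ", ch)
    m <- nrow(sub)
    c1 <- counts$p1[, sub$marker_id, drop = FALSE]
    c2 <- counts$p2[, sub$marker_id, drop = FALSE]
    # emission likelihoods per state, all lines at once
    e1 <- (1 - error_rate)^c1 * error_rate^c2      # hidden P1
    e2 <- error_rate^c1 * (1 - error_rate)^c2      # hidden P2
    if (m == 1) {
      post1 <- 0.5 * e1 / (0.5 * e1 + 0.5 * e2)
      out[, sub$marker_id] <- ifelse(post1 >= min_posterior, "P1",
                                     ifelse(1 - post1 >= min_posterior, "P2", NA))
      next
    }
    L <- sub$pos_bp[m] - sub$pos_bp[1]
    if (L <= 0) stop("zero-length chromosome ", ch)
    q <- pmin(0.5, expected_breakpoints_per_chrom * diff(sub$pos_bp) / L)
    # scaled forward-backward, vectorized over lines
    a1 <- matrix(0, n, m); a2 <- matrix(0, n, m)
    a1[, 1] <- 0.5 * e1[, 1]; a2[, 1] <- 0.5 * e2[, 1]
    s <- a1[, 1] + a2[, 1]
    a1[, 1] <- a1[, 1] / s; a2[, 1] <- a2[, 1] / s
    for (t in 2:m) {
      p1 <- (a1[, t - 1] * (1 - q[t - 1]) + a2[, t - 1] * q[t - 1]) * e1[, t]
      p2 <- (a1[, t - 1] * q[t - 1] + a2[, t - 1] * (1 - q[t - 1])) * e2[, t]
      s <- p1 + p2
      a1[, t] <- p1 / s; a2[, t] <- p2 / s
    }
    b1 <- matrix(0, n, m); b2 <- matrix(0, n, m)
    b1[, m] <- 1; b2[, m] <- 1
    for (t in (m - 1):1) {
      p1 <- (1 - q[t]) * e1[, t + 1] * b1[, t + 1] + q[t] * e2[, t + 1] * b2[, t + 1]
      p2 <- q[t] * e1[, t + 1] * b1[, t + 1] + (1 - q[t]) * e2[, t + 1] * b2[, t + 1]
      s <- p1 + p2
      b1[, t] <- p1 / s; b2[, t] <- p2 / s
    }
    post1 <- a1 * b1 / (a1 * b1 + a2 * b2)
    calls <- ifelse(post1 >= min_posterior, "P1",
                    ifelse(1 - post1 >= min_posterior, "P2", NA_character_))
    out[, sub$marker_id] <- calls
  }
  out
}
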