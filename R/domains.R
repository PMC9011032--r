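# design matrix for a continuous 2-breakpoint piecewise-linear model
.seg_X <- function(x, b) cbind(1, x, pmax(x - b[1], 0), pmax(x - b[2], 0))

.seg_rss <- function(x, y, b) {
  fit <- stats::lm.fit(.seg_X(x, b), y)
  sum(fit$residuals^2)
}

#' Fit a two-breakpoint segmented regression to a Marey map
#'
#' Fits the continuous piecewise-linear model used to delimit arm and center
#' recombination domains: genetic position (cM) as a function of physical
#' position with two breakpoints and three slopes. The fit minimizes residual
#' sum of squares by a grid search over breakpoint pairs restricted to marker
#' positions (between the 3rd and 3rd-from-last markers), refined by
#' Muggeo-style iterative linearization; breakpoint standard errors come from
#' the linearization's parameter covariance. A perfectly collinear input is
#' flagged `no_changepoint`.
#'
#' @param marey Data frame with columns `pos_bp` and `pos_cM`, sorted by
#'   `pos_bp` with `pos_cM` nondecreasing; at least 6 points (after
#'   truncation).
#' @param truncate_after_bp Optional physical position; markers beyond it are
#'   excluded prior to fitting (used where sparse terminal markers destabilise
#'   a boundary, as for one chromosome arm in the motivating data).
#' @param max_candidates Grid density cap for the coarse search.
#' @return Object of class `marey_segfit`: `breakpoints_bp`, `breakpoint_se_bp`,
#'   `slopes_cM_per_Mb` (left arm, center, right arm), `intercept_cM`, `rss`,
#'   `n`, `truncation_bp`, `no_changepoint`.
#' @export
fit_segmented_marey <- function(marey, truncate_after_bp = NULL,
                                max_candidates = 60) {
  marey <- as.data.frame(marey)
  stopifnot(all(c("pos_bp", "pos_cM") %in% names(marey)))
  x <- as.numeric(marey$pos_bp); y <- as.numeric(marey$pos_cM)
  o <- order(x); x <- x[o]; y <- y[o]
  if (!is.null(truncate_after_bp)) {
    keep <- x <= truncate_after_bp
    x <- x[keep]; y <- y[keep]
  }
  n <- length(x)
  if (n < 6) stop("need at least 6 points for a two-breakpoint fit")

  # degenerate case: collinear points carry no changepoint information
  f0 <- stats::lm.fit(cbind(1, x), y)
  rss0 <- sum(f0$residuals^2)
  if (rss0 <= 1e-8 * max(1, stats::var(y) * (n - 1))) {
    return(structure(list(breakpoints_bp = c(x[1], x[n]),
                          breakpoint_se_bp = c(NA_real_, NA_real_),
                          slopes_cM_per_Mb = rep(f0$coefficients[2] * 1e6, 3),
                          intercept_cM = f0$coefficients[1],
                          rss = rss0, n = n,
                          truncation_bp = truncate_after_bp,
                          no_changepoint = TRUE,
                          x_range = range(x), x = x, y = y),
                     class = "marey_segfit"))
  }

  lo <- x[3]; hi <- x[n - 2]
  cand <- unique(x[x >= lo & x <= hi])
  if (length(cand) > max_candidates)
    cand <- unique(stats::quantile(cand, probs = seq(0, 1, length.out = max_candidates),
                                   type = 1, names = FALSE))
  best <- NULL; best_rss <- Inf
  mid <- (x[1] + x[n]) / 2
  for (i in seq_along(cand)) {
    for (j in seq_along(cand)) {
      if (cand[j] <= cand[i]) next
      b <- c(cand[i], cand[j])
      rss <- .seg_rss(x, y, b)
      if (rss < best_rss - 1e-12) {
        best_rss <- rss; best <- b
      } else if (abs(rss - best_rss) <= 1e-12 && !is.null(best)) {
        # tie: prefer the more central breakpoint pair
        if (sum(abs(b - mid)) < sum(abs(best - mid))) best <- b
      }
    }
  }

  # Muggeo-style refinement: linearize the breakpoint dependence and iterate
  b <- best
  refine_fit <- NULL
  for (iter in seq_len(50)) {
    U1 <- pmax(x - b[1], 0); U2 <- pmax(x - b[2], 0)
    V1 <- -as.numeric(x > b[1]); V2 <- -as.numeric(x > b[2])
    fit <- stats::lm(y ~ x + U1 + U2 + V1 + V2)
    cf <- stats::coef(fit)
    cf[is.na(cf)] <- 0
    step <- c(if (abs(cf["U1"]) > 0) cf["V1"] / cf["U1"] else 0,
              if (abs(cf["U2"]) > 0) cf["V2"] / cf["U2"] else 0)
    step[!is.finite(step)] <- 0
    b_new <- pmin(pmax(b + step, lo), hi)
    if (b_new[2] - b_new[1] < (hi - lo) * 1e-4)
      b_new <- c(b_new[1], b_new[1] + (hi - lo) * 1e-4)
    moved <- max(abs(b_new - b))
    if (.seg_rss(x, y, b_new) <= .seg_rss(x, y, b)) b <- b_new
    refine_fit <- fit
    if (moved < 1) break
  }
  if (.seg_rss(x, y, b) > best_rss) b <- best  # keep grid optimum if refinement failed
  final_rss <- .seg_rss(x, y, b)

  # final linearization at the accepted breakpoints for slope/SE extraction
  U1 <- pmax(x - b[1], 0); U2 <- pmax(x - b[2], 0)
  V1 <- -as.numeric(x > b[1]); V2 <- -as.numeric(x > b[2])
  fit <- stats::lm(y ~ x + U1 + U2 + V1 + V2)
  cf <- stats::coef(fit); cf[is.na(cf)] <- 0
  vc <- suppressWarnings(stats::vcov(fit))  # near-zero RSS trips summary.lm
  se_b <- c(NA_real_, NA_real_)
  for (k in 1:2) {
    un <- c("U1", "U2")[k]; vn <- c("V1", "V2")[k]
    if (un %in% rownames(vc) && vn %in% rownames(vc) && abs(cf[un]) > 0)
      se_b[k] <- sqrt(vc[vn, vn]) / abs(cf[un])
  }
  slopes <- cumsum(c(cf["x"], cf["U1"], cf["U2"])) * 1e6
  structure(list(breakpoints_bp = unname(b),
                 breakpoint_se_bp = se_b,
                 slopes_cM_per_Mb = unname(slopes),
                 intercept_cM = unname(cf["(Intercept)"]),
                 rss = final_rss, n = n,
                 truncation_bp = truncate_after_bp,
                 no_changepoint = FALSE,
                 x_range = range(x), x = x, y = y),
            class = "marey_segfit")
}

#' @export
print.marey_segfit <- function(x, ...) {
  if (x$no_changepoint) {
    cat("Segmented Marey fit: no changepoint (collinear input); slope",
        signif(x$slopes_cM_per_Mb[1], 4), "cM/Mb\n")
  } else {
    cat("Segmented Marey fit (", x$n, " markers):\n", sep = "")
    cat("  breakpoints (Mb):",
        paste(sprintf("%.3f (SE %.3f)", x$breakpoints_bp / 1e6,
                      x$breakpoint_se_bp / 1e6), collapse = ", "), "\n")
    cat("  slopes (cM/Mb): ",
        paste(sprintf("%.2f", x$slopes_cM_per_Mb), collapse = " / "), "\n")
    cat("  RSS:", signif(x$rss, 4), "\n")
  }
  invisible(x)
}

#' @export
summary.marey_segfit <- function(object, ...) {
  data.frame(segment = c("left_arm", "center", "right_arm"),
             start_bp = c(object$x_range[1], object$breakpoints_bp),
             end_bp = c(object$breakpoints_bp, object$x_range[2]),
             slope_cM_per_Mb = object$slopes_cM_per_Mb)
}

#' @export
coef.marey_segfit <- function(object, ...) {
  c(breakpoint1_bp = object$breakpoints_bp[1],
    breakpoint2_bp = object$breakpoints_bp[2],
    slope_left = object$slopes_cM_per_Mb[1],
    slope_center = object$slopes_cM_per_Mb[2],
    slope_right = object$slopes_cM_per_Mb[3])
}

#' @export
predict.marey_segfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else
    if (is.data.frame(newdata)) newdata$pos_bp else as.numeric(newdata)
  b <- object$breakpoints_bp
  s <- object$slopes_cM_per_Mb / 1e6
  y0 <- object$intercept_cM
  if (object$no_changepoint) return(y0 + s[1] * x)
  y0 + s[1] * pmin(x, b[1]) +
    s[2] * pmin(pmax(x - b[1], 0), b[2] - b[1]) +
    s[3] * pmax(x - b[2], 0)
}

#' @export
plot.marey_segfit <- function(x, ...) {
  graphics::plot(x$x / 1e6, x$y, pch = 16, cex = 0.5,
                 xlab = "Physical position (Mb)",
                 ylab = "Genetic position (cM)", ...)
  xs <- seq(x$x_range[1], x$x_range[2], length.out = 400)
  graphics::lines(xs / 1e6, predict(x, xs), lwd = 2)
  if (!x$no_changepoint)
    graphics::abline(v = x$breakpoints_bp / 1e6, lty = 2, col = "grey40")
  invisible(x)
}

#' Call terminal tip domains from a Marey map and its segmented fit
#'
#' A tip is the maximal terminal run of at least `min_run` inter-marker
#' intervals whose local recombination rate is below `rate_fraction` times
#' the adjacent arm's fitted slope. The boundary is placed at the outermost
#' marker of the non-tip region; absent a qualifying run the tip span is 0.
#'
#' @param marey Data frame `pos_bp`, `pos_cM` for one chromosome.
#' @param fit The chromosome's [fit_segmented_marey()] result.
#' @param min_run Minimum number of qualifying terminal intervals (default 2).
#' @param rate_fraction Fraction of the arm slope below which an interval is
#'   "tip-like" (default 0.1).
#' @return List `left_tip_end_bp`, `right_tip_start_bp` (0-span tips are
#'   reported at the chromosome's terminal markers with `*_span0 = TRUE`).
#' @export
call_tip_domains <- function(marey, fit, min_run = 2, rate_fraction = 0.1) {
  marey <- as.data.frame(marey)
  x <- marey$pos_bp; y <- marey$pos_cM
  o <- order(x); x <- x[o]; y <- y[o]
  rate <- diff(y) / (diff(x) / 1e6)           # local cM/Mb
  thr_l <- rate_fraction * fit$slopes_cM_per_Mb[1]
  thr_r <- rate_fraction * fit$slopes_cM_per_Mb[3]
  run_from <- function(rates, thr) {
    k <- 0
    for (v in rates) {
      if (!is.na(v) && thr > 0 && v < thr) k <- k + 1 else break
    }
    k
  }
  kl <- run_from(rate, thr_l)
  kr <- run_from(rev(rate), thr_r)
  n <- length(x)
  left <- if (kl >= min_run) x[kl + 1] else x[1]
  right <- if (kr >= min_run) x[n - kr] else x[n]
  list(left_tip_end_bp = left, right_tip_start_bp = right,
       left_span0 = kl < min_run, right_span0 = kr < min_run)
}

#' Build a chromosome-domain table from segmented fits and tip calls
#'
#' Assembles the five-domain (left tip, left arm, center, right arm, right
#' tip) summary per chromosome: sizes in kb, percentages of chromosome
#' length (1 decimal), right-end positions, and recombination rates from the
#' fitted slopes rescaled so that each chromosome's genetic length is 50 cM.
#' Tip rates are reported as 0.
#'
#' @param chrom_fits Named list (one entry per chromosome) of lists with
#'   elements `fit` (a `marey_segfit`), `tips` (from [call_tip_domains()]),
#'   `total_cM` (the chromosome's map length), and `chrom_length_bp`.
#' @return Data frame of class `domain_table` with columns `chrom`, `domain`,
#'   `size_kb`, `size_pct`, `right_end_kb`, `rate_cM_per_Mb`.
#' @export
build_domain_table <- function(chrom_fits) {
  rows <- lapply(names(chrom_fits), function(ch) {
    z <- chrom_fits[[ch]]
    if (z$total_cM <= 0) stop("chromosome ", ch, " has zero genetic length")
    L <- z$chrom_length_bp
    ltip <- if (isTRUE(z$tips$left_span0)) 0 else z$tips$left_tip_end_bp
    rtip <- if (isTRUE(z$tips$right_span0)) L else z$tips$right_tip_start_bp
    b <- sort(pmin(pmax(z$fit$breakpoints_bp, ltip), rtip))
    bounds <- c(0, ltip, b[1], b[2], rtip, L)
    if (any(diff(bounds) < 0)) stop("inconsistent domain boundaries on ", ch)
    scale <- 50 / z$total_cM
    rates <- c(0, z$fit$slopes_cM_per_Mb * scale, 0)
    sizes <- diff(bounds)
    data.frame(chrom = ch,
               domain = c("left_tip", "left_arm", "center", "right_arm", "right_tip"),
               size_kb = sizes / 1000,
               size_pct = round(100 * sizes / L, 1),
               right_end_kb = bounds[-1] / 1000,
               rate_cM_per_Mb = rates)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("domain_table", class(out))
  out
}

#' @export
print.domain_table <- function(x, ...) {
  cat("Chromosome domain table (rates scaled to 50 cM per chromosome)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
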