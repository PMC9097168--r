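# Overlap of variant positions with selective-sweep windows: merged-interval
# counting, a uniform-redraw permutation test, per-tissue counts with length
# normalization and between-study comparisons.

# windows data frame (chrom, start, end; 0-based half-open) -> GRanges
.windows_gr <- function(windows) {
  GenomicRanges::GRanges(
    seqnames = windows$chrom,
    ranges = IRanges::IRanges(start = windows$start + 1L, end = windows$end))
}

#' Merge overlapping windows within a set
#'
#' Overlapping or adjacent windows are merged (via `GenomicRanges::reduce`)
#' before any overlap counting, so the result is invariant under re-merging.
#'
#' @param windows data frame with `chrom`, `start` (0-based, inclusive),
#'   `end` (exclusive).
#' @return merged windows in the same 0-based half-open convention, sorted.
#' @export
merge_windows <- function(windows) {
  stopifnot(all(c("chrom", "start", "end") %in% names(windows)))
  if (any(windows$start >= windows$end))
    stop_config("windows must satisfy start < end")
  red <- GenomicRanges::reduce(.windows_gr(windows))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1L,
                    end = GenomicRanges::end(red),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# fast membership of 1-based positions in merged (disjoint, sorted) windows
.in_merged <- function(chrom, pos, merged) {
  out <- logical(length(pos))
  for (cr in unique(chrom)) {
    sel <- chrom == cr
    w <- merged[merged$chrom == cr, , drop = FALSE]
    if (!nrow(w)) next
    bounds <- as.numeric(t(cbind(w$start, w$end)))
    # 0-based coordinate x: inside iff an odd number of bounds are <= x
    k <- findInterval(pos[sel] - 1L, bounds,
                      rightmost.closed = FALSE, left.open = FALSE)
    out[sel] <- k %% 2L == 1L
  }
  out
}

#' Which positions fall inside a window set
#'
#' @param positions data frame with `chrom` and `pos` (1-based).
#' @param windows window set (merged internally).
#' @return logical vector, one entry per position.
#' @export
position_in_windows <- function(positions, windows) {
  .in_merged(positions$chrom, positions$pos, merge_windows(windows))
}

#' Count variant positions overlapping a window set
#'
#' Windows are merged first; each position counts at most once. A width-1
#' interval per variant is the overlap unit. Positions and windows must
#' share a chromosome naming scheme: disjoint chromosome sets raise an
#' error listing the offenders.
#'
#' @inheritParams position_in_windows
#' @return integer overlap count.
#' @export
#' @examples
#' w <- data.frame(chrom = "c1", start = c(0, 20), end = c(10, 30))
#' p <- data.frame(chrom = "c1", pos = c(5, 15, 25))
#' count_window_overlaps(p, w)  # 2
count_window_overlaps <- function(positions, windows) {
  if (nrow(windows) == 0 || nrow(positions) == 0) return(0L)
  pc <- unique(positions$chrom); wc <- unique(windows$chrom)
  if (!length(intersect(pc, wc)))
    stop_config("chromosome naming mismatch between positions and windows: ",
                "positions use {", paste(pc, collapse = ", "),
                "}, windows use {", paste(wc, collapse = ", "), "}")
  sum(position_in_windows(positions, windows))
}

#' Permutation test for variant overlap with sweep windows
#'
#' Each permutation redraws all variant positions uniformly over the genome
#' (per chromosome, proportional to length) and recounts the overlap with
#' the merged windows, the randomization regioneR applies to a query set.
#' The empirical p-value uses the +1 correction,
#' `p = (1 + #\{perm >= observed\}) / (N + 1)`, so it is never zero and is
#' floored at `1/(N+1)`.
#'
#' @param positions data frame with `chrom`, `pos` (1-based).
#' @param windows window set (0-based half-open; merged internally).
#' @param chrom_lengths named vector of chromosome lengths covering every
#'   position and window.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional seed; fixed seed gives an identical permuted-count
#'   vector.
#' @return object of class `permutation_result`: observed count, permuted
#'   counts, expected (their mean), empirical `p.value` and `z`.
#' @export
sweep_permutation_test <- function(positions, windows, chrom_lengths,
                                   n_perm = 1000, seed = NULL) {
  if (!is_count(n_perm)) stop_config("n_perm must be a positive count")
  chroms <- names(chrom_lengths)
  if (!all(positions$chrom %in% chroms))
    stop_config("positions on chromosomes absent from the genome")
  if (!all(windows$chrom %in% chroms))
    stop_config("windows on chromosomes absent from the genome")
  if (any(windows$end > chrom_lengths[windows$chrom]) ||
      any(positions$pos > chrom_lengths[positions$chrom]))
    stop_config("genome shorter than the supplied positions/windows")

  merged <- merge_windows(windows)
  obs <- sum(.in_merged(positions$chrom, positions$pos, merged))

  # merged windows in concatenated genome coordinates for a vectorized
  # membership check per permutation
  offset <- setNames(cumsum(c(0, as.numeric(chrom_lengths)))[seq_along(chroms)],
                     chroms)
  gbounds <- as.numeric(t(cbind(merged$start + offset[merged$chrom],
                                merged$end + offset[merged$chrom])))
  o <- order(gbounds)
  gbounds <- gbounds[o]
  total <- sum(as.numeric(chrom_lengths))
  npos <- nrow(positions)

  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      x <- runif(npos) * total        # 0-based global coordinates
      sum(findInterval(x, gbounds) %% 2L == 1L)
    }, integer(1))
  })

  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  sdp <- sd(perm)
  structure(list(observed = obs, permuted = perm,
                 expected = mean(perm), p.value = p,
                 z = if (!is.na(sdp) && sdp > 0) (obs - mean(perm)) / sdp
                     else NA_real_,
                 n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation overlap test (N =", x$n_perm, "): observed =", x$observed,
      ", expected =", format(x$expected, digits = 4),
      ", p =", format(x$p.value, digits = 4),
      ", z =", format(x$z, digits = 3), "\n")
  invisible(x)
}

#' Per-tissue sweep overlap counts and length-normalized rates
#'
#' Counts, per tissue and per window source, the eQTL variant positions
#' falling inside the source's merged windows, and normalizes by the merged
#' window length (counts per megabase) so sources with systematically wider
#' windows are comparable.
#'
#' @param eqtl_positions data frame with `chrom`, `pos`, `tissue` and
#'   `variant_id` (counted once per tissue).
#' @param windows window data frame with a `source` column.
#' @return list with matrices `counts` and `rates` (tissue x source) and the
#'   named vector `window_mb` of merged lengths.
#' @export
per_region_counts <- function(eqtl_positions, windows) {
  stopifnot(all(c("chrom", "pos", "tissue") %in% names(eqtl_positions)))
  sources <- sort(unique(windows$source))
  tissues <- sort(unique(eqtl_positions$tissue))
  counts <- matrix(0L, nrow = length(tissues), ncol = length(sources),
                   dimnames = list(tissues, sources))
  mb <- setNames(numeric(length(sources)), sources)
  for (s in sources) {
    merged <- merge_windows(windows[windows$source == s, , drop = FALSE])
    mb[s] <- sum(merged$end - merged$start) / 1e6
    for (t in tissues) {
      d <- eqtl_positions[eqtl_positions$tissue == t, , drop = FALSE]
      if ("variant_id" %in% names(d)) d <- d[!duplicated(d$variant_id), ]
      counts[t, s] <- sum(.in_merged(d$chrom, d$pos, merged))
    }
  }
  rates <- sweep(counts, 2L, mb, "/")
  list(counts = counts, rates = rates, window_mb = mb)
}

#' Dunn post-hoc rank test
#'
#' Pairwise z-statistics between groups based on pooled ranks, with a tie
#' correction, following a Kruskal-Wallis test; p-values are two-sided and
#' multiplicity-adjusted (Bonferroni by default).
#'
#' @param x numeric values.
#' @param g group labels.
#' @param method p-adjustment method (see [stats::p.adjust()]).
#' @return data frame with `group1`, `group2`, `z`, `p.value`, `p.adj`.
#' @export
dunn_test <- function(x, g, method = "bonferroni") {
  g <- factor(g)
  if (nlevels(g) < 2) stop_config("dunn_test needs at least two groups")
  r <- rank(x)
  N <- length(x)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  mr <- tapply(r, g, mean)
  ng <- tapply(r, g, length)
  cmb <- combn(levels(g), 2)
  z <- apply(cmb, 2, function(pair) {
    (mr[pair[1]] - mr[pair[2]]) /
      sqrt(s2 * (1 / ng[pair[1]] + 1 / ng[pair[2]]))
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(group1 = cmb[1, ], group2 = cmb[2, ], z = as.numeric(z),
             p.value = p, p.adj = p.adjust(p, method = method),
             stringsAsFactors = FALSE)
}

#' Compare sweep sources on length-normalized per-tissue rates
#'
#' Paired two-sided Wilcoxon signed-rank test between the two sources'
#' per-tissue rates (controls for window-length differences), and a
#' Kruskal-Wallis test across tissues followed by Dunn pairwise comparisons
#' with Bonferroni adjustment.
#'
#' @param rates tissue x source matrix of normalized rates (from
#'   [per_region_counts()]).
#' @return list with `wilcoxon` (htest), `kruskal` (htest) and `dunn`
#'   (data frame).
#' @export
compare_sweep_sources <- function(rates) {
  if (ncol(rates) != 2) stop_config("expected exactly two sources")
  d <- rates[, 1] - rates[, 2]
  if (all(d == 0))
    stop_config("all paired differences are zero; the Wilcoxon signed-rank ",
                "test is undefined")
  wt <- suppressWarnings(
    wilcox.test(rates[, 1], rates[, 2], paired = TRUE, exact = FALSE))
  values <- as.vector(rates)
  tissues <- rep(rownames(rates), times = ncol(rates))
  kw <- kruskal.test(values, factor(tissues))
  dn <- dunn_test(values, tissues)
  list(wilcoxon = wt, kruskal = kw, dunn = dn)
}
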