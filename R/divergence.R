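# Moderated two-class divergence statistic with permutation-based
# median-false-positive FDR control.
#
# Each orthologous region contributes one unpaired two-class comparison:
# the species-A structure values versus the species-B values, moderated by an
# additive exchangeability constant s0. Significance comes from global
# permutations of the species labels over dataset columns (one reassignment
# applied to all regions, preserving inter-region correlation); the FDR at a
# candidate cut pair is the median, over permutations, of the number of
# permuted scores beyond the cuts, divided by the number of observed calls.

#' Moderated unpaired difference statistic for one region
#'
#' `d = (mean_A - mean_B) / (s + s0)` where `s` is the pooled standard error
#' of the mean difference (classical unpaired two-sample form). Antisymmetric
#' under class swap.
#'
#' @param values_A,values_B numeric vectors with >= 2 values each.
#' @param s0 exchangeability constant (>= 0) stabilising low-variance regions.
#' @return single numeric `d`.
#' @export
region_statistic <- function(values_A, values_B, s0 = 0) {
  if (length(values_A) < 2 || length(values_B) < 2)
    stopf("each class needs at least 2 values")
  if (s0 < 0) stopf("`s0` must be >= 0")
  nA <- length(values_A); nB <- length(values_B)
  sp2 <- ((nA - 1) * var(values_A) + (nB - 1) * var(values_B)) / (nA + nB - 2)
  s <- sqrt(sp2 * (1 / nA + 1 / nB))
  (mean(values_A) - mean(values_B)) / (s + s0)
}

# vectorised statistic over all rows of V for many label assignments at once.
# W: columns x perms 0/1 matrix of A-membership. Returns list(d, s).
sam_stat_block <- function(V, V2, s1tot, s2tot, W, nA, nB, s0) {
  S1A <- V %*% W
  S2A <- V2 %*% W
  mA <- S1A / nA
  mB <- (s1tot - S1A) / nB
  ssA <- pmax(S2A - S1A^2 / nA, 0)
  ssB <- pmax((s2tot - S2A) - (s1tot - S1A)^2 / nB, 0)
  sp2 <- (ssA + ssB) / (nA + nB - 2)
  s <- sqrt(sp2 * (1 / nA + 1 / nB))
  list(d = (mA - mB) / (s + s0), s = s, num = mA - mB)
}

#' Estimate the exchangeability constant s0
#'
#' @param s non-negative per-region pooled standard errors.
#' @param method `"median"` (the median of `s`; the default) or
#'   `"percentile_grid"`: evaluate candidate percentiles of `s` and return the
#'   one minimising the coefficient of variation of the median absolute
#'   deviation of `d` across `s`-quantile bands (requires `numerators`).
#' @param numerators per-region mean differences, needed for the grid method.
#' @param probs candidate percentiles for the grid method.
#' @param n_bands number of `s`-quantile bands for the grid method.
#' @return single numeric s0.
#' @export
estimate_s0 <- function(s, method = c("median", "percentile_grid"),
                        numerators = NULL, probs = seq(0, 1, 0.05),
                        n_bands = 10L) {
  method <- match.arg(method)
  if (!length(s)) stopf("empty input")
  if (any(s < 0)) stopf("`s` values must be non-negative")
  if (method == "median") return(median(s))
  if (is.null(numerators) || length(numerators) != length(s))
    stopf("percentile_grid needs `numerators` matching `s`")
  br <- unique(quantile(s, seq(0, 1, length.out = n_bands + 1)))
  band <- cut(s, br, include.lowest = TRUE)
  cand <- unique(quantile(s, probs))
  cv <- vapply(cand, function(s0) {
    disp <- tapply(abs(numerators / (s + s0)), band, mad)
    disp <- disp[is.finite(disp) & disp > 0]
    if (length(disp) < 2) return(Inf)
    sd(disp) / mean(disp)
  }, numeric(1))
  as.numeric(cand[which.min(cv)])
}

# all distinct assignments of nA columns (out of m) to class A, as 0/1 matrix
enumerate_assignments <- function(m, nA) {
  combos <- utils::combn(m, nA)
  W <- matrix(0, m, ncol(combos))
  W[cbind(as.vector(combos), rep(seq_len(ncol(combos)), each = nA))] <- 1
  W
}

# SAM-style cut pair for a given delta: smallest upper order statistic whose
# departure from the permutation-expected score reaches delta (and the
# mirrored lower cut). k0 = index where the expected scores cross zero.
delta_cuts <- function(d_sorted, dbar, delta) {
  k0 <- which.min(abs(dbar))
  diffs <- d_sorted - dbar
  up <- which(seq_along(d_sorted) >= k0 & diffs >= delta)
  lo <- which(seq_along(d_sorted) <= k0 & diffs <= -delta)
  c(cut_low = if (length(lo)) d_sorted[max(lo)] else -Inf,
    cut_up = if (length(up)) d_sorted[min(up)] else Inf)
}

#' Call structurally divergent regions with permutation FDR control
#'
#' Computes the moderated statistic for every region, builds the permutation
#' null by reassigning species labels to dataset columns (exhaustively when
#' the number of distinct assignments is at most `exhaustive_max`, otherwise
#' `n_perm` Monte-Carlo draws), and selects the loosest cut pair whose
#' estimated FDR (median permuted exceedance count over observed calls) does
#' not exceed `fdr_target`. Calls are necessarily bipolar: polarity +1 marks
#' regions open in species A / closed in species B, -1 the reverse.
#'
#' @param x a normalised `StructureMatrix` with >= 2 columns per species.
#' @param fdr_target target FDR in (0, 1); default 2e-4.
#' @param n_perm Monte-Carlo permutation count (ignored when the label space
#'   is enumerated exhaustively); default 1e5.
#' @param seed integer seed for Monte-Carlo label draws.
#' @param s0 exchangeability constant; estimated from the observed pooled
#'   standard errors via `s0_method` when `NULL`.
#' @param s0_method passed to [estimate_s0()].
#' @param cut_method `"delta"` (asymmetric SAM-style cut search on the
#'   observed order statistics; default) or `"abs"` (symmetric `|d|` cutoff).
#' @param exhaustive_max enumerate all label assignments when their number is
#'   at most this (default 10000).
#' @param species optional length-2 character giving which species label is
#'   class A then class B; defaults to the order of appearance.
#' @return an object of class `DivergenceResult`: `regions` (the input region
#'   table plus `d`, `polarity`, `mean_A`, `mean_B`), and global fields `s0`,
#'   `cut_up`, `cut_low`, `n_perm_used`, `exhaustive`, `fdr_target`,
#'   `fdr_achieved`, `n_calls`, `no_calls`, `seed`, and `expected_scores`
#'   (data.frame of sorted observed scores against permutation-expected
#'   scores, the Q-Q surface).
#' @export
call_divergence <- function(x, fdr_target = 2e-4, n_perm = 1e5, seed = 1L,
                            s0 = NULL, s0_method = "median",
                            cut_method = c("delta", "abs"),
                            exhaustive_max = 10000L, species = NULL) {
  stopifnot(inherits(x, "StructureMatrix"))
  if (x$stage != "normalised")
    stopf("call_divergence expects a quantile-normalised StructureMatrix")
  fdr_target <- check_fraction(fdr_target, "fdr_target", open_lo = TRUE, open_hi = TRUE)
  n_perm <- check_count(n_perm, "n_perm")
  seed <- check_seed(seed)
  cut_method <- match.arg(cut_method)

  sp <- x$datasets$species
  if (is.null(species)) species <- unique(sp)
  if (length(species) != 2 || !all(species %in% sp))
    stopf("need exactly two species present in the dataset labels")
  isA <- sp == species[1]
  nA <- sum(isA); nB <- sum(!isA); m <- length(sp)
  if (nA < 2 || nB < 2) stopf("need >= 2 dataset columns per species")

  V <- x$values
  n <- nrow(V)
  V2 <- V * V
  s1tot <- rowSums(V); s2tot <- rowSums(V2)

  obs <- sam_stat_block(V, V2, s1tot, s2tot,
                        matrix(as.numeric(isA), m, 1), nA, nB, s0 = 0)
  s_obs <- as.vector(obs$s)
  num_obs <- as.vector(obs$num)
  if (is.null(s0))
    s0 <- estimate_s0(s_obs, method = s0_method, numerators = num_obs)
  if (s0 == 0 && any(s_obs == 0))
    stopf("zero pooled standard error with s0 = 0; supply a positive s0")
  d_obs <- num_obs / (s_obs + s0)

  n_assign <- choose(m, nA)
  exhaustive <- n_assign <= exhaustive_max
  if (exhaustive) {
    W <- enumerate_assignments(m, nA)
  } else {
    W <- withr::with_seed(seed, {
      idx <- replicate(n_perm, sample.int(m, nA))
      Wm <- matrix(0, m, n_perm)
      Wm[cbind(as.vector(idx), rep(seq_len(n_perm), each = nA))] <- 1
      Wm
    })
  }
  P <- ncol(W)

  # permuted scores, chunked to bound memory at scale; sorted columns are
  # kept in memory when small, otherwise recomputed on the second pass
  chunk <- max(50L, min(P, floor(4e7 / n)))
  d_sorted <- sort(d_obs)
  keep_sorted <- as.numeric(n) * P <= 5e7
  perm_sorted_chunks <- function(fun) {
    for (from in seq(1, P, by = chunk)) {
      to <- min(from + chunk - 1L, P)
      D <- sam_stat_block(V, V2, s1tot, s2tot, W[, from:to, drop = FALSE],
                          nA, nB, s0)$d
      fun(apply(D, 2, sort))
    }
  }
  sortsum <- numeric(n)
  sorted_cols <- list()
  perm_sorted_chunks(function(S) {
    sortsum <<- sortsum + rowSums(S)
    if (keep_sorted) sorted_cols[[length(sorted_cols) + 1L]] <<- S
  })
  dbar <- sortsum / P

  # candidate cut pairs, scanned loosest-first
  if (cut_method == "delta") {
    diffs <- d_sorted - dbar
    cand <- sort(unique(abs(diffs[is.finite(diffs)])))
    cand <- cand[cand > 0]
    if (length(cand) > 120)
      cand <- unique(quantile(cand, seq(0, 1, length.out = 120), type = 1))
    cut_tab <- vapply(cand, function(dd) delta_cuts(d_sorted, dbar, dd),
                      numeric(2))
  } else {
    cand <- sort(unique(abs(d_obs)))
    if (length(cand) > 120)
      cand <- unique(quantile(cand, seq(0, 1, length.out = 120), type = 1))
    cut_tab <- rbind(cut_low = -cand, cut_up = cand)
  }
  cuts_low <- cut_tab["cut_low", ]; cuts_up <- cut_tab["cut_up", ]
  ncand <- length(cand)

  # exceedance counts beyond every candidate cut pair, per permutation
  count_chunk <- function(S) {
    vapply(seq_len(ncol(S)), function(j) {
      col <- S[, j]
      lo <- ifelse(is.finite(cuts_low), findInterval(cuts_low, col), 0)
      up <- ifelse(is.finite(cuts_up),
                   n - findInterval(cuts_up, col, left.open = TRUE), 0)
      lo + up
    }, numeric(ncand))
  }
  if (keep_sorted) {
    counts <- do.call(cbind, lapply(sorted_cols, count_chunk))
  } else {
    parts <- list()
    perm_sorted_chunks(function(S) parts[[length(parts) + 1L]] <<- count_chunk(S))
    counts <- do.call(cbind, parts)
  }
  counts <- matrix(counts, nrow = ncand)

  chosen <- NULL
  for (k in seq_len(ncand)) {   # ascending = loosest first
    calls <- sum(d_obs >= cuts_up[k]) + sum(d_obs <= cuts_low[k])
    if (calls == 0) break
    fdr <- median(counts[k, ]) / calls
    if (fdr <= fdr_target) {
      chosen <- list(cuts = c(cut_low = cuts_low[k], cut_up = cuts_up[k]),
                     calls = calls, fdr = fdr)
      break
    }
  }

  regions <- x$regions
  regions$d <- d_obs
  regions$mean_A <- as.numeric(mean_structure(x, species[1]))
  regions$mean_B <- as.numeric(mean_structure(x, species[2]))
  if (is.null(chosen)) {
    warnf("no cut pair achieves FDR <= %g; zero regions called", fdr_target)
    regions$polarity <- 0L
    res <- list(cut_low = -Inf, cut_up = Inf, fdr_achieved = 0,
                n_calls = 0L, no_calls = TRUE)
  } else {
    regions$polarity <- ifelse(regions$d >= chosen$cuts["cut_up"], 1L,
                        ifelse(regions$d <= chosen$cuts["cut_low"], -1L, 0L))
    res <- list(cut_low = unname(chosen$cuts["cut_low"]),
                cut_up = unname(chosen$cuts["cut_up"]),
                fdr_achieved = chosen$fdr,
                n_calls = chosen$calls, no_calls = FALSE)
  }

  structure(c(list(regions = regions, species = species, s0 = s0,
                   n_perm_used = P, exhaustive = exhaustive,
                   fdr_target = fdr_target, seed = seed,
                   cut_method = cut_method,
                   expected_scores = data.frame(rank = seq_len(n),
                                                expected = dbar,
                                                observed = d_sorted)),
              res),
            class = "DivergenceResult")
}

#' @export
print.DivergenceResult <- function(x, ...) {
  cat(sprintf(
    "DivergenceResult: %d/%d regions called divergent (%.2f%%)\n  s0 = %.4g, cuts [%.3g, %.3g], FDR target %g achieved %.3g, %s%d permutations\n",
    x$n_calls, nrow(x$regions), 100 * x$n_calls / nrow(x$regions),
    x$s0, x$cut_low, x$cut_up, x$fdr_target, x$fdr_achieved,
    if (x$exhaustive) "exhaustive " else "", x$n_perm_used))
  invisible(x)
}

#' Classify regions into divergence classes
#'
#' Partitions regions into `nondivergent`, `divergent_open_A` (+1) and
#' `divergent_closed_A` (-1), and flags the absolute-value-restricted
#' subclasses: +1 calls whose mean normalised structure is positive in
#' species A and negative in species B (and mirrored for -1), i.e. divergence
#' in relative *and* absolute compartment assignment.
#'
#' @param result a [call_divergence()] result.
#' @param abs_threshold absolute open/closed boundary on the normalised scale
#'   (default 0).
#' @return data.frame `region_id`, `class`, `polarity`, `absolute` (logical).
#' @export
classify_regions <- function(result, abs_threshold = 0) {
  stopifnot(inherits(result, "DivergenceResult"))
  r <- result$regions
  cls <- ifelse(r$polarity == 1L, "divergent_open_A",
         ifelse(r$polarity == -1L, "divergent_closed_A", "nondivergent"))
  absolute <- (r$polarity == 1L & r$mean_A > abs_threshold & r$mean_B < abs_threshold) |
              (r$polarity == -1L & r$mean_A < abs_threshold & r$mean_B > abs_threshold)
  data.frame(region_id = r$region_id, class = cls, polarity = r$polarity,
             absolute = absolute)
}
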