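#' Smooth per-guide depletion scores along the protein
#'
#' Nadaraya-Watson kernel regression of the guide z-scores on their residue
#' coordinates: `signal(a) = sum_g K((a - aa_g)/h) z_g / sum_g K(...)` with
#' a Gaussian kernel and bandwidth `h` in residues. `support(a)` is the
#' kernel mass `sum_g K(...)`; residues with support below `min_support`
#' are masked (`NA` signal), so the track is only interpreted where guides
#' actually land. Control guides carry no position and are excluded.
#'
#' @param scores Output of [score_guides()] (needs `guide_id`, `z`).
#' @param library Guide library with `target_aa` per guide.
#' @param bandwidth Gaussian kernel bandwidth in residues (default 5).
#' @param min_support Mask residues whose kernel support falls below this
#'   (default 0.1).
#' @param protein_length Residues in the protein; defaults to the library's
#'   `protein_length` attribute, else the maximum targeted residue.
#' @return A `residue_track` data.frame with columns `residue`, `signal`,
#'   `support`, `p_emp` (NA until [permutation_null()] fills it);
#'   attributes `bandwidth`, `protein_length`.
#' @examples
#' fx <- make_itgb1_like_fixture(seed = 1, n_controls = 20)
#' sc <- simulate_screen(fx$library, fx$truth, seed = 2)
#' gs <- score_guides(sc, fx$library)
#' tr <- smooth_track(gs, fx$library)
#' head(tr)
#' @export
smooth_track <- function(scores, library, bandwidth = 5, min_support = 0.1,
                         protein_length = NULL) {
  stopifnot(is.data.frame(scores), bandwidth > 0)
  z <- scores$z[match(library$guide_id, scores$guide_id)]
  keep <- !library$is_control & !is.na(z)
  if (!any(keep)) stop("no targeting guides with finite scores")
  aa <- library$target_aa[keep]
  z <- z[keep]
  L <- protein_length %||% attr(library, "protein_length") %||% max(aa)
  K <- kernel_matrix(L, aa, bandwidth)
  support <- rowSums(K)
  signal <- as.vector(K %*% z) / support
  signal[support < min_support] <- NA_real_
  out <- data.frame(residue = seq_len(L), signal = signal, support = support,
                    p_emp = NA_real_)
  class(out) <- c("residue_track", "data.frame")
  attr(out, "bandwidth") <- bandwidth
  attr(out, "protein_length") <- L
  attr(out, "guide_aa") <- aa
  attr(out, "guide_z") <- z
  attr(out, "min_support") <- min_support
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

kernel_matrix <- function(L, aa, h) {
  u <- outer(seq_len(L), aa, FUN = function(a, g) (a - g) / h)
  exp(-0.5 * u * u)
}

#' Empirical per-residue p-values from a score-permutation null
#'
#' Shuffles the guide z-scores over the fixed guide positions `B` times and
#' re-smooths each shuffle, preserving the spatial density of the library.
#' The one-sided (depletion) empirical p-value at residue `a` is
#' `(1 + #\{null signal(a) <= observed signal(a)\}) / (B + 1)`, so the
#' smallest attainable value is `1 / (B + 1)`. Masked residues keep `NA`.
#'
#' @param track Output of [smooth_track()].
#' @param B Number of permutations (>= 100).
#' @param seed Optional RNG seed.
#' @return The input track with `p_emp` filled in.
#' @export
permutation_null <- function(track, B = 1000L, seed = NULL) {
  stopifnot(inherits(track, "residue_track"), B >= 100L)
  aa <- attr(track, "guide_aa")
  z <- attr(track, "guide_z")
  h <- attr(track, "bandwidth")
  L <- attr(track, "protein_length")
  K <- kernel_matrix(L, aa, h)
  support <- rowSums(K)
  obs <- track$signal
  with_seed_or_not(seed, {
    zp <- vapply(seq_len(B), function(b) sample(z), numeric(length(z)))
    null_sig <- (K %*% zp) / support            # L x B matrix
    le <- rowSums(null_sig <= obs)              # NA rows stay NA
    p <- (1 + le) / (B + 1)
    track$p_emp <- ifelse(is.na(obs), NA_real_, p)
    attr(track, "B") <- B
    track
  })
}

#' Call depleted regions from a residue track
#'
#' Benjamini-Hochberg-adjusts the per-residue empirical p-values over all
#' supported residues, keeps residues with adjusted p at or below `alpha`,
#' merges consecutive significant residues allowing gaps up to `max_gap`,
#' and drops merged regions shorter than `min_len`. Region score is the
#' mean smoothed signal over the region, region p the minimum adjusted p
#' within it; regions are ranked by score ascending (most depleted first).
#'
#' @param track A `residue_track` with `p_emp` (see [permutation_null()]).
#' @param alpha FDR level (default 0.05).
#' @param min_len Minimum region length in residues (default 3).
#' @param max_gap Maximum non-significant gap bridged inside a region
#'   (default 2).
#' @return `data.frame` with columns `start_aa`, `end_aa`, `score`, `p`,
#'   `rank`; zero rows when nothing is significant.
#' @export
call_regions <- function(track, alpha = 0.05, min_len = 3L, max_gap = 2L) {
  stopifnot(inherits(track, "residue_track"))
  if (all(is.na(track$p_emp))) stop("track has no empirical p-values; run permutation_null() first")
  ok <- !is.na(track$p_emp)
  adj <- rep(NA_real_, nrow(track))
  adj[ok] <- p.adjust(track$p_emp[ok], method = "BH")
  sig <- which(!is.na(adj) & adj <= alpha)
  empty <- data.frame(start_aa = integer(), end_aa = integer(),
                      score = numeric(), p = numeric(), rank = integer())
  if (!length(sig)) return(empty)
  runs <- merge_positions(sig, max_gap)
  runs <- runs[(runs$end - runs$start + 1L) >= min_len, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  out <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    idx <- runs$start[i]:runs$end[i]
    data.frame(start_aa = runs$start[i], end_aa = runs$end[i],
               score = mean(track$signal[idx], na.rm = TRUE),
               p = min(adj[idx], na.rm = TRUE))
  }))
  out <- out[order(out$score), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# group sorted positions into runs, bridging gaps of at most max_gap
# non-member positions
merge_positions <- function(pos, max_gap) {
  pos <- sort(unique(pos))
  brk <- c(TRUE, diff(pos) > max_gap + 1L)
  grp <- cumsum(brk)
  data.frame(start = tapply(pos, grp, min), end = tapply(pos, grp, max))
}

#' Consensus regions across independent screens
#'
#' Combines region calls from two or more screens of the same protein.
#' `"intersect"` (default, the strict reading of consensus) keeps, for each
#' overlapping combination across all screens, the common residue interval;
#' `"union"` merges overlapping calls into their envelope. Scores are
#' averaged over the member calls.
#'
#' @param calls_list List (length >= 2) of region `data.frame`s from
#'   [call_regions()].
#' @param mode `"intersect"` or `"union"`.
#' @return Region `data.frame` (`start_aa`, `end_aa`, `score`, `p`, `rank`).
#' @export
consensus_regions <- function(calls_list, mode = c("intersect", "union")) {
  mode <- match.arg(mode)
  stopifnot(is.list(calls_list), length(calls_list) >= 2L)
  acc <- calls_list[[1]]
  for (i in seq_along(calls_list)[-1]) {
    b <- calls_list[[i]]
    if (!nrow(acc) || !nrow(b)) {
      if (mode == "intersect") {
        acc <- acc[0, , drop = FALSE]
      } else {
        acc <- rbind(acc[, c("start_aa", "end_aa", "score", "p")],
                     b[, c("start_aa", "end_aa", "score", "p")])
      }
      next
    }
    rows <- list()
    for (j in seq_len(nrow(acc))) for (k in seq_len(nrow(b))) {
      s <- max(acc$start_aa[j], b$start_aa[k])
      e <- min(acc$end_aa[j], b$end_aa[k])
      if (s > e) next
      if (mode == "union") {
        s <- min(acc$start_aa[j], b$start_aa[k])
        e <- max(acc$end_aa[j], b$end_aa[k])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start_aa = s, end_aa = e,
        score = mean(c(acc$score[j], b$score[k])),
        p = max(acc$p[j], b$p[k]))
    }
    acc <- if (length(rows)) do.call(rbind, rows) else
      acc[0, c("start_aa", "end_aa", "score", "p"), drop = FALSE]
    if (mode == "union" && nrow(acc) > 1L) acc <- merge_intervals(acc)
  }
  acc <- acc[!duplicated(acc[, c("start_aa", "end_aa")]), , drop = FALSE]
  acc <- acc[order(acc$score), , drop = FALSE]
  acc$rank <- seq_len(nrow(acc))
  rownames(acc) <- NULL
  acc
}

merge_intervals <- function(df) {
  df <- df[order(df$start_aa), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1]) {
    last <- nrow(out)
    if (df$start_aa[i] <= out$end_aa[last]) {
      out$end_aa[last] <- max(out$end_aa[last], df$end_aa[i])
      out$score[last] <- mean(c(out$score[last], df$score[i]))
      out$p[last] <- max(out$p[last], df$p[i])
    } else {
      out <- rbind(out, df[i, , drop = FALSE])
    }
  }
  out
}

#' Recovery metrics of region calls against simulated truth
#'
#' For each truth domain, the best Jaccard overlap (inclusive residue
#' counting: `|intersection| / |union|`) over all calls is reported.
#' `recall` is the fraction of truth domains recovered at Jaccard >= 0.5;
#' `precision` is the fraction of calls overlapping any truth domain by at
#' least one residue.
#'
#' @param calls Region `data.frame` from [call_regions()].
#' @param truth A [sim_truth()].
#' @return List with `per_domain` (data.frame: `start_aa`, `end_aa`,
#'   `best_jaccard`), `mean_jaccard`, `recall`, `precision`, `n_calls`.
#' @examples
#' calls <- data.frame(start_aa = 150, end_aa = 168, score = -3,
#'                     p = 0.001, rank = 1)
#' truth <- sim_truth(798, data.frame(start_aa = 153, end_aa = 171, d = 1))
#' evaluate_calls(calls, truth)$per_domain
#' @export
evaluate_calls <- function(calls, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  dom <- truth$domains
  jac <- function(s1, e1, s2, e2) {
    inter <- max(0L, min(e1, e2) - max(s1, s2) + 1L)
    if (inter == 0L) return(0)
    inter / (max(e1, e2) - min(s1, s2) + 1L)
  }
  best <- vapply(seq_len(nrow(dom)), function(i) {
    if (!nrow(calls)) return(0)
    max(vapply(seq_len(nrow(calls)), function(j)
      jac(dom$start_aa[i], dom$end_aa[i], calls$start_aa[j],
          calls$end_aa[j]), numeric(1)))
  }, numeric(1))
  overlaps_truth <- vapply(seq_len(nrow(calls)), function(j) {
    any(vapply(seq_len(nrow(dom)), function(i)
      jac(dom$start_aa[i], dom$end_aa[i], calls$start_aa[j],
          calls$end_aa[j]) > 0, logical(1)))
  }, logical(1))
  list(per_domain = data.frame(start_aa = dom$start_aa, end_aa = dom$end_aa,
                               best_jaccard = best),
       mean_jaccard = if (nrow(dom)) mean(best) else NA_real_,
       recall = if (nrow(dom)) mean(best >= 0.5) else NA_real_,
       precision = if (nrow(calls)) mean(overlaps_truth) else NA_real_,
       n_calls = nrow(calls))
}
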