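#' Score per-guide depletion against non-targeting controls
#'
#' For each reference/screened replicate pair, guide frequencies are
#' computed with a pseudocount (`freq = (count + pc) / (colsum + pc * n)`),
#' the raw log2 fold-change `log2(freq_scr / freq_ref)` is centered on the
#' median of the control guides, and per-guide LFCs are averaged over
#' replicate pairs (then re-centered so the control median is exactly 0).
#' The robust z-score divides by `1.4826 * MAD` of the control LFCs, so a
#' control-like guide scores ~0 and depleted guides score negative.
#'
#' @param counts A `screen_counts` object (see [simulate_screen()] or
#'   [read_counts()]).
#' @param library Guide library `data.frame`; must contain every guide in
#'   `counts` with its `is_control` flag.
#' @param pseudocount Added to every count before frequencies (default 0.5).
#' @return `data.frame` with columns `guide_id`, `lfc`, `z`,
#'   `n_replicates_used`, `is_control`, in library order.
#' @examples
#' fx <- make_itgb1_like_fixture(seed = 1, n_controls = 20)
#' sc <- simulate_screen(fx$library, fx$truth, seed = 2)
#' head(score_guides(sc, fx$library))
#' @export
score_guides <- function(counts, library, pseudocount = 0.5) {
  stopifnot(inherits(counts, "screen_counts"), is.data.frame(library))
  if (!setequal(counts$guide_ids, library$guide_id))
    stop("guide sets in counts and library differ")
  m <- counts$counts[match(library$guide_id, counts$guide_ids), , drop = FALSE]
  if (any(colSums(m) == 0)) stop("zero-depth sample column")
  ref_idx <- which(counts$samples$condition == "reference")
  scr_idx <- which(counts$samples$condition == "screened")
  if (!length(ref_idx) || !length(scr_idx))
    stop("need at least one reference and one screened sample")
  n_pairs <- min(length(ref_idx), length(scr_idx))
  if (length(ref_idx) != length(scr_idx))
    warning("unequal replicate counts; pairing the first ", n_pairs,
            " of each arm")

  is_ctrl <- library$is_control
  if (!any(is_ctrl))
    warning("no control guides; centering on the all-guide median")
  center_set <- if (any(is_ctrl)) is_ctrl else rep(TRUE, nrow(library))

  freq <- function(col) (col + pseudocount) /
    (sum(col) + pseudocount * nrow(m))
  lfc_mat <- vapply(seq_len(n_pairs), function(i) {
    raw <- log2(freq(m[, scr_idx[i]]) / freq(m[, ref_idx[i]]))
    raw - median(raw[center_set])
  }, numeric(nrow(m)))
  lfc <- rowMeans(lfc_mat)
  lfc <- lfc - median(lfc[center_set])   # exact control centering

  ctrl_lfc <- lfc[center_set]
  sd_robust <- mad(ctrl_lfc)             # 1.4826 * median abs deviation
  z <- if (sd_robust > 0) (lfc - median(ctrl_lfc)) / sd_robust
       else rep(NA_real_, length(lfc))
  data.frame(guide_id = library$guide_id, lfc = lfc, z = z,
             n_replicates_used = n_pairs, is_control = is_ctrl)
}

#' Permutation-based gene ranking for multi-guide libraries
#'
#' A deliberately simple gene-level consumer for non-tiling libraries: the
#' gene score is the median z of its guides, and its one-sided depletion
#' p-value comes from `B` seeded draws of same-size non-targeting-control
#' guide sets, `p = (1 + #\{null <= observed\}) / (B + 1)`, followed by
#' Benjamini-Hochberg adjustment across genes. This is not an
#' alpha-RRA/MAGeCK reimplementation; it is a calibrated stand-in ranking.
#'
#' @param scores Output of [score_guides()].
#' @param library Guide library mapping `guide_id` to `gene`.
#' @param B Permutation draws per gene (default 1000).
#' @param seed Optional RNG seed.
#' @return `data.frame` with columns `gene`, `score`, `p`, `fdr`,
#'   `n_guides`, `flagged` (genes with < 2 guides), sorted by score.
#' @export
score_genes <- function(scores, library, B = 1000L, seed = NULL) {
  stopifnot(is.data.frame(scores), all(c("guide_id", "z") %in% names(scores)),
            B >= 1L)
  lib <- library[match(scores$guide_id, library$guide_id), , drop = FALSE]
  ctrl_z <- scores$z[lib$is_control]
  ctrl_z <- ctrl_z[!is.na(ctrl_z)]
  if (length(ctrl_z) < 20L)
    stop("gene ranking requires >= 20 control guides (found ",
         length(ctrl_z), ")")
  tgt <- !lib$is_control
  genes <- split(scores$z[tgt], lib$gene[tgt])

  with_seed_or_not(seed, {
    res <- lapply(names(genes), function(g) {
      z <- genes[[g]][!is.na(genes[[g]])]
      obs <- median(z)
      k <- length(z)
      null_med <- if (k <= length(ctrl_z)) {
        vapply(seq_len(B), function(b) median(sample(ctrl_z, k)),
               numeric(1))
      } else {   # more guides than controls: resample with replacement
        apply(matrix(sample(ctrl_z, B * k, replace = TRUE), nrow = B), 1,
              median)
      }
      p <- (1 + sum(null_med <= obs)) / (B + 1)
      data.frame(gene = g, score = obs, p = p, n_guides = k,
                 flagged = k < 2L)
    })
    out <- do.call(rbind, res)
    out$fdr <- p.adjust(out$p, method = "BH")
    out <- out[order(out$score, out$p), c("gene", "score", "p", "fdr",
                                          "n_guides", "flagged")]
    rownames(out) <- NULL
    out
  })
}
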