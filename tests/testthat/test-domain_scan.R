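toy_scores_lib <- function(aa, z, L, n_ctrl = 0) {
  n <- length(aa)
  lib <- data.frame(
    guide_id = c(sprintf("g%03d", seq_len(n)),
                 if (n_ctrl) sprintf("c%03d", seq_len(n_ctrl))),
    gene = "g", protospacer = "A", strand = "+",
    pam_pos_nt = NA_integer_,
    cut_nt = c(aa * 3L, rep(NA_integer_, n_ctrl)),
    target_aa = c(aa, rep(NA_integer_, n_ctrl)),
    is_control = c(rep(FALSE, n), rep(TRUE, n_ctrl)))
  attr(lib, "protein_length") <- L
  scores <- data.frame(guide_id = lib$guide_id,
                       lfc = c(z, rep(0, n_ctrl)),
                       z = c(z, rep(0, n_ctrl)),
                       is_control = lib$is_control)
  list(scores = scores, lib = lib)
}

test_that("a constant score field smooths to a constant track", {
  x <- toy_scores_lib(aa = c(5, 12, 20, 33, 40), z = rep(2.5, 5), L = 50)
  tr <- smooth_track(x$scores, x$lib, bandwidth = 5)
  expect_true(all(abs(tr$signal[!is.na(tr$signal)] - 2.5) < 1e-9))
})

test_that("a vanishing bandwidth recovers per-residue guide means", {
  x <- toy_scores_lib(aa = c(10, 10, 25), z = c(1, 3, -4), L = 40)
  tr <- smooth_track(x$scores, x$lib, bandwidth = 1e-3)
  expect_equal(tr$signal[10], 2)        # mean of the two guides at 10
  expect_equal(tr$signal[25], -4)
  expect_true(is.na(tr$signal[15]))     # no support between guides
})

test_that("smoothing equals the brute-force kernel sum", {
  for (seed in c(1, 99)) {
    withr::with_seed(seed, {
      aa <- sample(1:400, 200, replace = TRUE)
      z <- rnorm(200)
    })
    x <- toy_scores_lib(aa = aa, z = z, L = 400)
    for (h in c(2, 5, 11)) {
      tr <- smooth_track(x$scores, x$lib, bandwidth = h, min_support = 0)
      bf <- brute_force_smooth(aa, z, L = 400, h = h)
      expect_lt(max(abs(tr$signal - bf$signal)), 1e-10)
      expect_lt(max(abs(tr$support - bf$support)), 1e-10)
    }
  }
})

test_that("smoothing is linear in z and invariant to guide order", {
  withr::with_seed(5, {
    aa <- sample(1:100, 60, replace = TRUE)
    z <- rnorm(60)
  })
  x <- toy_scores_lib(aa, z, L = 100)
  tr <- smooth_track(x$scores, x$lib)
  perm <- sample(seq_along(aa))
  xp <- toy_scores_lib(aa[perm], z[perm], L = 100)
  trp <- smooth_track(xp$scores, xp$lib)
  expect_equal(trp$signal, tr$signal)
  x2 <- toy_scores_lib(aa, 2 * z, L = 100)
  tr2 <- smooth_track(x2$scores, x2$lib)
  expect_equal(tr2$signal, 2 * tr$signal)
})

test_that("permutation p-values respect the add-one floor and find implants", {
  withr::with_seed(8, {
    aa <- sort(sample(1:200, 120, replace = TRUE))
    z <- rnorm(120, 0, 0.5)
  })
  z[aa >= 80 & aa <= 100] <- -8       # implanted strong depletion block
  x <- toy_scores_lib(aa, z, L = 200)
  tr <- smooth_track(x$scores, x$lib)
  B <- 200
  tr <- permutation_null(tr, B = B, seed = 10)
  expect_true(all(tr$p_emp >= 1 / (B + 1), na.rm = TRUE))
  expect_equal(min(tr$p_emp[80:100]), 1 / (B + 1))
  calls <- call_regions(tr, alpha = 0.05)
  expect_gte(nrow(calls), 1L)
  expect_lte(calls$start_aa[1], 100)
  expect_gte(calls$end_aa[1], 80)
})

test_that("region merging follows the gap and length rules exactly", {
  # craft a track with known significant residues via a fake p field
  mk_track <- function(sig_res, L = 200) {
    tr <- structure(
      data.frame(residue = 1:L, signal = -1, support = 1,
                 p_emp = ifelse(1:L %in% sig_res, 1e-4, 0.9)),
      class = c("residue_track", "data.frame"),
      bandwidth = 5, protein_length = L)
    tr
  }
  # single run 153..171 is one call
  c1 <- call_regions(mk_track(153:171), alpha = 0.05, max_gap = 2)
  expect_equal(c1[, c("start_aa", "end_aa")],
               data.frame(start_aa = 153L, end_aa = 171L))
  # {150..160, 163..170}: gap of 2 bridges at max_gap >= 2? gap residues
  # 161..162 (2 missing) bridge when max_gap = 2
  c2 <- call_regions(mk_track(c(150:160, 163:170)), max_gap = 2)
  expect_equal(nrow(c2), 1L)
  c2b <- call_regions(mk_track(c(150:160, 164:170)), max_gap = 2)
  expect_equal(nrow(c2b), 2L)
  c3 <- call_regions(mk_track(c(150:160, 164:170)), max_gap = 3)
  expect_equal(c3[, c("start_aa", "end_aa")],
               data.frame(start_aa = 150L, end_aa = 170L))
  # min_len filters short runs
  c4 <- call_regions(mk_track(c(10:11, 50:60)), min_len = 3)
  expect_equal(c4$start_aa, 50L)
  # nothing significant: empty frame, not an error
  c5 <- call_regions(mk_track(integer(0)))
  expect_equal(nrow(c5), 0L)
})

test_that("lowering alpha never enlarges the significant set", {
  withr::with_seed(12, {
    aa <- sample(1:150, 90, replace = TRUE)
    z <- rnorm(90)
  })
  z[aa <= 30] <- z[aa <= 30] - 3
  x <- toy_scores_lib(aa, z, L = 150)
  tr <- permutation_null(smooth_track(x$scores, x$lib), B = 300, seed = 2)
  n_sig <- function(alpha) {
    ok <- !is.na(tr$p_emp)
    sum(p.adjust(tr$p_emp[ok], "BH") <= alpha)
  }
  alphas <- c(0.2, 0.1, 0.05, 0.01)
  expect_true(all(diff(vapply(alphas, n_sig, numeric(1))) <= 0))
})

test_that("consensus intersects call sets across screens", {
  a <- data.frame(start_aa = 153L, end_aa = 171L, score = -4, p = 0.001,
                  rank = 1L)
  b <- data.frame(start_aa = 150L, end_aa = 168L, score = -3, p = 0.002,
                  rank = 1L)
  cons <- consensus_regions(list(a, b))
  expect_equal(cons$start_aa, 153L)
  expect_equal(cons$end_aa, 168L)
  expect_equal(cons$score, -3.5)
  # idempotence on identical sets
  same <- consensus_regions(list(a, a))
  expect_equal(same[, c("start_aa", "end_aa")],
               a[, c("start_aa", "end_aa")])
  # disjoint sets yield nothing
  d <- data.frame(start_aa = 300L, end_aa = 320L, score = -2, p = 0.01,
                  rank = 1L)
  expect_equal(nrow(consensus_regions(list(a, d))), 0L)
  # union mode keeps the envelope
  u <- consensus_regions(list(a, b), mode = "union")
  expect_equal(u[, c("start_aa", "end_aa")],
               data.frame(start_aa = 150L, end_aa = 171L))
})

test_that("recovery metrics use inclusive-residue Jaccard", {
  truth <- sim_truth(798, data.frame(start_aa = 153, end_aa = 171, d = 1))
  exact <- data.frame(start_aa = 153L, end_aa = 171L, score = -1, p = 0.01,
                      rank = 1L)
  expect_equal(evaluate_calls(exact, truth)$per_domain$best_jaccard, 1)
  off <- data.frame(start_aa = 150L, end_aa = 168L, score = -1, p = 0.01,
                    rank = 1L)
  ev <- evaluate_calls(off, truth)
  expect_equal(ev$per_domain$best_jaccard, 16 / 22)
  expect_equal(ev$per_domain$best_jaccard,
               jaccard_enum(150, 168, 153, 171))
  expect_equal(ev$recall, 1)       # 16/22 >= 0.5
  expect_equal(ev$precision, 1)
  disjoint <- data.frame(start_aa = 400L, end_aa = 420L, score = -1,
                         p = 0.01, rank = 1L)
  ev2 <- evaluate_calls(disjoint, truth)
  expect_equal(ev2$per_domain$best_jaccard, 0)
  expect_equal(ev2$precision, 0)
})
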