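#' Ground truth for a simulated tiling screen
#'
#' Describes the protein, the implanted functional domains (intervals with a
#' per-residue in-frame disruption probability `d`), the selection regime,
#' and the experiment scale. Defaults mirror a pooled in vivo dropout
#' screen: three weeks of in vitro pre-depletion culture at one division per
#' day (21 generations), a further ~3 weeks of in vivo growth (20
#' generations) under selection deficit 0.3 for loss-of-function cells, at
#' least 1000 cells per guide and one million reads per sample.
#'
#' @param protein_length Protein length in residues.
#' @param domains `data.frame` with columns `start_aa`, `end_aa`, `d`
#'   (1-based inclusive intervals, non-overlapping, `d` in \[0, 1\]); zero
#'   rows means a neutral protein.
#' @param s_scr,s_ref Per-generation fitness deficit of loss-of-function
#'   cells in the screened / reference arm.
#' @param T_pre Pre-depletion generations shared by both arms.
#' @param T_scr Post-split generations (screened arm at `s_scr`, reference
#'   arm continues at `s_ref`).
#' @param coverage Cells instantiated per guide.
#' @param depth Sequencing reads per sample.
#' @param bottleneck Optional cells per guide surviving engraftment of the
#'   screened arm (`NULL` for no bottleneck).
#' @param seed Integer seed recorded with the truth.
#' @return An object of class `sim_truth`.
#' @examples
#' truth <- sim_truth(798, data.frame(start_aa = 153, end_aa = 171, d = 1))
#' @export
sim_truth <- function(protein_length,
                      domains = data.frame(start_aa = integer(),
                                           end_aa = integer(), d = numeric()),
                      s_scr = 0.3, s_ref = 0, T_pre = 21L, T_scr = 20L,
                      coverage = 1000L, depth = 1e6, bottleneck = NULL,
                      seed = NULL) {
  protein_length <- as.integer(protein_length)
  stopifnot(protein_length >= 1L, is.data.frame(domains),
            all(c("start_aa", "end_aa", "d") %in% names(domains)),
            s_scr >= 0, s_scr <= 1, s_ref >= 0, s_ref <= 1,
            T_pre >= 0, T_scr >= 0, coverage >= 1, depth >= 1)
  if (nrow(domains)) {
    domains <- domains[order(domains$start_aa), , drop = FALSE]
    rownames(domains) <- NULL
    with(domains, {
      stopifnot(all(start_aa >= 1), all(end_aa <= protein_length),
                all(start_aa <= end_aa), all(d >= 0), all(d <= 1))
      if (any(start_aa[-1] <= end_aa[-nrow(domains)]))
        stop("truth domains overlap")
    })
  }
  if (!is.null(bottleneck)) stopifnot(bottleneck >= 1)
  structure(list(protein_length = protein_length, domains = domains,
                 s_scr = s_scr, s_ref = s_ref, T_pre = as.numeric(T_pre),
                 T_scr = as.numeric(T_scr), coverage = as.integer(coverage),
                 depth = as.numeric(depth), bottleneck = bottleneck,
                 seed = seed),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0("<sim_truth> %d aa, %d domain(s); s_scr=%g s_ref=%g ",
                     "T_pre=%g T_scr=%g coverage=%d depth=%g\n"),
              x$protein_length, nrow(x$domains), x$s_scr, x$s_ref,
              x$T_pre, x$T_scr, x$coverage, x$depth))
  invisible(x)
}

#' In-frame disruption probability at given residues
#'
#' Looks up `d` from the truth domains at each residue; residues outside
#' every domain have `d = 0`. A guide on a domain boundary takes the value
#' at its own attributed residue only.
#'
#' @param truth A [sim_truth()].
#' @param aa Integer vector of residue indices.
#' @return Numeric vector of `d` values.
#' @export
disruption_at <- function(truth, aa) {
  stopifnot(inherits(truth, "sim_truth"))
  d <- numeric(length(aa))
  if (nrow(truth$domains)) {
    for (i in seq_len(nrow(truth$domains))) {
      hit <- !is.na(aa) & aa >= truth$domains$start_aa[i] &
        aa <= truth$domains$end_aa[i]
      d[hit] <- truth$domains$d[i]
    }
  }
  d[is.na(aa)] <- NA_real_
  d
}

#' Forward-simulate a pooled tiling dropout screen
#'
#' For each guide, `coverage` cells receive the guide; per-allele repair
#' outcomes (from `model`, with `d` looked up at the guide's residue;
#' controls cut nothing and stay fully functional) split the cells into a
#' loss-of-function class and a functional class. Class abundances then
#' evolve through `T_pre` generations of pre-depletion at `s_ref`, after
#' which the screened arm (optionally bottlenecked at engraftment) grows
#' `T_scr` generations at `s_scr` while the reference arm continues at
#' `s_ref`. Each sample's read counts are one multinomial draw of size
#' `depth` over guides proportional to final abundances.
#'
#' Two propagation modes are available: `"expectation"` (default)
#' propagates class frequencies deterministically, leaving stochasticity to
#' the engraftment bottleneck and sequencing; `"wright-fisher"` resamples
#' the whole population multinomially each generation at constant size
#' `coverage * n_guides`.
#'
#' @param library Guide library from [design_tiling_library()].
#' @param truth A [sim_truth()] with `protein_length` covering every
#'   targeting guide.
#' @param n_replicates Replicates per arm. Screened replicates are
#'   independent selection realizations (separate animals); reference
#'   replicates are independent sequencing draws from one culture.
#' @param model A [repair_outcome_model()].
#' @param mode `"expectation"` or `"wright-fisher"`.
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return An object of class `screen_counts`: list with `guide_ids`,
#'   `samples` (data.frame: `name`, `condition`, `replicate`), integer
#'   matrix `counts` (guides x samples, columns summing to `depth`), and
#'   the `truth` used.
#' @examples
#' fx <- make_itgb1_like_fixture(seed = 1, n_controls = 10)
#' sc <- simulate_screen(fx$library, fx$truth, n_replicates = 2, seed = 2)
#' colSums(sc$counts)
#' @export
simulate_screen <- function(library, truth, n_replicates = 2L,
                            model = repair_outcome_model(),
                            mode = c("expectation", "wright-fisher"),
                            seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "sim_truth"), n_replicates >= 1L,
            is.data.frame(library), nrow(library) >= 1L)
  tgt <- library[!library$is_control, , drop = FALSE]
  if (nrow(tgt) && max(tgt$target_aa) > truth$protein_length)
    stop("library targets residues beyond truth$protein_length")

  d <- disruption_at(truth, library$target_aa)
  f <- ifelse(library$is_control, 0, loss_fraction(model, ifelse(is.na(d), 0, d)))
  n_g <- nrow(library)

  with_seed_or_not(seed, {
    if (mode == "expectation") {
      # class weights after shared pre-depletion (per starting cell)
      w_lof <- f * (1 - truth$s_ref)^truth$T_pre
      w_wt <- 1 - f
      a_ref <- f * (1 - truth$s_ref)^(truth$T_pre + truth$T_scr) + (1 - f)
      scr_cols <- lapply(seq_len(n_replicates), function(r) {
        if (!is.null(truth$bottleneck)) {
          p_lof <- ifelse(w_lof + w_wt > 0, w_lof / (w_lof + w_wt), 0)
          n_lof <- rbinom(n_g, truth$bottleneck, p_lof)
          n_lof * (1 - truth$s_scr)^truth$T_scr + (truth$bottleneck - n_lof)
        } else {
          w_lof * (1 - truth$s_scr)^truth$T_scr + w_wt
        }
      })
      ref_cols <- replicate(n_replicates, a_ref, simplify = FALSE)
    } else {
      pop0 <- wf_init(n_g, truth$coverage, f)
      pop_pre <- wf_evolve(pop0, fit_lof = 1 - truth$s_ref, gens = truth$T_pre)
      ref_pop <- wf_evolve(pop_pre, fit_lof = 1 - truth$s_ref,
                           gens = truth$T_scr)
      ref_cols <- replicate(n_replicates, rowSums(ref_pop), simplify = FALSE)
      scr_cols <- lapply(seq_len(n_replicates), function(r) {
        p <- pop_pre
        if (!is.null(truth$bottleneck)) {
          keep <- min(1, truth$bottleneck / truth$coverage)
          p <- matrix(rbinom(length(p), as.vector(p), keep), nrow = n_g)
        }
        rowSums(wf_evolve(p, fit_lof = 1 - truth$s_scr, gens = truth$T_scr))
      })
    }

    seq_col <- function(a) {
      tot <- sum(a)
      if (tot <= 0) stop("screen arm went extinct; cannot sequence")
      as.integer(rmultinom(1, size = truth$depth, prob = a / tot))
    }
    counts <- vapply(c(ref_cols, scr_cols), seq_col, integer(n_g))
    samples <- data.frame(
      name = c(sprintf("reference_%d", seq_len(n_replicates)),
               sprintf("screened_%d", seq_len(n_replicates))),
      condition = rep(c("reference", "screened"), each = n_replicates),
      replicate = rep(seq_len(n_replicates), times = 2L))
    colnames(counts) <- samples$name
    rownames(counts) <- library$guide_id
    structure(list(guide_ids = library$guide_id, samples = samples,
                   counts = counts, truth = truth),
              class = "screen_counts")
  })
}

# columns: lof, wt cell counts per guide
wf_init <- function(n_g, coverage, f) {
  n_lof <- rbinom(n_g, coverage, f)
  cbind(lof = n_lof, wt = coverage - n_lof)
}

# constant-size Wright-Fisher resampling over all guide x class categories
wf_evolve <- function(pop, fit_lof, gens) {
  n_total <- sum(pop)
  for (g in seq_len(round(gens))) {
    w <- c(pop[, "lof"] * fit_lof, pop[, "wt"])
    if (sum(w) <= 0) break
    draw <- as.integer(rmultinom(1, n_total, w / sum(w)))
    pop <- cbind(lof = draw[seq_len(nrow(pop))],
                 wt = draw[-seq_len(nrow(pop))])
  }
  pop
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("<screen_counts> %d guides x %d samples (depth %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts[, 1]), big.mark = ",")))
  print(x$samples)
  invisible(x)
}

#' Integrin-beta-1-like simulation fixture
#'
#' A synthetic stand-in for a saturating tiling screen of a 798-residue
#' single-pass receptor: a random 2394-nt CDS (seeded sense codons), its
#' full tiling library with non-targeting controls, and a ground truth that
#' implants five functional domains at residues 153-171, 248-254, 280-295,
#' 305-314 and 359-363, the first carrying the largest in-frame disruption
#' probability. The CDS is synthetic; only the domain coordinates and the
#' screen scale are modeled on a real experiment.
#'
#' @param seed Integer seed (CDS, controls and truth derive from it).
#' @param n_controls Non-targeting controls in the library.
#' @param d_max Disruption probability of the strongest domain (153-171).
#' @param d_other Disruption probability of the remaining four domains.
#' @param coverage,depth,s_scr,s_ref,T_pre,T_scr,bottleneck Passed to
#'   [sim_truth()].
#' @return List with elements `cds`, `library`, `truth`.
#' @examples
#' fx <- make_itgb1_like_fixture(seed = 7)
#' fx$truth$domains
#' @export
make_itgb1_like_fixture <- function(seed, n_controls = 99L, d_max = 1,
                                    d_other = 0.8, coverage = 500L,
                                    depth = 1e6, s_scr = 0.3, s_ref = 0,
                                    T_pre = 21L, T_scr = 20L,
                                    bottleneck = NULL) {
  n_aa <- 798L
  sense_codons <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA"))
  seq <- with_seed_or_not(stage_seed(seed, "fixture"),
                          paste(sample(sense_codons, n_aa, replace = TRUE),
                                collapse = ""))
  cds <- coding_sequence("itgb1_like_synthetic", seq)
  lib <- design_tiling_library(cds, n_controls = n_controls,
                               seed = stage_seed(seed, "design"))
  truth <- sim_truth(
    protein_length = n_aa,
    domains = data.frame(start_aa = c(153L, 248L, 280L, 305L, 359L),
                         end_aa = c(171L, 254L, 295L, 314L, 363L),
                         d = c(d_max, rep(d_other, 4L))),
    s_scr = s_scr, s_ref = s_ref, T_pre = T_pre, T_scr = T_scr,
    coverage = coverage, depth = depth, bottleneck = bottleneck, seed = seed)
  list(cds = cds, library = lib, truth = truth)
}
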