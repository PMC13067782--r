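#' Diploid Cas9 repair-outcome model
#'
#' After a Cas9 double-strand break, error-prone repair yields a frameshift
#' indel with probability `p_frameshift` (default 2/3) or an in-frame indel
#' with probability `p_inframe` (default 1/3), independently on each allele.
#' A frameshift abolishes the allele; an in-frame indel abolishes it only
#' with probability `d`, the per-residue disruption parameter (0 for an
#' unimportant position, 1 inside a critical functional domain). An
#' `efficiency` knob (default 1: every allele is cut and repaired) scales
#' the per-allele probability of receiving any edit.
#'
#' @param p_frameshift Per-allele frameshift probability.
#' @param p_inframe Per-allele in-frame probability; must sum to 1 with
#'   `p_frameshift`.
#' @param ploidy Number of alleles per cell (integer >= 1).
#' @param efficiency Per-allele editing efficiency in \[0, 1\].
#' @return An object of class `repair_outcome_model`.
#' @examples
#' m <- repair_outcome_model()
#' loss_fraction(m, d = 0)   # 4/9 of cells retain no functional allele
#' loss_fraction(m, d = 1)   # 1: every edited cell loses function
#' @export
repair_outcome_model <- function(p_frameshift = 2 / 3,
                                 p_inframe = 1 - p_frameshift,
                                 ploidy = 2L, efficiency = 1) {
  stopifnot(p_frameshift >= 0, p_frameshift <= 1,
            p_inframe >= 0, p_inframe <= 1,
            efficiency >= 0, efficiency <= 1)
  if (abs(p_frameshift + p_inframe - 1) > 1e-12)
    stop("p_frameshift + p_inframe must equal 1")
  ploidy <- as.integer(ploidy)
  if (is.na(ploidy) || ploidy < 1L) stop("ploidy must be an integer >= 1")
  structure(list(p_frameshift = p_frameshift, p_inframe = p_inframe,
                 ploidy = ploidy, efficiency = efficiency),
            class = "repair_outcome_model")
}

#' Fraction of guide-receiving cells with zero functional alleles
#'
#' Each allele independently becomes non-functional with probability
#' `efficiency * (p_frameshift + p_inframe * d)`; a cell displays loss of
#' function only when all `ploidy` alleles are hit, so
#' `loss_fraction = (efficiency * (p_frameshift + p_inframe * d))^ploidy`.
#' With the defaults (2/3 frameshift, 1/3 in-frame, diploid, full editing)
#' this spans 4/9 (~44\%, non-disruptive in-frame mutations, d = 0) up to
#' 100\% (fully critical site, d = 1).
#'
#' @param model A [repair_outcome_model()].
#' @param d Disruption probability of an in-frame mutation at the targeted
#'   residue; vectorized over \[0, 1\].
#' @return Numeric vector of loss-of-function cell fractions.
#' @examples
#' loss_fraction(repair_outcome_model(), d = c(0, 0.5, 1))
#' @export
loss_fraction <- function(model, d) {
  stopifnot(inherits(model, "repair_outcome_model"))
  if (any(is.na(d)) || any(d < 0) || any(d > 1))
    stop("d must lie in [0, 1]")
  (model$efficiency * (model$p_frameshift + model$p_inframe * d))^model$ploidy
}

#' Monte-Carlo allele-outcome simulation
#'
#' Mechanistic simulation of `n_cells` cells: each allele is independently
#' edited (with probability `efficiency`), repaired as frameshift or
#' in-frame, and an in-frame allele is disrupted with probability `d`.
#' Returns the empirical fraction of cells with no functional allele, the
#' stochastic counterpart of the closed-form [loss_fraction()].
#'
#' @inheritParams loss_fraction
#' @param n_cells Number of simulated cells.
#' @param seed Optional RNG seed.
#' @return Empirical loss-of-function fraction (scalar).
#' @examples
#' simulate_allele_outcomes(repair_outcome_model(), d = 0, n_cells = 1e4,
#'                          seed = 1)
#' @export
simulate_allele_outcomes <- function(model, d, n_cells, seed = NULL) {
  stopifnot(inherits(model, "repair_outcome_model"),
            length(d) == 1L, d >= 0, d <= 1, n_cells >= 1)
  with_seed_or_not(seed, {
    n <- as.integer(n_cells) * model$ploidy
    edited <- runif(n) < model$efficiency
    frameshift <- runif(n) < model$p_frameshift
    disrupted <- runif(n) < d
    nonfunctional <- edited & (frameshift | (!frameshift & disrupted))
    per_cell <- matrix(nonfunctional, ncol = model$ploidy)
    mean(rowSums(per_cell) == model$ploidy)
  })
}

#' Selection parameters for the two screen arms
#'
#' Loss-of-function cells grow with relative fitness `1 - s` per generation.
#' The reference arm (in vitro culture) applies deficit `s_ref` for `T_ref`
#' generations; the screened arm (in vivo growth) applies `s_scr` for
#' `T_scr` generations.
#'
#' @param s_ref,s_scr Per-generation fitness deficits in \[0, 1\].
#' @param T_ref,T_scr Generation counts (>= 0).
#' @return An object of class `selection_params`.
#' @export
selection_params <- function(s_ref = 0, s_scr = 0.3, T_ref = 20L,
                             T_scr = 20L) {
  stopifnot(s_ref >= 0, s_ref <= 1, s_scr >= 0, s_scr <= 1,
            T_ref >= 0, T_scr >= 0)
  structure(list(s_ref = s_ref, s_scr = s_scr,
                 T_ref = as.numeric(T_ref), T_scr = as.numeric(T_scr)),
            class = "selection_params")
}

#' Expected guide abundance ratio under selection
#'
#' A guide's cell population is a mixture of a loss-of-function class
#' (fraction `f`, from [loss_fraction()]) and a fully functional class.
#' Relative to the functional class, arm `c` retains abundance
#' `A_c = f * (1 - s_c)^{T_c} + (1 - f)`. The screened-to-reference ratio
#' `A_scr / A_ref` (before the population-level renormalization applied by
#' the scoring stage) is the expected depletion of that guide; its log2 is
#' floored at `log2_floor` when the screened abundance is zero.
#'
#' @param f Loss-of-function cell fraction(s) in \[0, 1\]; vectorized.
#' @param sel A [selection_params()].
#' @param log2_floor Lower bound for the log2 ratio (default -10).
#' @return A data.frame with columns `a_scr`, `a_ref`, `ratio`, `lfc`.
#' @examples
#' sel <- selection_params(s_ref = 0, s_scr = 0.2, T_ref = 10, T_scr = 10)
#' expected_abundance_ratio(4 / 9, sel)
#' @export
expected_abundance_ratio <- function(f, sel, log2_floor = -10) {
  stopifnot(inherits(sel, "selection_params"))
  if (any(is.na(f)) || any(f < 0) || any(f > 1)) stop("f must lie in [0, 1]")
  a_scr <- f * (1 - sel$s_scr)^sel$T_scr + (1 - f)
  a_ref <- f * (1 - sel$s_ref)^sel$T_ref + (1 - f)
  ratio <- a_scr / a_ref
  lfc <- ifelse(ratio > 0, pmax(log2(ratio), log2_floor), log2_floor)
  data.frame(a_scr = a_scr, a_ref = a_ref, ratio = ratio, lfc = lfc)
}
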