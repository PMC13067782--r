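# Independent oracles, written before (and kept independent of) the package
# implementations they check.

# Exhaustive trinucleotide-window scan for SpCas9 guides on both strands.
# Walks every window with explicit substring arithmetic; no code shared with
# design_tiling_library().
brute_force_guides <- function(seq, flank5 = "", flank3 = "") {
  len <- nchar(seq)
  rc1 <- function(s) chartr("ACGT", "TGCA",
                            paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  out <- list()
  n_dropped <- 0L
  for (i in seq_len(max(0L, len - 2L))) {
    win <- substr(seq, i, i + 2L)
    # plus strand: window is the PAM itself (NGG)
    if (substr(win, 2L, 3L) == "GG") {
      cut <- i - 3L
      if (cut >= 1L && cut <= len) {
        ext <- paste0(flank5, seq)
        off <- nchar(flank5)
        if (off + i - 20L >= 1L) {
          out[[length(out) + 1L]] <- data.frame(
            strand = "+", pam_pos_nt = i, cut_nt = cut,
            protospacer = substr(ext, off + i - 20L, off + i - 1L))
        } else n_dropped <- n_dropped + 1L
      }
    }
    # minus strand: window is CCN on the coding strand
    if (substr(win, 1L, 2L) == "CC") {
      cut <- i + 6L
      if (cut >= 1L && cut <= len) {
        ext <- paste0(seq, flank3)
        if (i + 22L <= nchar(ext)) {
          out[[length(out) + 1L]] <- data.frame(
            strand = "-", pam_pos_nt = i, cut_nt = cut,
            protospacer = rc1(substr(ext, i + 3L, i + 22L)))
        } else n_dropped <- n_dropped + 1L
      }
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(strand = character(), pam_pos_nt = integer(),
               cut_nt = integer(), protospacer = character())
  attr(df, "n_dropped") <- n_dropped
  df
}

# Direct double-loop Gaussian kernel regression.
brute_force_smooth <- function(aa, z, L, h) {
  sig <- numeric(L)
  sup <- numeric(L)
  for (a in seq_len(L)) {
    num <- 0
    den <- 0
    for (g in seq_along(aa)) {
      k <- exp(-((a - aa[g])^2) / (2 * h^2))
      num <- num + k * z[g]
      den <- den + k
    }
    sig[a] <- num / den
    sup[a] <- den
  }
  list(signal = sig, support = sup)
}

# Random valid CDS (sense codons only, so the frame carries no stops).
random_cds <- function(n_codons, seed, id = "rand") {
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  withr::with_seed(seed, {
    coding_sequence(id, paste(sample(codons, n_codons, replace = TRUE),
                              collapse = ""))
  })
}

# Inclusive-interval Jaccard by explicit residue enumeration.
jaccard_enum <- function(s1, e1, s2, e2) {
  a <- s1:e1; b <- s2:e2
  length(intersect(a, b)) / length(union(a, b))
}
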