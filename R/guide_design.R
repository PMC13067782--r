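#' Coding sequence container
#'
#' Bundle a coding sequence (CDS) with optional flanking genomic context.
#' The sequence must be plain DNA (`A`/`C`/`G`/`T`), non-empty, and an exact
#' number of codons; the encoded protein length is `nchar(seq) / 3`.
#' Flanks supply protospacer context for guides whose 20-nt protospacer
#' overhangs a CDS end (the PAM and cut site must still lie inside the CDS).
#'
#' @param id Sequence identifier (used as the default gene name).
#' @param seq CDS nucleotide string over `A`,`C`,`G`,`T`; length a multiple
#'   of 3.
#' @param flank5,flank3 Optional upstream / downstream context strings.
#' @return An object of class `coding_sequence`.
#' @examples
#' cds <- coding_sequence("toy", "ATGGCTGGTTCAGACTAA")
#' protein_length(cds)
#' @export
coding_sequence <- function(id, seq, flank5 = "", flank3 = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- toupper(as.character(seq))
  flank5 <- toupper(as.character(flank5))
  flank3 <- toupper(as.character(flank3))
  check_dna(seq, what = sprintf("CDS '%s'", id))
  if (nchar(seq) == 0L)
    stop("CDS '", id, "' is empty")
  if (nchar(seq) %% 3L != 0L)
    stop("CDS '", id, "' length (", nchar(seq), ") is not a multiple of 3")
  for (fl in list(c("flank5", flank5), c("flank3", flank3)))
    if (nzchar(fl[[2]])) check_dna(fl[[2]], what = paste0(fl[[1]], " of '", id, "'"))
  structure(list(id = id, seq = seq, flank5 = flank5, flank3 = flank3),
            class = "coding_sequence")
}

check_dna <- function(seq, what = "sequence") {
  bad <- regmatches(seq, regexpr("[^ACGT]", seq))
  if (length(bad) && nzchar(bad))
    stop(what, " contains non-ACGT character '", bad, "'",
         if (bad %in% c("U")) " (RNA input? expected DNA)" else "")
  invisible(TRUE)
}

#' @rdname coding_sequence
#' @param x A `coding_sequence`.
#' @export
protein_length <- function(x) {
  stopifnot(inherits(x, "coding_sequence"))
  nchar(x$seq) %/% 3L
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d nt (%d aa), flanks %d/%d nt\n",
              x$id, nchar(x$seq), protein_length(x),
              nchar(x$flank5), nchar(x$flank3)))
  invisible(x)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Map a CDS cut-site coordinate to its residue
#'
#' The blunt SpCas9 cut falls between two nucleotides; `cut_nt` is the first
#' nucleotide 3' of the cut on the coding strand, and the guide is attributed
#' to the residue whose codon contains that nucleotide:
#' `floor((cut_nt - 1) / 3) + 1` (1-based).
#'
#' @param cut_nt Integer vector of 1-based CDS nucleotide coordinates.
#' @param cds_length CDS length in nucleotides.
#' @return Integer vector of 1-based residue indices.
#' @examples
#' map_cut_to_residue(c(1, 3, 4, 457), cds_length = 2394)
#' @export
map_cut_to_residue <- function(cut_nt, cds_length) {
  cut_nt <- as.integer(cut_nt)
  if (any(is.na(cut_nt)) || any(cut_nt < 1L) || any(cut_nt > cds_length))
    stop("cut_nt out of range [1, ", cds_length, "]")
  (cut_nt - 1L) %/% 3L + 1L
}

#' Design a saturating tiling sgRNA library
#'
#' Enumerates one guide per NGG PAM inside the CDS, on both strands, whose
#' blunt cut site (between protospacer positions 17 and 18, i.e. 3 bp 5' of
#' the PAM) falls inside the CDS. Plus-strand PAM starting at coding-strand
#' position `p` cuts at `cut_nt = p - 3`; a minus-strand PAM (a `CCN` on the
#' coding strand starting at `q`; `pam_pos_nt = q`) cuts at `cut_nt = q + 6`.
#' Protospacers overhanging a CDS end are completed from the flanks when
#' available, otherwise the candidate is dropped and recorded in the
#' `"dropped"` attribute. Non-targeting controls are seeded random 20-mers
#' checked against both strands of the CDS.
#'
#' @param cds A [coding_sequence()].
#' @param n_controls Number of non-targeting control guides to append.
#' @param gene Gene label for targeting guides (default: `cds$id`).
#' @param seed Integer seed for control-protospacer generation; required for
#'   reproducible control sequences when `n_controls > 0`.
#' @return A `data.frame` with columns `guide_id`, `gene`, `protospacer`,
#'   `strand`, `pam_pos_nt`, `cut_nt`, `target_aa`, `is_control`; targeting
#'   guides sorted by `cut_nt` then strand, controls last with `NA`
#'   positional fields. Attributes: `protein_length`, `cds_id`, `dropped`
#'   (data.frame of overhang-dropped candidates).
#' @examples
#' cds <- coding_sequence("toy", paste(rep("ATGGCAGGTTCA", 5), collapse = ""))
#' lib <- design_tiling_library(cds, n_controls = 3, seed = 1)
#' head(lib)
#' @export
design_tiling_library <- function(cds, n_controls = 0L, gene = cds$id,
                                  seed = NULL) {
  stopifnot(inherits(cds, "coding_sequence"))
  n_controls <- as.integer(n_controls)
  stopifnot(n_controls >= 0L)
  s <- cds$seq
  len <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]

  rows <- list()
  dropped <- list()

  # plus strand: NGG with first PAM base at p; full PAM inside the CDS
  gg <- which(ch[-len] == "G" & ch[-1] == "G")   # positions of first G
  for (g1 in gg) {
    p <- g1 - 1L
    if (p < 1L || p + 2L > len) next
    cut_nt <- p - 3L
    if (cut_nt < 1L || cut_nt > len) next
    lo <- p - 20L
    if (lo >= 1L) {
      proto <- substr(s, lo, p - 1L)
    } else {
      need <- 1L - lo                      # bases missing on the 5' side
      if (nchar(cds$flank5) >= need) {
        proto <- paste0(substr(cds$flank5, nchar(cds$flank5) - need + 1L,
                               nchar(cds$flank5)),
                        substr(s, 1L, p - 1L))
      } else {
        dropped[[length(dropped) + 1L]] <-
          data.frame(pam_pos_nt = p, strand = "+", reason = "protospacer_overhang")
        next
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      protospacer = proto, strand = "+", pam_pos_nt = p, cut_nt = cut_nt)
  }

  # minus strand: NGG on the minus strand appears as CCN on the coding
  # strand starting at q; the minus-strand protospacer lies 3' of q + 2
  cc <- which(ch[-len] == "C" & ch[-1] == "C")
  for (q in cc) {
    if (q + 2L > len) next
    cut_nt <- q + 6L
    if (cut_nt < 1L || cut_nt > len) next
    hi <- q + 22L
    if (hi <= len) {
      proto <- revcomp(substr(s, q + 3L, hi))
    } else {
      need <- hi - len
      if (nchar(cds$flank3) >= need) {
        proto <- revcomp(paste0(substr(s, q + 3L, len),
                                substr(cds$flank3, 1L, need)))
      } else {
        dropped[[length(dropped) + 1L]] <-
          data.frame(pam_pos_nt = q, strand = "-", reason = "protospacer_overhang")
        next
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      protospacer = proto, strand = "-", pam_pos_nt = q, cut_nt = cut_nt)
  }

  lib <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protospacer = character(), strand = character(),
               pam_pos_nt = integer(), cut_nt = integer())
  if (nrow(lib)) {
    lib <- lib[order(lib$cut_nt, lib$strand != "+"), , drop = FALSE]
    lib$target_aa <- map_cut_to_residue(lib$cut_nt, len)
    lib$gene <- gene
    lib$is_control <- FALSE
    lib$guide_id <- sprintf("%s_nt%04d_%s", gene, lib$cut_nt,
                            ifelse(lib$strand == "+", "fw", "rv"))
    stopifnot(!anyDuplicated(lib[, c("pam_pos_nt", "strand")]))
  } else {
    lib$target_aa <- integer(); lib$gene <- character()
    lib$is_control <- logical(); lib$guide_id <- character()
  }

  if (n_controls > 0L) {
    protos <- with_seed_or_not(seed, random_control_protospacers(n_controls, s))
    ctrl <- data.frame(
      protospacer = protos, strand = NA_character_, pam_pos_nt = NA_integer_,
      cut_nt = NA_integer_, target_aa = NA_integer_, gene = "control",
      is_control = TRUE, guide_id = sprintf("ctrl_%03d", seq_len(n_controls)))
    lib <- rbind(lib, ctrl)
  }

  lib <- lib[, c("guide_id", "gene", "protospacer", "strand", "pam_pos_nt",
                 "cut_nt", "target_aa", "is_control")]
  rownames(lib) <- NULL
  attr(lib, "protein_length") <- len %/% 3L
  attr(lib, "cds_id") <- cds$id
  attr(lib, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(pam_pos_nt = integer(), strand = character(), reason = character())
  lib
}

# Seeded random 20-mers rejected if they match the target on either strand.
random_control_protospacers <- function(n, cds_seq) {
  rc <- revcomp(cds_seq)
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 100L * n) stop("could not generate control protospacers")
    cand <- paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
                  collapse = "")
    if (grepl(cand, cds_seq, fixed = TRUE) || grepl(cand, rc, fixed = TRUE))
      next
    out <- c(out, cand)
  }
  out
}

#' Guide-count arithmetic for a multi-gene library plan
#'
#' Sanity-check the size of a fixed-density library (a set number of guides
#' per gene plus shared non-targeting controls), as used for pooled screens
#' that are not saturating tiling libraries.
#'
#' @param n_genes Number of targeted genes.
#' @param guides_per_gene Guides designed per gene.
#' @param n_controls Non-targeting controls in the pool.
#' @return A list with `n_targeting`, `n_controls` and `n_total`.
#' @examples
#' plan_library(n_genes = 581, guides_per_gene = 5, n_controls = 68)
#' @export
plan_library <- function(n_genes, guides_per_gene, n_controls = 0L) {
  stopifnot(n_genes >= 1, guides_per_gene >= 1, n_controls >= 0)
  n_t <- as.integer(n_genes) * as.integer(guides_per_gene)
  list(n_targeting = n_t, n_controls = as.integer(n_controls),
       n_total = n_t + as.integer(n_controls))
}
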