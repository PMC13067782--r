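#' Read coding sequences from a FASTA file
#'
#' Parses a (possibly multi-record) FASTA file into [coding_sequence()]
#' objects, preserving record order. Sequences are uppercased; any letter
#' outside `A`/`C`/`G`/`T` (including RNA `U`) is rejected with the
#' offending line number. CRLF line endings and trailing blank lines are
#' accepted.
#'
#' @param path FASTA file path.
#' @return List of `coding_sequence` objects, named by record id (the
#'   first whitespace-delimited token of each header).
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("empty FASTA file: ", path)
  if (!startsWith(lines[nonblank[1]], ">"))
    stop("malformed FASTA: line ", nonblank[1], " is not a header")
  for (i in nonblank) {
    ln <- lines[i]
    if (startsWith(ln, ">")) next
    bad <- regmatches(ln, regexpr("[^ACGTacgt]", trimws(ln)))
    if (length(bad) && nzchar(bad))
      stop("invalid sequence character '", bad, "' on line ", i,
           if (toupper(bad) == "U") " (RNA input? expected DNA)" else "")
  }
  # character validation done above; Biostrings handles record assembly
  dss <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(dss), "\\s+"), `[`, character(1), 1L)
  out <- lapply(seq_along(dss), function(i)
    coding_sequence(ids[i], as.character(dss[[i]])))
  names(out) <- ids
  out
}

#' Write / read a guide-library TSV
#'
#' Single tab-separated dialect used throughout the package: UTF-8, LF line
#' endings, a header row, 1-based inclusive coordinates, and `NA` for the
#' positional fields of control guides.
#'
#' @param library Guide library `data.frame` (see
#'   [design_tiling_library()]).
#' @param path Output / input file path.
#' @param protein_length Optional override when reading a library whose
#'   protein length is not `max(target_aa)` (stored as `# protein_length`
#'   metadata on write).
#' @return `write_library` returns `path` invisibly; `read_library` returns
#'   the library `data.frame` with its `protein_length` attribute.
#' @export
write_library <- function(library, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  pl <- attr(library, "protein_length")
  if (!is.null(pl))
    writeLines(paste0("# protein_length\t", pl), con, sep = "\n")
  writeLines(paste(names(library), collapse = "\t"), con, sep = "\n")
  body <- apply(library, 1, function(r) paste(ifelse(is.na(r), "NA",
                                                     trimws(r)),
                                              collapse = "\t"))
  if (length(body)) writeLines(body, con, sep = "\n")
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path, protein_length = NULL) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  meta <- grep("^# ", lines, value = TRUE)
  lines <- lines[!startsWith(lines, "# ")]
  lib <- read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("guide_id", "gene", "protospacer", "strand", "pam_pos_nt",
            "cut_nt", "target_aa", "is_control")
  if (!all(need %in% names(lib)))
    stop("library TSV missing columns: ",
         paste(setdiff(need, names(lib)), collapse = ", "))
  if (anyDuplicated(lib$guide_id)) stop("duplicated guide_id in library")
  lib$is_control <- as.logical(lib$is_control)
  pl_meta <- sub("^# protein_length\t", "",
                 grep("^# protein_length\t", meta, value = TRUE))
  attr(lib, "protein_length") <- protein_length %||%
    (if (length(pl_meta)) as.integer(pl_meta[1]) else
       max(lib$target_aa, na.rm = TRUE))
  lib
}

#' Write / read a guide-count matrix TSV
#'
#' Layout: a `#condition` metadata line naming each sample column's
#' condition (`reference` or `screened`), a header row (`guide_id` plus
#' sample names), then one integer row per guide. Replicate indices are the
#' per-condition column order. Writing then reading a canonical matrix is
#' byte-identical.
#'
#' @param counts A `screen_counts` object.
#' @param path File path.
#' @return `write_counts` returns `path` invisibly; `read_counts` returns a
#'   `screen_counts` object (without simulation truth).
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "screen_counts"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("#condition", counts$samples$condition),
                   collapse = "\t"), con, sep = "\n")
  writeLines(paste(c("guide_id", counts$samples$name), collapse = "\t"),
             con, sep = "\n")
  body <- vapply(seq_along(counts$guide_ids), function(i)
    paste(c(counts$guide_ids[i], counts$counts[i, ]), collapse = "\t"),
    character(1))
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("counts TSV too short: ", path)
  if (!startsWith(lines[1], "#condition"))
    stop("counts TSV must start with a '#condition' metadata line")
  cond <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  bad <- setdiff(unique(cond), c("reference", "screened"))
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  header <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  sample_names <- header[-1]
  if (length(sample_names) != length(cond))
    stop("condition line and header disagree on sample count")
  cells <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  guide_ids <- vapply(cells, `[`, character(1), 1L)
  if (anyDuplicated(guide_ids)) stop("duplicated guide_id in counts")
  mat <- t(vapply(cells, function(r) {
    v <- r[-1]
    if (length(v) != length(sample_names))
      stop("row for guide '", r[1], "' has ", length(v), " values, expected ",
           length(sample_names))
    iv <- suppressWarnings(as.numeric(v))
    if (any(is.na(iv)) || any(iv != floor(iv)))
      stop("non-integer count for guide '", r[1], "'")
    if (any(iv < 0)) stop("negative count for guide '", r[1], "'")
    as.integer(iv)
  }, integer(length(sample_names))))
  colnames(mat) <- sample_names
  rownames(mat) <- guide_ids
  repl <- stats::ave(seq_along(cond), cond, FUN = seq_along)
  structure(list(guide_ids = guide_ids,
                 samples = data.frame(name = sample_names, condition = cond,
                                      replicate = repl),
                 counts = mat, truth = NULL),
            class = "screen_counts")
}

#' Write analysis tables
#'
#' `write_track` writes the per-residue track (`residue`, `signal`,
#' `support`, `p_emp`); `write_regions` writes region calls with 1-based
#' inclusive coordinates; `write_regions_bed` exports the same calls in
#' BED-like 0-based half-open coordinates (`start0 = start_aa - 1`,
#' `end0 = end_aa`) for browser-style protein tracks.
#'
#' @param track A `residue_track`.
#' @param regions Region calls from [call_regions()].
#' @param path File path.
#' @param name Track name used in the BED `name` column prefix.
#' @return The path, invisibly.
#' @export
write_track <- function(track, path) {
  write_tsv_plain(as.data.frame(track)[, c("residue", "signal", "support",
                                           "p_emp")], path)
}

#' @rdname write_track
#' @export
write_regions <- function(regions, path) {
  write_tsv_plain(regions[, c("start_aa", "end_aa", "score", "p", "rank")],
                  path)
}

#' @rdname write_track
#' @export
write_regions_bed <- function(regions, path, name = "region") {
  bed <- data.frame(chrom = "protein",
                    start0 = regions$start_aa - 1L,
                    end0 = regions$end_aa,
                    name = sprintf("%s_%d", name, regions$rank),
                    score = regions$score)
  con <- file(path, open = "wb")
  on.exit(close(con))
  body <- apply(bed, 1, function(r) paste(trimws(r), collapse = "\t"))
  writeLines(as.character(body), con, sep = "\n")
  invisible(path)
}

write_tsv_plain <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    body <- apply(df, 1, function(r) paste(ifelse(is.na(r), "NA", trimws(r)),
                                           collapse = "\t"))
    writeLines(as.character(body), con, sep = "\n")
  }
  invisible(path)
}

#' Write / read guide scores TSV
#' @param scores Output of [score_guides()].
#' @param path File path.
#' @return The path invisibly / the scores `data.frame`.
#' @export
write_scores <- function(scores, path) write_tsv_plain(scores, path)

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("guide_id", "lfc", "z") %in% names(df)))
    stop("scores TSV missing guide_id/lfc/z columns")
  if ("is_control" %in% names(df)) df$is_control <- as.logical(df$is_control)
  df
}
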