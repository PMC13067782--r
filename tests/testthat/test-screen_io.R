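test_that("FASTA round trip preserves records, order and sequence", {
  cds1 <- random_cds(20, seed = 1, id = "alpha")
  cds2 <- random_cds(30, seed = 2, id = "beta")
  f <- tempfile(fileext = ".fa")
  write_cds_fasta(list(cds1, cds2), f, width = 17)
  back <- read_cds_fasta(f)
  expect_equal(names(back), c("alpha", "beta"))
  expect_equal(back$alpha$seq, cds1$seq)
  expect_equal(back$beta$seq, cds2$seq)
})

test_that("CRLF and trailing-blank-line FASTA parse identically to LF", {
  cds <- random_cds(15, seed = 3, id = "crlf")
  lf <- tempfile(); crlf <- tempfile()
  lines <- c(">crlf", substring(cds$seq, c(1, 21, 41), c(20, 40, 45)))
  writeLines(lines, lf, sep = "\n")
  writeLines(c(lines, "", ""), crlf, sep = "\r\n")
  a <- read_cds_fasta(lf)
  b <- read_cds_fasta(crlf)
  expect_equal(a$crlf$seq, b$crlf$seq)
})

test_that("malformed FASTA fails with a line-numbered message", {
  f1 <- tempfile()
  writeLines(c("ACGT", ">late-header"), f1)
  expect_error(read_cds_fasta(f1), "line 1")
  f2 <- tempfile()
  writeLines(c(">rna", "ACGUACG"), f2)
  expect_error(read_cds_fasta(f2), "line 2.*RNA")
  f3 <- tempfile()
  writeLines(c(">x", "ACGT", "ACXT"), f3)
  expect_error(read_cds_fasta(f3), "'X' on line 3")
  expect_error(read_cds_fasta(tempfile()), "not found")
})

test_that("library TSV round trips with metadata intact", {
  cds <- random_cds(50, seed = 9)
  lib <- design_tiling_library(cds, n_controls = 5, seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_library(lib, f)
  back <- read_library(f)
  expect_equal(back$guide_id, lib$guide_id)
  expect_equal(back$cut_nt, lib$cut_nt)
  expect_equal(back$is_control, lib$is_control)
  expect_equal(attr(back, "protein_length"), 50L)
})

test_that("counts TSV round trips byte-identically and rejects bad input", {
  fx <- make_itgb1_like_fixture(seed = 5, n_controls = 5, coverage = 50,
                                depth = 1e4)
  sc <- simulate_screen(fx$library, fx$truth, n_replicates = 2, seed = 6)
  f1 <- tempfile(); f2 <- tempfile()
  write_counts(sc, f1)
  back <- read_counts(f1)
  expect_equal(unname(back$counts), unname(sc$counts))
  expect_equal(back$samples$condition, sc$samples$condition)
  expect_equal(back$samples$replicate, sc$samples$replicate)
  write_counts(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  bad <- function(lines) {
    f <- tempfile(); writeLines(lines, f); f
  }
  expect_error(read_counts(bad(c("#condition\ttumor", "guide_id\ts1",
                                 "g1\t5"))), "unknown condition")
  expect_error(read_counts(bad(c("#condition\treference", "guide_id\ts1",
                                 "g1\t5.5"))), "non-integer")
  expect_error(read_counts(bad(c("#condition\treference", "guide_id\ts1",
                                 "g1\t-2"))), "negative")
  expect_error(read_counts(bad(c("#condition\treference", "guide_id\ts1",
                                 "g1\t5", "g1\t6"))), "duplicated")
  expect_error(read_counts(bad(c("guide_id\ts1", "g1\t5", "g2\t6"))),
               "#condition")
})

test_that("a hand-written three-guide counts file parses to the expected matrix", {
  f <- tempfile()
  writeLines(c("#condition\treference\tscreened",
               "guide_id\tday0\ttumor",
               "gA\t10\t1",
               "gB\t20\t40",
               "gC\t5\t5"), f)
  sc <- read_counts(f)
  expect_equal(unname(sc$counts),
               matrix(c(10L, 20L, 5L, 1L, 40L, 5L), ncol = 2))
  expect_equal(sc$guide_ids, c("gA", "gB", "gC"))
  expect_equal(sc$samples$condition, c("reference", "screened"))
})

test_that("run configuration enforces its schema", {
  cfg <- list(fasta = "x.fa", seed = 1,
              simulation = list(s_scr = 0.3),
              analysis = list(alpha = 0.05))
  expect_s3_class(read_run_config(cfg), "run_config")
  expect_error(read_run_config(c(cfg, list(typo_key = 1))), "unknown config")
  expect_error(read_run_config(list(fasta = "x.fa", seed = 1,
                                    analysis = list(Alpha = 1))),
               "unknown config")
  expect_error(read_run_config(list(seed = 1)), "fasta")
  expect_error(read_run_config(list(fasta = "x.fa")), "seed")
  expect_error(read_run_config(list(fasta = "x", seed = 1,
                                    simulation = list(s_scr = 1.5))),
               "\\[0, 1\\]")
  expect_error(read_run_config(list(fasta = "x", seed = 1,
                                    simulation = list(coverage = 0))),
               "positive")
  # YAML file path input
  f <- tempfile(fileext = ".yaml")
  writeLines(c("fasta: x.fa", "seed: 7", "n_controls: 12",
               "simulation:", "  s_scr: 0.25",
               "  domains:",
               "    - start_aa: 10", "      end_aa: 20", "      d: 1.0"),
             f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2$seed, 7)
  expect_equal(cfg2$simulation$domains[[1]]$end_aa, 20)
})

test_that("the pipeline reruns byte-identically from one seed", {
  dirbase <- tempfile()
  cds <- random_cds(100, seed = 41, id = "toygene")
  fa <- tempfile(fileext = ".fa")
  write_cds_fasta(cds, fa)
  cfg <- list(fasta = fa, seed = 17, n_controls = 25,
              simulation = list(
                domains = list(list(start_aa = 30, end_aa = 55, d = 1)),
                s_scr = 0.3, T_pre = 5, T_scr = 15, coverage = 300,
                depth = 2e5, n_replicates = 2),
              analysis = list(B = 300))
  out1 <- file.path(dirbase, "run1"); out2 <- file.path(dirbase, "run2")
  r1 <- suppressMessages(run_pipeline(cfg, out1))
  r2 <- suppressMessages(run_pipeline(cfg, out2))
  files <- c("library.tsv", "counts.tsv", "truth.json", "scores.tsv",
             "track.tsv", "regions.tsv", "regions.bed", "evaluation.json",
             "manifest.json", "pipeline.log")
  for (f in files) {
    expect_true(file.exists(file.path(out1, f)), label = f)
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     label = f)
  }
  # manifest records the seed; artifacts reload cleanly
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(man$seed, 17L)
  lib <- read_library(file.path(out1, "library.tsv"))
  expect_equal(nrow(lib), nrow(r1$library))
  # deleting an intermediate and rerunning regenerates it identically
  md5_scores <- tools::md5sum(file.path(out1, "scores.tsv"))
  unlink(file.path(out1, "scores.tsv"))
  suppressMessages(run_pipeline(cfg, out1))
  expect_identical(unname(tools::md5sum(file.path(out1, "scores.tsv"))),
                   unname(md5_scores))
})

test_that("the command-line front end designs a library from FASTA", {
  skip_if_not(nzchar(Sys.which("Rscript")))
  cli <- system.file("cli", "tilescan.R", package = "tilescreen")
  cds <- random_cds(60, seed = 77, id = "cligene")
  fa <- tempfile(fileext = ".fa")
  out <- tempfile(fileext = ".tsv")
  write_cds_fasta(cds, fa)
  res <- system2("Rscript", c(cli, "design", "--fasta", fa, "--controls",
                              "4", "--seed", "3", "--out", out),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  lib <- read_library(out)
  ref <- design_tiling_library(cds, n_controls = 4, gene = "cligene",
                               seed = 3)
  expect_equal(lib$guide_id, ref$guide_id)
  expect_equal(lib$protospacer, ref$protospacer)
})
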