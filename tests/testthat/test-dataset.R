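test_that("interior windows are cut verbatim and terminal flanks are filled", {
  expect_equal(extract_window("AAAAKCCCC", 5, zeta = 2), "AAKCC")
  # value frozen from the index-clamping oracle
  expect_equal(oracle_window("KCD", 1, 2), "KKKCD")
  expect_equal(extract_window("KCD", 1, zeta = 2), "KKKCD")
  long <- paste0(strrep("A", 60), "K", strrep("G", 60))
  expect_equal(nchar(extract_window(long, 61)), 49)
})

test_that("window extraction matches the clamping oracle over all K sites", {
  withr::with_seed(5, {
    for (rep in 1:25) {
      len <- sample(5:60, 1)
      seqc <- sample(kptm_alphabet(), len, replace = TRUE)
      seqc[sample(len, 1)] <- "K"
      s <- paste(seqc, collapse = "")
      zeta <- sample(1:24, 1)
      for (p in which(seqc == "K")) {
        w <- extract_window(s, p, zeta)
        expect_identical(w, oracle_window(s, p, zeta))
        expect_equal(nchar(w), 2 * zeta + 1)
        expect_identical(substr(w, zeta + 1, zeta + 1), "K")
      }
    }
  })
})

test_that("non-K centres and out-of-range positions are rejected", {
  expect_error(extract_window("AAAAKCCCC", 2, 2), class = "kptm_center_residue_error")
  expect_error(extract_window("AAK", 9, 2), class = "kptm_index_error")
})

test_that("build_benchmark yields one sample per K with union label sets", {
  prot <- tibble::tibble(id = "P1", sequence = "ACKDEFKGHIKLM")
  ann <- tibble::tibble(protein_id = "P1", position = c(3, 3, 7),
                        ptm_type = c("acetylation", "succinylation", "methylation"))
  ds <- build_benchmark(prot, ann, zeta = 2)
  expect_equal(nrow(ds), 3) # one sample per K residue
  expect_equal(sort(ds$labels),
               sort(c("acetylation,succinylation", "methylation", "")))
  expect_equal(label_multiplicity(ds)$n_samples, c(1, 1, 1, 0, 0, 0))
})

test_that("invalid annotations are dropped with a warning", {
  prot <- tibble::tibble(id = "P1", sequence = "AAKAA")
  ann <- tibble::tibble(protein_id = c("P1", "P1", "PX", "P1"),
                        position = c(3, 2, 3, 99),
                        ptm_type = c("acetylation", "acetylation",
                                     "acetylation", "acetylation"))
  expect_warning(ds <- build_benchmark(prot, ann, zeta = 2), "Dropped 3")
  expect_equal(sum(ds$labels != ""), 1)
  expect_error(build_benchmark(prot[0, ], ann), class = "kptm_empty_input")
})

test_that("duplicate windows collapse to one sample with the label union", {
  # same local context in two proteins; one modified, one not -> positive wins
  prot <- tibble::tibble(id = c("P1", "P2"),
                         sequence = c("CCKCC", "CCKCC"))
  ann <- tibble::tibble(protein_id = "P1", position = 3, ptm_type = "methylation")
  ds <- build_benchmark(prot, ann, zeta = 2)
  expect_equal(nrow(ds), 1)
  expect_equal(ds$labels, "methylation")
})

test_that("building twice from the same inputs is identical (dedup idempotence)", {
  b <- small_benchmark()
  ds1 <- build_benchmark(b$sim$proteins, b$sim$annotations, zeta = 6)
  ds2 <- build_benchmark(b$sim$proteins, b$sim$annotations, zeta = 6)
  expect_identical(as.data.frame(ds1), as.data.frame(ds2))
})

test_that("per-PTM views partition the dataset and reconstruct the label matrix", {
  ds <- small_benchmark()$dataset
  lm <- label_matrix(ds)
  for (ptm in kptm_labels()) {
    v <- per_ptm_view(ds, ptm)
    expect_equal(nrow(v$positives) + nrow(v$negatives), nrow(ds))
    expect_equal(nrow(v$positives), sum(lm[, ptm]))
    # positives in the view are exactly the rows flagged in the label matrix
    expect_setequal(v$positives$window, ds$window[lm[, ptm]])
  }
  # a 2-label sample is positive in both views
  prot <- tibble::tibble(id = "P1", sequence = "AAKAA")
  ann <- tibble::tibble(protein_id = "P1", position = c(3, 3),
                        ptm_type = c("acetylation", "methylation"))
  ds2 <- build_benchmark(prot, ann, zeta = 1)
  expect_equal(nrow(per_ptm_view(ds2, "acetylation")$positives), 1)
  expect_equal(nrow(per_ptm_view(ds2, "methylation")$positives), 1)
  expect_error(per_ptm_view(ds2, "phosphorylation"), class = "kptm_key_error")
})

test_that("dataset TSV round-trips losslessly", {
  ds <- small_benchmark()$dataset
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(as.data.frame(back), as.data.frame(ds))
  expect_equal(attr(back, "zeta"), attr(ds, "zeta"))
})

test_that("FASTA and annotation IO round-trip, sanitizing nonstandard residues", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "MKVAAU", ">P2", "KKXK"), fa)
  expect_warning(prot <- read_proteins(fa), "wildcard")
  expect_equal(prot$id, c("P1", "P2"))
  expect_equal(prot$sequence, c("MKVAAZ", "KKZK"))
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_proteins(prot, fa2)
  expect_equal(read_proteins(fa2), prot)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "protein_id\tposition\tptm_type",
               "P1\t2\tacetylation"), tsv)
  ann <- read_annotations(tsv)
  expect_equal(ann$position, 2L)
})
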