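test_that("encoder dimensions follow the bookkeeping formula for any zeta", {
  for (zeta in c(1, 3, 24)) {
    w <- random_windows(3, zeta, seed = zeta)
    len <- 2 * zeta + 1
    expect_equal(ncol(encode_aaf(w)), 5 * len)
    expect_equal(ncol(encode_binary(w)), 21 * len)
    kv <- 0:min(4, 2 * zeta - 1)
    expect_equal(ncol(encode_cksaap(w, kv)), 441 * length(kv))
  }
  # the reference operating point: 245 + 1029 + 2205 + 48 = 3527
  w49 <- random_windows(4, 24, seed = 9)
  model <- fit_coupling(w49[1:2], w49[3:4])
  ens <- encode_ensemble(w49, model)
  expect_equal(ncol(ens), 3527)
  expect_equal(ncol(encode_coupling(w49, model)), 48)
  expect_false(any(!is.finite(as.matrix(ens))))
})

test_that("one-hot binary encoding matches the fixed alphabet order", {
  b <- encode_binary("AKZ") # zeta = 1, offsets -1, 0, +1
  expect_equal(unname(unlist(b[1, 1:21])),
               as.numeric(strsplit("100000000000000000000", "")[[1]]))
  expect_equal(unname(unlist(b[1, 43:63])),
               as.numeric(strsplit("000000000000000000001", "")[[1]]))
  g <- encode_binary("GKA")
  expect_equal(unname(which(unlist(g[1, 1:21]) == 1)),
               match("G", kptm_alphabet())) # 6th letter of the alphabet
  expect_equal(sum(b), 3) # exactly one bit per position
})

test_that("AAF encoding is position-major and zero for the wildcard", {
  z <- encode_aaf("ZZKZZ")
  expect_equal(sum(abs(z[, grep("p0", names(z), invert = TRUE, value = TRUE)])), 0)
  a <- encode_aaf("AAKCC")
  tab <- aaf_table()
  expect_equal(unname(unlist(a[1, 1:5])),
               unname(unlist(tab[tab$residue == "A", -1])))
})

test_that("CKSAAP blocks are frequencies that sum to one and match brute force", {
  w <- random_windows(200, 24, seed = 17)
  enc <- as.matrix(encode_cksaap(w, 0:4))
  for (k in 0:4) {
    block <- enc[, grepl(paste0("^cksaap:k", k, ":"), colnames(enc))]
    expect_equal(unname(rowSums(block)), rep(1, 200))
  }
  for (i in seq(1, 200, by = 7)) {
    expect_equal(unname(enc[i, ]), unname(oracle_cksaap(w[i], 0:4)),
                 tolerance = 1e-12)
  }
  expect_error(encode_cksaap("AKC", k_values = 5), class = "kptm_window_too_short")
})

test_that("coupling tables are smoothed conditional distributions", {
  pos <- c("AAKCC", "ACKCD", "AAKCD")
  neg <- c("CCKAA", "CDKAA", "CCKAD")
  eps <- 1e-4
  m <- fit_coupling(pos, neg, pseudocount = eps)
  # every conditional column and marginal sums to 1
  for (cls in c("pos", "neg")) {
    for (tab in m[[cls]]) {
      if (is.matrix(tab)) expect_equal(unname(colSums(tab)), rep(1, 21),
                                       tolerance = 1e-9)
      else expect_equal(sum(tab), 1, tolerance = 1e-9)
    }
  }
  # hand count at offset -2 given context 'A' at offset -1 (n_b = 2 in pos):
  # residue 'A' observed twice; residue 'C' never
  t2 <- m$pos[["-2"]]
  a <- match("A", kptm_alphabet()); c_ <- match("C", kptm_alphabet())
  expect_equal(t2[a, a], (2 + eps) / (2 + 21 * eps))
  expect_equal(t2[c_, a], eps / (2 + 21 * eps))
})

test_that("coupling differences vanish for identical classes and negate on swap", {
  w <- random_windows(30, 4, seed = 2)
  same <- fit_coupling(w[1:15], w[1:15])
  expect_equal(max(abs(as.matrix(encode_coupling(w, same)))), 0)
  ab <- fit_coupling(w[1:15], w[16:30])
  ba <- fit_coupling(w[16:30], w[1:15])
  fa <- as.matrix(encode_coupling(w, ab))
  fb <- as.matrix(encode_coupling(w, ba))
  expect_identical(fa, -fb)
  expect_true(all(fa >= -1 & fa <= 1))
  expect_error(encode_coupling(random_windows(2, 3), ab),
               class = "kptm_shape_error")
})

test_that("coupling models round-trip through JSON", {
  w <- random_windows(20, 3, seed = 8)
  m <- fit_coupling(w[1:10], w[11:20])
  path <- withr::local_tempfile(fileext = ".json")
  write_coupling(m, path)
  back <- read_coupling(path)
  expect_equal(back$zeta, m$zeta)
  expect_equal(as.matrix(encode_coupling(w, back)),
               as.matrix(encode_coupling(w, m)))
})

test_that("ensemble standardization learns on training rows and transfers", {
  w <- random_windows(40, 3, seed = 4)
  model <- fit_coupling(w[1:10], w[11:20])
  tr <- suppressWarnings(
    encode_ensemble(w[1:30], model, standardize = TRUE))
  scaler <- attr(tr, "scaler")
  m <- as.matrix(tr)
  nonconst <- apply(as.matrix(encode_ensemble(w[1:30], model)), 2, sd) > 0
  expect_lt(max(abs(colMeans(m))), 1e-9)
  expect_lt(max(abs(apply(m[, nonconst], 2, sd) - 1)), 1e-9)
  # frozen parameters applied unchanged to the held-out rows
  va_raw <- encode_ensemble(w[31:40], model)
  va <- apply_scaler(va_raw, scaler)
  expect_equal(as.matrix(va)[1, 1],
               (as.matrix(va_raw)[1, 1] - scaler$mean[1]) / scaler$sd[1])
  # encoder subsets keep their prefix contract
  cpl <- encode_ensemble(w, model, encoders = "coupling")
  expect_equal(ncol(cpl), 6)
  expect_true(all(startsWith(names(cpl), "coupling:")))
})

test_that("encoding is deterministic", {
  w <- random_windows(10, 5, seed = 21)
  model <- fit_coupling(w[1:5], w[6:10])
  expect_identical(encode_ensemble(w, model), encode_ensemble(w, model))
})
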