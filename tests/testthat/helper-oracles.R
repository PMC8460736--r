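# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (string/set manipulation, explicit loops) so they
# cannot share a defect with the vectorized implementation paths.

random_windows <- function(n, zeta, seed = 1) {
  withr::with_seed(seed, {
    alpha <- kptm_alphabet()
    vapply(seq_len(n), function(i) {
      chars <- sample(alpha, 2 * zeta + 1, replace = TRUE)
      chars[zeta + 1] <- "K"
      paste(chars, collapse = "")
    }, character(1))
  })
}

# window extraction via index clamping (missing flank slots point at the
# nearest existing residue, i.e. the terminus)
oracle_window <- function(sequence, position, zeta) {
  chars <- strsplit(sequence, "")[[1]]
  idx <- pmin(pmax((position - zeta):(position + zeta), 1L), length(chars))
  paste(chars[idx], collapse = "")
}

# k-spaced pair frequencies by direct pair enumeration
oracle_cksaap <- function(window, k_values) {
  chars <- strsplit(window, "")[[1]]
  len <- length(chars)
  alpha <- kptm_alphabet()
  pair_names <- paste0(rep(alpha, each = 21), rep(alpha, 21))
  unlist(lapply(sort(k_values), function(k) {
    cnt <- stats::setNames(numeric(441), pair_names)
    for (i in 1:(len - k - 1)) {
      p <- paste0(chars[i], chars[i + k + 1])
      cnt[p] <- cnt[p] + 1
    }
    cnt / (len - k - 1)
  }))
}

# textbook one-way ANOVA from between/within mean squares, two groups
oracle_anova_f <- function(y1, y2) {
  n1 <- length(y1); n2 <- length(y2); n <- n1 + n2
  gm <- mean(c(y1, y2))
  msb <- (n1 * (mean(y1) - gm)^2 + n2 * (mean(y2) - gm)^2) / (2 - 1)
  msw <- (sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)) / (n - 2)
  msb / msw
}

# Chou's metrics by per-sample set materialisation (null-label convention)
oracle_metrics <- function(truth, pred) {
  to_set <- function(s) {
    v <- strsplit(s, ",")[[1]]
    v <- v[nzchar(v)]
    if (length(v) == 0) "Non-K-PTM" else v
  }
  n <- length(truth)
  acc <- aim <- cov <- at <- af <- 0
  for (i in seq_len(n)) {
    y <- to_set(truth[i]); yp <- to_set(pred[i])
    it <- length(intersect(y, yp)); un <- length(union(y, yp))
    aim <- aim + it / length(yp)
    cov <- cov + it / length(y)
    acc <- acc + it / un
    at <- at + as.numeric(setequal(y, yp))
    af <- af + (un - it) / 6
  }
  c(aiming = aim / n, coverage = cov / n, accuracy = acc / n,
    absolute_true = at / n, absolute_false = af / n)
}

# tiny deterministic two-blob features for SVM/hardness tests
toy_blobs <- function(n_per = 30, sep = 4, seed = 3) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(2 * n_per), ncol = 2),
               matrix(stats::rnorm(2 * n_per, mean = sep), ncol = 2))
  })
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c(FALSE, TRUE), each = n_per))
}

# small synthetic benchmark shared by model-level tests (cached per session)
small_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- generate_kptm(kptm_sim_config(n_proteins = 60, seed = 11))
      ds <- build_benchmark(sim$proteins, sim$annotations, zeta = 6)
      cache <<- list(sim = sim, dataset = ds)
    }
    cache
  }
})
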