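# Approximate vertebrate proteome residue frequencies (UniProtKB average),
# used as the background composition of simulated proteins.
.background_freqs <- c(
  A = 8.3, C = 1.4, D = 5.5, E = 6.7, F = 3.9, G = 7.1, H = 2.3, I = 6.0,
  K = 5.8, L = 9.7, M = 2.4, N = 4.1, P = 4.7, Q = 3.9, R = 5.6, S = 8.3,
  T = 5.4, V = 6.9, W = 1.1, Y = 2.9) / 100

# Default planted motifs: each PTM type prefers distinct residues at
# distinct near-centre offsets, written with high probability so the
# positional signal is strong and recoverable. Offsets sit inside the
# coupling-visible window, making the sequence-coupling encoder the
# intended dominant signal.
default_motifs <- function() {
  list(
    acetylation   = tibble(offset = c(-4L, -1L, 1L), residue = c("R", "G", "H"),
                           weight = 0.9),
    crotonylation = tibble(offset = c(-2L, 2L), residue = c("F", "W"),
                           weight = 0.9),
    methylation   = tibble(offset = c(-3L, 3L), residue = c("P", "C"),
                           weight = 0.9),
    succinylation = tibble(offset = c(-6L, 5L), residue = c("D", "E"),
                           weight = 0.9),
    glutarylation = tibble(offset = c(-5L, 4L), residue = c("M", "Y"),
                           weight = 0.9))
}

#' Synthetic K-PTM data generator configuration
#'
#' Describes a simulated study: proteins drawn residue-by-residue from a
#' background composition, a fraction of lysines selected as modified
#' sites, label sets drawn to match a target multiplicity histogram and
#' per-PTM prevalence, and PTM-type-specific positional residue
#' preferences (motifs) written into the flanks of modified sites. The
#' defaults emulate the benchmark conditions this package targets: a
#' roughly 1:16 modified:unmodified ratio, a multiplicity histogram
#' heavily dominated by single-label sites
#' (0.808/0.170/0.015/0.005/0.001 for 1..5 labels), per-PTM prevalence
#' dominated by acetylation, and strong planted motifs.
#'
#' @param n_proteins Number of proteins.
#' @param protein_length Two integers: uniform min/max protein length.
#' @param background Named residue frequency vector (20 standard residues;
#'   normalised internally).
#' @param motifs Named list (one per PTM type) of tibbles with columns
#'   `offset`, `residue`, `weight` — each row writes `residue` at
#'   `offset` from the site with probability `weight`.
#' @param positive_fraction Per-lysine probability of being a modified
#'   site (default 1/17, i.e. 1:16).
#' @param multiplicity_probs Probabilities of a modified site carrying
#'   1..5 labels.
#' @param label_weights Relative prevalence of the five PTM types.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `kptm_sim_config`.
#' @export
kptm_sim_config <- function(n_proteins = 200L, protein_length = c(120L, 400L),
                            background = NULL, motifs = default_motifs(),
                            positive_fraction = 1 / 17,
                            multiplicity_probs = c(4089, 861, 77, 26, 6) / 5059,
                            label_weights = c(acetylation = 4154,
                                              crotonylation = 208,
                                              methylation = 325,
                                              succinylation = 1253,
                                              glutarylation = 236),
                            seed = 0L) {
  background <- background %||% .background_freqs
  background <- background / sum(background)
  stopifnot(length(protein_length) == 2L, positive_fraction > 0,
            positive_fraction < 1,
            abs(sum(multiplicity_probs) - 1) < 1e-8,
            setequal(names(motifs), kptm_labels()))
  structure(list(n_proteins = as.integer(n_proteins),
                 protein_length = as.integer(protein_length),
                 background = background, motifs = motifs,
                 positive_fraction = positive_fraction,
                 multiplicity_probs = multiplicity_probs,
                 label_weights = label_weights[kptm_labels()],
                 seed = as.integer(seed)),
            class = "kptm_sim_config")
}

#' Generate synthetic proteins, annotations and a ground-truth manifest
#'
#' Draws proteins from the background composition, selects modified
#' lysines at the configured rate, assigns each a label set (multiplicity
#' then types), and resamples the flanking residues of each modified site
#' according to every assigned label's motif (never overwriting a lysine,
#' so the site list stays exact). The manifest records every planted site
#' and, per PTM, the sequence-coupling feature columns its motif makes
#' informative (the columns at the motif offsets).
#'
#' @param config A [kptm_sim_config()].
#' @return A list with `proteins` (tibble `id`, `sequence`), `annotations`
#'   (tibble `protein_id`, `position`, `ptm_type`) and `manifest` (a list:
#'   seed, site table with label sets, per-PTM informative coupling
#'   columns, motif table). Write with [write_proteins()],
#'   [write_annotations()] and [jsonlite::write_json()].
#' @examples
#' sim <- generate_kptm(kptm_sim_config(n_proteins = 5, seed = 1))
#' sim$annotations
#' @export
generate_kptm <- function(config = kptm_sim_config()) {
  stopifnot(inherits(config, "kptm_sim_config"))
  residues <- names(config$background)
  withr::with_seed(config$seed, {
    lens <- sample(config$protein_length[1]:config$protein_length[2],
                   config$n_proteins, replace = TRUE)
    chars <- lapply(lens, function(n)
      sample(residues, n, replace = TRUE, prob = config$background))
    ids <- sprintf("SYN%04d", seq_len(config$n_proteins))
    sites <- purrr::map_dfr(seq_along(chars), function(i) {
      pos <- which(chars[[i]] == "K")
      if (length(pos) == 0) return(NULL)
      tibble(protein = i, position = pos)
    })
    if (nrow(sites) == 0) abort("No lysines generated; increase n_proteins.",
                                class = "kptm_config_error")
    is_mod <- stats::runif(nrow(sites)) < config$positive_fraction
    label_sets <- vector("list", nrow(sites))
    for (s in which(is_mod)) {
      m <- sample.int(5L, 1L, prob = config$multiplicity_probs)
      label_sets[[s]] <- sample(kptm_labels(), m, prob = config$label_weights)
      # imprint each assigned label's motif into the flanks
      i <- sites$protein[s]
      p <- sites$position[s]
      for (lab in label_sets[[s]]) {
        mot <- config$motifs[[lab]]
        for (r in seq_len(nrow(mot))) {
          q <- p + mot$offset[r]
          if (q >= 1L && q <= lens[i] && chars[[i]][q] != "K" &&
              stats::runif(1) < mot$weight[r]) {
            chars[[i]][q] <- mot$residue[r]
          }
        }
      }
    }
  })
  proteins <- tibble(id = ids,
                     sequence = vapply(chars, paste, character(1), collapse = ""))
  site_tbl <- tibble(protein_id = ids[sites$protein],
                     position = sites$position,
                     labels = vapply(label_sets, function(s)
                       join_labels(s %||% character(0)), character(1)))
  annotations <- site_tbl |>
    dplyr::filter(.data$labels != "") |>
    dplyr::mutate(ptm_type = split_labels(.data$labels)) |>
    tidyr::unnest("ptm_type") |>
    dplyr::select("protein_id", "position", "ptm_type")
  manifest <- list(
    seed = config$seed,
    n_proteins = config$n_proteins,
    n_sites = nrow(site_tbl),
    n_modified = sum(site_tbl$labels != ""),
    positive_fraction = config$positive_fraction,
    sites = site_tbl,
    informative_coupling = informative_coupling_columns(config$motifs),
    motifs = purrr::imap_dfr(config$motifs, ~dplyr::mutate(.x, ptm = .y,
                                                           .before = 1L)))
  list(proteins = proteins, annotations = annotations, manifest = manifest)
}

# Coupling columns a motif makes informative: the columns at the motif
# offsets themselves, where the planted residue preference shifts the
# class-conditional probability of the observed residue.
informative_coupling_columns <- function(motifs) {
  lapply(motifs, function(mot) {
    offs <- unique(mot$offset)
    offs <- offs[offs != 0]
    paste0("coupling:p", sort(offs))
  })
}
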