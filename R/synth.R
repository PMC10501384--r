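# Seeded generator of labelled benchmark datasets: fixed-length RNA
# windows with a central adenosine, where class signal is carried by a
# noised consensus motif planted at the center of positives plus a mild
# A/U-rich flanking composition bias.

#' Synthetic dataset configuration
#'
#' Positives carry the consensus `motif` centered so that its adenosine
#' sits on the window's central position; negatives are background
#' sequences with a central A and no planted motif. The difficulty knob
#' `eps` in `[0, 0.5)` degrades the class signal: each motif position is
#' resampled from the background with probability `2 * eps`, and the
#' flanking composition bias of positives is scaled by `1 - 2 * eps`, so
#' `eps = 0` gives the exact motif with full compositional bias and
#' `eps -> 0.5` approaches pure background (no signal).
#'
#' @param m number of sequences.
#' @param n odd window length (default 101).
#' @param motif consensus string planted in positives (default
#'   `"GGACU"`, the canonical m6A context).
#' @param motif_a 1-based position of the modified A within the motif
#'   (default 3).
#' @param eps difficulty in `[0, 0.5)` (default 0.1).
#' @param background base composition of negatives and of the corrupted
#'   draws, in A/C/G/U order (default uniform).
#' @param pos_bias flanking composition of positives at `eps = 0`
#'   (default A/U-rich, `c(0.32, 0.18, 0.18, 0.32)`, reflecting the
#'   U/A-rich context of plant m6A sites).
#' @param class_balance positive fraction (default 0.5).
#' @param seed integer seed.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(m, n = 101L, motif = "GGACU", motif_a = 3L,
                         eps = 0.1, background = rep(0.25, 4),
                         pos_bias = c(0.32, 0.18, 0.18, 0.32),
                         class_balance = 0.5, seed = 1L) {
  stopifnot(m >= 4, n %% 2L == 1L, eps >= 0, eps < 0.5,
            class_balance > 0, class_balance < 1,
            abs(sum(background) - 1) < 1e-8, abs(sum(pos_bias) - 1) < 1e-8)
  if (nchar(motif) > n) stop("motif longer than the window")
  mot <- strsplit(toupper(gsub("T", "U", motif)), "")[[1]]
  if (mot[motif_a] != "A") stop("motif position ", motif_a, " must be A")
  structure(list(m = as.integer(m), n = as.integer(n), motif = mot,
                 motif_a = as.integer(motif_a), eps = eps,
                 background = background, pos_bias = pos_bias,
                 class_balance = class_balance, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a labelled synthetic dataset
#'
#' Fully reproducible from `cfg$seed`. The truth table records, per
#' record, the label and (for positives) the 1-based start of the planted
#' motif.
#'
#' @param cfg a [synth_config()].
#' @return List of class `synth_data` with elements `sequences` (an
#'   [rna_set] with labels), `truth` (data frame: id, label,
#'   motif_start), and `config`.
#' @export
synth_generate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  center <- (cfg$n + 1L) %/% 2L
  mstart <- center - cfg$motif_a + 1L
  if (mstart < 1L || mstart + length(cfg$motif) - 1L > cfg$n) {
    stop("motif does not fit the window at the central A")
  }
  p_flank <- cfg$background + (1 - 2 * cfg$eps) *
    (cfg$pos_bias - cfg$background)
  with_seed(cfg$seed, {
    n_pos <- round(cfg$m * cfg$class_balance)
    label <- integer(cfg$m)
    label[sample.int(cfg$m, n_pos)] <- 1L
    seqs <- character(cfg$m)
    for (i in seq_len(cfg$m)) {
      if (label[i] == 1L) {
        s <- sample(RNA_ALPHABET, cfg$n, replace = TRUE, prob = p_flank)
        for (j in seq_along(cfg$motif)) {
          s[mstart + j - 1L] <- if (stats::runif(1) < 2 * cfg$eps) {
            sample(RNA_ALPHABET, 1L, prob = cfg$background)
          } else cfg$motif[j]
        }
      } else {
        s <- sample(RNA_ALPHABET, cfg$n, replace = TRUE,
                    prob = cfg$background)
      }
      s[center] <- "A"
      seqs[i] <- paste(s, collapse = "")
    }
    ids <- sprintf("seq_%04d", seq_len(cfg$m))
    structure(list(sequences = rna_set(ids, seqs, label),
                   truth = data.frame(id = ids, label = label,
                                      motif_start = ifelse(label == 1L,
                                                           mstart, NA)),
                   config = cfg),
              class = "synth_data")
  })
}

#' Datasets of graded separability
#'
#' One dataset per `eps` value, sharing all other configuration fields.
#' Pipeline AUC is expected to decrease (within cross-validation noise)
#' as `eps` rises.
#'
#' @param cfg a [synth_config()] (its `eps` is ignored).
#' @param eps_grid difficulty values in `[0, 0.5)`.
#' @return Named list of `synth_data`, one per grid value.
#' @export
difficulty_sweep <- function(cfg, eps_grid = c(0, 0.1, 0.2, 0.3, 0.4)) {
  stopifnot(all(eps_grid >= 0), all(eps_grid < 0.5))
  out <- lapply(eps_grid, function(e) {
    cfg$eps <- e
    synth_generate(cfg)
  })
  names(out) <- paste0("eps_", eps_grid)
  out
}
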