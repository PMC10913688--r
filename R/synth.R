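## Synthetic benchmark generator: 41-bp windows centred on a cytosine,
## with a planted degenerate motif separating true from spurious sites and
## a configurable negative:positive imbalance (7.6 by default, mirroring
## the promoter-5mC benchmark).

#' A degenerate position weight matrix around a consensus
#'
#' Builds a PWM whose consensus base carries `weight` probability per
#' column and the remaining mass is spread evenly over the other three
#' bases.
#'
#' @param consensus consensus DNA string (default `"TGACGT"`, width 6).
#' @param weight per-column consensus probability in (0, 1].
#' @return a 4 x width matrix with rownames A, C, G, T; columns sum to 1.
#' @export
consensus_pwm <- function(consensus = "TGACGT", weight = 0.85) {
  stopifnot(weight > 0, weight <= 1)
  idx <- .base_index(toupper(consensus))
  w <- nchar(consensus)
  pwm <- matrix((1 - weight) / 3, nrow = 4, ncol = w,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm[cbind(idx, seq_len(w))] <- weight
  pwm
}

#' Specification of a synthetic promoter-5mC dataset
#'
#' Describes a generator run: class counts, window length, the planted
#' motif PWM and its offset, background base composition, label noise and
#' seed. Positives carry a motif sampled from the PWM; both classes have
#' the centre base forced to C, so the only class signal is the motif —
#' mirroring the real task, where every window centres on a candidate
#' cytosine.
#'
#' @param n_pos,n_neg class counts (non-negative).
#' @param window_length window size in nucleotides (odd; default 41).
#' @param motif a 4 x width PWM over A,C,G,T whose columns sum to 1.
#' @param motif_offset 0-based start of the motif within the window.
#' @param background length-4 base composition (A,C,G,T), summing to 1.
#' @param label_noise probability in \[0, 0.5) of flipping each label.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos, n_neg, window_length = 41,
                           motif = consensus_pwm(), motif_offset = 10,
                           background = c(0.25, 0.25, 0.25, 0.25),
                           label_noise = 0, seed = 1) {
  if (n_pos < 0 || n_neg < 0) stop("spec error: negative class count")
  if (window_length %% 2 != 1) stop("spec error: window_length must be odd")
  if (!is.matrix(motif) || nrow(motif) != 4 ||
      any(abs(colSums(motif) - 1) > 1e-8) || any(motif < 0))
    stop("spec error: motif must be a 4-row PWM with columns summing to 1")
  if (motif_offset < 0 || motif_offset + ncol(motif) > window_length)
    stop("spec error: motif does not fit inside the window")
  if (label_noise < 0 || label_noise >= 0.5)
    stop("spec error: label_noise must lie in [0, 0.5)")
  if (abs(sum(background) - 1) > 1e-8 || any(background < 0))
    stop("spec error: background must be a length-4 simplex vector")
  structure(list(n_pos = n_pos, n_neg = n_neg,
                 window_length = as.integer(window_length), motif = motif,
                 motif_offset = as.integer(motif_offset),
                 background = background, label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' The canonical synthetic benchmark fixture
#'
#' 800 positives and 6,080 negatives (negative:positive ratio 7.6, the
#' benchmark imbalance), 41-bp windows, a width-6 PWM with 0.85 consensus
#' weight per column planted at offset 10, uniform background, no label
#' noise, seed 1.
#'
#' @return a [synthetic_spec()].
#' @export
default_benchmark_spec <- function() {
  synthetic_spec(n_pos = 800, n_neg = 6080, window_length = 41,
                 motif = consensus_pwm("TGACGT", 0.85), motif_offset = 10,
                 background = c(0.25, 0.25, 0.25, 0.25),
                 label_noise = 0, seed = 1)
}

#' Generate a labelled synthetic dataset
#'
#' Samples background bases i.i.d. from the spec's composition, plants the
#' PWM in positive windows at `motif_offset`, forces the centre base of
#' every window to C, and optionally flips labels with probability
#' `label_noise`. Identical specs (including seed) generate identical
#' datasets.
#'
#' @param spec a [synthetic_spec()].
#' @return a [m5c_dataset()]; positives first, then negatives (labels may
#'   deviate where noise flipped them).
#' @examples
#' d <- generate_dataset(synthetic_spec(n_pos = 5, n_neg = 38, seed = 7))
#' dataset_summary(d)$ratio
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_pos + spec$n_neg
  L <- spec$window_length
  ALPH <- c("A", "C", "G", "T")
  mat <- matrix(sample(ALPH, n * L, replace = TRUE, prob = spec$background),
                nrow = n, ncol = L)
  if (spec$n_pos > 0) {
    w <- ncol(spec$motif)
    for (j in seq_len(w)) {
      mat[seq_len(spec$n_pos), spec$motif_offset + j] <-
        sample(ALPH, spec$n_pos, replace = TRUE, prob = spec$motif[, j])
    }
  }
  mat[, (L + 1L) / 2L] <- "C"     # centre candidate cytosine, both classes
  label <- rep(c(1L, 0L), c(spec$n_pos, spec$n_neg))
  if (spec$label_noise > 0) {
    flip <- stats::runif(n) < spec$label_noise
    label[flip] <- 1L - label[flip]
  }
  id <- c(sprintf("pos_%05d", seq_len(spec$n_pos)),
          sprintf("neg_%05d", seq_len(spec$n_neg)))
  m5c_dataset(id, do.call(paste0, as.data.frame(mat)), label)
}

#' Log-odds PWM score of each window
#'
#' Scores `sum(log(pwm[base_j, j] / background[base_j]))` over the motif
#' columns at the spec's offset — the Bayes-optimal statistic for the
#' generator, useful as an upper-bound sanity check on learned models.
#'
#' @param data a [m5c_dataset()].
#' @param spec the [synthetic_spec()] that generated it (or a compatible
#'   one supplying `motif`, `motif_offset`, `background`).
#' @return numeric vector of per-sequence scores.
#' @export
pwm_log_odds <- function(data, spec) {
  stopifnot(inherits(data, "m5c_dataset"), inherits(spec, "synthetic_spec"))
  w <- ncol(spec$motif)
  scores <- numeric(nrow(data))
  for (j in seq_len(w)) {
    b <- substr(data$bases, spec$motif_offset + j, spec$motif_offset + j)
    idx <- match(b, c("A", "C", "G", "T"))
    scores <- scores + log(spec$motif[cbind(idx, j)]) -
      log(spec$background[idx])
  }
  scores
}
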