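#' Configuration for the synthetic window generator
#'
#' The generator emulates the statistical structure the predictor
#' assumes: every window is a 41-mer centred on asparagine, and the
#' two classes differ in the probability of carrying the canonical
#' N-X-[S/T] sequon, i.e. serine or threonine two positions
#' downstream of the central N.  Positives additionally avoid proline
#' at X (the known sequon constraint).  All other positions are drawn
#' from a background residue distribution.
#'
#' @param n_pos,n_neg Number of positive / negative windows.
#' @param sequon_prob_pos Probability that a positive window carries
#'   S/T at centre + 2 (default 0.95).
#' @param sequon_prob_neg Same for negatives (default 0.05).
#' @param background Probability weights over the 20 standard residues
#'   (default uniform); need not be normalised.
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return List of class `nglyc_simconfig`.
#' @export
sim_config <- function(n_pos = 200L, n_neg = 200L,
                       sequon_prob_pos = 0.95, sequon_prob_neg = 0.05,
                       background = NULL, seed = 1L) {
  if (is.null(background)) background <- rep(1, 20L)
  stopifnot(n_pos >= 0, n_neg >= 0,
            sequon_prob_pos >= 0, sequon_prob_pos <= 1,
            sequon_prob_neg >= 0, sequon_prob_neg <= 1,
            length(background) == 20L, all(background >= 0))
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 sequon_prob_pos = sequon_prob_pos,
                 sequon_prob_neg = sequon_prob_neg,
                 background = background / sum(background),
                 seed = as.integer(seed)),
            class = "nglyc_simconfig")
}

# One 41-mer drawn from the current RNG stream (no seeding here).
draw_window <- function(cfg, label) {
  p_seq <- if (label == 1L) cfg$sequon_prob_pos else cfg$sequon_prob_neg
  w <- sample(AA_LETTERS, 41L, replace = TRUE, prob = cfg$background)
  w[21L] <- "N"
  if (label == 1L && w[22L] == "P") {
    bg <- cfg$background
    bg[AA_LETTERS == "P"] <- 0
    w[22L] <- sample(AA_LETTERS, 1L, prob = bg)
  }
  if (stats::runif(1) < p_seq) {
    w[23L] <- sample(c("S", "T"), 1L)
  } else {
    bg <- cfg$background
    bg[AA_LETTERS %in% c("S", "T")] <- 0
    w[23L] <- sample(AA_LETTERS, 1L, prob = bg)
  }
  paste(w, collapse = "")
}

#' Generate a single synthetic site window
#'
#' @param cfg An `nglyc_simconfig`.
#' @param label Class label, `1L` or `0L`.
#' @param seed RNG seed for this draw.
#' @return A [site_window()] with the requested label and `N` (code
#'   12) at the central position 21.
#' @export
generate_window <- function(cfg, label, seed = cfg$seed) {
  stopifnot(inherits(cfg, "nglyc_simconfig"), label %in% c(0L, 1L))
  w <- with_seed(seed, draw_window(cfg, label))
  site_window(encode_residue(w), site_position = NA_integer_,
              label = as.integer(label))
}

#' Generate a labelled synthetic window dataset
#'
#' Draws `n_pos` positive and `n_neg` negative windows and shuffles
#' them reproducibly.  The output is a window table directly usable by
#' every downstream function ([nglyc_fit()], [cross_validate()], ...)
#' and writable with [write_window_table()].
#'
#' @param cfg An `nglyc_simconfig`.
#' @return Data frame with columns `id`, `window`, `label`, plus the
#'   generating configuration in attribute `"sim_config"`.
#' @export
generate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "nglyc_simconfig"))
  with_seed(cfg$seed, {
    lab <- c(rep(1L, cfg$n_pos), rep(0L, cfg$n_neg))
    wins <- vapply(lab, function(l) draw_window(cfg, l), character(1))
    ids <- c(sprintf("pos_%04d", seq_len(cfg$n_pos)),
             sprintf("neg_%04d", seq_len(cfg$n_neg)))
    ord <- sample.int(length(lab))
    out <- data.frame(id = ids[ord], window = wins[ord],
                      label = lab[ord], stringsAsFactors = FALSE)
    attr(out, "sim_config") <- cfg
    out
  })
}
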