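#' Specification for a synthetic methylation-window benchmark
#'
#' The generator emulates the shape of published 4mC benchmarks: two
#' balanced label classes of fixed-length windows (41 nt) with the candidate
#' cytosine at the centre, and a tunable class signal in the form of a short
#' motif planted near the centre. Positives receive the motif with
#' probability `p_positive`, negatives with probability `q_negative`; with
#' `p_positive == q_negative` the two classes are statistically identical
#' (a null benchmark). Background bases are drawn i.i.d.; a small N rate
#' keeps the five-symbol code paths exercised.
#'
#' @param n_per_class Records per label class.
#' @param length Window length (odd; default 41).
#' @param motif Motif string over A/C/G/T (default `"CC"`, echoing the
#'   methylated-cytosine context).
#' @param motif_offset Motif start relative to the central position (0 means
#'   the motif begins on the central base). Default 0.
#' @param p_positive,q_negative Planting probabilities for the two classes;
#'   `q_negative <= p_positive` required.
#' @param n_rate Background probability of the ambiguous base N (default
#'   0.01; the remaining mass is uniform over A, C, G, T).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `fourmc_sim_spec`.
#' @export
sim_spec <- function(n_per_class = 100L, length = 41L, motif = "CC",
                     motif_offset = 0L, p_positive = 0.9, q_negative = 0.1,
                     n_rate = 0.01, seed = 1L) {
  if (length %% 2L == 0L) abort("`length` must be odd (central base)")
  if (grepl("[^ACGT]", motif)) abort("`motif` must be over A/C/G/T")
  if (!(q_negative >= 0 && q_negative <= p_positive && p_positive <= 1)) {
    abort("need 0 <= q_negative <= p_positive <= 1")
  }
  if (n_rate < 0 || n_rate >= 1) abort("`n_rate` must be in [0, 1)")
  center <- (length - 1L) %/% 2L  # 0-based
  start <- center + motif_offset  # 0-based motif start
  if (start < 0L || start + nchar(motif) > length) {
    abort(paste0("motif (", nchar(motif), " nt at offset ", motif_offset,
                 ") overruns the ", length, "-nt window"))
  }
  structure(
    list(n_per_class = as.integer(n_per_class), length = as.integer(length),
         motif = motif, motif_offset = as.integer(motif_offset),
         p_positive = p_positive, q_negative = q_negative,
         n_rate = n_rate, seed = as.integer(seed)),
    class = "fourmc_sim_spec"
  )
}

#' Generate a synthetic labelled window dataset
#'
#' Each record is drawn i.i.d. from the background distribution, the motif
#' is planted (class-dependently) at its fixed offset, and the central base
#' is then forced to C so every record satisfies the central-cytosine
#' invariant.
#'
#' @param spec A [sim_spec()].
#' @return A labelled tibble (`id`, `seq`, `label`) with `n_per_class`
#'   positives followed by `n_per_class` negatives; passes
#'   [validate_windows()].
#' @export
simulate_windows <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "fourmc_sim_spec"))
  local_rng(spec$seed)
  probs <- c(rep((1 - spec$n_rate) / 4, 4), spec$n_rate)
  center1 <- (spec$length - 1L) %/% 2L + 1L  # 1-based
  start1 <- center1 + spec$motif_offset
  motif_chars <- strsplit(spec$motif, "", fixed = TRUE)[[1]]
  motif_idx <- start1:(start1 + length(motif_chars) - 1L)

  draw_class <- function(n, plant_prob, label, prefix) {
    seqs <- character(n)
    for (i in seq_len(n)) {
      chars <- sample(DNA_ALPHABET, spec$length, replace = TRUE, prob = probs)
      if (runif(1) < plant_prob) chars[motif_idx] <- motif_chars
      chars[center1] <- "C"
      seqs[i] <- paste(chars, collapse = "")
    }
    tibble(id = paste0(prefix, seq_len(n)), seq = seqs,
           label = rep(as.integer(label), n))
  }

  out <- dplyr::bind_rows(
    draw_class(spec$n_per_class, spec$p_positive, 1L, "pos_"),
    draw_class(spec$n_per_class, spec$q_negative, 0L, "neg_")
  )
  validate_windows(out, length = spec$length)
  out
}

#' Write a synthetic benchmark as a positive/negative FASTA pair
#'
#' @param spec A [sim_spec()].
#' @param positive,negative Output FASTA paths.
#' @return The generated tibble, invisibly.
#' @export
simulate_fasta_pair <- function(spec, positive, negative) {
  data <- simulate_windows(spec)
  write_fasta_pair(data, positive, negative)
  invisible(data)
}
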