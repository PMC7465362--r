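#' In silico saturation mutagenesis map
#'
#' For every record, every window position and every substitution symbol
#' (A, C, G, T, N), the base is substituted, the window re-encoded with the
#' model's scheme and re-scored, and the absolute change in predicted
#' probability recorded. The map is the element-wise mean over records, so a
#' substitution equal to the original base contributes exactly 0. A peak at
#' the window centre indicates the model keys on the methylation context.
#'
#' @param net A trained `fourmc_cnn` carrying its encoding scheme.
#' @param data A labelled window dataset (`id`, `seq`, `label`).
#' @param positives_only Average over label-1 records only (default `FALSE`:
#'   the whole dataset).
#' @return An object of class `fourmc_mutagenesis`: `values` (L x 5 matrix,
#'   rows = positions, columns = A,C,G,T,N), `n_sequences`, `scheme`.
#' @export
mutagenesis_map <- function(net, data, positives_only = FALSE) {
  if (!isTRUE(net$trained)) abort("model is untrained")
  if (is.null(net$scheme)) {
    abort("model carries no encoding scheme; cannot re-encode mutated windows")
  }
  data <- as_tibble(data)
  if (positives_only) data <- data[data$label == 1L, ]
  if (nrow(data) == 0L) abort("no records to average over")
  L <- nchar(data$seq[1])
  p_orig <- predict(net, data)
  values <- matrix(0, nrow = L, ncol = 5L,
                   dimnames = list(NULL, DNA_ALPHABET))
  for (i in seq_len(L)) {
    for (a in DNA_ALPHABET) {
      mutated <- data
      substr(mutated$seq, i, i) <- a
      p_mut <- predict(net, mutated)
      values[i, a] <- mean(abs(p_mut - p_orig))
    }
  }
  structure(
    list(values = values, n_sequences = nrow(data), scheme = net$scheme),
    class = "fourmc_mutagenesis"
  )
}

# Schemes whose encoded rows align 1:1 with sequence positions, giving a
# per-base gradient; DNC rows align with dinucleotide positions directly.
SALIENCY_BASE_SCHEMES <- c("BE", "NCP", "NCPNF")

#' Gradient-times-input saliency map aggregated by dinucleotide
#'
#' Per record, the gradient of the pre-sigmoid logit with respect to the
#' encoded input is multiplied pointwise with the encoded input and summed
#' over channels to give a per-position importance. The 2-mer score at
#' position i (the left base) is importance(i) + importance(i+1),
#' accumulated into the cell of the observed dinucleotide; the map is the
#' mean over records. For the DNC scheme the encoded rows *are* dinucleotide
#' positions, so their channel-summed gradient-times-input is binned
#' directly. Schemes with no dinucleotide-aligned gradient path (TNC, MMI)
#' are rejected.
#'
#' @inheritParams mutagenesis_map
#' @return An object of class `fourmc_saliency`: `values` ((L-1) x 25
#'   matrix, rows = 2-mer positions indexed by the left base, columns = the
#'   25 dinucleotides), `position_score` (length L-1 mean observed-2-mer
#'   score), `n_sequences`, `scheme`.
#' @export
saliency_map <- function(net, data, positives_only = FALSE) {
  if (!isTRUE(net$trained)) abort("model is untrained")
  scheme <- net$scheme
  if (is.null(scheme) || !scheme %in% c(SALIENCY_BASE_SCHEMES, "DNC")) {
    abort(paste0(
      "no gradient path from scheme '",
      if (is.null(scheme)) "<none>" else scheme,
      "' to sequence positions; saliency supports BE, NCP, NCPNF and DNC"
    ))
  }
  data <- as_tibble(data)
  if (positives_only) data <- data[data$label == 1L, ]
  if (nrow(data) == 0L) abort("no records to average over")
  L <- nchar(data$seq[1])
  tensor <- encode_dataset(data, scheme)
  grad <- input_gradient(net, tensor$x)
  gxi <- grad * tensor$x
  d <- dim(gxi)
  imp <- matrix(rowSums(matrix(gxi, d[1] * d[2], d[3])), d[1], d[2])

  dinucs <- kmer_alphabet(2L)
  n_pos <- L - 1L
  values <- matrix(0, nrow = n_pos, ncol = length(dinucs),
                   dimnames = list(NULL, dinucs))
  two_mers <- do.call(rbind, lapply(data$seq, function(s) {
    substring(s, seq_len(n_pos), seq_len(n_pos) + 1L)
  }))
  if (scheme %in% SALIENCY_BASE_SCHEMES) {
    score <- imp[, seq_len(n_pos), drop = FALSE] +
      imp[, seq_len(n_pos) + 1L, drop = FALSE]
  } else {
    score <- imp  # DNC: one row per dinucleotide position already
  }
  for (r in seq_len(nrow(data))) {
    cell <- cbind(seq_len(n_pos), match(two_mers[r, ], dinucs))
    values[cell] <- values[cell] + score[r, ]
  }
  values <- values / nrow(data)
  structure(
    list(values = values, position_score = rowSums(values),
         n_sequences = nrow(data), scheme = scheme),
    class = "fourmc_saliency"
  )
}

#' Write an attribution map as a CSV matrix
#'
#' @param map A `fourmc_mutagenesis` or `fourmc_saliency`.
#' @param path Output path. Rows are positions, columns symbols/dinucleotides.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  df <- as_tibble(map$values)
  df <- dplyr::mutate(df, position = seq_len(nrow(df)), .before = 1)
  readr::write_csv(df, path)
  invisible(path)
}

map_long <- function(map) {
  df <- as_tibble(map$values)
  df$position <- seq_len(nrow(df))
  tidyr::pivot_longer(df, -"position", names_to = "symbol",
                      values_to = "score")
}

#' @method autoplot fourmc_mutagenesis
#' @export
autoplot.fourmc_mutagenesis <- function(object, ...) {
  ggplot2::ggplot(map_long(object),
                  ggplot2::aes(x = .data$position,
                               y = factor(.data$symbol, levels = rev(DNA_ALPHABET)),
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean |Δp|") +
    ggplot2::labs(x = "window position", y = "substituted base",
                  title = "In silico mutagenesis") +
    ggplot2::theme_minimal()
}

#' @method autoplot fourmc_saliency
#' @export
autoplot.fourmc_saliency <- function(object, ...) {
  long <- map_long(object)
  long$symbol <- factor(long$symbol, levels = rev(sort(unique(long$symbol))))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$position, y = .data$symbol,
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(name = "grad × input") +
    ggplot2::labs(x = "2-mer position (left base)", y = "dinucleotide",
                  title = "Saliency map") +
    ggplot2::theme_minimal()
}

#' Render an attribution map as an image file
#'
#' Writes the heat map (position on the x-axis, substituted base or
#' dinucleotide on the y-axis) to a PNG/SVG/PDF file, chosen by the path's
#' extension.
#'
#' @param map A `fourmc_mutagenesis` or `fourmc_saliency`.
#' @param path Output image path.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(map, path, width = 8, height = 4) {
  if (is.null(map$values) || length(map$values) == 0L) {
    abort("map is empty; nothing to render")
  }
  ggplot2::ggsave(path, autoplot(map), width = width, height = height,
                  dpi = 150)
  invisible(path)
}
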