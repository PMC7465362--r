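## Six sequence-encoding schemes. Every encoder is a pure function from one
## window string to a positions x channels numeric matrix; encode_dataset()
## stacks them into an n x positions x channels array for the classifier.

ENCODING_SCHEMES <- c("BE", "DNC", "TNC", "NCP", "NCPNF", "MMI")

## Chemical-property coordinates (ring structure, hydrogen bond, functional
## group): purines A/G carry two rings (x = 1), A/T pair through weak
## hydrogen bonds (y = 1), amino bases A/C get z = 1; N is all-zero.
NCP_TABLE <- matrix(
  c(
    1, 1, 1,  # A
    0, 0, 1,  # C
    1, 0, 0,  # G
    0, 1, 0,  # T
    0, 0, 0   # N
  ),
  nrow = 5, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "T", "N"), c("x", "y", "z"))
)

#' Encoding-scheme output shapes
#'
#' Returns the (positions, channels) shape a scheme produces for windows of
#' length `L`. For L = 41: BE 41x5, DNC 40x25, TNC 39x125, NCP 41x3,
#' NCPNF 41x4 (41x5 with `ncpnf_pad5`), MMI 55x1.
#'
#' @param scheme One of `"BE"`, `"DNC"`, `"TNC"`, `"NCP"`, `"NCPNF"`, `"MMI"`.
#' @param L Window length. Default 41.
#' @param ncpnf_pad5 If `TRUE`, NCPNF reports 5 channels (an all-zero fifth
#'   channel is appended for strict shape parity with the 5-row description
#'   of this encoding; the fifth channel carries no information).
#' @return Integer vector `c(positions, channels)`.
#' @export
scheme_shape <- function(scheme, L = 41L, ncpnf_pad5 = FALSE) {
  scheme <- match_scheme(scheme)
  switch(scheme,
    BE = c(L, 5L),
    DNC = c(L - 1L, 25L),
    TNC = c(L - 2L, 125L),
    NCP = c(L, 3L),
    NCPNF = c(L, if (ncpnf_pad5) 5L else 4L),
    MMI = c(55L, 1L)
  )
}

match_scheme <- function(scheme) {
  scheme <- toupper(scheme)
  if (!scheme %in% ENCODING_SCHEMES) {
    abort(paste0(
      "unknown encoding scheme '", scheme, "'; choose one of ",
      paste(ENCODING_SCHEMES, collapse = ", ")
    ))
  }
  scheme
}

seq_to_chars <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (any(!chars %in% DNA_ALPHABET)) {
    abort("sequence contains symbols outside {A,C,G,T,N}")
  }
  chars
}

#' Per-base one-hot (binary) encoding
#'
#' Each base becomes a 5-bit indicator in channel order A, C, G, T, N:
#' A = (1,0,0,0,0), C = (0,1,0,0,0), G = (0,0,1,0,0), T = (0,0,0,1,0) and
#' N = (0,0,0,0,0) (the ambiguous base is the zero vector, so its row sum is
#' 0, not 1). A window of m bases yields 5 x m features.
#'
#' @param seq A DNA window string over A/C/G/T/N.
#' @return An L x 5 numeric matrix (rows = positions, columns = A,C,G,T,N).
#' @export
#' @examples
#' encode_binary("ACGTN")
encode_binary <- function(seq) {
  chars <- seq_to_chars(seq)
  m <- matrix(0, nrow = length(chars), ncol = 5L,
              dimnames = list(NULL, DNA_ALPHABET))
  hit <- chars != "N"
  m[cbind(which(hit), match(chars[hit], DNA_ALPHABET))] <- 1
  m
}

#' All k-mers over A,C,G,N,T in frozen channel order
#'
#' Lexicographic over the fixed symbol order A < C < G < N < T. The order is
#' arbitrary but frozen: trained models depend on it.
#'
#' @param k k-mer size.
#' @return Character vector of the 5^k k-mers.
#' @export
kmer_alphabet <- function(k) {
  g <- expand.grid(rep(list(DNA_ALPHABET_SORTED), k), stringsAsFactors = FALSE)
  # expand.grid varies its first column fastest; lexicographic order needs
  # the *last* character fastest, so paste the columns reversed.
  do.call(paste0, g[, rev(seq_len(k)), drop = FALSE])
}

#' Positional k-mer one-hot encoding (DNC / TNC)
#'
#' The L - k + 1 overlapping k-mers of the window are each one-hot encoded
#' over the 5^k k-mer alphabet ([kmer_alphabet()]). For 41-nt windows this
#' gives the di-nucleotide composition (DNC, k = 2) as 40 positions x 25
#' channels and the tri-nucleotide composition (TNC, k = 3) as 39 x 125.
#' The positional layout (rather than a global composition vector) is what
#' lets a 1-D convolution and the dinucleotide saliency analysis see *where*
#' each k-mer occurs.
#'
#' @inheritParams encode_binary
#' @param k k-mer size, 2 (DNC) or 3 (TNC).
#' @return An (L-k+1) x 5^k one-hot matrix.
#' @export
encode_kmer_onehot <- function(seq, k) {
  if (!k %in% c(2L, 3L)) {
    abort("`k` must be 2 (DNC) or 3 (TNC)")
  }
  chars <- seq_to_chars(seq)
  n_pos <- length(chars) - k + 1L
  if (n_pos < 1L) abort("sequence shorter than k")
  kmers <- vapply(seq_len(n_pos), function(i) {
    paste(chars[i:(i + k - 1L)], collapse = "")
  }, character(1))
  alphabet <- kmer_alphabet(k)
  m <- matrix(0, nrow = n_pos, ncol = length(alphabet),
              dimnames = list(NULL, alphabet))
  m[cbind(seq_len(n_pos), match(kmers, alphabet))] <- 1
  m
}

#' Nucleotide chemical property (NCP) encoding
#'
#' Three 0/1 coordinates per base for ring structure (purine vs pyrimidine),
#' hydrogen-bond strength and amino/keto functional group:
#' A = (1,1,1), C = (0,0,1), G = (1,0,0), T = (0,1,0), N = (0,0,0).
#'
#' @inheritParams encode_binary
#' @return An L x 3 numeric matrix with columns `x`, `y`, `z`.
#' @export
encode_ncp <- function(seq) {
  chars <- seq_to_chars(seq)
  m <- NCP_TABLE[match(chars, rownames(NCP_TABLE)), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' NCP plus cumulative nucleotide frequency (NCPNF) encoding
#'
#' Appends to the three NCP coordinates the cumulative nucleotide density:
#' for position i (1-based), d_i = (occurrences of the base at i among
#' positions 1..i) / i. d_1 is always 1 and d_i is in (0, 1].
#'
#' @inheritParams encode_binary
#' @param pad5 Append an all-zero fifth channel for strict 5-row shape
#'   parity. Default `FALSE` (4 informative channels).
#' @return An L x 4 (or L x 5) numeric matrix.
#' @export
encode_ncpnf <- function(seq, pad5 = FALSE) {
  chars <- seq_to_chars(seq)
  L <- length(chars)
  density <- vapply(seq_len(L), function(i) {
    sum(chars[seq_len(i)] == chars[i]) / i
  }, numeric(1))
  m <- cbind(encode_ncp(seq), d = density)
  rownames(m) <- NULL
  if (pad5) m <- cbind(m, pad = 0)
  m
}

## Unordered tuple sets for the MMI features. T2 is the 15 unordered pairs;
## T3 is the complete multiset of unordered triples over the 5-symbol
## alphabet (35 members), i.e. all non-decreasing triples in the order
## A, C, G, T, N.
mmi_tuple_sets <- function() {
  sym <- DNA_ALPHABET
  t2 <- list()
  for (i in 1:5) for (j in i:5) t2[[length(t2) + 1L]] <- c(sym[i], sym[j])
  t3 <- list()
  for (i in 1:5) for (j in i:5) for (k in j:5) {
    t3[[length(t3) + 1L]] <- c(sym[i], sym[j], sym[k])
  }
  list(T2 = t2, T3 = t3)
}

# Canonical key of an unordered tuple: symbols sorted into A,C,G,T,N order.
tuple_key <- function(tup) {
  paste(tup[order(match(tup, DNA_ALPHABET))], collapse = "")
}

# p * ln(num / den), defined as 0 whenever any frequency entering the
# logarithm is 0 (the zero-frequency convention for these features).
safe_plogr <- function(p, num, den) {
  if (p == 0 || num == 0 || den == 0) return(0)
  p * log(num / den)
}

#' Multivariate mutual information (MMI) features
#'
#' A 55-element feature vector: the 5 mononucleotide frequencies
#' f(a) = count(a)/L; 15 pairwise terms
#' I2(a,b) = f2(a,b) * ln(f2(a,b) / (f(a) f(b))) over the unordered pairs,
#' where f2 counts unordered adjacent pairs over the L-1 windows; and 35
#' triple terms
#' I3(a,b,c) = I2(a,b) - f3(a,b,c) * ln(f3(a,b,c) f(c) / (f2(a,c) f2(b,c)))
#' over the complete unordered triple set, where f3 counts unordered
#' adjacent triples over the L-2 windows. Any logarithmic term touching a
#' zero frequency is defined as 0.
#'
#' @inheritParams encode_binary
#' @return A 55 x 1 numeric matrix (single-channel feature vector), with
#'   feature names as row names.
#' @export
encode_mmi <- function(seq) {
  chars <- seq_to_chars(seq)
  L <- length(chars)
  if (L < 3L) abort("MMI needs at least 3 bases")
  tuples <- mmi_tuple_sets()

  f1 <- vapply(DNA_ALPHABET, function(a) sum(chars == a) / L, numeric(1))

  pair_keys <- vapply(seq_len(L - 1L), function(i) {
    tuple_key(chars[i:(i + 1L)])
  }, character(1))
  f2 <- function(a, b) sum(pair_keys == tuple_key(c(a, b))) / (L - 1L)

  triple_keys <- vapply(seq_len(L - 2L), function(i) {
    tuple_key(chars[i:(i + 2L)])
  }, character(1))
  f3 <- function(a, b, c) sum(triple_keys == tuple_key(c(a, b, c))) / (L - 2L)

  i2 <- function(a, b) safe_plogr(f2(a, b), f2(a, b), f1[a] * f1[b])

  v2 <- vapply(tuples$T2, function(t) i2(t[1], t[2]), numeric(1))
  v3 <- vapply(tuples$T3, function(t) {
    a <- t[1]; b <- t[2]; c <- t[3]
    i2(a, b) - safe_plogr(f3(a, b, c), f3(a, b, c) * f1[c],
                          f2(a, c) * f2(b, c))
  }, numeric(1))

  feats <- c(f1, v2, v3)
  names(feats) <- c(
    paste0("f_", DNA_ALPHABET),
    paste0("I2_", vapply(tuples$T2, paste, character(1), collapse = "")),
    paste0("I3_", vapply(tuples$T3, paste, character(1), collapse = ""))
  )
  matrix(feats, ncol = 1L, dimnames = list(names(feats), "mmi"))
}

#' Encode one window with a named scheme
#'
#' @inheritParams encode_binary
#' @param scheme One of `"BE"`, `"DNC"`, `"TNC"`, `"NCP"`, `"NCPNF"`, `"MMI"`.
#' @param ncpnf_pad5 See [encode_ncpnf()].
#' @return A positions x channels numeric matrix.
#' @export
encode_window <- function(seq, scheme, ncpnf_pad5 = FALSE) {
  scheme <- match_scheme(scheme)
  switch(scheme,
    BE = encode_binary(seq),
    DNC = encode_kmer_onehot(seq, 2L),
    TNC = encode_kmer_onehot(seq, 3L),
    NCP = encode_ncp(seq),
    NCPNF = encode_ncpnf(seq, pad5 = ncpnf_pad5),
    MMI = encode_mmi(seq)
  )
}

#' Encode a labelled dataset into a feature tensor
#'
#' Applies one encoding scheme to every record and stacks the per-window
#' matrices into an `n x positions x channels` array, with the label vector
#' aligned to the first dimension.
#'
#' @param data A data frame with columns `id`, `seq`, `label`; all sequences
#'   the same length.
#' @inheritParams encode_window
#' @return A list of class `fourmc_tensor`: `x` (3-d array), `y` (integer
#'   labels), `scheme`, `ids`.
#' @export
encode_dataset <- function(data, scheme, ncpnf_pad5 = FALSE) {
  data <- as_tibble(data)
  scheme <- match_scheme(scheme)
  if (nrow(data) == 0L) abort("cannot encode an empty dataset")
  lens <- unique(nchar(data$seq))
  if (length(lens) != 1L) {
    abort("all sequences must share one length; found lengths ",
          paste(lens, collapse = ", "))
  }
  shape <- scheme_shape(scheme, lens, ncpnf_pad5 = ncpnf_pad5)
  x <- array(0, dim = c(nrow(data), shape[1], shape[2]))
  for (i in seq_len(nrow(data))) {
    x[i, , ] <- encode_window(data$seq[i], scheme, ncpnf_pad5 = ncpnf_pad5)
  }
  structure(
    list(x = x, y = as.integer(data$label), scheme = scheme, ids = data$id),
    class = "fourmc_tensor"
  )
}

#' @export
print.fourmc_tensor <- function(x, ...) {
  d <- dim(x$x)
  cat("<fourmc_tensor> scheme=", x$scheme, " records=", d[1],
      " positions=", d[2], " channels=", d[3], "\n", sep = "")
  invisible(x)
}

#' Export an encoded tensor as flat CSV
#'
#' One row per record; columns named `<scheme>_p<position>_c<channel>`, plus
#' leading `id` and `label` columns.
#'
#' @param tensor A `fourmc_tensor` from [encode_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tensor_csv <- function(tensor, path) {
  d <- dim(tensor$x)
  flat <- matrix(aperm(tensor$x, c(1, 3, 2)), nrow = d[1])  # position-major
  cols <- as.vector(outer(
    seq_len(d[3]), seq_len(d[2]),
    function(ch, p) paste0(tensor$scheme, "_p", p, "_c", ch)
  ))
  df <- tibble(id = tensor$ids, label = tensor$y)
  df <- dplyr::bind_cols(df, as_tibble(flat, .name_repair = ~cols))
  readr::write_csv(df, path)
  invisible(path)
}

#' Save / load an encoded tensor as a binary array container
#'
#' Serializes the full `fourmc_tensor` (array, labels, scheme, ids) with R's
#' native serialization; [read_tensor_rds()] restores it exactly. Use the
#' CSV export ([write_tensor_csv()]) for interchange with other tools.
#'
#' @param tensor A `fourmc_tensor` from [encode_dataset()].
#' @param path Output path.
#' @return `path` (write) or the restored `fourmc_tensor` (read).
#' @export
write_tensor_rds <- function(tensor, path) {
  saveRDS(tensor, path)
  invisible(path)
}

#' @rdname write_tensor_rds
#' @export
read_tensor_rds <- function(path) {
  readRDS(path)
}
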