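#' Read a labelled FASTA file of methylation windows
#'
#' Reads one FASTA file whose records are fixed-length DNA windows (41 nt by
#' default, centred on the candidate cytosine) and assigns every record the
#' same binary label. Benchmarks of this kind are distributed as one file per
#' class, so labels travel outside the FASTA; combine the two classes with
#' [read_fasta_pair()].
#'
#' Sequences are uppercased on read. Multi-line (wrapped) sequence bodies are
#' accepted. Each record is validated: length must equal `length`, the
#' alphabet is restricted to A/C/G/T/N, and unless `require_central_c =
#' FALSE` the central base (0-based position `(length - 1) / 2`) must be a
#' cytosine.
#'
#' @param path Path to a FASTA file.
#' @param label Binary class label for every record in the file (1 = 4mC
#'   positive, 0 = negative).
#' @param length Required window length. Default 41.
#' @param require_central_c Enforce the central-cytosine invariant. Default
#'   `TRUE`.
#' @return A tibble with columns `id`, `seq`, `label`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">w1", strrep("A", 20), "C", strrep("A", 20)), tf)
#' # (wrapped body: 20 A's, the central C, 20 A's)
#' read_methyl_fasta(tf, label = 1)
read_methyl_fasta <- function(path, label, length = 41L, require_central_c = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  if (!label %in% c(0L, 1L)) {
    abort("`label` must be 0 or 1")
  }
  check_fasta_shape(path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("malformed FASTA in ", path, ": ", conditionMessage(e)))
    }
  )
  data <- tibble(
    id = names(set),
    seq = unname(toupper(as.character(set))),
    label = as.integer(label)
  )
  validate_windows(data, length = length, require_central_c = require_central_c)
}

# Cheap structural pre-check so a malformed file fails with the offending
# line number rather than a parser-internal message.
check_fasta_shape <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    abort(paste0("malformed FASTA in ", path, ": file is empty"))
  }
  if (!startsWith(lines[nonblank[1]], ">")) {
    abort(paste0(
      "malformed FASTA in ", path, ": line ", nonblank[1],
      " does not start with '>'"
    ))
  }
  invisible(TRUE)
}

#' Read a positive/negative FASTA pair into one labelled dataset
#'
#' @param positive,negative Paths to the 4mC (label 1) and non-4mC (label 0)
#'   FASTA files.
#' @inheritParams read_methyl_fasta
#' @return A tibble with columns `id`, `seq`, `label` (positives first).
#' @export
read_fasta_pair <- function(positive, negative, length = 41L,
                            require_central_c = TRUE) {
  dplyr::bind_rows(
    read_methyl_fasta(positive, 1L, length, require_central_c),
    read_methyl_fasta(negative, 0L, length, require_central_c)
  )
}

#' Validate a window dataset
#'
#' Checks the dataset invariants: required columns, a single shared window
#' length, the A/C/G/T/N alphabet, binary labels, and (optionally) a central
#' cytosine in every record. Errors name the first offending record.
#'
#' @param data A data frame with columns `id`, `seq`, `label`.
#' @inheritParams read_methyl_fasta
#' @return The validated data, invisibly returned as a tibble.
#' @export
validate_windows <- function(data, length = 41L, require_central_c = TRUE) {
  data <- as_tibble(data)
  missing <- setdiff(c("id", "seq", "label"), names(data))
  if (length(missing) > 0L) {
    abort(paste0("dataset is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(data$label %in% c(0L, 1L))) {
    bad <- data$id[which(!data$label %in% c(0L, 1L))[1]]
    abort(paste0("record '", bad, "': label must be 0 or 1"))
  }
  lens <- nchar(data$seq)
  if (any(lens != length)) {
    i <- which(lens != length)[1]
    abort(paste0(
      "record '", data$id[i], "': sequence length ", lens[i],
      " != required length ", length
    ))
  }
  bad_alpha <- grepl("[^ACGTN]", data$seq)
  if (any(bad_alpha)) {
    i <- which(bad_alpha)[1]
    abort(paste0(
      "record '", data$id[i],
      "': sequence contains symbols outside {A,C,G,T,N}"
    ))
  }
  if (require_central_c && nrow(data) > 0L) {
    center <- (length - 1L) %/% 2L + 1L  # 1-based index of 0-based (L-1)/2
    central <- substr(data$seq, center, center)
    if (any(central != "C")) {
      i <- which(central != "C")[1]
      abort(paste0(
        "record '", data$id[i], "': central base (position ",
        center - 1L, ", 0-based) is '", central[i], "', expected 'C'"
      ))
    }
  }
  invisible(data)
}

#' Write a window dataset as FASTA
#'
#' Writes single-line sequence bodies. Labels are not stored in FASTA; use
#' one file per class ([write_fasta_pair()]) or [write_windows_tsv()] to
#' keep them.
#'
#' @param data A data frame with columns `id`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methyl_fasta <- function(data, path) {
  set <- Biostrings::BStringSet(setNames(data$seq, data$id))
  Biostrings::writeXStringSet(set, path, width = 100000L)
  invisible(path)
}

#' Write a labelled dataset as a positive/negative FASTA pair
#'
#' @param data A data frame with columns `id`, `seq`, `label`.
#' @param positive,negative Output paths for label-1 and label-0 records.
#' @return A named character vector of the two paths, invisibly.
#' @export
write_fasta_pair <- function(data, positive, negative) {
  write_methyl_fasta(data[data$label == 1L, ], positive)
  write_methyl_fasta(data[data$label == 0L, ], negative)
  invisible(c(positive = positive, negative = negative))
}

#' Export a window dataset as TSV
#'
#' @param data A data frame with columns `id`, `seq`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_tsv <- function(data, path) {
  readr::write_tsv(as_tibble(data)[, c("id", "seq", "label")], path)
  invisible(path)
}

#' Stratified train/independent split
#'
#' Splits a labelled dataset into a training part and an independent
#' (held-out) part, stratified by label so both parts stay balanced up to
#' rounding. The split is deterministic for a fixed seed. The common
#' convention for these benchmarks is 75% training / 25% independent.
#'
#' @param data A data frame with columns `id`, `seq`, `label`.
#' @param train_fraction Fraction assigned to training, strictly in (0, 1).
#' @param seed Integer seed controlling the shuffle.
#' @return A list with tibbles `train` and `test`; disjoint, jointly covering
#'   the input.
#' @export
split_dataset <- function(data, train_fraction = 0.75, seed = 1L) {
  data <- as_tibble(data)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("`train_fraction` must be strictly between 0 and 1")
  }
  counts <- table(factor(data$label, levels = c(0L, 1L)))
  if (any(counts < 2L)) {
    abort("need at least 2 records per class to split")
  }
  local_rng(seed)
  # per-class quota: floors first, then the remainder of the overall target
  # round(n * fraction) goes to the classes with the largest fractional
  # parts, so the total is exact and both classes stay balanced +/- rounding
  n_class <- as.integer(counts)
  target_total <- round(sum(n_class) * train_fraction)
  exact <- n_class * train_fraction
  quota <- pmin(floor(exact), n_class - 1L)
  leftover <- target_total - sum(quota)
  if (leftover > 0) {
    order_rem <- order(exact - floor(exact), decreasing = TRUE)
    for (j in head(order_rem, leftover)) {
      quota[j] <- min(quota[j] + 1L, n_class[j] - 1L)
    }
  }
  quota <- pmax(quota, 1L)
  train_idx <- unlist(lapply(seq_along(c(0L, 1L)), function(ci) {
    idx <- which(data$label == c(0L, 1L)[ci])
    sample(idx, quota[ci])
  }), use.names = FALSE)
  list(
    train = data[sort(train_idx), ],
    test = data[setdiff(seq_len(nrow(data)), sort(train_idx)), ]
  )
}

#' Greedy sequence-identity redundancy filter
#'
#' A naive stand-in for clustering tools such as CD-HIT-EST: records are
#' scanned in input order and a record is dropped when its ungapped identity
#' (matching positions / window length) to any already-retained record is at
#' least `identity_threshold`. It does not replicate CD-HIT-EST's word
#' filtering or clustering and is provided as plumbing only.
#'
#' @param data A data frame with columns `id`, `seq`, `label`; all sequences
#'   the same length.
#' @param identity_threshold Identity cut-off in (0, 1].
#' @return The retained records, in input order.
#' @export
filter_redundant <- function(data, identity_threshold = 0.65) {
  data <- as_tibble(data)
  if (!(identity_threshold > 0 && identity_threshold <= 1)) {
    abort("`identity_threshold` must be in (0, 1]")
  }
  if (nrow(data) <= 1L) {
    return(data)
  }
  chars <- do.call(rbind, strsplit(data$seq, "", fixed = TRUE))
  L <- ncol(chars)
  keep <- integer(0)
  for (i in seq_len(nrow(data))) {
    redundant <- FALSE
    for (j in keep) {
      if (sum(chars[i, ] == chars[j, ]) / L >= identity_threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) keep <- c(keep, i)
  }
  data[keep, ]
}

#' Per-label record counts
#'
#' @param data A data frame with a `label` column.
#' @return A tibble with columns `label` and `n`.
#' @export
count_labels <- function(data) {
  dplyr::count(as_tibble(data), .data$label)
}

# Seed the RNG for the duration of the calling function only, restoring the
# caller's RNG state on exit.
local_rng <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  set.seed(as.integer(seed))
  invisible(seed)
}
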