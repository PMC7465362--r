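# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive re-derivation (explicit loops, direct
# arithmetic) kept separate from the package's implementation path.

# random valid window: uniform A/C/G/T/N background, central C
random_window <- function(L = 41L, n_rate = 0.05) {
  probs <- c(rep((1 - n_rate) / 4, 4), n_rate)
  chars <- sample(c("A", "C", "G", "T", "N"), L, replace = TRUE, prob = probs)
  chars[(L - 1L) %/% 2L + 1L] <- "C"
  paste(chars, collapse = "")
}

make_dataset <- function(n, L = 41L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    id = paste0("r", seq_len(n)),
    seq = vapply(seq_len(n), function(i) random_window(L), character(1)),
    label = rep_len(c(1L, 0L), n)
  )
}

# direct evaluation of the four metric formulas, plain arithmetic
metrics_direct <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den,
    acc = (tp + tn) / (tp + tn + fp + fn),
    sn = tp / (tp + fn),
    sp = tn / (tn + fp)
  )
}

# O(n^2) concordant-pair AUC: ties counted half
auc_pairwise <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# brute-force MMI features: explicit loops over windows, multiset
# comparison by sorted characters (independent of the package's keying)
mmi_brute <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  sym <- c("A", "C", "G", "T", "N")
  f1 <- vapply(sym, function(a) sum(ch == a) / L, numeric(1))
  f2 <- function(a, b) {
    n <- 0
    for (i in 1:(L - 1)) {
      if (identical(sort(ch[i:(i + 1)]), sort(c(a, b)))) n <- n + 1
    }
    n / (L - 1)
  }
  f3 <- function(a, b, c) {
    n <- 0
    for (i in 1:(L - 2)) {
      if (identical(sort(ch[i:(i + 2)]), sort(c(a, b, c)))) n <- n + 1
    }
    n / (L - 2)
  }
  zlog <- function(p, num, den) if (p == 0 || num == 0 || den == 0) 0 else p * log(num / den)
  i2 <- function(a, b) zlog(f2(a, b), f2(a, b), f1[a] * f1[b])
  out <- as.numeric(f1)
  for (i in 1:5) for (j in i:5) out <- c(out, i2(sym[i], sym[j]))
  for (i in 1:5) for (j in i:5) for (k in j:5) {
    a <- sym[i]; b <- sym[j]; c <- sym[k]
    out <- c(out, i2(a, b) - zlog(f3(a, b, c), f3(a, b, c) * f1[c],
                                  f2(a, c) * f2(b, c)))
  }
  unname(out)
}

# quick trained model on a small separable benchmark, shared by the
# interpretation tests (memoised per session)
small_trained_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- simulate_windows(sim_spec(n_per_class = 80, motif = "CCCC",
                                     p_positive = 1, q_negative = 0,
                                     seed = 401))
      m <- train_on_windows(
        d, "BE",
        config = train_config(epochs = 30L, patience = 30L, seed = 402)
      )
      attr(m, "data") <- d
      cache <<- m
    }
    cache
  }
})
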